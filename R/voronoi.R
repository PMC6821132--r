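#' Voronoi domain regularity of a planar cell mosaic
#'
#' Builds the Voronoi tessellation of a point mosaic inside a
#' rectangular window, discards every domain that touches the window
#' boundary (whose true extent is unknowable from the observed field),
#' and summarises the remaining interior domain areas by the regularity
#' index: mean area divided by the standard deviation of areas. Regular
#' (repulsion-driven) mosaics have large indices; a completely random
#' arrangement gives an index near 1.9, and a perfect lattice has zero
#' area variance and no finite index (flagged as degenerate).
#'
#' Each domain is computed by clipping the window against the
#' perpendicular-bisector half-planes of the site's neighbours, visiting
#' neighbours in order of distance and stopping once no farther site can
#' cut the cell (farther than twice the maximal site-to-vertex
#' distance). Areas use the shoelace formula.
#'
#' @param points A data frame with columns `x`, `y` (any planar units).
#' @param window Rectangle `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   bounding box of the points.
#' @param min_interior Minimum number of interior domains required to
#'   report an index (default 10).
#' @return An object of class `mosaic_analysis`: a list with the points,
#'   window, `interior_areas`, `n_points`, `n_interior`, `mean_area`,
#'   `sd_area`, `regularity_index` (`NA` when degenerate) and
#'   `degenerate` (TRUE when all interior areas are identical, as in a
#'   perfect lattice). Use [glance()][generics::glance] for a one-row
#'   summary.
#' @examples
#' pts <- generate_mosaic(200, exclusion_radius = 0.04,
#'                        window = c(0, 1, 0, 1), seed = 3)
#' generics::glance(voronoi_regularity(pts))
#' @export
voronoi_regularity <- function(points, window = NULL, min_interior = 10) {
  require_columns(points, c("x", "y"))
  x <- points$x
  y <- points$y
  n <- length(x)
  window <- window %||% attr(points, "window") %||%
    c(min(x), max(x), min(y), max(y))
  check_window(window)
  if (anyDuplicated(cbind(x, y))) {
    stop("Duplicate points are not allowed in a mosaic.", call. = FALSE)
  }
  areas <- numeric(n)
  boundary <- logical(n)
  tol <- 1e-9 * max(window[2] - window[1], window[4] - window[3])
  for (i in seq_len(n)) {
    cell <- voronoi_cell(i, x, y, window)
    areas[i] <- polygon_area(cell$x, cell$y)
    boundary[i] <- any(
      cell$x < window[1] + tol | cell$x > window[2] - tol |
        cell$y < window[3] + tol | cell$y > window[4] - tol
    )
  }
  interior <- areas[!boundary]
  if (length(interior) < min_interior) {
    stop("Only ", length(interior), " interior Voronoi domains ",
         "(minimum ", min_interior, "); the field is too sparse or too ",
         "boundary-dominated to report a regularity index.", call. = FALSE)
  }
  m <- mean(interior)
  s <- stats::sd(interior)
  degenerate <- s <= 1e-12 * m
  structure(
    list(
      points = tibble::tibble(x = x, y = y),
      window = window,
      interior_areas = interior,
      n_points = n,
      n_interior = length(interior),
      mean_area = m,
      sd_area = s,
      regularity_index = if (degenerate) NA_real_ else m / s,
      degenerate = degenerate
    ),
    class = "mosaic_analysis"
  )
}

# Voronoi cell of site i: window rectangle clipped by the bisector
# half-plane of every neighbour that can reach the cell
voronoi_cell <- function(i, x, y, window) {
  px <- c(window[1], window[2], window[2], window[1])
  py <- c(window[3], window[3], window[4], window[4])
  xi <- x[i]
  yi <- y[i]
  d2 <- (x - xi)^2 + (y - yi)^2
  ord <- order(d2)
  ord <- ord[ord != i]
  rmax2 <- max((px - xi)^2 + (py - yi)^2)
  for (j in ord) {
    if (d2[j] > 4 * rmax2) break
    # keep the side closer to site i than to site j
    a <- 2 * (x[j] - xi)
    b <- 2 * (y[j] - yi)
    cc <- x[j]^2 + y[j]^2 - xi^2 - yi^2
    clipped <- clip_halfplane(px, py, a, b, cc)
    px <- clipped$x
    py <- clipped$y
    if (length(px) == 0) break
    rmax2 <- max((px - xi)^2 + (py - yi)^2)
  }
  list(x = px, y = py)
}

# Sutherland-Hodgman clip of polygon (px, py) by half-plane a*x+b*y <= c
clip_halfplane <- function(px, py, a, b, c) {
  n <- length(px)
  if (n == 0) return(list(x = numeric(), y = numeric()))
  s <- a * px + b * py - c
  inside <- s <= 0
  outx <- numeric(2 * n)
  outy <- numeric(2 * n)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      k <- k + 1L
      outx[k] <- px[i]
      outy[k] <- py[i]
    }
    if (inside[i] != inside[j]) {
      t <- s[i] / (s[i] - s[j])
      k <- k + 1L
      outx[k] <- px[i] + t * (px[j] - px[i])
      outy[k] <- py[i] + t * (py[j] - py[i])
    }
  }
  list(x = outx[seq_len(k)], y = outy[seq_len(k)])
}

polygon_area <- function(px, py) {
  n <- length(px)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(px * py[j] - px[j] * py)) / 2
}
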