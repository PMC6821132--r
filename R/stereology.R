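#' Regional area weights for whole-retina estimation
#'
#' Fractions of total retinal area covered by the central, middle and
#' peripheral sampling annuli. The defaults are the standard weights for
#' mouse retinal whole-mounts (central 11%, middle 33%, peripheral 56%).
#'
#' @param central,middle,peripheral Area fractions in `[0, 1]`, summing
#'   to 1 (within 1e-9).
#' @return A named numeric vector of class `region_weights`.
#' @export
region_weights <- function(central = 0.11, middle = 0.33,
                           peripheral = 0.56) {
  w <- c(central = central, middle = middle, peripheral = peripheral)
  if (any(w < 0 | w > 1)) {
    stop("Weights must lie in [0, 1].", call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-9) {
    stop("Region weights must sum to 1 (got ", sum(w), ").", call. = FALSE)
  }
  structure(w, class = c("region_weights", "numeric"))
}

#' Area-weighted mean density across retinal regions
#'
#' Averages field-of-view densities within each region, then combines
#' the three regional means with the regional area weights:
#' `sum_r w_r * mean(density_r)`.
#'
#' @param samples A data frame with columns `region` (values `central`,
#'   `middle`, `peripheral`) and `density` (cells/mm^2, >= 0), one row
#'   per field of view. All three regions must be present.
#' @param weights A [region_weights()] vector.
#' @return Weighted mean density (cells/mm^2).
#' @examples
#' fov <- tibble::tibble(
#'   region = rep(c("central", "middle", "peripheral"), each = 3),
#'   density = c(1010, 990, 1000, 805, 795, 800, 505, 495, 500)
#' )
#' weighted_mean_density(fov, region_weights())
#' @export
weighted_mean_density <- function(samples, weights = region_weights()) {
  require_columns(samples, c("region", "density"))
  if (!inherits(weights, "region_weights")) {
    weights <- do.call(region_weights, as.list(weights))
  }
  if (any(samples$density < 0)) {
    stop("Densities must be non-negative.", call. = FALSE)
  }
  regions <- c("central", "middle", "peripheral")
  missing <- setdiff(regions, unique(samples$region))
  if (length(missing)) {
    stop("Missing region(s): ", paste(missing, collapse = ", "),
         ". All three regions are required.", call. = FALSE)
  }
  means <- samples |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(mean_density = mean(.data$density), .groups = "drop")
  sum(unclass(weights)[regions] *
        means$mean_density[match(regions, means$region)])
}

#' Total cell number from a mean density and tissue area
#'
#' @param density Mean density in cells/mm^2 (>= 0).
#' @param area Tissue area in mm^2 (> 0).
#' @return Estimated total cell count.
#' @export
total_count <- function(density, area) {
  if (any(density < 0)) stop("`density` must be non-negative.", call. = FALSE)
  if (any(area <= 0)) stop("`area` must be positive.", call. = FALSE)
  density * area
}

#' Sample square fields of view from a retinal point pattern
#'
#' Places `n_fov_per_region` non-overlapping square fields at each of
#' three eccentricities — 0.15R (central, just outside the optic nerve
#' head where vessels first bifurcate), 0.5R (middle, the midpoint of
#' the centre-to-edge line) and 0.9R (peripheral, a few cell bodies from
#' the rim) — at randomised angular positions, and counts the points in
#' each.
#'
#' @param pattern A `retina_pattern` (see [generate_retina()]) or any
#'   data frame with columns `x`, `y` and a `radius` attribute.
#' @param fov_side Side length of the square field (mm).
#' @param n_fov_per_region Fields per region (>= 1; default 3).
#' @param seed Integer seed for the angular positions.
#' @param eccentricities Radial field centres as fractions of the disc
#'   radius, named `central`, `middle`, `peripheral`.
#' @return A tibble with columns `region`, `fov_id`, `count` and
#'   `density` (cells/mm^2).
#' @export
sample_fields <- function(pattern, fov_side, n_fov_per_region = 3,
                          seed = 1L,
                          eccentricities = c(central = 0.15, middle = 0.5,
                                             peripheral = 0.9)) {
  require_columns(pattern, c("x", "y"))
  radius <- attr(pattern, "radius")
  if (is.null(radius)) {
    stop("`pattern` must carry a `radius` attribute (mm).", call. = FALSE)
  }
  if (n_fov_per_region < 1 || n_fov_per_region != round(n_fov_per_region)) {
    stop("`n_fov_per_region` must be a positive integer.", call. = FALSE)
  }
  half_diag <- fov_side * sqrt(2) / 2
  too_far <- eccentricities * radius + half_diag > radius
  if (any(too_far)) {
    stop("Field of view protrudes outside the disc at eccentricity ",
         paste(names(eccentricities)[too_far], collapse = ", "),
         "; reduce `fov_side`.", call. = FALSE)
  }
  local_rng(seed)
  purrr::map_dfr(names(eccentricities), function(reg) {
    ecc_r <- eccentricities[[reg]] * radius
    centres <- place_fov_centres(ecc_r, n_fov_per_region, fov_side)
    purrr::map_dfr(seq_len(n_fov_per_region), function(i) {
      cx <- centres$x[i]
      cy <- centres$y[i]
      inside <- abs(pattern$x - cx) <= fov_side / 2 &
        abs(pattern$y - cy) <= fov_side / 2
      tibble::tibble(
        region = reg,
        fov_id = i,
        count = sum(inside),
        density = sum(inside) / fov_side^2
      )
    })
  })
}

# non-overlapping square fields on a circle of radius ecc_r
place_fov_centres <- function(ecc_r, n, fov_side) {
  min_sep <- fov_side * sqrt(2) # centre distance guaranteeing disjoint squares
  for (attempt in 1:200) {
    th <- stats::runif(n, 0, 2 * pi)
    xs <- ecc_r * cos(th)
    ys <- ecc_r * sin(th)
    if (n == 1) return(tibble::tibble(x = xs, y = ys))
    dmat <- as.matrix(stats::dist(cbind(xs, ys)))
    if (min(dmat[upper.tri(dmat)]) >= min_sep) {
      return(tibble::tibble(x = xs, y = ys))
    }
  }
  stop("Could not place ", n, " non-overlapping fields at eccentricity ",
       "radius ", signif(ecc_r, 3), "; reduce `fov_side` or the field ",
       "count.", call. = FALSE)
}

#' One-call whole-retina total from a point pattern
#'
#' Convenience pipeline: [sample_fields()] then [weighted_mean_density()]
#' then [total_count()] with the pattern's own disc area.
#'
#' @inheritParams sample_fields
#' @param weights A [region_weights()] vector.
#' @return A one-row tibble with `weighted_density`, `area` and
#'   `total_estimate`.
#' @export
estimate_total <- function(pattern, fov_side, n_fov_per_region = 3,
                           seed = 1L, weights = region_weights()) {
  fov <- sample_fields(pattern, fov_side, n_fov_per_region, seed)
  dens <- weighted_mean_density(fov, weights)
  area <- attr(pattern, "total_area")
  tibble::tibble(
    weighted_density = dens,
    area = area,
    total_estimate = total_count(dens, area)
  )
}
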