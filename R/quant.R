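#' Classify microglial envelopment of a cell soma
#'
#' Maps the fraction of a soma's circumference covered by phagocyte
#' processes to the standard interaction categories: untouched somata
#' are `none`; any contact short of half the circumference is `touched`;
#' at least 50% coverage is `partially_enveloped`; complete coverage is
#' `fully_enveloped`. A small tolerance `epsilon` absorbs rasterised
#' contact measurement, so coverage of at least `1 - epsilon` counts as
#' full envelopment.
#'
#' @param fraction Numeric vector of circumference-coverage fractions in
#'   `[0, 1]`.
#' @param epsilon Full-envelopment tolerance (default 0.005 of the
#'   circumference).
#' @return A factor with ordered levels `none`, `touched`,
#'   `partially_enveloped`, `fully_enveloped`; same length as
#'   `fraction`.
#' @examples
#' classify_engulfment(c(0, 0.2, 0.5, 0.997, 1))
#' @export
classify_engulfment <- function(fraction, epsilon = 0.005) {
  if (!is.numeric(fraction)) {
    stop("`fraction` must be numeric.", call. = FALSE)
  }
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE)) {
    stop("Coverage fractions must lie in [0, 1].", call. = FALSE)
  }
  lv <- c("none", "touched", "partially_enveloped", "fully_enveloped")
  lab <- dplyr::case_when(
    fraction == 0 ~ "none",
    fraction < 0.5 ~ "touched",
    fraction < 1 - epsilon ~ "partially_enveloped",
    TRUE ~ "fully_enveloped"
  )
  factor(lab, levels = lv, ordered = TRUE)
}

#' Classify a table of soma contact fractions
#'
#' Data-frame-first wrapper around [classify_engulfment()]; adds a
#' `label` column.
#'
#' @param data A data frame with a numeric `fraction` column (and
#'   typically a `soma_id`).
#' @param epsilon Full-envelopment tolerance passed on.
#' @return The input as a tibble with `label` appended.
#' @export
classify_contacts <- function(data, epsilon = 0.005) {
  require_columns(data, "fraction")
  dplyr::mutate(
    tibble::as_tibble(data),
    label = classify_engulfment(.data$fraction, epsilon = epsilon)
  )
}

#' Lysosome index: marker pixels per phagocyte
#'
#' The lysosomal marker content of a field normalised to the number of
#' phagocytes in it, a per-cell proxy for phagocytic capacity.
#'
#' @param marker_pixels Count of marker-positive pixels (>= 0).
#' @param n_cells Number of phagocytes in the field (>= 1; fields with
#'   no scored cells carry no index and are discarded upstream).
#' @return Pixels per cell.
#' @export
lysosome_index <- function(marker_pixels, n_cells) {
  if (any(marker_pixels < 0)) {
    stop("`marker_pixels` must be non-negative.", call. = FALSE)
  }
  if (any(n_cells < 1)) {
    stop("Lysosome index is undefined for fields with no cells.",
         call. = FALSE)
  }
  marker_pixels / n_cells
}

#' Rescale a series to a 0-100 scale by its maximum
#'
#' Divides every value by the series maximum and multiplies by 100, so
#' the maximum maps to exactly 100. Used to put per-cell marker indices
#' and total cell counts on a common axis for cross-developmental
#' comparison.
#'
#' @param values Non-empty numeric vector with a positive maximum.
#' @return `values * 100 / max(values)`.
#' @export
normalize_series <- function(values) {
  if (!is.numeric(values) || length(values) == 0) {
    stop("`values` must be a non-empty numeric vector.", call. = FALSE)
  }
  m <- max(values)
  if (m <= 0) {
    stop("Cannot normalise a series whose maximum is not positive.",
         call. = FALSE)
  }
  values * 100 / m
}

#' Percent of a field covered by a binary mask
#'
#' The fraction of pixels that are marker-positive, as a percentage.
#' Equivalently 100 minus the percentage of negative space.
#'
#' @param mask A non-empty logical (or 0/1) matrix.
#' @return Coverage percent in `[0, 100]`.
#' @export
network_coverage <- function(mask) {
  mask <- check_mask(mask)
  100 * sum(mask) / length(mask)
}

#' Automatic histogram thresholding (Li or triangle)
#'
#' Segments a grayscale image into foreground and background with one of
#' two published histogram-threshold algorithms. `"li"` iterates the
#' minimum-cross-entropy update (the next threshold is the logarithmic
#' mean of the two class means) to a fixed point. `"triangle"` draws a
#' line from the histogram peak to the far end of the longer tail and
#' thresholds at the bin farthest from that line. Both assume a dark
#' background with brighter foreground structures.
#'
#' @param image A numeric matrix of intensities with at least two
#'   distinct values.
#' @param method `"li"` or `"triangle"`.
#' @param n_bins Histogram bins for the triangle method (default 256).
#' @return A logical mask (`image > threshold`) with the threshold
#'   attached as attribute `threshold`.
#' @export
auto_threshold <- function(image, method = c("li", "triangle"),
                           n_bins = 256) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix.", call. = FALSE)
  }
  rng <- range(image)
  if (diff(rng) == 0) {
    stop("Threshold undefined: the image is constant.", call. = FALSE)
  }
  t_val <- switch(method,
    li = threshold_li(image),
    triangle = threshold_triangle(image, n_bins)
  )
  structure(image > t_val, threshold = t_val)
}

threshold_li <- function(image, tol = NULL, max_iter = 200) {
  rng <- range(image)
  eps <- 1e-6 * diff(rng)
  work <- as.numeric(image) - rng[1] + eps # log needs positive values
  tol <- tol %||% (diff(rng) * 1e-6)
  t_cur <- mean(work)
  for (i in seq_len(max_iter)) {
    back <- work[work <= t_cur]
    fore <- work[work > t_cur]
    if (!length(back) || !length(fore)) break
    mb <- mean(back)
    mf <- mean(fore)
    t_new <- (mf - mb) / (log(mf) - log(mb))
    if (abs(t_new - t_cur) < tol) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  t_cur + rng[1] - eps
}

threshold_triangle <- function(image, n_bins = 256) {
  rng <- range(image)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(as.numeric(image), breaks = breaks,
                      plot = FALSE)$counts
  peak <- which.max(h)
  nz <- which(h > 0)
  first <- nz[1]
  last <- nz[length(nz)]
  # walk down the longer tail
  if ((last - peak) >= (peak - first)) {
    idx <- peak:last
  } else {
    idx <- peak:first
  }
  x1 <- idx[1]
  y1 <- h[peak]
  x2 <- idx[length(idx)]
  y2 <- h[x2]
  dx <- x2 - x1
  dy <- y2 - y1
  norm <- sqrt(dx^2 + dy^2)
  d <- abs(dy * (idx - x1) - dx * (h[idx] - y1)) / norm
  t_bin <- idx[which.max(d)]
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  mids[t_bin]
}

#' Assign debris puncta to cell classes by enclosure
#'
#' A punctum counts as engulfed by a class only if its entire footprint
#' lies inside that class's mask (enclosed on all sides); puncta that
#' straddle a mask boundary or sit in background are `unassigned`. A
#' permissive centroid rule (punctum assigned to the class under its
#' centre) is available as an alternative.
#'
#' @param debris A data frame with columns `x`, `y` (0-based pixel-centre
#'   coordinates: x along columns, y along rows) and `radius` (pixels);
#'   one row per punctum.
#' @param class_masks Named list of logical matrices of identical shape,
#'   e.g. `list(microglia = ..., astrocyte = ...)`. Masks must be
#'   disjoint.
#' @param method `"enclosure"` (default) or `"centroid"`.
#' @return A tibble with one row per class plus `unassigned`: columns
#'   `class`, `n` and `fraction` (fractions sum to 1).
#' @export
debris_localization <- function(debris, class_masks,
                                method = c("enclosure", "centroid")) {
  method <- match.arg(method)
  require_columns(debris, c("x", "y", "radius"))
  if (nrow(debris) == 0) {
    stop("No debris puncta to localise.", call. = FALSE)
  }
  if (!is.list(class_masks) || is.null(names(class_masks)) ||
      any(!nzchar(names(class_masks)))) {
    stop("`class_masks` must be a named list of masks.", call. = FALSE)
  }
  class_masks <- lapply(class_masks, check_mask)
  dims <- lapply(class_masks, dim)
  if (length(unique(dims)) != 1) {
    stop("All class masks must share the same shape.", call. = FALSE)
  }
  overlap <- Reduce(`+`, class_masks)
  if (any(overlap > 1)) {
    stop("Class masks overlap; classes must be disjoint.", call. = FALSE)
  }
  nr <- dims[[1]][1]
  nc <- dims[[1]][2]
  assign_one <- function(x, y, radius) {
    hits <- vapply(class_masks, function(m) {
      if (method == "centroid") {
        i <- round(y) + 1
        j <- round(x) + 1
        i >= 1 && i <= nr && j >= 1 && j <= nc && m[i, j]
      } else {
        fp <- disk_mask(nr, nc, x, y, radius)
        if (!any(fp)) return(FALSE)
        all(m[fp])
      }
    }, logical(1))
    if (sum(hits) > 1) {
      stop("Punctum fully enclosed by two disjoint classes; inconsistent ",
           "masks.", call. = FALSE)
    }
    if (any(hits)) names(class_masks)[hits] else "unassigned"
  }
  assigned <- purrr::pmap_chr(
    debris[, c("x", "y", "radius")],
    function(x, y, radius) assign_one(x, y, radius)
  )
  counts <- table(factor(assigned,
                         levels = c(names(class_masks), "unassigned")))
  tibble::tibble(
    class = names(counts),
    n = as.integer(counts),
    fraction = as.numeric(counts) / nrow(debris)
  )
}

#' Normalise a measurement to its within-litter control mean
#'
#' Divides each value by the mean of the control group within its litter
#' (block), removing litter-to-litter variability before group
#' comparisons.
#'
#' @param data A data frame.
#' @param value Column of measurements (tidy-eval).
#' @param litter Column identifying the litter/block (tidy-eval).
#' @param group Column identifying the experimental group (tidy-eval).
#' @param control Value of `group` that defines the control (default
#'   `"control"`).
#' @return The input as a tibble with a `normalized` column appended
#'   (control mean maps to 1 within each litter).
#' @export
normalize_by_litter <- function(data, value, litter, group,
                                control = "control") {
  value <- rlang::enquo(value)
  litter <- rlang::enquo(litter)
  group <- rlang::enquo(group)
  out <- data |>
    tibble::as_tibble() |>
    dplyr::group_by(!!litter) |>
    dplyr::mutate(
      .ctrl_mean = mean((!!value)[(!!group) == control]),
      normalized = (!!value) / .data$.ctrl_mean
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".ctrl_mean")
  if (anyNA(out$normalized)) {
    stop("Some litters have no '", control, "' samples to normalise ",
         "against.", call. = FALSE)
  }
  out
}

check_mask <- function(mask) {
  if (is.logical(mask) && is.matrix(mask)) {
    if (length(mask) == 0) stop("Mask region is empty.", call. = FALSE)
    return(mask)
  }
  if (is.numeric(mask) && is.matrix(mask) && all(mask %in% c(0, 1))) {
    if (length(mask) == 0) stop("Mask region is empty.", call. = FALSE)
    return(mask == 1)
  }
  stop("Masks must be logical (or 0/1) matrices.", call. = FALSE)
}
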