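#' Generate a whole-retina point pattern with an eccentricity gradient
#'
#' Samples an inhomogeneous Poisson point pattern on a disc whose
#' intensity interpolates linearly in eccentricity between a central and
#' an edge density, emulating the centre-dense arrangement of astrocytes
#' in a flat-mounted retina (origin at the optic-nerve-head position).
#' Sampling is by thinning a homogeneous pattern at the maximum
#' intensity, so the realised pattern is an exact draw from the target
#' process.
#'
#' @param density_center Intensity at the disc centre (cells/mm^2, >= 0).
#' @param density_edge Intensity at the disc rim (cells/mm^2, >= 0).
#' @param radius Disc radius in mm (> 0).
#' @param seed Integer seed.
#' @return A tibble of class `retina_pattern` with columns `x`, `y` (mm)
#'   and attributes `radius`, `total_area` (mm^2) and `true_count` (the
#'   realised number of points).
#' @examples
#' ret <- generate_retina(800, 300, radius = 2, seed = 7)
#' attr(ret, "true_count")
#' @export
generate_retina <- function(density_center, density_edge, radius, seed = 1L) {
  if (density_center < 0 || density_edge < 0) {
    stop("Densities must be non-negative.", call. = FALSE)
  }
  if (radius <= 0) stop("`radius` must be positive.", call. = FALSE)
  local_rng(seed)
  lambda_max <- max(density_center, density_edge)
  n_cand <- stats::rpois(1, lambda_max * pi * radius^2)
  # uniform points on the disc
  r <- radius * sqrt(stats::runif(n_cand))
  th <- stats::runif(n_cand, 0, 2 * pi)
  if (lambda_max > 0) {
    lambda <- density_center + (density_edge - density_center) * (r / radius)
    keep <- stats::runif(n_cand) < lambda / lambda_max
  } else {
    keep <- logical(n_cand)
  }
  out <- tibble::tibble(x = (r * cos(th))[keep], y = (r * sin(th))[keep])
  structure(
    out,
    class = c("retina_pattern", class(out)),
    radius = radius,
    total_area = pi * radius^2,
    true_count = nrow(out)
  )
}

#' Generate a repulsive (hard-core) or random planar mosaic
#'
#' Dart-throwing hard-core process on a rectangular window: candidate
#' points are drawn uniformly and rejected if they fall within
#' `exclusion_radius` of an already-accepted point, emulating the local
#' cell-cell repulsion that produces regular cellular mosaics. With
#' `exclusion_radius = 0` the result is a binomial (completely spatially
#' random) pattern.
#'
#' @param n_points Number of points to place (>= 1).
#' @param exclusion_radius Minimum allowed pairwise distance (>= 0), in
#'   the same units as the window.
#' @param window Rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param seed Integer seed.
#' @param max_attempts Candidate draws allowed before declaring the
#'   packing infeasible (default `1000 * n_points`).
#' @return A tibble with columns `x`, `y` and attributes `window` and
#'   `exclusion_radius`.
#' @export
generate_mosaic <- function(n_points, exclusion_radius,
                            window = c(0, 1, 0, 1), seed = 1L,
                            max_attempts = 1000 * n_points) {
  if (n_points < 1 || n_points != round(n_points)) {
    stop("`n_points` must be a positive integer.", call. = FALSE)
  }
  if (exclusion_radius < 0) {
    stop("`exclusion_radius` must be non-negative.", call. = FALSE)
  }
  check_window(window)
  local_rng(seed)
  xs <- numeric(n_points)
  ys <- numeric(n_points)
  accepted <- 0L
  attempts <- 0L
  r2 <- exclusion_radius^2
  while (accepted < n_points) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("Packing infeasible: could not place ", n_points, " points with ",
           "exclusion radius ", exclusion_radius, " in ", max_attempts,
           " attempts.", call. = FALSE)
    }
    cx <- stats::runif(1, window[1], window[2])
    cy <- stats::runif(1, window[3], window[4])
    if (accepted == 0L || r2 == 0 ||
        min((xs[seq_len(accepted)] - cx)^2 +
            (ys[seq_len(accepted)] - cy)^2) >= r2) {
      accepted <- accepted + 1L
      xs[accepted] <- cx
      ys[accepted] <- cy
    }
  }
  structure(
    tibble::tibble(x = xs, y = ys),
    window = window,
    exclusion_radius = exclusion_radius
  )
}

#' Generate a label-mask scene with exact ground truth
#'
#' Rasterises a synthetic field of view: disjoint microglial and
#' astrocytic somata (disks), a marker mask (lysosome-like puncta placed
#' inside microglia, or a line-segment arbor network), debris puncta
#' placed wholly inside a chosen class (or in background), and
#' per-soma circumference contact fractions with engulfment labels. All
#' ground truths (pixel counts, class memberships, labels) are recorded
#' exactly by construction, so downstream quantification can be checked
#' against them.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param n_microglia,n_astrocytes Numbers of somata per class.
#' @param soma_radius Soma disk radius in pixels.
#' @param marker Either `"puncta"` (disks inside microglia) or `"arbor"`
#'   (random thick line segments across the field).
#' @param marker_target_coverage Approximate percent of the field the
#'   marker mask should cover (>= 0; the recorded truth is the exact
#'   realised coverage).
#' @param n_debris Number of debris puncta.
#' @param debris_class_probs Named placement probabilities over
#'   `c("microglia", "astrocyte", "other")`; must sum to 1. Default
#'   emulates a wild-type field where nearly all debris sits inside
#'   microglia.
#' @param debris_radius Debris punctum radius in pixels (smaller than
#'   `soma_radius`).
#' @param n_contacts Number of astrocyte somata scored for microglial
#'   envelopment; contact fractions are drawn per label category.
#' @param seed Integer seed.
#' @return A list of class `quant_scene`: `image_shape`, `class_masks`
#'   (logical matrices `microglia`, `astrocyte`), `marker_mask`,
#'   `debris` (tibble `id, x, y, radius, true_class`), `soma_contacts`
#'   (tibble `soma_id, fraction, true_label`), and `truths` (list with
#'   `coverage_percent`, `marker_pixels`, `n_microglia`,
#'   `lysosome_index`, `debris_fractions`).
#' @export
generate_quant_scene <- function(image_shape = c(256, 256),
                                 n_microglia = 5,
                                 n_astrocytes = 8,
                                 soma_radius = 7,
                                 marker = c("puncta", "arbor"),
                                 marker_target_coverage = 1,
                                 n_debris = 40,
                                 debris_class_probs = c(microglia = 0.93,
                                                        astrocyte = 0.05,
                                                        other = 0.02),
                                 debris_radius = 1.5,
                                 n_contacts = 20,
                                 seed = 1L) {
  marker <- match.arg(marker)
  if (marker_target_coverage < 0 || marker_target_coverage > 100) {
    stop("`marker_target_coverage` must lie in [0, 100].", call. = FALSE)
  }
  probs <- debris_class_probs[c("microglia", "astrocyte", "other")]
  if (anyNA(probs) || abs(sum(probs) - 1) > 1e-9) {
    stop("`debris_class_probs` must be named microglia/astrocyte/other ",
         "and sum to 1.", call. = FALSE)
  }
  if (debris_radius >= soma_radius) {
    stop("`debris_radius` must be smaller than `soma_radius` so puncta ",
         "can be fully enclosed.", call. = FALSE)
  }
  local_rng(seed)
  nr <- image_shape[1]
  nc <- image_shape[2]

  # disjoint somata via dart throwing on centres
  n_somata <- n_microglia + n_astrocytes
  centres <- place_disjoint_disks(n_somata, nr, nc, soma_radius)
  cls <- rep(c("microglia", "astrocyte"), c(n_microglia, n_astrocytes))
  mask_m <- matrix(FALSE, nr, nc)
  mask_a <- matrix(FALSE, nr, nc)
  for (i in seq_len(n_somata)) {
    d <- disk_mask(nr, nc, centres$x[i], centres$y[i], soma_radius)
    if (cls[i] == "microglia") mask_m <- mask_m | d else mask_a <- mask_a | d
  }
  if (any(mask_m & mask_a)) {
    stop("Scene generation error: class masks overlap.", call. = FALSE)
  }

  # marker mask
  marker_mask <- matrix(FALSE, nr, nc)
  target_px <- marker_target_coverage / 100 * nr * nc
  if (target_px > 0) {
    if (marker == "puncta") {
      mg_centres <- centres[cls == "microglia", , drop = FALSE]
      if (nrow(mg_centres) == 0) {
        stop("Puncta marker requested but no microglia in scene.",
             call. = FALSE)
      }
      stall <- 0L
      while (sum(marker_mask) < target_px && stall < 200L) {
        before <- sum(marker_mask)
        j <- sample.int(nrow(mg_centres), 1)
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0, soma_radius - debris_radius)
        marker_mask <- marker_mask | disk_mask(
          nr, nc,
          mg_centres$x[j] + rad * cos(ang),
          mg_centres$y[j] + rad * sin(ang),
          debris_radius
        )
        # puncta live inside microglia, whose area bounds the achievable
        # coverage; stop once additions stall
        stall <- if (sum(marker_mask) == before) stall + 1L else 0L
      }
    } else {
      guard <- 0L
      while (sum(marker_mask) < target_px && guard < 2000L) {
        guard <- guard + 1L
        marker_mask <- marker_mask | segment_mask(
          nr, nc,
          stats::runif(1, 0, nc - 1), stats::runif(1, 0, nr - 1),
          stats::runif(1, 0, nc - 1), stats::runif(1, 0, nr - 1),
          half_width = 1.2
        )
      }
    }
  }

  # debris puncta: fully enclosed in a soma of the target class, or in
  # background for "other"
  true_class <- if (n_debris > 0) {
    sample(names(probs), n_debris, replace = TRUE, prob = probs)
  } else {
    character()
  }
  debris <- purrr::map_dfr(seq_len(n_debris), function(i) {
    klass <- true_class[i]
    if (klass %in% c("microglia", "astrocyte")) {
      pool <- centres[cls == klass, , drop = FALSE]
      j <- sample.int(nrow(pool), 1)
      ang <- stats::runif(1, 0, 2 * pi)
      # keep the whole footprint one pixel clear of the soma rim so
      # rasterised enclosure is exact
      rad <- stats::runif(1, 0, max(soma_radius - debris_radius - 1.5, 0))
      tibble::tibble(
        id = i,
        x = pool$x[j] + rad * cos(ang),
        y = pool$y[j] + rad * sin(ang),
        radius = debris_radius,
        true_class = klass
      )
    } else {
      repeat {
        x <- stats::runif(1, debris_radius + 1, nc - debris_radius - 2)
        y <- stats::runif(1, debris_radius + 1, nr - debris_radius - 2)
        fp <- disk_mask(nr, nc, x, y, debris_radius + 1)
        if (!any(fp & (mask_m | mask_a))) break
      }
      tibble::tibble(id = i, x = x, y = y, radius = debris_radius,
                     true_class = "other")
    }
  })

  # soma contact fractions: draw a label, then a fraction inside the
  # label's range so truth labels are independent of the classifier
  labels <- sample(c("none", "touched", "partially_enveloped",
                     "fully_enveloped"), n_contacts, replace = TRUE)
  fraction <- vapply(labels, function(l) {
    switch(l,
      none = 0,
      touched = stats::runif(1, 0.01, 0.49),
      partially_enveloped = stats::runif(1, 0.5, 0.99),
      fully_enveloped = 1
    )
  }, numeric(1))
  soma_contacts <- tibble::tibble(
    soma_id = seq_len(n_contacts),
    fraction = unname(fraction),
    true_label = labels
  )

  debris_counts <- table(factor(debris$true_class,
                                levels = c("microglia", "astrocyte",
                                           "other")))
  truths <- list(
    coverage_percent = 100 * sum(marker_mask) / (nr * nc),
    marker_pixels = sum(marker_mask),
    n_microglia = n_microglia,
    lysosome_index = if (n_microglia > 0) {
      sum(marker_mask) / n_microglia
    } else {
      NA_real_
    },
    debris_fractions = if (n_debris > 0) {
      as.numeric(debris_counts) / n_debris
    } else {
      rep(NA_real_, 3)
    }
  )
  names(truths$debris_fractions) <- c("microglia", "astrocyte", "other")

  structure(
    list(
      image_shape = c(nr, nc),
      class_masks = list(microglia = mask_m, astrocyte = mask_a),
      marker_mask = marker_mask,
      debris = debris,
      soma_contacts = soma_contacts,
      truths = truths
    ),
    class = "quant_scene"
  )
}

place_disjoint_disks <- function(n, nr, nc, radius, gap = 3) {
  min_d2 <- (2 * radius + gap)^2
  xs <- numeric(n)
  ys <- numeric(n)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > 20000L) {
      stop("Could not place ", n, " disjoint somata in the field; reduce ",
           "counts or radius.", call. = FALSE)
    }
    x <- stats::runif(1, radius + 1, nc - radius - 2)
    y <- stats::runif(1, radius + 1, nr - radius - 2)
    if (placed == 0L ||
        min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >=
          min_d2) {
      placed <- placed + 1L
      xs[placed] <- x
      ys[placed] <- y
    }
  }
  tibble::tibble(x = xs, y = ys)
}

# pixel-centre rasterisation: pixel (row i, col j) has centre
# (x = j, y = i) in 0-based scene coordinates; only the bounding box is
# evaluated
disk_mask <- function(nr, nc, cx, cy, radius) {
  out <- matrix(FALSE, nr, nc)
  rows <- max(1, floor(cy - radius) + 1):min(nr, ceiling(cy + radius) + 1)
  cols <- max(1, floor(cx - radius) + 1):min(nc, ceiling(cx + radius) + 1)
  if (!length(rows) || !length(cols)) return(out)
  xs <- matrix(rep(cols - 1, each = length(rows)), length(rows))
  ys <- matrix(rep(rows - 1, times = length(cols)), length(rows))
  out[rows, cols] <- (xs - cx)^2 + (ys - cy)^2 <= radius^2
  out
}

segment_mask <- function(nr, nc, x0, y0, x1, y1, half_width = 1) {
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1), times = nc), nr, nc)
  dx <- x1 - x0
  dy <- y1 - y0
  len2 <- dx^2 + dy^2
  if (len2 == 0) return(disk_mask(nr, nc, x0, y0, half_width))
  t <- pmin(pmax(((xs - x0) * dx + (ys - y0) * dy) / len2, 0), 1)
  (xs - (x0 + t * dx))^2 + (ys - (y0 + t * dy))^2 <= half_width^2
}

# seed the RNG for the calling generator, restoring the caller's state
local_rng <- function(seed, envir = parent.frame()) {
  withr::local_seed(seed, .local_envir = envir)
  invisible(NULL)
}

check_window <- function(window) {
  if (!is.numeric(window) || length(window) != 4 ||
      window[2] <= window[1] || window[4] <= window[3]) {
    stop("`window` must be c(xmin, xmax, ymin, ymax) with positive extent.",
         call. = FALSE)
  }
  invisible(window)
}
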