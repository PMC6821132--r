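#' Closed-form death-window model
#'
#' During a developmental death window, a population declines from an
#' initial count `S` to a final count `N_T` over `n` days. At any
#' histological snapshot only a fraction `D` of the scored population is
#' visibly dead or dying, because each corpse remains detectable for a
#' finite clearance (visibility) time `V` (hours). Treating `D` and `V` as
#' constant across the window, the expected per-day loss fraction is
#' `d = D * 24 / V` and the final count is
#'
#' \deqn{N_T = S \, (1 - D \cdot 24/V)^n.}
#'
#' `predict_final_count()` evaluates this forward model;
#' [solve_clearance_time()] inverts it for `V`.
#'
#' @param S Initial cell count at the window start (cells, > 0).
#' @param D Visible-dying fraction at a snapshot (dimensionless, in
#'   `[0, 1)`): visibly dying cells / total scored cells.
#' @param V Clearance (visibility) time in hours (> 0).
#' @param n Window length in days (>= 0).
#'
#' @return Expected cell count at the window end (cells). Vectorised over
#'   all arguments.
#' @seealso [solve_clearance_time()], [loss_projection()]
#' @examples
#' # near-zero apoptosis barely dents the population over 9 days
#' predict_final_count(S = 26987, D = 0.000583, V = 2.47, n = 9)
#' @export
predict_final_count <- function(S, D, V, n) {
  stopifnot(is.numeric(S), is.numeric(D), is.numeric(V), is.numeric(n))
  if (any(S <= 0)) stop("`S` must be positive.", call. = FALSE)
  if (any(V <= 0)) stop("`V` must be positive (hours).", call. = FALSE)
  if (any(D < 0 | D >= 1)) stop("`D` must lie in [0, 1).", call. = FALSE)
  if (any(n < 0)) stop("`n` must be non-negative (days).", call. = FALSE)
  d <- per_day_loss_fraction(D, V)
  if (any(d >= 1)) {
    stop("Per-day loss fraction D*24/V is >= 1: the model is outside its ",
         "valid regime (the whole population would be lost in under a day).",
         call. = FALSE)
  }
  S * (1 - d)^n
}

#' Per-day loss fraction implied by a snapshot dying fraction
#'
#' A corpse visible for `V` hours is counted in `24 / V` fewer daily
#' cohorts than a full day's deaths, so the expected fraction of the
#' population lost per day is `d = D * 24 / V`.
#'
#' @inheritParams predict_final_count
#' @return Dimensionless per-day loss fraction.
#' @keywords internal
per_day_loss_fraction <- function(D, V) D * 24 / V

#' Solve the death-window model for the clearance time
#'
#' Inverts the death-window model
#' \eqn{N_T = S (1 - D \cdot 24/V)^n} for the corpse clearance
#' (visibility) time:
#'
#' \deqn{V = \frac{24 D}{1 - (N_T/S)^{1/n}}.}
#'
#' This answers: how quickly must dying cells be cleared for the observed
#' snapshot dying fraction `D` to account for the measured decline from
#' `S` to `N_T` over `n` days?
#'
#' @inheritParams predict_final_count
#' @param N_T Final cell count at the window end (cells, `0 < N_T < S`).
#'
#' @return Clearance time in hours. Exactly inverts
#'   [predict_final_count()]: `predict_final_count(S, D, V, n) == N_T`.
#' @examples
#' # rat retinal ganglion cells, P1 -> P11
#' solve_clearance_time(S = 200000, N_T = 117000, D = 0.005375, n = 10)
#' # engulfed retinal astrocytes, P5 -> P14, in minutes:
#' 60 * solve_clearance_time(S = 26987, N_T = 6513, D = 0.00556, n = 9)
#' @export
solve_clearance_time <- function(S, N_T, D, n) {
  stopifnot(is.numeric(S), is.numeric(N_T), is.numeric(D), is.numeric(n))
  if (any(S <= 0)) stop("`S` must be positive.", call. = FALSE)
  if (any(N_T <= 0)) {
    stop("`N_T` must be positive: the model cannot reach zero cells in ",
         "finite time.", call. = FALSE)
  }
  if (any(N_T > S)) {
    stop("`N_T` exceeds `S`: the model describes decline only.",
         call. = FALSE)
  }
  if (any(N_T == S)) {
    stop("`N_T` equals `S`: no decline, clearance time is undefined.",
         call. = FALSE)
  }
  if (any(D <= 0)) {
    stop("`D` must be positive: with no visible death the clearance time ",
         "is undefined.", call. = FALSE)
  }
  if (any(D >= 1)) stop("`D` must lie in (0, 1).", call. = FALSE)
  if (any(n <= 0)) stop("`n` must be positive (days).", call. = FALSE)
  24 * D / (1 - (N_T / S)^(1 / n))
}

#' Solve clearance times for a table of death-window scenarios
#'
#' Data-frame-first wrapper around [solve_clearance_time()]: each row is
#' one scenario with columns `s`, `n_t`, `d` and `n`; the result gains
#' `v_hours` and `v_minutes` columns.
#'
#' @param data A data frame with numeric columns `s` (initial count),
#'   `n_t` (final count), `d` (visible-dying fraction) and `n` (window
#'   length, days).
#' @return The input as a tibble with `v_hours` and `v_minutes` appended.
#' @examples
#' tibble::tibble(
#'   scenario = c("RGC validation", "engulfment"),
#'   s = c(200000, 26987), n_t = c(117000, 6513),
#'   d = c(0.005375, 0.00556), n = c(10, 9)
#' ) |> solve_clearance()
#' @export
solve_clearance <- function(data) {
  require_columns(data, c("s", "n_t", "d", "n"))
  dplyr::mutate(
    tibble::as_tibble(data),
    v_hours = solve_clearance_time(.data$s, .data$n_t, .data$d, .data$n),
    v_minutes = .data$v_hours * 60
  )
}

#' Predict final counts for a table of death-window scenarios
#'
#' Data-frame-first wrapper around [predict_final_count()]: rows carry
#' `s`, `d`, `v` and `n`; the result gains a `n_t` column.
#'
#' @param data A data frame with numeric columns `s`, `d`, `v` (hours)
#'   and `n` (days).
#' @return The input as a tibble with `n_t` appended.
#' @export
predict_decline <- function(data) {
  require_columns(data, c("s", "d", "v", "n"))
  dplyr::mutate(
    tibble::as_tibble(data),
    n_t = predict_final_count(.data$s, .data$d, .data$v, .data$n)
  )
}

#' Project the day-by-day population decline
#'
#' Steps the death-window model through each day of the window, recording
#' the expected count `N_k = S (1 - D*24/V)^k` and the per-day losses
#' `N_k - N_{k+1}`.
#'
#' @inheritParams predict_final_count
#' @return An object of class `loss_projection`: a tibble with columns
#'   `day` (0..n), `count` (expected cells) and `loss` (cells lost since
#'   the previous day; `NA` on day 0), carrying the model parameters and
#'   `mean_daily_loss = (N_0 - N_n)/n` as attributes. Retrieve summaries
#'   with [glance()][generics::glance].
#' @examples
#' proj <- loss_projection(S = 26987, D = 0.0003, V = 2.47, n = 9)
#' generics::glance(proj)
#' @export
loss_projection <- function(S, D, V, n) {
  stopifnot(length(S) == 1, length(D) == 1, length(V) == 1, length(n) == 1)
  if (n <= 0 || n != round(n)) {
    stop("`n` must be a positive whole number of days for a day-by-day ",
         "projection.", call. = FALSE)
  }
  days <- 0:n
  counts <- predict_final_count(S, D, V, days)
  out <- tibble::tibble(
    day = days,
    count = counts,
    loss = c(NA_real_, -diff(counts))
  )
  structure(
    out,
    class = c("loss_projection", class(out)),
    params = list(S = S, D = D, V = V, n = n),
    mean_daily_loss = (counts[1] - counts[n + 1]) / n
  )
}

#' Cumulative cell loss extrapolated from the mean daily loss
#'
#' Multiplies the projection's mean daily loss by `k` days. This is the
#' deliberate linearised extrapolation used to estimate corpses
#' accumulating over a period outside (or inside) the modelled window; it
#' is not the geometric partial sum over the first `k` days, which is
#' available via `method = "geometric"`.
#'
#' @param projection A [loss_projection()] object.
#' @param k Number of days to extrapolate over (> 0).
#' @param method `"linear"` (default): `mean_daily_loss * k`.
#'   `"geometric"`: the model's own cumulative loss over the first `k`
#'   days, `S - S (1 - d)^k`.
#' @return Cells lost over `k` days (numeric scalar).
#' @export
cumulative_loss <- function(projection, k, method = c("linear", "geometric")) {
  method <- match.arg(method)
  if (!inherits(projection, "loss_projection")) {
    stop("`projection` must be a loss_projection object.", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    stop("`k` must be a positive number of days.", call. = FALSE)
  }
  p <- attr(projection, "params")
  switch(method,
    linear = attr(projection, "mean_daily_loss") * k,
    geometric = p$S - predict_final_count(p$S, p$D, p$V, k)
  )
}

#' Estimate the visible-dying fraction with a t-based confidence interval
#'
#' Summarises per-animal (or per-field) visibly-dying fractions into a
#' mean and a two-sided Student-t confidence interval, the uncertainty
#' carrier for [corpse_density_band()].
#'
#' @param per_sample_fractions Numeric vector of fractions in `[0, 1)`,
#'   one per independent sample; at least 2.
#' @param confidence Two-sided confidence level (default 0.95).
#' @param label Optional text label (marker, ages) carried along.
#' @return An object of class `visible_fraction_estimate`: a list with
#'   `per_sample_fractions`, `mean`, `ci_low`, `ci_high`, `confidence`
#'   and `label`. [tidy()][generics::tidy] returns it as a one-row tibble.
#' @examples
#' estimate_visible_fraction(c(0, 0.001, 0.0005, 0.0009))
#' @export
estimate_visible_fraction <- function(per_sample_fractions,
                                      confidence = 0.95,
                                      label = NULL) {
  x <- per_sample_fractions
  if (!is.numeric(x) || length(x) < 2) {
    stop("Need at least 2 per-sample fractions to form an interval.",
         call. = FALSE)
  }
  if (any(x < 0 | x >= 1)) {
    stop("Fractions must lie in [0, 1).", call. = FALSE)
  }
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1) {
    stop("`confidence` must lie in (0, 1).", call. = FALSE)
  }
  m <- mean(x)
  se <- stats::sd(x) / sqrt(length(x))
  half <- stats::qt(1 - (1 - confidence) / 2, df = length(x) - 1) * se
  structure(
    list(
      per_sample_fractions = x,
      mean = m,
      ci_low = m - half,
      ci_high = m + half,
      confidence = confidence,
      label = label
    ),
    class = "visible_fraction_estimate"
  )
}

#' Build a visible-fraction estimate from known bounds
#'
#' Constructor for the case where the mean and interval endpoints are
#' already known (e.g. published values) rather than derived from raw
#' per-sample data.
#'
#' @param mean,ci_low,ci_high Dying fractions in `[0, 1)` with
#'   `ci_low <= mean <= ci_high`.
#' @param label Optional text label.
#' @return A `visible_fraction_estimate` object.
#' @export
visible_fraction_estimate <- function(mean, ci_low, ci_high, label = NULL) {
  vals <- c(ci_low, mean, ci_high)
  if (any(vals < 0 | vals >= 1)) {
    stop("Fractions must lie in [0, 1).", call. = FALSE)
  }
  if (ci_low > mean || mean > ci_high) {
    stop("Need ci_low <= mean <= ci_high.", call. = FALSE)
  }
  structure(
    list(per_sample_fractions = NULL, mean = mean, ci_low = ci_low,
         ci_high = ci_high, confidence = NA_real_, label = label),
    class = "visible_fraction_estimate"
  )
}

#' Expected corpse-density band under a no-clearance scenario
#'
#' Propagates the confidence band of a visible-dying fraction through the
#' death-window model to a band of expected corpse densities: for each of
#' `D = ci_low, mean, ci_high` the model is run, the mean daily loss is
#' extrapolated over `k` days ([cumulative_loss()]), and the accumulated
#' corpse count is divided by the tissue area. This predicts the density
#' of uncleared corpses if phagocytic clearance were absent.
#'
#' @inheritParams predict_final_count
#' @param estimate A `visible_fraction_estimate` (see
#'   [estimate_visible_fraction()]).
#' @param k Days of corpse accumulation (> 0).
#' @param area Tissue area in mm^2 (> 0).
#' @return A tibble with one row per band member (`bound` = `"low"`,
#'   `"mid"`, `"high"`), the `d` used, the accumulated `cells_lost` and
#'   the corpse `density` (cells/mm^2), ordered low <= mid <= high.
#' @examples
#' est <- visible_fraction_estimate(
#'   mean = 0.0003, ci_low = 0.0002, ci_high = 0.0006
#' )
#' corpse_density_band(S = 26987, V = 2.47, n = 9, estimate = est,
#'                     k = 6, area = 10)
#' @export
corpse_density_band <- function(S, V, n, estimate, k, area) {
  if (!inherits(estimate, "visible_fraction_estimate")) {
    stop("`estimate` must be a visible_fraction_estimate.", call. = FALSE)
  }
  if (!is.numeric(area) || length(area) != 1 || area <= 0) {
    stop("`area` must be a positive area in mm^2.", call. = FALSE)
  }
  if (estimate$ci_low > estimate$mean || estimate$mean > estimate$ci_high) {
    stop("Estimate bounds are out of order.", call. = FALSE)
  }
  ds <- c(low = estimate$ci_low, mid = estimate$mean, high = estimate$ci_high)
  lost <- purrr::map_dbl(ds, function(D) {
    cumulative_loss(loss_projection(S, D, V, n), k)
  })
  tibble::tibble(
    bound = names(ds),
    d = unname(ds),
    cells_lost = unname(lost),
    density = unname(lost) / area
  )
}

require_columns <- function(data, cols) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame.", call. = FALSE)
  }
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("`data` is missing required column(s): ",
         paste(missing, collapse = ", "), ".", call. = FALSE)
  }
  invisible(data)
}
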