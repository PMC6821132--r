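#' Configuration for the stochastic death-and-clearance simulator
#'
#' Bundles and validates the parameters of the generative process behind
#' the death-window model: cells die with a constant hazard calibrated so
#' that the expected fraction lost per day equals `per_day_loss`, and each
#' corpse remains visible for a clearance period before disappearing.
#'
#' @param S0 Initial number of live cells (> 0).
#' @param per_day_loss Expected fraction of live cells lost per day,
#'   `d` in `[0, 1)`.
#' @param clearance_hours Corpse visibility duration `V` in hours (> 0).
#' @param n_days Simulated duration in whole days (>= 1).
#' @param timestep_hours Simulation step in hours; must not exceed
#'   `clearance_hours`. Default 0.1 h. The per-step death probability is
#'   `1 - exp(-h * dt)` with hourly hazard `h = -log(1 - d)/24`, so the
#'   daily survival probability is exactly `1 - d` for any step size.
#' @param corpse_lifetime `"fixed"` (every corpse visible for exactly
#'   `clearance_hours`) or `"exponential"` (lifetimes exponentially
#'   distributed with that mean).
#' @param seed Integer seed; every simulation from the same config is
#'   bit-identical.
#' @return A `death_sim_config` list.
#' @seealso [simulate_death_process()]
#' @export
death_sim_config <- function(S0,
                             per_day_loss,
                             clearance_hours,
                             n_days,
                             timestep_hours = 0.1,
                             corpse_lifetime = c("fixed", "exponential"),
                             seed = 1L) {
  corpse_lifetime <- match.arg(corpse_lifetime)
  if (!is.numeric(S0) || length(S0) != 1 || S0 <= 0 || S0 != round(S0)) {
    stop("`S0` must be a positive integer count.", call. = FALSE)
  }
  if (per_day_loss < 0 || per_day_loss >= 1) {
    stop("`per_day_loss` must lie in [0, 1).", call. = FALSE)
  }
  if (clearance_hours <= 0) {
    stop("`clearance_hours` must be positive.", call. = FALSE)
  }
  if (n_days < 1 || n_days != round(n_days)) {
    stop("`n_days` must be a positive whole number of days.", call. = FALSE)
  }
  if (timestep_hours <= 0 || timestep_hours > clearance_hours) {
    stop("`timestep_hours` must be positive and no longer than the ",
         "clearance window.", call. = FALSE)
  }
  structure(
    list(S0 = as.integer(S0), per_day_loss = per_day_loss,
         clearance_hours = clearance_hours, n_days = as.integer(n_days),
         timestep_hours = timestep_hours, corpse_lifetime = corpse_lifetime,
         seed = as.integer(seed)),
    class = "death_sim_config"
  )
}

#' Simulate a declining population observed by daily snapshots
#'
#' Runs the stochastic death-and-clearance process and scores it the way
#' a histologist would: once per simulated day (at mid-day, to avoid
#' phase artefacts at day boundaries) the live cells and currently
#' visible corpses are censused, giving the observed visible-dying
#' fraction `visible / (live + visible)`. Under quasi-steady state
#' (corpse production balancing clearance) this fraction approximates
#' `per_day_loss * clearance_hours / 24`.
#'
#' @param config A [death_sim_config()].
#' @return A tibble of class `snapshot_series` with one row per snapshot:
#'   `day` (mid-day sample times 0.5, 1.5, ...), `live`, `visible`,
#'   `cleared` (cumulative cleared corpses) and `observed_fraction`.
#'   `live + visible + cleared == S0` at every snapshot. The config is
#'   attached as attribute `config`.
#' @examples
#' cfg <- death_sim_config(S0 = 20000, per_day_loss = 0.05,
#'                         clearance_hours = 2.5, n_days = 5, seed = 42)
#' sim <- simulate_death_process(cfg)
#' mean(sim$observed_fraction)  # ~ 0.05 * 2.5 / 24
#' @export
simulate_death_process <- function(config) {
  if (!inherits(config, "death_sim_config")) {
    stop("`config` must be a death_sim_config.", call. = FALSE)
  }
  dt <- config$timestep_hours
  n_steps <- ceiling(config$n_days * 24 / dt)
  hazard <- -log(1 - config$per_day_loss) / 24
  p_step <- 1 - exp(-hazard * dt)

  withr::local_seed(config$seed)

  live <- config$S0
  deaths_per_step <- integer(n_steps)
  live_after_step <- integer(n_steps)
  for (s in seq_len(n_steps)) {
    k <- if (live > 0 && p_step > 0) stats::rbinom(1L, live, p_step) else 0L
    deaths_per_step[s] <- k
    live <- live - k
    live_after_step[s] <- live
  }
  step_end_times <- seq_len(n_steps) * dt
  # death times are spread uniformly within their step (the continuous
  # embedding of the discrete scheme); visibility lasts exactly V hours
  # (fixed) or Exp(mean V) (exponential)
  n_dead <- sum(deaths_per_step)
  death_times <- rep.int(step_end_times - dt, deaths_per_step) +
    stats::runif(n_dead) * dt
  clear_times <- if (config$corpse_lifetime == "fixed") {
    death_times + config$clearance_hours
  } else {
    death_times + stats::rexp(length(death_times),
                              rate = 1 / config$clearance_hours)
  }

  snap_days <- seq_len(config$n_days) - 0.5
  snap_times <- snap_days * 24
  # live count at snapshot = live after the last step ending <= snap time
  idx <- findInterval(snap_times, step_end_times)
  live_at <- ifelse(idx == 0, config$S0, live_after_step[pmax(idx, 1L)])
  visible <- vapply(snap_times, function(t) {
    sum(death_times <= t & clear_times > t)
  }, integer(1))
  died_by <- vapply(snap_times, function(t) sum(death_times <= t),
                    integer(1))
  cleared <- died_by - visible

  out <- tibble::tibble(
    day = snap_days,
    live = as.integer(live_at),
    visible = as.integer(visible),
    cleared = as.integer(cleared),
    observed_fraction = visible / (live_at + visible)
  )
  structure(out, class = c("snapshot_series", class(out)), config = config)
}

#' Recover the clearance time from a simulated snapshot series
#'
#' End-to-end estimator check: takes the first and last live counts as
#' `S` and `N_T`, the time-averaged observed dying fraction as `D`, and
#' delegates to [solve_clearance_time()].
#'
#' @param series A `snapshot_series` (see [simulate_death_process()]) or
#'   any data frame with columns `day`, `live` and `observed_fraction`.
#' @param n Window length in days; defaults to the span of the snapshot
#'   times (`max(day) - min(day)`), which is the interval the first and
#'   last live counts actually straddle.
#' @return Estimated clearance time in hours.
#' @export
recover_clearance_time <- function(series, n = NULL) {
  require_columns(series, c("day", "live", "observed_fraction"))
  if (nrow(series) < 2) {
    stop("Need at least 2 snapshots.", call. = FALSE)
  }
  n <- n %||% (max(series$day) - min(series$day))
  S <- series$live[which.min(series$day)]
  N_T <- series$live[which.max(series$day)]
  if (N_T >= S) {
    stop("Snapshot series shows no decline in live cells; clearance time ",
         "is unidentifiable.", call. = FALSE)
  }
  D <- mean(series$observed_fraction)
  if (D <= 0) {
    stop("No visible corpses were ever observed; clearance time is ",
         "unidentifiable.", call. = FALSE)
  }
  solve_clearance_time(S = S, N_T = N_T, D = D, n = n)
}
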