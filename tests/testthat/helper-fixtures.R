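# Shared fixtures built in code.

# Deterministic snapshot series consistent with the closed-form model:
# mid-day live counts on an exact geometric decline, observed fraction
# at its quasi-steady value d*V/24.
analytic_series <- function(S0 = 5e4, d = 0.005, V = 3, n_days = 8) {
  days <- seq(0.5, n_days - 0.5, by = 1)
  tibble::tibble(
    day = days,
    live = S0 * (1 - d)^days,
    visible = NA_real_,
    cleared = NA_real_,
    observed_fraction = d * V / 24
  )
}

# Square lattice with optional positional jitter, inside a window with
# enough margin that the inner sites are interior Voronoi domains.
jittered_lattice <- function(k = 8, spacing = 1, jitter = 0, seed = 1) {
  withr::with_seed(seed, {
    g <- expand.grid(i = seq_len(k), j = seq_len(k))
    tibble::tibble(
      x = g$i * spacing + stats::runif(k^2, -jitter, jitter),
      y = g$j * spacing + stats::runif(k^2, -jitter, jitter)
    )
  })
}

lattice_window <- function(k = 8, spacing = 1) {
  c(0, (k + 1) * spacing, 0, (k + 1) * spacing)
}

# Minimum pairwise distance of a point table.
min_pair_dist <- function(pts) {
  d <- as.matrix(stats::dist(cbind(pts$x, pts$y)))
  diag(d) <- Inf
  min(d)
}
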