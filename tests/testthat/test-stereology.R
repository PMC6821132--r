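test_that("weighted mean density combines regional means correctly", {
  fov <- tibble::tibble(
    region = rep(c("central", "middle", "peripheral"), each = 2),
    density = c(1000, 1000, 800, 800, 500, 500)
  )
  # forced arithmetic on the standard area weights
  expect_equal(weighted_mean_density(fov), 654)
  # uniform density is returned unchanged (weights sum to 1)
  uni <- dplyr::mutate(fov, density = 750)
  expect_equal(weighted_mean_density(uni), 750)
  # degenerate weights isolate one region
  expect_equal(weighted_mean_density(fov, region_weights(1, 0, 0)), 1000)
  # order of fields within regions is irrelevant
  expect_equal(weighted_mean_density(fov[sample(6), ]),
               weighted_mean_density(fov))
})

test_that("weights and samples are validated", {
  expect_error(region_weights(0.5, 0.3, 0.1), "sum to 1")
  expect_error(region_weights(-0.1, 0.5, 0.6), "\\[0, 1\\]")
  fov <- tibble::tibble(region = "central", density = 100)
  expect_error(weighted_mean_density(fov), "Missing region")
  neg <- tibble::tibble(
    region = c("central", "middle", "peripheral"),
    density = c(-5, 10, 10)
  )
  expect_error(weighted_mean_density(neg), "non-negative")
})

test_that("density converts to a total count by area", {
  expect_equal(total_count(654, 20), 13080)
  expect_equal(total_count(0, 12), 0)
  expect_error(total_count(100, 0), "positive")
  expect_error(total_count(-1, 10), "non-negative")
})

test_that("field sampling sees the intensity surface it is given", {
  # homogeneous retina: regional means statistically indistinguishable
  flat <- generate_retina(700, 700, radius = 2, seed = 51)
  fov <- sample_fields(flat, fov_side = 0.25, n_fov_per_region = 3,
                       seed = 52)
  means <- fov |>
    dplyr::group_by(region) |>
    dplyr::summarise(m = mean(density), .groups = "drop")
  expect_lt(diff(range(means$m)) / 700, 0.35)
  # centre-dense gradient shows up as central > peripheral
  grad <- generate_retina(900, 200, radius = 2, seed = 53)
  gfov <- sample_fields(grad, fov_side = 0.25, n_fov_per_region = 3,
                        seed = 54)
  gm <- gfov |>
    dplyr::group_by(region) |>
    dplyr::summarise(m = mean(density), .groups = "drop")
  expect_gt(gm$m[gm$region == "central"],
            gm$m[gm$region == "peripheral"])
  # invalid requests
  expect_error(sample_fields(flat, 0.25, 0, seed = 1), "positive integer")
  expect_error(sample_fields(flat, 1.5, 3, seed = 1), "protrudes")
})

test_that("whole-retina estimate is unbiased on homogeneous patterns", {
  ratios <- vapply(1:25, function(s) {
    p <- generate_retina(600, 600, radius = 2, seed = s)
    estimate_total(p, fov_side = 0.25, seed = s + 1000)$total_estimate /
      attr(p, "true_count")
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.03)
})

test_that("area weighting corrects the gradient bias of naive means", {
  # centre-dense pattern: unweighted regional averaging over-counts the
  # small dense centre, so the weighted estimate must be lower
  diffs <- vapply(1:10, function(s) {
    p <- generate_retina(900, 200, radius = 2, seed = s)
    fov <- sample_fields(p, fov_side = 0.25, seed = s + 100)
    weighted_mean_density(fov) - mean(fov$density)
  }, numeric(1))
  expect_lt(mean(diffs), 0)
})
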