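test_that("engulfment classification follows the circumference rules", {
  expect_equal(as.character(classify_engulfment(0)), "none")
  expect_equal(as.character(classify_engulfment(0.2)), "touched")
  # the half-circumference boundary belongs to partial envelopment
  expect_equal(as.character(classify_engulfment(0.5)),
               "partially_enveloped")
  expect_equal(as.character(classify_engulfment(0.499)), "touched")
  expect_equal(as.character(classify_engulfment(1)), "fully_enveloped")
  # rasterisation tolerance: 99.7% counts as full envelopment
  expect_equal(as.character(classify_engulfment(0.997)),
               "fully_enveloped")
  expect_equal(as.character(classify_engulfment(0.99)),
               "partially_enveloped")
  expect_error(classify_engulfment(1.2), "\\[0, 1\\]")
  expect_error(classify_engulfment(-0.1), "\\[0, 1\\]")
})

test_that("engulfment labels partition [0,1] monotonically", {
  f <- seq(0, 1, length.out = 2001)
  lab <- classify_engulfment(f)
  expect_false(anyNA(lab))
  # labels never step backwards as coverage grows
  expect_true(all(diff(as.integer(lab)) >= 0))
  # scene truths drawn per label agree with the classifier
  sc <- generate_quant_scene(n_contacts = 60, seed = 17)
  got <- classify_contacts(sc$soma_contacts)
  expect_equal(as.character(got$label), got$true_label)
})

test_that("lysosome index is marker pixels per cell", {
  expect_equal(lysosome_index(0, 10), 0)
  expect_equal(lysosome_index(5000, 10), 500)
  expect_error(lysosome_index(100, 0), "undefined")
  expect_error(lysosome_index(-1, 5), "non-negative")
  sc <- generate_quant_scene(seed = 9)
  expect_equal(lysosome_index(sum(sc$marker_mask), sc$truths$n_microglia),
               sc$truths$lysosome_index)
})

test_that("series normalisation maps the maximum to 100", {
  expect_equal(normalize_series(c(2, 4)), c(50, 100))
  expect_equal(normalize_series(c(7, 7)), c(100, 100))
  x <- c(3, 1, 4, 1, 5)
  expect_equal(order(normalize_series(x)), order(x))
  # idempotent after one application
  expect_equal(normalize_series(normalize_series(x)),
               normalize_series(x))
  expect_error(normalize_series(numeric()), "non-empty")
  expect_error(normalize_series(c(0, 0)), "not positive")
})

test_that("network coverage complements negative space exactly", {
  full <- matrix(TRUE, 10, 10)
  expect_equal(network_coverage(full), 100)
  half <- matrix(c(TRUE, FALSE), 10, 10)
  expect_equal(network_coverage(half), 50)
  sc <- generate_quant_scene(marker = "arbor", marker_target_coverage = 15,
                             seed = 2)
  expect_equal(network_coverage(sc$marker_mask),
               sc$truths$coverage_percent)
  negative_space <- 100 * sum(!sc$marker_mask) / length(sc$marker_mask)
  expect_equal(network_coverage(sc$marker_mask) + negative_space, 100)
  expect_error(network_coverage(matrix(logical(0), 0, 0)), "empty")
  expect_error(network_coverage(matrix(0.5, 2, 2)), "logical")
})

test_that("histogram thresholding separates foreground from background", {
  # clean two-level image: both methods recover the bright pixels exactly
  bi <- matrix(0, 60, 60)
  bi[1:12, ] <- 200
  for (m in c("li", "triangle")) {
    mask <- auto_threshold(bi, m)
    expect_true(all(mask == (bi == 200)), info = m)
  }
  # noisy blobs: recovered foreground area within 5% of truth
  withr::with_seed(71, {
    img <- matrix(abs(rnorm(200 * 200, 10, 3)), 200)
    truth <- matrix(FALSE, 200, 200)
    xs <- matrix(rep(0:199, each = 200), 200)
    ys <- matrix(rep(0:199, times = 200), 200)
    for (k in 1:5) {
      cx <- runif(1, 25, 175)
      cy <- runif(1, 25, 175)
      truth <- truth | ((xs - cx)^2 + (ys - cy)^2 <= 14^2)
    }
    img[truth] <- img[truth] + 100
  })
  for (m in c("li", "triangle")) {
    mask <- auto_threshold(img, m)
    expect_equal(sum(mask) / sum(truth), 1, tolerance = 0.05, info = m)
  }
  expect_error(auto_threshold(matrix(5, 4, 4)), "constant")
})

test_that("debris is assigned only when fully enclosed", {
  m <- matrix(FALSE, 30, 30)
  m[5:25, 5:25] <- TRUE
  deb <- tibble::tibble(
    id = 1:3,
    x = c(14, 4.2, 28),  # inside / straddling the edge / outside
    y = c(14, 14, 28),
    radius = 2
  )
  out <- debris_localization(deb, list(microglia = m))
  expect_equal(out$n[out$class == "microglia"], 1L)
  expect_equal(out$n[out$class == "unassigned"], 2L)
  expect_equal(sum(out$fraction), 1)
  # the permissive centroid rule claims the straddler too
  cen <- debris_localization(deb, list(microglia = m), method = "centroid")
  expect_equal(cen$n[cen$class == "microglia"], 2L)
  expect_error(debris_localization(deb[0, ], list(microglia = m)),
               "No debris")
  expect_error(
    debris_localization(deb, list(a = m, b = m)),
    "overlap"
  )
})

test_that("scene debris fractions are reproduced exactly", {
  sc <- generate_quant_scene(seed = 9)
  out <- debris_localization(sc$debris, sc$class_masks)
  expect_equal(out$fraction[match(c("microglia", "astrocyte"), out$class)],
               unname(sc$truths$debris_fractions[c("microglia",
                                                   "astrocyte")]))
  expect_equal(sum(out$fraction), 1)
  # microglia-deficient condition: debris accumulates in astrocytes
  mut <- generate_quant_scene(
    debris_class_probs = c(microglia = 0.05, astrocyte = 0.8,
                           other = 0.15),
    n_debris = 60, seed = 12
  )
  mout <- debris_localization(mut$debris, mut$class_masks)
  expect_equal(
    mout$fraction[match(c("microglia", "astrocyte"), mout$class)],
    unname(mut$truths$debris_fractions[c("microglia", "astrocyte")])
  )
})

test_that("litter normalisation rescales to the control mean", {
  d <- tibble::tibble(
    litter = rep(c("A", "B"), each = 4),
    group = rep(c("control", "control", "mutant", "mutant"), 2),
    coverage = c(40, 60, 30, 20, 80, 120, 60, 40)
  )
  out <- normalize_by_litter(d, coverage, litter, group)
  # control mean maps to 1 in each litter despite a 2x litter effect
  ctrl <- out |>
    dplyr::filter(group == "control") |>
    dplyr::group_by(litter) |>
    dplyr::summarise(m = mean(normalized), .groups = "drop")
  expect_equal(ctrl$m, c(1, 1))
  # mutant effect is identical across litters after normalisation
  mut <- out |> dplyr::filter(group == "mutant")
  expect_equal(mut$normalized[1:2], mut$normalized[3:4])
  no_ctrl <- d |> dplyr::mutate(group = "mutant")
  expect_error(normalize_by_litter(no_ctrl, coverage, litter, group),
               "no 'control'")
})
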