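test_that("the default pipeline reproduces the published extremes and ranking", {
  fit <- assess(load_jilin_fixture(), assessment_config())
  v <- fit$result$composite
  expect_equal(fit$result$amplitude, 2.2)
  expect_identical(names(which.max(v)), "Fuyu")
  expect_identical(names(which.min(v)), "Tiaobei")
  expect_equal(max(v), 0.9376, tolerance = 3e-3)
  expect_equal(min(v), 0.8636, tolerance = 3e-3)
  expect_equal(mean(v), 8 / 9, tolerance = 1e-9)
  expect_identical(fit$result$ranking, jilin_published_order)
})

test_that("equal weights on the published proportions give the derived Fuyu index", {
  # oracle: V = 1 - (row sum)/10 over Fuyu's printed proportion row
  v <- composite_index(jilin_proportions / rep(colSums(jilin_proportions),
                                               each = 9),
                       rep(0.1, 10), rep("contrarian", 10))
  expect_equal(v[["Fuyu"]], 0.9368, tolerance = 2e-4)
  # equal weights preserve the published ranking (robustness regression)
  p <- ew_proportions(translate(zscore_standardize(load_jilin_fixture()), 2.2))
  v_eq <- composite_index(p, rep(0.1, 10), rep("contrarian", 10))
  expect_identical(rank_regions(v_eq), jilin_published_order)
})

test_that("composite index handles both orientations and both modes", {
  p <- cbind(c(0.2, 0.8), c(0.6, 0.4))
  rownames(p) <- c("r1", "r2")
  w <- c(0.3, 0.7)
  # mixed orientations, weighted complement
  v <- composite_index(p, w, c("positive", "contrarian"))
  expect_equal(unname(v), c(0.3 * 0.2 + 0.7 * 0.4, 0.3 * 0.8 + 0.7 * 0.6))
  # literal ratio
  vr <- composite_index(p, w, c("positive", "contrarian"), "literal_ratio")
  expect_equal(unname(vr), c(0.3 * 0.2, 0.3 * 0.8) / c(0.7 * 0.4, 0.7 * 0.6))
  # ratio undefined without both orientation sets
  expect_error(composite_index(p, w, c("contrarian", "contrarian"),
                               "literal_ratio"),
               class = "ecoentropy_degenerate_error")
  expect_error(composite_index(p, c(0.5, 0.6), c("positive", "contrarian")),
               "sum to 1", class = "ecoentropy_validation_error")
})

test_that("with one contrarian indicator the smaller share scores higher", {
  cat1 <- indicator_descriptor("a", category = "water",
                               orientation = "contrarian")
  m <- indicator_matrix(matrix(c(10, 2), ncol = 1), c("hi", "lo"), cat1)
  std <- translate(zscore_standardize(m))
  p <- ew_proportions(std)
  v <- composite_index(p, 1, "contrarian")
  expect_gt(v[["lo"]], v[["hi"]])
})

test_that("ranking is descending with stable ties", {
  expect_identical(rank_regions(c(B = 0.5, A = 0.5)), c("B", "A"))
  expect_identical(rank_regions(c(only = 0.4)), "only")
  expect_identical(rank_regions(c(a = 0.1, b = 0.9, c = 0.5)),
                   c("b", "c", "a"))
})

test_that("mean composite index is (n-1)/n for any contrarian weights", {
  for (seed in 1:8) {
    n <- sample(3:9, 1)
    m <- sample(2:6, 1)
    x <- random_indicator_matrix(seed + 40, n = n, m = m)
    fit <- assess(x)
    expect_equal(mean(fit$result$composite), (n - 1) / n, tolerance = 1e-9)
  }
})

test_that("the pipeline is invariant to positive rescaling of raw columns", {
  x <- random_indicator_matrix(55, n = 6, m = 4)
  base <- assess(x)
  scaled <- indicator_matrix(sweep(x$values, 2L, c(0.01, 3, 100, 7), `*`),
                             x$regions, x$catalog)
  other <- assess(scaled)
  expect_equal(other$std$z, base$std$z, tolerance = 1e-9)
  expect_equal(other$weighting$weights, base$weighting$weights,
               tolerance = 1e-9)
  expect_equal(other$result$composite, base$result$composite,
               tolerance = 1e-9)
})

test_that("permuting input regions permutes V identically", {
  x <- random_indicator_matrix(7, n = 5, m = 4)
  base <- assess(x)
  perm <- c(4, 1, 5, 3, 2)
  xp <- indicator_matrix(x$values[perm, ], x$regions[perm], x$catalog)
  permuted <- assess(xp)
  expect_equal(permuted$result$composite, base$result$composite[perm],
               tolerance = 1e-12)
  expect_identical(sort(permuted$result$ranking), sort(base$result$ranking))
})

test_that("assess matches an independent step-by-step re-evaluation", {
  for (seed in 1:10) {
    x <- random_indicator_matrix(seed + 200, n = 5, m = 4)
    fit <- assess(x)
    orc <- oracle_pipeline(x$values, fit$result$amplitude)
    expect_equal(unname(fit$result$composite), orc$V, tolerance = 1e-12)
  }
})

test_that("stage errors carry the stage name", {
  fx <- degenerate_fixtures()
  expect_error(assess(fx$zero_variance), "\\[standardization\\]",
               class = "ecoentropy_degenerate_error")
  expect_error(assess(random_indicator_matrix(1),
                      assessment_config(amplitude = 1e-6)),
               "\\[translation\\]", class = "ecoentropy_amplitude_error")
})

test_that("amplitude sensitivity shows discrimination decay with growing A", {
  jl <- load_jilin_fixture()
  sens <- amplitude_sensitivity(jl, amplitudes = c(2.2, 5, 50))
  expect_true(all(is.na(sens$error)))
  expect_lt(sens$weight_spread[3], sens$weight_spread[1])
  expect_true(all(diff(sens$weight_spread) < 0))
  # ranking stable on the fixture across nearby amplitudes
  sens2 <- amplitude_sensitivity(jl, amplitudes = c(2.2, 3.0))
  expect_identical(sens2$ranking[1], sens2$ranking[2])
  # single default amplitude reproduces assess()
  fit <- assess(jl)
  one <- amplitude_sensitivity(jl, amplitudes = 2.2)
  run <- attr(one, "runs")[[1]]
  expect_equal(run$result$composite, fit$result$composite, tolerance = 1e-12)
  # invalid entries are reported but do not kill the valid ones
  mixed <- amplitude_sensitivity(jl, amplitudes = c(1.0, 2.2))
  expect_match(mixed$error[1], "A > \\|min\\(z\\)\\|")
  expect_true(is.na(mixed$error[2]))
})
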