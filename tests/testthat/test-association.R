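test_that("frequency estimates use Wald intervals clipped to [0, 1]", {
  fr <- frequency_estimate(0, 100)
  expect_equal(fr$freq, 0)
  expect_equal(fr$ci_lo, 0)
  fr <- frequency_estimate(50, 100)
  expect_equal(fr$freq, 0.5)
  expect_equal(fr$ci_lo, 0.5 - stats::qnorm(0.975) * sqrt(0.25 / 100))
  expect_equal(round(fr$ci_lo, 3), 0.402)
  expect_equal(round(fr$ci_hi, 3), 0.598)
  # consistency with the printed control frequency and implied denominator
  expect_equal(round(frequency_estimate(517, 718)$freq, 2), 0.72)
  expect_error(frequency_estimate(1, 0), "positive")
  expect_error(frequency_estimate(5, 4), "count")
})

test_that("a dosage-independent phenotype gives OR 1 and p ~ 1", {
  d <- rep(c(0, 2), each = 20)
  y <- rep(c(1, 0, 1, 0), each = 10)
  row <- fit_additive(d, y, feature = "null")
  expect_equal(row$or., 1, tolerance = 1e-8)
  expect_equal(row$p, 1, tolerance = 1e-6)
  expect_false(row$separation)
})

test_that("the additive fit matches the Newton oracle to 1e-6", {
  set.seed(31)
  for (i in 1:20) {
    n <- 40
    d <- sample(0:2, n, replace = TRUE)
    p <- plogis(-0.3 + 0.5 * d)
    y <- as.integer(runif(n) < p)
    if (length(unique(y)) < 2 || length(unique(d)) < 2) next
    row <- fit_additive(d, y)
    if (row$separation) next
    oracle <- newton_logistic(d, y)
    expect_equal(row$beta, oracle[2], tolerance = 1e-6)
  }
})

test_that("with binary dosage the fitted OR is the closed-form 2x2 OR", {
  set.seed(7)
  d <- sample(0:1, 120, replace = TRUE)
  y <- as.integer(runif(120) < plogis(-0.5 + 0.9 * d))
  row <- fit_additive(d, y)
  a <- sum(d == 1 & y == 1); b <- sum(d == 1 & y == 0)
  c_ <- sum(d == 0 & y == 1); dd <- sum(d == 0 & y == 0)
  expect_equal(row$or., (a * dd) / (b * c_), tolerance = 1e-6)
})

test_that("separation is flagged, not raised", {
  d <- c(rep(2, 15), rep(0, 15))
  y <- c(rep(1, 15), rep(0, 15))
  row <- fit_additive(d, y)
  expect_true(row$separation)
  expect_equal(row$or., Inf)
  expect_true(is.na(row$ci_lo))
})

test_that("degenerate inputs to the additive fit raise", {
  expect_error(fit_additive(rep(1, 10), rep(0:1, 5)), "constant dosage")
  expect_error(fit_additive(0:9, rep(1, 10)), "both phenotype classes")
})

test_that("Bonferroni families split the level exactly", {
  expect_identical(bonferroni_family(4)$threshold, 0.0125)
  expect_identical(bonferroni_family(10)$threshold, 0.005)
  expect_identical(bonferroni_family(1)$threshold, 0.05)
  for (m in c(2, 7, 16, 24))
    expect_identical(bonferroni_family(m)$threshold * m, 0.05)
  expect_error(bonferroni_family(0), "at least 1")
})

test_that("the frequency filter is disjunctive across scopes", {
  fr <- data.frame(feature = rep(c("x", "y"), each = 3),
                   scope = rep(c("all", "stratum:W", "stratum:B"), 2),
                   freq = c(0.02, 0.06, 0.02, 0.049, 0.049, 0.049))
  expect_equal(frequency_filter(fr), "x")
  expect_equal(frequency_filter(fr[0, ]), character(0))
  # exactly at threshold is retained
  fr$freq[4] <- 0.05
  expect_equal(frequency_filter(fr), c("x", "y"))
})

test_that("binary correlation is the phi coefficient", {
  x <- rep(c(1, 0), each = 40)
  expect_equal(binary_correlation(x, x), 1)
  expect_equal(binary_correlation(x, 1 - x), -1)
  # 2x2 with counts (30, 10, 10, 30)
  a <- c(rep(1, 40), rep(0, 40))
  b <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  expect_equal(binary_correlation(a, b), 0.5)
  expect_error(binary_correlation(rep(1, 5), c(0, 1, 0, 1, 0)), "constant")
})

test_that("allele association scans annotate per-gene families", {
  cfg <- small_config(n = 400, seed = 5,
                      effects = data.frame(feature = "allele:DPB1*04:01",
                                           beta = log(0.5)))
  tab <- generate_cohort(cfg)$table
  res <- allele_association(tab, "DPB1")
  full <- res[res$scope == "all", ]
  expect_true(all(full$bonferroni_m == length(unique(full$feature))))
  expect_equal(full$threshold[1] * full$bonferroni_m[1], 0.05)
  target <- full[full$feature == "DPB1*04:01", ]
  expect_lt(target$or., 1)
  expect_lt(target$p, 0.05)
})
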