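test_that("double homozygotes need no phase inference", {
  tab <- make_cohort(status = rep(c("case", "control"), 5),
                     DPA1 = rep_pairs(list(c("01:03", "01:03"),
                                           c("02:01", "02:01")), c(6, 4)),
                     DPB1 = rep_pairs(list(c("04:01", "04:01"),
                                           c("17:01", "17:01")), c(6, 4)))
  em <- em_fit(tab)
  expect_true(em$converged)
  f <- setNames(em$haplotypes$freq,
                paste(em$haplotypes$a, em$haplotypes$b, sep = "~"))
  expect_equal(unname(f["01:03~04:01"]), 0.6)
  expect_equal(unname(f["02:01~17:01"]), 0.4)
})

test_that("a lone double heterozygote sits at the symmetric fixed point", {
  tab <- make_cohort(status = "case",
                     DPA1 = list(c("01:03", "02:01")),
                     DPB1 = list(c("04:01", "17:01")))
  em <- em_fit(tab)
  expect_equal(sort(em$haplotypes$freq), rep(0.25, 4))
  expect_equal(sort(em$configs$prob), c(0.5, 0.5))  # two configs at 0.5
})

test_that("EM is monotone, normalised and reproducible", {
  set.seed(13)
  for (i in 1:10) {
    cfg <- small_config(n = 120, seed = 100 + i)
    tab <- generate_cohort(cfg)$table
    em <- em_fit(tab)
    expect_true(all(diff(em$trace) > -1e-9))
    expect_equal(sum(em$haplotypes$freq), 1, tolerance = 1e-9)
    expect_true(all(em$haplotypes$freq >= 0))
    # per-subject posteriors sum to one
    psum <- as.numeric(tapply(em$configs$prob, em$configs$group, sum))
    expect_equal(psum, rep(1, length(psum)), tolerance = 1e-12)
    expect_true(em$converged)
  }
})

test_that("EM matches the exhaustive likelihood oracle on small instances", {
  set.seed(17)
  for (rep in 1:2) {
    a_alleles <- c("01:03", "02:01", "02:02")
    b_alleles <- c("04:01", "17:01", "01:01")
    hf <- matrix(rexp(9), 3)
    hf <- hf / sum(hf)
    haps <- as.vector(outer(a_alleles, b_alleles, paste, sep = "~"))
    draw <- function() sample(haps, 2, replace = TRUE, prob = as.vector(hf))
    pairs <- replicate(50, draw(), simplify = FALSE)
    sides <- function(k, i) vapply(strsplit(vapply(pairs, `[`,
      character(1), k), "~"), `[`, character(1), i)
    tab <- make_cohort(status = rep(c("case", "control"), 25),
                       DPA1 = lapply(seq_len(50), function(j)
                         c(sides(1, 1)[j], sides(2, 1)[j])),
                       DPB1 = lapply(seq_len(50), function(j)
                         c(sides(1, 2)[j], sides(2, 2)[j])))
    em <- em_fit(tab, tol = 1e-12)
    oracle <- em_oracle(tab$DPA1_1, tab$DPA1_2, tab$DPB1_1, tab$DPB1_2,
                        seed = 1000 + rep)
    f_em <- setNames(em$haplotypes$freq,
                     paste(em$haplotypes$a, em$haplotypes$b, sep = "~"))
    for (h in oracle$hap)
      expect_equal(unname(f_em[h]), oracle$freq[oracle$hap == h],
                   tolerance = 1e-4)
  }
})

test_that("EM agrees with direct counting when phase is nearly unambiguous", {
  # >= 95% of subjects homozygous at one locus
  set.seed(23)
  n <- 300
  a_hom <- sample(c("01:03", "02:01"), n, replace = TRUE, prob = c(.7, .3))
  b1 <- sample(c("04:01", "17:01", "01:01"), n, replace = TRUE)
  b2 <- sample(c("04:01", "17:01", "01:01"), n, replace = TRUE)
  amb <- seq_len(n) <= 10   # ~3% double heterozygotes
  a2 <- ifelse(amb, ifelse(a_hom == "01:03", "02:01", "01:03"), a_hom)
  tab <- make_cohort(status = rep(c("case", "control"), n / 2),
                     DPA1 = lapply(seq_len(n), function(i)
                       c(a_hom[i], a2[i])),
                     DPB1 = lapply(seq_len(n), function(i) c(b1[i], b2[i])))
  em <- em_fit(tab)
  direct <- direct_count_frequencies(tab)
  key <- paste(direct$a, direct$b, sep = "~")
  f_em <- setNames(em$haplotypes$freq,
                   paste(em$haplotypes$a, em$haplotypes$b, sep = "~"))
  for (i in seq_along(key))
    expect_lt(abs(unname(f_em[key[i]]) - direct$freq[i]), 0.005)
})

test_that("haplotype 2x2 tests reproduce hand-computed statistics", {
  # cases: 100 chromosomes, 20 carrying H; controls: 100 chromosomes, 40
  tab <- make_cohort(
    status = c(rep("case", 50), rep("control", 50)),
    DPA1 = rep_pairs(list(c("01:03", "01:03"), c("02:01", "02:01"),
                          c("01:03", "01:03"), c("02:01", "02:01")),
                     c(10, 40, 20, 30)),
    DPB1 = rep_pairs(list(c("04:01", "04:01"), c("17:01", "17:01"),
                          c("04:01", "04:01"), c("17:01", "17:01")),
                     c(10, 40, 20, 30)))
  em <- em_fit(tab)
  ht <- haplotype_test(em, tab)
  row <- ht[ht$haplotype == "DPA1*01:03~DPB1*04:01", ]
  expect_equal(row$case_count, 20, tolerance = 1e-9)
  expect_equal(row$control_count, 40, tolerance = 1e-9)
  expect_equal(row$or., 0.375, tolerance = 1e-9)
  expect_equal(row$chisq, 200 * (20 * 60 - 80 * 40)^2 /
                 (100 * 100 * 60 * 140), tolerance = 1e-9)
  expect_equal(row$p, pchisq(row$chisq, 1, lower.tail = FALSE))
})

test_that("rare haplotypes are pooled into a binned pseudo-haplotype", {
  tab <- make_cohort(
    status = rep(c("case", "control"), 30),
    DPA1 = rep_pairs(list(c("01:03", "01:03"), c("02:01", "02:01"),
                          c("02:02", "02:02")), c(28, 28, 4)),
    DPB1 = rep_pairs(list(c("04:01", "04:01"), c("17:01", "17:01"),
                          c("01:01", "01:01")), c(28, 28, 4)))
  em <- em_fit(tab)
  ht <- haplotype_test(em, tab, min_expected = 5)
  expect_true("binned" %in% ht$haplotype)
  expect_false("DPA1*02:02~DPB1*01:01" %in% ht$haplotype)
})
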