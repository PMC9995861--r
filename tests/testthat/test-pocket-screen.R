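test_that("the opposing screen partitions by direction at p < alpha", {
  res <- data.frame(
    feature = c("DPA1*01:03", "DPA1*02:01", "DPA1*02:02", "DPA1*03:01"),
    or. = c(0.60, 1.49, 1.78, 2.05),
    p = c(5.92e-07, 0.00137, 0.00284, 0.0240))
  sets <- opposing_screen(res)
  expect_equal(sets$protective$feature, "DPA1*01:03")
  expect_equal(sort(sets$susceptible$feature),
               c("DPA1*02:01", "DPA1*02:02", "DPA1*03:01"))

  null_res <- transform(res, p = 0.5)
  sets <- opposing_screen(null_res)
  expect_equal(nrow(sets$protective), 0)
  expect_equal(nrow(sets$susceptible), 0)

  planted <- data.frame(feature = c("a", "b", "c", "d"),
                        or. = c(0.5, 2, 0.9, 1.2),
                        p = c(0.01, 0.01, 0.2, 0.04))
  sets <- opposing_screen(planted)
  expect_equal(sets$protective$feature, "a")
  expect_equal(sort(sets$susceptible$feature), c("b", "d"))
})

test_that("candidate residues carry their pocket annotations", {
  reg <- hla_registry()
  beta <- candidate_residues(reg, "04:01", c("06:01", "18:01", "104:01"),
                             "beta")
  expect_equal(beta$position, c(9, 11, 36, 55, 65, 69, 76, 84))
  ann <- setNames(beta$pockets, beta$position)
  expect_equal(unname(ann["84"]), "P1")
  expect_equal(unname(ann["76"]), "P2,P4")
  expect_true(grepl("P4", ann["69"]) && grepl("P7", ann["69"]))
  expect_equal(unname(ann["65"]), "P7")
  expect_equal(unname(ann["11"]), "P6")
  expect_true(all(c("9", "36", "55") %in% names(ann)) &&
                all(ann[c("9", "36", "55")] == "P9"))

  alpha <- candidate_residues(reg, "01:03", c("02:01", "02:02", "03:01"),
                              "alpha")
  ann <- setNames(alpha$pockets, alpha$position)
  expect_equal(unname(ann["31"]), "P1")
  expect_equal(unname(ann["11"]), "P6")
  expect_equal(unname(ann["66"]), "P6")

  # groups that differ at no pocket position yield an empty frame
  toy <- toy_registry()
  none <- candidate_residues(toy, "01:01", "01:01", "beta", positions = 1:3)
  expect_equal(nrow(none), 0)
})

test_that("combination specs parse the compact grammar", {
  spec <- parse_combo("a31:M + b84:G|V")
  expect_length(spec$terms, 2)
  expect_equal(spec$terms[[1]]$chain, "alpha")
  expect_equal(spec$terms[[1]]$position, 31)
  expect_equal(spec$terms[[2]]$residues, c("G", "V"))
  # case-insensitive
  spec2 <- parse_combo("A31:m + B84:g|v")
  expect_equal(spec2$label, spec$label)
  expect_error(parse_combo("x31:M"), "cannot parse")
  expect_equal(nrow(default_combo_specs()), 10)
})

test_that("combination dosages follow cis phase posteriors", {
  reg <- hla_registry()
  # unambiguous homozygote: two qualifying cis haplotypes
  tab <- make_cohort(status = c("case", "control"),
                     DPA1 = list(c("01:03", "01:03"), c("02:01", "02:01")),
                     DPB1 = list(c("04:01", "04:01"), c("17:01", "17:01")))
  em <- em_fit(tab)
  d <- combo_dosage(tab, "a31:M + b84:G|V", reg, em)
  expect_equal(unname(d), c(2, 0))

  # phase-ambiguous double heterozygote at a symmetric posterior: only the
  # configuration pairing 01:03 with 04:01 carries a qualifying haplotype,
  # so the expected dosage is 0.5 * 1
  tab2 <- make_cohort(
    status = rep(c("case", "control"), c(3, 2)),
    DPA1 = list(c("01:03", "02:01"), c("01:03", "01:03"),
                c("02:01", "02:01"), c("01:03", "01:03"),
                c("02:01", "02:01")),
    DPB1 = list(c("04:01", "17:01"), c("04:01", "04:01"),
                c("17:01", "17:01"), c("17:01", "17:01"),
                c("04:01", "04:01")))
  em2 <- em_fit(tab2)
  # the four haplotypes are equifrequent, so the double-het's posterior is
  # 0.5/0.5
  cfgs <- em2$configs[em2$configs$group == em2$subjects$group[1], ]
  expect_equal(sort(cfgs$prob), c(0.5, 0.5), tolerance = 1e-6)
  d2 <- combo_dosage(tab2, "a31:M + b84:G|V", reg, em2)
  expect_equal(unname(d2[1]), 0.5, tolerance = 1e-6)

  # nobody satisfies beta84 G/V
  tab3 <- make_cohort(status = c("case", "control"),
                      DPA1 = list(c("01:03", "01:03"), c("01:03", "01:03")),
                      DPB1 = list(c("17:01", "17:01"), c("01:01", "01:01")))
  em3 <- em_fit(tab3)
  expect_equal(unname(combo_dosage(tab3, "a31:M + b84:G|V", reg, em3)),
               c(0, 0))
  expect_error(combo_association(tab3, "a31:M + b84:G|V", reg, em3),
               "constant dosage")
})

test_that("a conjunction never exceeds its single-term dosages", {
  reg <- hla_registry()
  cfg <- small_config(n = 150, seed = 77)
  tab <- generate_cohort(cfg)$table
  em <- em_fit(tab)
  combo <- combo_dosage(tab, "a31:M + b84:G|V", reg, em)
  d_a <- combo_dosage(tab, "a31:M", reg, em)
  d_b <- combo_dosage(tab, "b84:G|V", reg, em)
  expect_true(all(combo <= pmin(d_a, d_b) + 1e-9))
  expect_true(all(combo >= -1e-12 & combo <= 2 + 1e-12))
})

test_that("summed expected combo dosage equals the EM-expected mass", {
  reg <- hla_registry()
  cfg <- small_config(n = 200, seed = 78)
  tab <- generate_cohort(cfg)$table
  em <- em_fit(tab)
  spec <- parse_combo("a31:M + b84:G|V")
  qual <- hlapocket:::satisfies_chain(reg, em$haplotypes$a, spec, "alpha") &
    hlapocket:::satisfies_chain(reg, em$haplotypes$b, spec, "beta")
  d <- combo_dosage(tab, spec, reg, em)
  counts <- hlapocket:::em_expected_counts(em)
  expect_equal(sum(d, na.rm = TRUE), sum(counts[qual]), tolerance = 1e-6)
  # and, at convergence, the EM frequencies carry the same mass
  expect_equal(sum(d, na.rm = TRUE),
               2 * em$n_subjects * sum(em$haplotypes$freq[qual]),
               tolerance = 1e-4)
})

test_that("the independent-pairing sensitivity mode matches its formula", {
  reg <- hla_registry()
  tab <- make_cohort(status = c("case", "control"),
                     DPA1 = list(c("01:03", "02:01"), c("01:03", "01:03")),
                     DPB1 = list(c("04:01", "17:01"), c("04:01", "04:01")))
  d <- combo_dosage(tab, "a31:M + b84:G|V", reg, mode = "independent")
  expect_equal(unname(d), c(1 * 1 / 2, 2 * 2 / 2))
})
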