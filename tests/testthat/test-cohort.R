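csv_text <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("cohort CSVs parse, normalise prefixes and reject bad input", {
  f <- csv_text(c(
    "subject_id,status,stratum,DPA1_1,DPA1_2,DPB1_1,DPB1_2",
    "s1,case,White,01:03,02:01,DPB1*04:01,17:01",
    "s2,control,Black,01:03,01:03,04:01:01:24,02:01",
    "s3,case,White,02:02,03:01,01:01,18:01"))
  tab <- read_cohort(f)
  expect_s3_class(tab, "hla_cohort")
  expect_equal(nrow(tab), 3)
  expect_equal(cohort_genes(tab), c("DPA1", "DPB1"))
  # prefix stripped, higher fields truncated, pairs stored sorted
  expect_equal(tab$DPB1_1[1], "04:01")
  expect_equal(tab$DPB1_2[1], "17:01")
  expect_equal(tab$DPB1_1[2], "02:01")  # sorted ahead of 04:01

  dup <- csv_text(c("subject_id,status,DPB1_1,DPB1_2",
                    "s1,case,04:01,04:01", "s1,control,01:01,01:01"))
  expect_error(read_cohort(dup), "duplicate subject_id")

  nocol <- csv_text(c("subject_id,DPB1_1,DPB1_2", "s1,04:01,04:01"))
  expect_error(read_cohort(nocol), "status")

  bad <- csv_text(c("subject_id,status,DPB1_1,DPB1_2",
                    "s1,case,04:01,04:01", "s2,control,junk*04,01:01"))
  expect_error(read_cohort(bad), "row 2, DPB1")
})

test_that("a half-typed gene is treated as missing, not a half-genotype", {
  f <- csv_text(c("subject_id,status,DPA1_1,DPA1_2,DPB1_1,DPB1_2",
                  "s1,case,01:03,02:01,04:01,",
                  "s2,control,01:03,01:03,04:01,04:01"))
  tab <- read_cohort(f)
  expect_true(is.na(tab$DPB1_1[1]) && is.na(tab$DPB1_2[1]))
  expect_false(is.na(tab$DPA1_1[1]))
  # the subject is excluded from DPB1 counts only
  cc <- chromosome_counts(tab, "DPB1")
  expect_equal(attr(cc, "n_chromosomes"), 2L)
  cc <- chromosome_counts(tab, "DPA1")
  expect_equal(attr(cc, "n_chromosomes"), 4L)
})

test_that("cohort tables round-trip through write_cohort", {
  f <- csv_text(c("subject_id,status,stratum,DPB1_1,DPB1_2",
                  "s1,case,White,04:01,17:01",
                  "s2,control,Black,,",
                  "s3,control,White,01:01,04:01"))
  tab <- read_cohort(f)
  f2 <- tempfile(fileext = ".csv")
  write_cohort(tab, f2)
  tab2 <- read_cohort(f2)
  expect_equal(as.data.frame(tab), as.data.frame(tab2))
})

test_that("chromosome counts follow the two-per-subject rule and filters", {
  tab <- make_cohort(status = c("case", "control"),
                     DPB1 = list(c("04:01", "04:01"), c("02:01", "04:01")))
  cc <- chromosome_counts(tab, "DPB1")
  expect_equal(cc[["04:01"]], 3L)
  expect_equal(cc[["02:01"]], 1L)
  expect_equal(sum(cc), attr(cc, "n_chromosomes"))
  ctrl <- chromosome_counts(tab, "DPB1", status = "control")
  expect_equal(ctrl[["04:01"]], 1L)
  expect_equal(ctrl[["02:01"]], 1L)
})

test_that("chromosome counts agree with the generator's truth ledger", {
  cfg <- small_config(n = 200, seed = 9)
  cfg$missingness <- numeric(0)
  gen <- generate_cohort(cfg)
  hap_b <- vapply(strsplit(c(gen$truth$hap1, gen$truth$hap2), "~"),
                  `[`, character(1), 2)
  ledger <- table(hap_b)
  cc <- chromosome_counts(gen$table, "DPB1")
  for (a in names(ledger))
    expect_equal(cc[[a]], as.integer(ledger[[a]]))
  expect_equal(attr(cc, "n_chromosomes"), 2L * cfg$n_subjects)
})

test_that("dosage helpers agree with manual counting", {
  reg <- hla_registry()
  tab <- make_cohort(status = c("case", "control", "case"),
                     DPB1 = list(c("04:01", "17:01"), c("04:01", "04:01"),
                                 c("01:01", "03:01")))
  expect_equal(allele_dosage(tab, "DPB1", "04:01"), c(1, 2, 0))
  # beta84 D carriers: 17:01, 01:01, 03:01
  expect_equal(residue_dosage(tab, reg, "beta", 84, "D"), c(1, 0, 2))
  # rs9277534 G: 01:01 and 03:01 only
  expect_equal(snp_dosage(tab, reg, "G"), c(0, 0, 2))
  # TCE group 1 = 17:01 here
  expect_equal(tce_dosage(tab, reg, 1), c(1, 0, 0))
})
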