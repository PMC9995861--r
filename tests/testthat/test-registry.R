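test_that("allele names parse to two-field resolution", {
  a <- parse_allele("DPA1*01:03")
  expect_equal(a$gene, "DPA1")
  expect_equal(a$name, "01:03")
  expect_equal(parse_allele("DPB1*04:01:01:24")$name, "04:01")
  expect_equal(parse_allele("DRB1*15:01:01:02N")$name, "15:01")
  expect_equal(parse_allele("DPB1*04:01N")$name, "04:01")
  expect_equal(parse_allele("04:01", gene = "DPB1")$name, "04:01")
  expect_equal(format(parse_allele("DQB1*03:19")), "DQB1*03:19")
  expect_error(parse_allele("DPZ9*01:01"), "unknown gene 'DPZ9'")
  expect_error(parse_allele("DPB1*04"), "fewer than two fields")
  expect_error(parse_allele("DPB1*xx:yy"), "malformed")
  expect_error(parse_allele("04:01"), "no gene")
})

test_that("residue lookups reproduce the printed classifications", {
  reg <- hla_registry()
  expect_equal(residue_at(reg, "DPB1*04:01", "beta", 84), "G")
  expect_equal(residue_at(reg, "DPB1*17:01", "beta", 84), "D")
  expect_equal(residue_at(reg, "DPB1*04:01", "beta", 96), "R")
  expect_equal(residue_at(reg, "DPB1*18:01", "beta", 84), "V")
  expect_equal(residue_at(reg, "DPA1*01:03", "alpha", 31), "M")
  expect_equal(residue_at(reg, "DPA1*02:01", "alpha", 31), "Q")
  expect_error(residue_at(reg, "DPB1*999:99", "beta", 84), "no residue")
  expect_error(residue_at(reg, "DPB1*04:01", "beta", 500), "no residue")
})

test_that("pocket position sets match the pocket table, including empties", {
  reg <- hla_registry()
  expect_equal(pocket_positions(reg, "P1", "beta"), c(80, 83, 84))
  expect_equal(pocket_positions(reg, "P1", "alpha"),
               c(24, 31, 32, 43, 52, 53, 54, 55))
  expect_equal(pocket_positions(reg, "P6", "alpha"), c(11, 62, 65, 66))
  expect_equal(pocket_positions(reg, "P9", "beta"), c(9, 28, 35, 36, 55, 59))
  expect_length(pocket_positions(reg, "P5", "alpha"), 0)
  expect_length(pocket_positions(reg, "P3", "beta"), 0)
  expect_length(pocket_positions(reg, "P8", "beta"), 0)
  expect_error(pocket_positions(reg, "P10", "beta"), "unknown pocket")
  # the beta pocket union carries every screened beta position
  all_beta <- unique(reg$pockets$position[reg$pockets$chain == "beta"])
  expect_true(all(c(9, 11, 36, 55, 65, 69, 76, 84) %in% all_beta))
})

test_that("registry tables round-trip through serialisation", {
  reg <- hla_registry()
  f <- tempfile(fileext = ".tsv")
  write_registry_table(reg, "pockets", f)
  reg2 <- hla_registry(pockets = f)
  expect_identical(reg$pockets, reg2$pockets)
  write_registry_table(reg, "residues", f)
  reg3 <- hla_registry(residues = f)
  expect_identical(reg$residues, reg3$residues)
})

test_that("expression-SNP classes partition the allele universe", {
  reg <- hla_registry()
  expect_equal(infer_expression_snp(reg, "DPB1*04:01"), "A")
  expect_equal(infer_expression_snp(reg, "DPB1*17:01"), "A")
  expect_equal(infer_expression_snp(reg, "DPB1*01:01"), "G")
  expect_equal(infer_expression_snp(reg, "DPB1*03:01"), "G")
  expect_error(infer_expression_snp(reg, "DPB1*999:99"),
               "unknown expression class")
  real <- reg$snp[reg$snp$allele != "99:99", ]
  expect_equal(sum(real$class == "A"), 17)
  expect_equal(sum(real$class == "G"), 27)
  expect_equal(anyDuplicated(reg$snp$allele), 0L)
})

test_that("TCE assignment uses entries first, then the exon-2 signature", {
  reg <- hla_registry()
  expect_equal(tce_assign(reg, "DPB1*17:01"), 1L)
  expect_equal(tce_assign(reg, "DPB1*03:01"), 2L)
  expect_equal(tce_assign(reg, "DPB1*04:01"), 3L)
  # a novel allele sharing 04:01's exon-2 signature inherits its group
  sig <- exon2_signature(reg, "DPB1*04:01")
  expect_equal(tce_assign(reg, "DPB1*999:99", exon2_seq = sig), 3L)
  expect_error(tce_assign(reg, "DPB1*999:99"), "cannot be assigned")
})

test_that("differing residues recover the published 14-position screen", {
  reg <- hla_registry()
  d <- differing_pocket_residues(reg, "04:01",
                                 c("06:01", "18:01", "104:01"), "beta")
  expect_equal(d, c(8, 9, 11, 36, 55, 56, 57, 65, 69, 76, 84, 85, 86, 87))
  da <- differing_pocket_residues(reg, "01:03",
                                  c("02:01", "02:02", "03:01"), "alpha")
  expect_equal(da, c(11, 31, 66))
})

test_that("differing residues: identity, toy fixture, symmetry", {
  reg <- hla_registry()
  grp <- c("04:01", "06:01")
  expect_length(differing_pocket_residues(reg, grp, grp, "beta"), 0)
  # synthetic two-allele registry differing only at position 2
  toy <- toy_registry()
  expect_equal(differing_pocket_residues(toy, "01:01", "02:01", "beta",
                                         positions = 1:3), 2)
  # symmetry over random allele subsets
  set.seed(20)
  alleles <- hla_registry()$snp$allele
  for (i in 1:10) {
    a <- sample(alleles, 3)
    b <- sample(alleles, 4)
    expect_equal(differing_pocket_residues(reg, a, b, "beta"),
                 differing_pocket_residues(reg, b, a, "beta"))
  }
  expect_error(differing_pocket_residues(reg, character(0), "04:01", "beta"),
               "non-empty")
})
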