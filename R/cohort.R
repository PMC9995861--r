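#' Read a cohort genotype table
#'
#' The cohort CSV carries one row per subject: `subject_id`, `status`
#' (`case`/`control`), an optional `stratum` label, and two allele columns
#' per gene (`DPB1_1`, `DPB1_2`, ...).  Allele cells may be bare two-field
#' names or carry the `GENE*` prefix; higher fields are truncated.  A subject
#' with an empty cell at either chromosome of a gene is treated as missing
#' that gene entirely (no half-genotypes), and is excluded only from that
#' gene's analyses.
#'
#' @param path CSV file path.
#' @param genes genes expected in the file; columns present in the file
#'   decide which are actually loaded.
#' @return a data frame of class `hla_cohort` with normalised columns
#'   `subject_id`, `status` (factor case/control), `stratum`, and
#'   `<gene>_1`/`<gene>_2` two-field names; attribute `genes` lists the
#'   loaded genes.
#' @export
read_cohort <- function(path, genes = hla_class2_genes) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  as_cohort(df, genes = genes)
}

#' Build a cohort table from a data frame
#'
#' Validation and normalisation backing [read_cohort()]; usable directly on
#' an in-memory data frame in the same column layout.
#'
#' @param df data frame with the cohort CSV columns.
#' @inheritParams read_cohort
#' @export
as_cohort <- function(df, genes = hla_class2_genes) {
  if (!all(c("subject_id", "status") %in% names(df)))
    stop("cohort table must have 'subject_id' and 'status' columns",
         call. = FALSE)
  if (anyDuplicated(df$subject_id)) {
    dup <- df$subject_id[duplicated(df$subject_id)][1]
    stop(sprintf("duplicate subject_id '%s'", dup), call. = FALSE)
  }
  if (!all(df$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'", call. = FALSE)
  present <- genes[vapply(genes, function(g)
    all(paste0(g, c("_1", "_2")) %in% names(df)), logical(1))]
  if (length(present) == 0)
    stop("no <gene>_1/<gene>_2 column pairs found", call. = FALSE)
  out <- data.frame(subject_id = as.character(df$subject_id),
                    status = factor(df$status, levels = c("control", "case")),
                    stratum = if ("stratum" %in% names(df))
                      as.character(df$stratum) else NA_character_,
                    stringsAsFactors = FALSE)
  for (g in present) {
    a1 <- try_normalize(df[[paste0(g, "_1")]], g)
    a2 <- try_normalize(df[[paste0(g, "_2")]], g)
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_character_
    a2[miss] <- NA_character_
    # unordered pair: store in canonical sorted order (unphased data)
    swap <- !miss & a2 < a1
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    out[[paste0(g, "_1")]] <- a1
    out[[paste0(g, "_2")]] <- a2
  }
  attr(out, "genes") <- present
  class(out) <- c("hla_cohort", "data.frame")
  out
}

# normalisation with row-numbered diagnostics; bare two-field names take a
# vectorised fast path, anything else goes through the full parser
try_normalize <- function(x, gene) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  filled <- !is.na(x) & nzchar(x)
  bare <- filled & grepl("^[0-9]{2,3}:[0-9]{2,3}$", x)
  out[bare] <- x[bare]
  for (i in which(filled & !bare)) {
    out[i] <- tryCatch(parse_allele(x[i], gene = gene)$name,
                       error = function(e)
                         stop(sprintf("row %d, %s: %s", i, gene,
                                      conditionMessage(e)), call. = FALSE))
  }
  out
}

#' Genes loaded in a cohort table
#' @param table an `hla_cohort`.
#' @export
cohort_genes <- function(table) attr(table, "genes")

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: a valid table round-trips identically.
#'
#' @param table an `hla_cohort`.
#' @param path output CSV path.
#' @export
write_cohort <- function(table, path) {
  df <- as.data.frame(table)
  df$status <- as.character(df$status)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# subset helper: rows matching status/stratum filters (NULL = no filter)
filter_subjects <- function(table, status = NULL, stratum = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(status)) keep <- keep & table$status == status
  if (!is.null(stratum)) keep <- keep & !is.na(table$stratum) &
      table$stratum == stratum
  table[keep, , drop = FALSE]
}

#' Chromosome counts per allele
#'
#' Each subject with a non-missing genotype at `gene` contributes two
#' chromosomes; homozygotes contribute both to one allele.  Optional status
#' and stratum filters restrict the subjects counted.
#'
#' @param table an `hla_cohort`.
#' @param gene gene symbol.
#' @param status optional `"case"` or `"control"`.
#' @param stratum optional stratum label.
#' @return named integer vector of chromosome counts with attribute
#'   `n_chromosomes` (the total, `2 x` subjects typed at the gene).
#' @export
chromosome_counts <- function(table, gene, status = NULL, stratum = NULL) {
  stopifnot(gene %in% cohort_genes(table))
  t <- filter_subjects(table, status, stratum)
  a <- c(t[[paste0(gene, "_1")]], t[[paste0(gene, "_2")]])
  a <- a[!is.na(a)]
  counts <- table(a)
  out <- stats::setNames(as.integer(counts), names(counts))
  attr(out, "n_chromosomes") <- length(a)
  out
}

#' Per-subject additive dosage of an allele
#'
#' Number of copies (0/1/2) of `allele` carried at `gene`; `NA` for subjects
#' missing the gene.
#'
#' @inheritParams chromosome_counts
#' @param allele bare two-field name or `GENE*`-prefixed.
#' @export
allele_dosage <- function(table, gene, allele) {
  name <- as_allele_name(allele)
  a1 <- table[[paste0(gene, "_1")]]
  a2 <- table[[paste0(gene, "_2")]]
  out <- (a1 == name) + (a2 == name)
  out  # NA propagates from missing genotypes
}

#' Per-subject dosage of a chain residue feature
#'
#' Number of chromosomes (0/1/2) whose allele at the carrying gene codes one
#' of `residues` at `position` of `chain`.  DPA1 carries alpha-chain
#' features, DPB1 beta-chain features.
#'
#' @inheritParams chromosome_counts
#' @param registry an [hla_registry()].
#' @param chain `"alpha"` or `"beta"`.
#' @param position mature-protein position.
#' @param residues one-letter codes counted as carrying the feature.
#' @export
residue_dosage <- function(table, registry, chain, position, residues) {
  gene <- chain_gene(chain)
  stopifnot(gene %in% cohort_genes(table))
  hit <- function(col) {
    out <- rep(NA, nrow(table))
    ok <- !is.na(col)
    out[ok] <- residues_of(registry, col[ok], chain, position) %in% residues
    out
  }
  hit(table[[paste0(gene, "_1")]]) + hit(table[[paste0(gene, "_2")]])
}

#' Per-subject dosage of an rs9277534 class
#'
#' Number of DPB1 chromosomes whose allele is inferred to carry the `A` or
#' `G` state of the 3' UTR expression SNP.
#'
#' @inheritParams residue_dosage
#' @param class `"A"` (low expression) or `"G"` (high expression).
#' @export
snp_dosage <- function(table, registry, class = c("A", "G")) {
  class <- match.arg(class)
  stopifnot("DPB1" %in% cohort_genes(table))
  hit <- function(col) {
    out <- rep(NA, nrow(table))
    ok <- !is.na(col)
    out[ok] <- expression_classes(registry, col[ok]) == class
    out
  }
  hit(table$DPB1_1) + hit(table$DPB1_2)
}

#' Per-subject dosage of a DPB1 TCE group
#'
#' @inheritParams residue_dosage
#' @param group TCE group 1, 2 or 3.
#' @export
tce_dosage <- function(table, registry, group) {
  stopifnot("DPB1" %in% cohort_genes(table), group %in% 1:3)
  hit <- function(col) {
    out <- rep(NA, nrow(table))
    ok <- !is.na(col)
    out[ok] <- tce_groups(registry, col[ok]) == group
    out
  }
  hit(table$DPB1_1) + hit(table$DPB1_2)
}

# case indicator aligned with the table rows (case = 1, control = 0)
status01 <- function(table) as.integer(table$status == "case")
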