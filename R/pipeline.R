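#' Run the full analysis pipeline on a cohort
#'
#' Executes the stages in their analytic order: allele frequencies with the
#' any-scope retention filter; allele-level additive association per gene
#' and scope; two-locus EM haplotype estimation and chi-squared haplotype
#' tests for DPA1~DPB1 and DQA1~DQB1; the opposing-directionality screen
#' with candidate pocket residues per chain; the targeted pocket-combination
#' association; the inferred rs9277534 expression-SNP association; the
#' residue / expression-SNP LD report; and the TCE-group association.
#' Stages whose genes are absent from the cohort are skipped with a
#' warning (e.g. a DPA1-less cohort still gets every beta-only stage).
#'
#' @param table an `hla_cohort`.
#' @param registry an [hla_registry()].
#' @param freq_threshold allele retention threshold (default 0.05).
#' @param alpha_screen nomination level of the opposing screen.
#' @param combos combination hypotheses (default [default_combo_specs()]).
#' @param combo_mode `"cis"` (EM phase posteriors) or `"independent"`.
#' @return list of class `pipeline_result` with per-stage data frames:
#'   `frequencies`, `retained`, `allele_assoc`, `dp_em`, `dp_haplotypes`,
#'   `dq_em`, `dq_haplotypes`, `screen`, `combo_assoc`, `snp_assoc`,
#'   `ld`, `tce_assoc`.
#' @export
run_pipeline <- function(table, registry = hla_registry(),
                         freq_threshold = 0.05, alpha_screen = 0.05,
                         combos = default_combo_specs(),
                         combo_mode = c("cis", "independent")) {
  combo_mode <- match.arg(combo_mode)
  genes <- cohort_genes(table)
  out <- list()

  out$frequencies <- do.call(rbind, lapply(genes, function(g)
    allele_frequencies(table, g)))
  out$retained <- frequency_filter(out$frequencies, freq_threshold)

  out$allele_assoc <- do.call(rbind, lapply(genes, function(g)
    allele_association(table, g, freq_threshold)))

  if (all(c("DPA1", "DPB1") %in% genes)) {
    out$dp_em <- em_fit(table, "DPA1", "DPB1")
    out$dp_haplotypes <- haplotype_test(out$dp_em, table)
  } else {
    warning("DPA1 or DPB1 absent: DP haplotype stage skipped")
  }
  if (all(c("DQA1", "DQB1") %in% genes)) {
    out$dq_em <- em_fit(table, "DQA1", "DQB1")
    out$dq_haplotypes <- haplotype_test(out$dq_em, table)
  }

  if (all(c("DPA1", "DPB1") %in% genes)) {
    out$screen <- pocket_screen(table, registry, out$dp_em, alpha_screen,
                                freq_threshold)
  } else if ("DPB1" %in% genes) {
    out$screen <- pocket_screen(table, registry, NULL, alpha_screen,
                                freq_threshold)
  }

  if ("DPB1" %in% genes) {
    have_alpha <- "DPA1" %in% genes
    out$combo_assoc <- do.call(rbind, lapply(seq_len(nrow(combos)),
      function(i) {
        if (combos$chains[i] != "beta" && !have_alpha) return(NULL)
        row <- tryCatch(
          combo_association(table, combos$combo[i], registry,
                            em = out$dp_em, mode = combo_mode,
                            family_m = nrow(combos)),
          error = function(e) NULL)
        if (!is.null(row)) row$pocket <- combos$pocket[i]
        row
      }))
    if (!have_alpha)
      warning("DPA1 absent: alpha+beta combinations skipped")
    out$snp_assoc <- snp_association(table, registry)
    out$ld <- ld_report(table, registry)
    out$tce_assoc <- tce_association(table, registry)
  }
  class(out) <- "pipeline_result"
  out
}

#' Write a pipeline result bundle to TSV files
#'
#' One TSV per tabular stage plus a JSON manifest recording the package
#' version, the written files and the stage ordering.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (nm in names(result)) {
    x <- result[[nm]]
    if (inherits(x, "haplo_em")) x <- x$haplotypes
    if (nm == "screen" && !is.null(x)) {
      for (part in c("alpha", "beta")) {
        if (is.null(x[[part]])) next
        f <- file.path(dir, sprintf("screen_%s_candidates.tsv", part))
        utils::write.table(x[[part]], f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files[[sprintf("screen_%s", part)]] <- basename(f)
      }
      next
    }
    if (is.data.frame(x)) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(x, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files[[nm]] <- basename(f)
    } else if (is.character(x)) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      writeLines(x, f)
      files[[nm]] <- basename(f)
    }
  }
  manifest <- list(
    package = "hlapocket",
    version = as.character(utils::packageVersion("hlapocket")),
    stages = names(result), files = files)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}
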