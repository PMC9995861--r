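#' @keywords internal
"_PACKAGE"

#' HLA class II loci handled by the package
#'
#' The five classical class II genes whose two-field genotype calls the
#' cohort table may carry.
#' @export
hla_class2_genes <- c("DRB1", "DQA1", "DQB1", "DPA1", "DPB1")

#' Parse an HLA allele name to two-field resolution
#'
#' Accepts the conventional `GENE*ff:ff[:ff[:ff]][suffix]` nomenclature and
#' truncates it to the two fields that determine the mature protein sequence.
#' Higher fields (synonymous and non-coding variation) and expression
#' suffixes (`N`, `L`, `S`, `C`, `A`, `Q`) are dropped.
#'
#' @param raw allele string, e.g. `"DPB1*04:01:01:24"`.  A bare two-field
#'   name (`"04:01"`) is accepted when `gene` is supplied.
#' @param gene optional gene symbol used when `raw` has no `GENE*` prefix.
#' @return an object of class `hla_allele`: a list with elements `gene` and
#'   `name` (the two-field name, e.g. `"04:01"`).
#' @examples
#' parse_allele("DPA1*01:03")
#' parse_allele("DPB1*04:01:01:24")
#' @export
parse_allele <- function(raw, gene = NULL) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stop("allele must be a single non-empty string", call. = FALSE)
  if (grepl("*", raw, fixed = TRUE)) {
    parts <- strsplit(raw, "*", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("malformed allele string '%s'", raw), call. = FALSE)
    gene <- parts[1]
    body <- parts[2]
  } else {
    body <- raw
  }
  if (is.null(gene))
    stop(sprintf("allele '%s' has no gene prefix and no gene was supplied", raw),
         call. = FALSE)
  if (!gene %in% hla_class2_genes)
    stop(sprintf("unknown gene '%s' in allele '%s'", gene, raw), call. = FALSE)
  fields <- strsplit(body, ":", fixed = TRUE)[[1]]
  if (length(fields) < 2L)
    stop(sprintf("allele '%s' has fewer than two fields", raw), call. = FALSE)
  two <- fields[1:2]
  # an expression suffix may ride on whatever field the name stops at; only a
  # suffix on field 2 can survive truncation
  two[2] <- sub("[NLSCAQ]$", "", two[2])
  if (!all(grepl("^[0-9]{2,3}$", two)))
    stop(sprintf("malformed allele fields in '%s'", raw), call. = FALSE)
  structure(list(gene = gene, name = paste(two, collapse = ":")),
            class = "hla_allele")
}

#' @export
format.hla_allele <- function(x, ...) paste0(x$gene, "*", x$name)

#' @export
print.hla_allele <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Vectorised two-field normalisation for genotype table columns.  Empty cells
# map to NA (missing); malformed cells raise with the offending value.
normalize_allele_names <- function(x, gene) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  filled <- !is.na(x) & nzchar(x)
  out[filled] <- vapply(x[filled],
                        function(v) parse_allele(v, gene = gene)$name,
                        character(1), USE.NAMES = FALSE)
  out
}

allele_label <- function(gene, name) paste0(gene, "*", name)
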