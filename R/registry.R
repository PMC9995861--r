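#' The packaged domain registry
#'
#' All domain knowledge the analysis needs is carried as data: the
#' allele-to-residue map at tracked mature-protein positions of the DP alpha
#' and beta chains, the binding-pocket position sets (P1..P9), the
#' allele-to-rs9277534 expression-SNP classes, and the allele-to-TCE-group
#' classification.  The packaged maps ship as plain-text TSV files under
#' `inst/extdata/` with `#provenance=` and `#coordinate=mature` headers;
#' positions use mature-protein numbering (position 1 is the first residue
#' after the signal peptide).
#'
#' @param residues,pockets,snp,tce optional paths to user-supplied
#'   replacement TSVs in the packaged column layout.
#' @return a list of class `hla_registry` with elements `residues`,
#'   `pockets`, `snp`, `tce` (data frames) plus internal lookup indices.
#' @examples
#' reg <- hla_registry()
#' residue_at(reg, "DPB1*04:01", "beta", 84)
#' @export
hla_registry <- function(residues = NULL, pockets = NULL, snp = NULL,
                         tce = NULL) {
  pkg_file <- function(f) system.file("extdata", f, package = "hlapocket",
                                      mustWork = TRUE)
  read_map <- function(path) {
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  }
  res <- read_map(residues %||% pkg_file("dp_residues_synthetic.tsv"))
  pk  <- read_map(pockets  %||% pkg_file("dp_pockets.tsv"))
  sn  <- read_map(snp      %||% pkg_file("dpb1_rs9277534_synthetic.tsv"))
  tc  <- read_map(tce      %||% pkg_file("dpb1_tce_synthetic.tsv"))
  stopifnot(all(c("gene", "allele", "chain", "position", "residue") %in%
                  names(res)),
            all(c("pocket", "chain", "position") %in% names(pk)),
            all(c("allele", "class") %in% names(sn)),
            all(c("allele", "group") %in% names(tc)))
  if (anyDuplicated(sn$allele))
    stop("expression-SNP map assigns more than one class to an allele")
  if (!all(sn$class %in% c("A", "G")))
    stop("expression-SNP classes must be 'A' or 'G'")
  if (!all(tc$group %in% 1:3))
    stop("TCE groups must be 1, 2 or 3")
  reg <- list(residues = res, pockets = pk, snp = sn, tce = tc)
  reg$res_key <- stats::setNames(
    res$residue, paste(res$gene, res$allele, res$chain, res$position))
  reg$snp_key <- stats::setNames(sn$class, sn$allele)
  reg$tce_key <- stats::setNames(tc$group, tc$allele)
  class(reg) <- "hla_registry"
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# default registry, cached per session
.registry_cache <- new.env(parent = emptyenv())

default_registry <- function() {
  if (is.null(.registry_cache$reg)) .registry_cache$reg <- hla_registry()
  .registry_cache$reg
}

as_allele_name <- function(allele, gene = NULL) {
  if (inherits(allele, "hla_allele")) return(allele$name)
  if (grepl("*", allele, fixed = TRUE)) return(parse_allele(allele)$name)
  allele
}

as_allele_gene <- function(allele, default) {
  if (inherits(allele, "hla_allele")) return(allele$gene)
  if (is.character(allele) && grepl("*", allele, fixed = TRUE))
    return(parse_allele(allele)$gene)
  default
}

chain_gene <- function(chain) if (chain == "alpha") "DPA1" else "DPB1"

#' Look up the residue carried by an allele at a tracked position
#'
#' Deterministic lookup in the registry's residue map; a missing allele or an
#' untracked position is an error, never a silent default.
#'
#' @param registry an [hla_registry()].
#' @param allele an `hla_allele`, a `"GENE*ff:ff"` string, or a bare
#'   two-field name (the gene is then implied by `chain`).
#' @param chain `"alpha"` (DPA1) or `"beta"` (DPB1).
#' @param position integer mature-protein position.
#' @return single one-letter amino-acid code.
#' @export
residue_at <- function(registry, allele, chain = c("beta", "alpha"),
                       position) {
  chain <- match.arg(chain)
  gene <- as_allele_gene(allele, chain_gene(chain))
  name <- as_allele_name(allele)
  key <- paste(gene, name, chain, position)
  hit <- registry$res_key[key]
  if (is.na(hit))
    stop(sprintf("no residue tracked for %s*%s %s position %s",
                 gene, name, chain, position), call. = FALSE)
  unname(hit)
}

# vectorised residue lookup over allele names (no prefix), errors on any gap
residues_of <- function(registry, names, chain, position) {
  gene <- chain_gene(chain)
  keys <- paste(gene, names, chain, position)
  hit <- registry$res_key[keys]
  if (anyNA(hit))
    stop(sprintf("no residue tracked for %s*%s %s position %s",
                 gene, names[which(is.na(hit))[1]], chain, position),
         call. = FALSE)
  unname(hit)
}

#' Positions forming a binding pocket
#'
#' Returns the fixed set of mature-protein positions that a pocket draws from
#' one chain; some pockets have no positions on one chain and return an empty
#' set.
#'
#' @inheritParams residue_at
#' @param pocket one of `"P1"`..`"P9"`.
#' @return sorted integer vector (possibly empty).
#' @export
pocket_positions <- function(registry, pocket, chain = c("beta", "alpha")) {
  chain <- match.arg(chain)
  if (!pocket %in% paste0("P", 1:9))
    stop(sprintf("unknown pocket '%s'", pocket), call. = FALSE)
  sort(registry$pockets$position[registry$pockets$pocket == pocket &
                                   registry$pockets$chain == chain])
}

#' Tracked positions for one chain
#'
#' @inheritParams residue_at
#' @param domain `"binding"` restricts to the membrane-distal domain that
#'   forms the peptide-binding site (mature positions <= 90, the alpha1/beta1
#'   domain); `"all"` returns every tracked position, including exon-3 and
#'   connecting-region positions such as beta 96 and 170.
#' @return sorted integer vector.
#' @export
tracked_positions <- function(registry, chain = c("beta", "alpha"),
                              domain = c("binding", "all")) {
  chain <- match.arg(chain)
  domain <- match.arg(domain)
  pos <- sort(unique(registry$residues$position[
    registry$residues$chain == chain]))
  if (domain == "binding") pos <- pos[pos <= 90] else pos
}

#' Positions at which two allele groups carry different residues
#'
#' For each requested position, the residue sets carried by `group_a` and by
#' `group_b` are compared; the position is reported when the two sets are not
#' identical.  This is the comparison underlying the opposing-directionality
#' residue screen: with a single protective allele against a group of
#' susceptible alleles it returns every position at which some susceptible
#' allele departs from the protective sequence.
#'
#' @inheritParams residue_at
#' @param group_a,group_b character vectors of allele names (bare two-field
#'   or `GENE*`-prefixed).
#' @param positions integer positions to examine; defaults to the chain's
#'   tracked binding-domain positions.
#' @return sorted integer vector of differing positions.
#' @export
differing_pocket_residues <- function(registry, group_a, group_b,
                                      chain = c("beta", "alpha"),
                                      positions = NULL) {
  chain <- match.arg(chain)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both allele groups must be non-empty", call. = FALSE)
  positions <- positions %||% tracked_positions(registry, chain, "binding")
  a <- vapply(group_a, as_allele_name, character(1))
  b <- vapply(group_b, as_allele_name, character(1))
  differs <- vapply(positions, function(p) {
    ra <- unique(residues_of(registry, a, chain, p))
    rb <- unique(residues_of(registry, b, chain, p))
    !setequal(ra, rb)
  }, logical(1))
  sort(positions[differs])
}

#' Infer the rs9277534 expression-SNP class from a DPB1 allele
#'
#' The A/G state of the 3' UTR SNP rs9277534 is in fixed correspondence with
#' the DPB1 allele, so it is inferred deterministically from the genotype
#' call rather than genotyped.  `A` tags low and `G` high DP expression.
#'
#' @inheritParams residue_at
#' @param allele a DPB1 allele.
#' @return `"A"` or `"G"`.
#' @export
infer_expression_snp <- function(registry, allele) {
  name <- as_allele_name(allele)
  hit <- registry$snp_key[name]
  if (is.na(hit))
    stop(sprintf("unknown expression class for DPB1*%s", name), call. = FALSE)
  unname(hit)
}

# vectorised class lookup over bare names; errors on any gap
expression_classes <- function(registry, names) {
  hit <- registry$snp_key[names]
  if (anyNA(hit))
    stop(sprintf("unknown expression class for DPB1*%s",
                 names[which(is.na(hit))[1]]), call. = FALSE)
  unname(hit)
}

#' Exon-2 protein signature of a DPB1 allele
#'
#' Concatenated residues at the tracked binding-domain positions; used as the
#' sequence key for assigning TCE groups to alleles absent from the packaged
#' classification (novel alleles differing only outside exon 2 share this
#' signature with a classified allele).
#'
#' @inheritParams residue_at
#' @export
exon2_signature <- function(registry, allele) {
  name <- as_allele_name(allele)
  pos <- tracked_positions(registry, "beta", "binding")
  paste(vapply(pos, function(p) residues_of(registry, name, "beta", p),
               character(1)), collapse = "")
}

#' Assign a DPB1 allele to its T-cell-epitope (TCE) group
#'
#' Direct lookup in the packaged classification; an allele absent from it can
#' still be assigned through `exon2_seq`, the exon-2 protein signature it
#' shares with a classified allele (novel alleles with novelties outside exon
#' 2 inherit that allele's group).
#'
#' @inheritParams residue_at
#' @param allele a DPB1 allele.
#' @param exon2_seq optional exon-2 protein signature (see
#'   [exon2_signature()]).
#' @return integer group 1, 2 or 3.
#' @export
tce_assign <- function(registry, allele, exon2_seq = NULL) {
  name <- as_allele_name(allele)
  hit <- registry$tce_key[name]
  if (!is.na(hit)) return(unname(hit))
  if (!is.null(exon2_seq)) {
    sigs <- vapply(registry$tce$allele,
                   function(a) exon2_signature(registry, a), character(1))
    m <- match(exon2_seq, sigs)
    if (!is.na(m)) return(registry$tce$group[m])
  }
  stop(sprintf("DPB1*%s cannot be assigned a TCE group", name), call. = FALSE)
}

# vectorised TCE lookup over bare names (entries only)
tce_groups <- function(registry, names) {
  hit <- registry$tce_key[names]
  if (anyNA(hit))
    stop(sprintf("DPB1*%s cannot be assigned a TCE group",
                 names[which(is.na(hit))[1]]), call. = FALSE)
  unname(hit)
}

#' Write registry mapping tables back to TSV
#'
#' Serialises one registry component in the packaged column layout with its
#' provenance header, so user-supplied updates round-trip through
#' [hla_registry()].
#'
#' @inheritParams residue_at
#' @param component one of `"residues"`, `"pockets"`, `"snp"`, `"tce"`.
#' @param path output file.
#' @param provenance header text recorded in the file.
#' @export
write_registry_table <- function(registry, component, path,
                                 provenance = "user-supplied") {
  df <- registry[[match.arg(component,
                            c("residues", "pockets", "snp", "tce"))]]
  writeLines(c(paste0("#provenance=", provenance), "#coordinate=mature"),
             path)
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}
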