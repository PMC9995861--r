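#' Opposing-directionality screen
#'
#' Candidate discovery step: among features (alleles or haplotypes) with an
#' uncorrected p-value below `alpha_screen`, partition into a protective set
#' (OR < 1) and a susceptible set (OR > 1).  The screen deliberately uses
#' the uncorrected level — it nominates candidates for the targeted pocket
#' analysis, whose own correction family is the number of combinations
#' actually tested.
#'
#' @param results data frame with at least `feature`, `or.` and `p` columns
#'   (e.g. from [fit_additive()] or [haplotype_test()] with its `haplotype`
#'   column renamed, or any mix).
#' @param alpha_screen nomination level (default 0.05, uncorrected).
#' @return list of class `directionality_sets` with data frames
#'   `protective` and `susceptible` (disjoint by construction).
#' @export
opposing_screen <- function(results, alpha_screen = 0.05) {
  if ("haplotype" %in% names(results) && !"feature" %in% names(results))
    names(results)[names(results) == "haplotype"] <- "feature"
  sig <- !is.na(results$p) & results$p < alpha_screen &
    is.finite(results$or.)
  structure(list(
    protective = results[sig & results$or. < 1, , drop = FALSE],
    susceptible = results[sig & results$or. > 1, , drop = FALSE],
    alpha_screen = alpha_screen), class = "directionality_sets")
}

# alleles of `gene` implicated by a directionality set: bare allele features
# of that gene plus that gene's side of any A1~B1 haplotype features
implicated_alleles <- function(features, gene) {
  out <- character(0)
  for (f in features) {
    parts <- strsplit(f, "~", fixed = TRUE)[[1]]
    for (p in parts) {
      if (startsWith(p, paste0(gene, "*")))
        out <- c(out, sub("^[A-Z0-9]+\\*", "", p))
    }
  }
  sort(unique(out))
}

#' Candidate pocket residues from opposing allele groups
#'
#' Runs [differing_pocket_residues()] between the protective and susceptible
#' allele groups of one chain, keeps the positions that participate in a
#' binding pocket, and annotates each with its pocket(s) and the residues
#' carried by either group.  A position belonging to several pockets is
#' reported with all of them.
#'
#' @param registry an [hla_registry()].
#' @param protective,susceptible character vectors of allele names for the
#'   chain's gene; both must be non-empty.
#' @param chain `"alpha"` or `"beta"`.
#' @param positions positions to screen (default: tracked binding-domain
#'   positions of the chain).
#' @return data frame: `position`, `pockets` (comma-separated), `chain`,
#'   `protective_residues`, `susceptible_residues`.
#' @export
candidate_residues <- function(registry, protective, susceptible,
                               chain = c("beta", "alpha"),
                               positions = NULL) {
  chain <- match.arg(chain)
  diffs <- differing_pocket_residues(registry, protective, susceptible,
                                     chain, positions)
  pk <- registry$pockets[registry$pockets$chain == chain, ]
  in_pocket <- diffs[diffs %in% pk$position]
  if (length(in_pocket) == 0)
    return(data.frame(position = integer(0), pockets = character(0),
                      chain = character(0),
                      protective_residues = character(0),
                      susceptible_residues = character(0),
                      stringsAsFactors = FALSE))
  prot <- vapply(protective, as_allele_name, character(1))
  susc <- vapply(susceptible, as_allele_name, character(1))
  do.call(rbind, lapply(in_pocket, function(p) {
    data.frame(
      position = p,
      pockets = paste(sort(unique(pk$pocket[pk$position == p])),
                      collapse = ","),
      chain = chain,
      protective_residues = paste(
        sort(unique(residues_of(registry, prot, chain, p))), collapse = ","),
      susceptible_residues = paste(
        sort(unique(residues_of(registry, susc, chain, p))), collapse = ","),
      stringsAsFactors = FALSE)
  }))
}

#' Parse a pocket-combination specification
#'
#' Compact grammar: terms joined by `+` are required conjunctively; within a
#' term, `|` lists alternative residues.  A term is `a<pos>:<residues>` for
#' the alpha chain or `b<pos>:<residues>` for the beta chain, e.g.
#' `"a31:M + b84:G|V"` (case-insensitive).
#'
#' @param text specification string.
#' @return object of class `combo_spec`: list with `terms` (each a list
#'   `chain`, `position`, `residues`) and the normalised `label`.
#' @export
parse_combo <- function(text) {
  raw <- strsplit(text, "+", fixed = TRUE)[[1]]
  terms <- lapply(raw, function(t) {
    t <- gsub(" ", "", t)
    m <- regmatches(t, regexec("^([abAB])([0-9]+):([A-Za-z|]+)$", t))[[1]]
    if (length(m) == 0)
      stop(sprintf("cannot parse combination term '%s'", t), call. = FALSE)
    list(chain = if (tolower(m[2]) == "a") "alpha" else "beta",
         position = as.integer(m[3]),
         residues = toupper(strsplit(m[4], "|", fixed = TRUE)[[1]]))
  })
  if (length(terms) == 0) stop("empty combination", call. = FALSE)
  label <- paste(vapply(terms, function(t)
    sprintf("%s%d:%s", substr(t$chain, 1, 1), t$position,
            paste(t$residues, collapse = "|")), character(1)),
    collapse = " + ")
  structure(list(terms = terms, label = label), class = "combo_spec")
}

#' @export
format.combo_spec <- function(x, ...) x$label

#' @export
print.combo_spec <- function(x, ...) {
  cat("<combo_spec>", x$label, "\n")
  invisible(x)
}

combo_chains <- function(spec)
  unique(vapply(spec$terms, `[[`, character(1), "chain"))

# does allele `name` (of the chain's gene) satisfy every term on `chain`?
satisfies_chain <- function(registry, names, spec, chain) {
  terms <- Filter(function(t) t$chain == chain, spec$terms)
  out <- rep(TRUE, length(names))
  for (t in terms)
    out <- out & residues_of(registry, names, chain, t$position) %in%
      t$residues
  out
}

#' The targeted pocket-combination hypotheses
#'
#' The ten predetermined alpha/beta residue combinations examined in the
#' pocket analysis: protective and susceptible arms of P1 (alpha31 +
#' beta84), P6 (alpha11 + beta11), and the beta-only P9 (beta36 + beta55),
#' P7 (beta65 + beta69) and P4 (beta69 + beta76) pairs.
#'
#' @return data frame with `pocket`, `combo` (specification string) and
#'   `chains`.
#' @export
default_combo_specs <- function() {
  data.frame(
    pocket = c("P1", "P1", "P6", "P6", "P9", "P9", "P7", "P7", "P4", "P4"),
    combo = c("a31:M + b84:G|V", "a31:Q + b84:D",
              "a11:A + b11:G",   "a11:M + b11:L",
              "b36:A + b55:A",   "b36:V + b55:D",
              "b65:I + b69:K",   "b65:L + b69:E",
              "b69:K + b76:M",   "b69:E + b76:V|I"),
    chains = c("alpha+beta", "alpha+beta", "alpha+beta", "alpha+beta",
               "beta", "beta", "beta", "beta", "beta", "beta"),
    stringsAsFactors = FALSE)
}

#' Per-subject dosage of a pocket combination
#'
#' For a beta-only combination the dosage is the number of DPB1 alleles
#' (0/1/2) satisfying every beta term.  For an alpha+beta combination the
#' combination must ride one chromosome: the dosage is the expected number
#' of cis DPA1~DPB1 haplotypes whose alpha allele satisfies the alpha terms
#' and whose beta allele satisfies the beta terms, taken under the
#' subject's EM phase posterior (`mode = "cis"`, the default).  The
#' `"independent"` sensitivity mode ignores phase and pairs the two chains'
#' satisfying allele counts at random (`n_alpha * n_beta / 2`).
#'
#' @param table an `hla_cohort`.
#' @param spec a [parse_combo()] result or specification string.
#' @param registry an [hla_registry()].
#' @param em a DPA1~DPB1 [em_fit()] (required for alpha+beta specs in cis
#'   mode).
#' @param mode `"cis"` or `"independent"`.
#' @return named numeric vector aligned with `table` rows (`NA` where a
#'   required genotype is missing), values in \[0, 2\].
#' @export
combo_dosage <- function(table, spec, registry, em = NULL,
                         mode = c("cis", "independent")) {
  mode <- match.arg(mode)
  if (is.character(spec)) spec <- parse_combo(spec)
  chains <- combo_chains(spec)
  beta_only <- identical(chains, "beta")
  out <- rep(NA_real_, nrow(table))
  names(out) <- table$subject_id
  if (beta_only) {
    b1 <- table$DPB1_1; b2 <- table$DPB1_2
    ok <- !is.na(b1)
    out[ok] <- satisfies_chain(registry, b1[ok], spec, "beta") +
      satisfies_chain(registry, b2[ok], spec, "beta")
    return(out)
  }
  if (identical(chains, "alpha")) {
    a1 <- table$DPA1_1; a2 <- table$DPA1_2
    ok <- !is.na(a1)
    out[ok] <- satisfies_chain(registry, a1[ok], spec, "alpha") +
      satisfies_chain(registry, a2[ok], spec, "alpha")
    return(out)
  }
  if (mode == "independent") {
    a1 <- table$DPA1_1; a2 <- table$DPA1_2
    b1 <- table$DPB1_1; b2 <- table$DPB1_2
    ok <- !is.na(a1) & !is.na(b1)
    na_ <- satisfies_chain(registry, a1[ok], spec, "alpha") +
      satisfies_chain(registry, a2[ok], spec, "alpha")
    nb <- satisfies_chain(registry, b1[ok], spec, "beta") +
      satisfies_chain(registry, b2[ok], spec, "beta")
    out[ok] <- na_ * nb / 2
    return(out)
  }
  if (is.null(em))
    stop("alpha+beta combinations in cis mode need a DPA1~DPB1 EM fit",
         call. = FALSE)
  qual <- satisfies_chain(registry, em$haplotypes$a, spec, "alpha") &
    satisfies_chain(registry, em$haplotypes$b, spec, "beta")
  dos <- em_expected_dosage(em, qual)
  out[match(names(dos), table$subject_id)] <- dos
  out
}

#' Association of a pocket combination with case status
#'
#' [fit_additive()] on the [combo_dosage()] vector; the Bonferroni family
#' size is the number of combination hypotheses tested together.
#'
#' @inheritParams combo_dosage
#' @param family_m number of combinations in the testing family (default
#'   10, the full targeted set).
#' @param alpha family-wise level.
#' @return one-row data frame from [fit_additive()] plus `bonferroni_m` and
#'   `threshold`.
#' @export
combo_association <- function(table, spec, registry, em = NULL,
                              mode = c("cis", "independent"),
                              family_m = 10, alpha = 0.05) {
  if (is.character(spec)) spec <- parse_combo(spec)
  d <- combo_dosage(table, spec, registry, em, mode)
  fam <- bonferroni_family(family_m, alpha)
  row <- fit_additive(d, table$status, feature = spec$label)
  row$bonferroni_m <- fam$m
  row$threshold <- fam$threshold
  row
}

#' The full discovery screen for one cohort
#'
#' Runs allele association for DPA1 and DPB1 (and the DPA1~DPB1 haplotype
#' tests when `em` is given), applies the opposing-directionality screen,
#' and derives candidate pocket residues per chain.
#'
#' @inheritParams combo_dosage
#' @param alpha_screen nomination level for [opposing_screen()].
#' @param freq_threshold allele-frequency retention threshold.
#' @return list with `sets` (per-gene directionality sets over full-cohort
#'   results), `alpha` and `beta` candidate-residue data frames (NULL when
#'   a side of the screen is empty).
#' @export
pocket_screen <- function(table, registry, em = NULL, alpha_screen = 0.05,
                          freq_threshold = 0.05) {
  dp_genes <- intersect(c("DPA1", "DPB1"), cohort_genes(table))
  res <- do.call(rbind, lapply(dp_genes, function(g)
    allele_association(table, g, freq_threshold)[
      , c("feature", "or.", "p", "scope")]))
  res <- res[res$scope == "all", ]
  if (!is.null(em)) {
    ht <- haplotype_test(em, table)
    ht <- ht[!ht$binned, ]
    res <- rbind(res, data.frame(feature = ht$haplotype, or. = ht$or.,
                                 p = ht$p, scope = "all",
                                 stringsAsFactors = FALSE))
  }
  sets <- opposing_screen(res, alpha_screen)
  out <- list(sets = sets, alpha = NULL, beta = NULL)
  for (ch in c("alpha", "beta")) {
    g <- chain_gene(ch)
    prot <- implicated_alleles(sets$protective$feature, g)
    susc <- implicated_alleles(sets$susceptible$feature, g)
    susc <- setdiff(susc, prot)   # an allele cannot sit on both sides
    if (length(prot) && length(susc))
      out[[ch]] <- candidate_residues(registry, prot, susc, ch)
  }
  out
}
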