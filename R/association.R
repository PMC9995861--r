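#' Chromosome-frequency estimate with a Wald interval
#'
#' Allelic and residue frequencies are estimated on the number of
#' chromosomes carrying the feature out of all counted chromosomes, with a
#' normal-approximation (Wald) 95% interval clipped to \[0, 1\].
#'
#' @param count chromosomes carrying the feature.
#' @param total chromosomes counted.
#' @param feature label carried through to the output row.
#' @param conf confidence level (default 0.95).
#' @return one-row data frame: `feature`, `count`, `total`, `freq`,
#'   `ci_lo`, `ci_hi`.
#' @export
frequency_estimate <- function(count, total, feature = NA_character_,
                               conf = 0.95) {
  if (total <= 0) stop("total chromosomes must be positive", call. = FALSE)
  if (count < 0 || count > total)
    stop("count must lie in [0, total]", call. = FALSE)
  p <- count / total
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(p * (1 - p) / total)
  data.frame(feature = feature, count = count, total = total, freq = p,
             ci_lo = max(0, p - half), ci_hi = min(1, p + half),
             stringsAsFactors = FALSE)
}

#' Additive-model logistic association
#'
#' Fits the additive genetic model: disease log-odds linear in the
#' per-subject dosage (0/1/2 copies, or an expected dosage in \[0, 2\] for
#' phase-ambiguous combinations).  The fit is maximum-likelihood logistic
#' regression (binomial IRLS, convergence 1e-10, at most 100 iterations);
#' the per-dosage-unit odds ratio is `exp(slope)` with a Wald 95% interval
#' and two-sided Wald p-value.  Complete or quasi-complete separation is
#' flagged and reported as an infinite (or zero) odds ratio with missing
#' interval, not raised as an error.
#'
#' @param dosage numeric vector in \[0, 2\]; `NA` rows are dropped.
#' @param status case indicator (0/1) or factor with levels control/case,
#'   aligned with `dosage`.
#' @param feature label carried through to the output row.
#' @return one-row data frame: `feature`, `n`, `beta`, `se`, `or.`,
#'   `ci_lo`, `ci_hi`, `p`, `separation`, `unstable`.
#' @export
fit_additive <- function(dosage, status, feature = NA_character_) {
  if (is.factor(status)) status <- as.integer(status == "case")
  keep <- !is.na(dosage) & !is.na(status)
  d <- as.numeric(dosage[keep])
  y <- as.integer(status[keep])
  if (length(unique(y)) < 2)
    stop("both phenotype classes must be present", call. = FALSE)
  if (length(unique(d)) < 2)
    stop(sprintf("constant dosage for feature '%s'", feature), call. = FALSE)
  fit <- suppressWarnings(
    stats::glm(y ~ d, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  b <- unname(stats::coef(fit)[2])
  se <- unname(sqrt(diag(stats::vcov(fit)))[2])
  separation <- !is.finite(b) || abs(b) > 10 || !is.finite(se) || se > 100
  unstable <- !separation && se > 2
  if (separation) {
    or. <- if (b > 0) Inf else 0
    out <- data.frame(feature = feature, n = length(y), beta = b, se = se,
                      or. = or., ci_lo = NA_real_, ci_hi = NA_real_,
                      p = NA_real_, separation = TRUE, unstable = FALSE,
                      stringsAsFactors = FALSE)
    return(out)
  }
  z <- stats::qnorm(0.975)
  data.frame(feature = feature, n = length(y), beta = b, se = se,
             or. = exp(b), ci_lo = exp(b - z * se), ci_hi = exp(b + z * se),
             p = 2 * stats::pnorm(-abs(b / se)),
             separation = FALSE, unstable = unstable,
             stringsAsFactors = FALSE)
}

#' Bonferroni correction family
#'
#' One family per gene (or per targeted hypothesis set): the family-wise
#' level is split evenly over the `m` tests.
#'
#' @param m number of tests in the family.
#' @param alpha family-wise level (default 0.05).
#' @return list with `m`, `alpha` and `threshold = alpha / m`.
#' @export
bonferroni_family <- function(m, alpha = 0.05) {
  if (m < 1) stop("family size must be at least 1", call. = FALSE)
  list(m = m, alpha = alpha, threshold = alpha / m)
}

#' Frequency filter across analysis scopes
#'
#' A feature is retained when its chromosome frequency reaches `threshold`
#' in ANY scope — the full cohort or either stratum — mirroring the
#' disjunctive "full, White sub-cohort, or Black sub-cohort" rule.
#'
#' @param freqs data frame with columns `feature`, `scope`, `freq` (one row
#'   per feature x scope).
#' @param threshold minimum frequency (default 0.05, inclusive).
#' @return character vector of retained feature labels.
#' @export
frequency_filter <- function(freqs, threshold = 0.05) {
  if (nrow(freqs) == 0) return(character(0))
  keep <- tapply(freqs$freq, freqs$feature, function(f) any(f >= threshold))
  sort(names(keep)[keep])
}

#' Pearson correlation of two binary chromosome-level features
#'
#' The phi coefficient of two 0/1 indicators over the same chromosomes.
#'
#' @param x,y 0/1 vectors of equal length, both non-constant.
#' @export
binary_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("constant feature vector", call. = FALSE)
  stats::cor(as.numeric(x), as.numeric(y))
}

#' Per-allele frequency table for a gene across scopes
#'
#' @param table an `hla_cohort`.
#' @param gene gene symbol.
#' @param scopes named list of `list(status=, stratum=)` filters; the
#'   default covers the full cohort and each observed stratum.
#' @return data frame with `feature`, `scope`, `count`, `total`, `freq`,
#'   `ci_lo`, `ci_hi`.
#' @export
allele_frequencies <- function(table, gene, scopes = default_scopes(table)) {
  do.call(rbind, lapply(names(scopes), function(sc) {
    cc <- chromosome_counts(table, gene,
                            status = scopes[[sc]]$status,
                            stratum = scopes[[sc]]$stratum)
    tot <- attr(cc, "n_chromosomes")
    if (tot == 0 || length(cc) == 0) return(NULL)
    out <- do.call(rbind, lapply(names(cc), function(a)
      frequency_estimate(cc[[a]], tot, feature = allele_label(gene, a))))
    out$scope <- sc
    out[, c("feature", "scope", "count", "total", "freq", "ci_lo", "ci_hi")]
  }))
}

default_scopes <- function(table) {
  sc <- list(all = list(status = NULL, stratum = NULL))
  for (s in sort(unique(stats::na.omit(table$stratum))))
    sc[[paste0("stratum:", s)]] <- list(status = NULL, stratum = s)
  sc
}

#' Allele-level additive association scan for one gene
#'
#' Fits the additive model for every allele that passes the any-scope
#' frequency filter, in the full cohort and within each stratum, and
#' annotates the per-gene Bonferroni threshold (family size = number of
#' alleles tested in the full cohort).
#'
#' @inheritParams allele_frequencies
#' @param freq_threshold retention threshold for [frequency_filter()].
#' @param alpha family-wise level for the Bonferroni family.
#' @return data frame of [fit_additive()] rows plus `scope`, `gene`,
#'   `bonferroni_m`, `threshold`.
#' @export
allele_association <- function(table, gene, freq_threshold = 0.05,
                               alpha = 0.05) {
  fr <- allele_frequencies(table, gene)
  # the filter looks at case+control pooled frequencies per scope
  kept <- frequency_filter(fr, freq_threshold)
  if (length(kept) == 0) return(NULL)
  fam <- bonferroni_family(length(kept), alpha)
  scopes <- default_scopes(table)
  out <- do.call(rbind, lapply(names(scopes), function(sc) {
    t <- filter_subjects(table, scopes[[sc]]$status, scopes[[sc]]$stratum)
    do.call(rbind, lapply(kept, function(lab) {
      d <- allele_dosage(t, gene, sub("^[A-Z0-9]+\\*", "", lab))
      row <- tryCatch(fit_additive(d, t$status, feature = lab),
                      error = function(e) NULL)
      if (is.null(row)) return(NULL)
      row$scope <- sc
      row
    }))
  }))
  if (is.null(out)) return(NULL)
  out$gene <- gene
  out$bonferroni_m <- fam$m
  out$threshold <- fam$threshold
  out
}

#' Expression-SNP association
#'
#' Additive association of the inferred rs9277534 A (low-expression) and G
#' (high-expression) dosages with case status, per scope.
#'
#' @inheritParams allele_association
#' @param registry an [hla_registry()].
#' @export
snp_association <- function(table, registry, alpha = 0.05) {
  scopes <- default_scopes(table)
  out <- do.call(rbind, lapply(names(scopes), function(sc) {
    t <- filter_subjects(table, scopes[[sc]]$status, scopes[[sc]]$stratum)
    do.call(rbind, lapply(c("A", "G"), function(cl) {
      d <- snp_dosage(t, registry, cl)
      lab <- sprintf("rs9277534_%s_%s", cl,
                     if (cl == "A") "Low" else "High")
      row <- tryCatch(fit_additive(d, t$status, feature = lab),
                      error = function(e) NULL)
      if (is.null(row)) return(NULL)
      row$scope <- sc
      row
    }))
  }))
  out
}

#' TCE-group association
#'
#' Additive association of each DPB1 TCE-group dosage with case status; the
#' Bonferroni family has one test per group.
#'
#' @inheritParams snp_association
#' @export
tce_association <- function(table, registry, alpha = 0.05) {
  fam <- bonferroni_family(3, alpha)
  scopes <- default_scopes(table)
  out <- do.call(rbind, lapply(names(scopes), function(sc) {
    t <- filter_subjects(table, scopes[[sc]]$status, scopes[[sc]]$stratum)
    do.call(rbind, lapply(1:3, function(g) {
      d <- tce_dosage(t, registry, g)
      row <- tryCatch(fit_additive(d, t$status,
                                   feature = sprintf("TCE_group_%d", g)),
                      error = function(e) NULL)
      if (is.null(row)) return(NULL)
      row$scope <- sc
      row
    }))
  }))
  if (!is.null(out)) {
    out$bonferroni_m <- fam$m
    out$threshold <- fam$threshold
  }
  out
}
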