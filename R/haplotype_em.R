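#' Two-locus EM haplotype frequency estimation
#'
#' Estimates A1~B1 haplotype frequencies (e.g. DPA1~DPB1) from unphased
#' two-field genotypes by expectation-maximisation under Hardy-Weinberg
#' equilibrium.  Only double heterozygotes are phase-ambiguous: for them the
#' E-step weights the two phase configurations proportionally to the product
#' of current haplotype frequencies, and the M-step re-estimates frequencies
#' from expected chromosome counts.  Initialisation is the (deterministic)
#' product of marginal allele frequencies; the log-likelihood is checked to
#' be non-decreasing at every iteration.
#'
#' @param table an `hla_cohort`.
#' @param geneA,geneB the two genes (default DPA1, DPB1).
#' @param tol convergence tolerance on the log-likelihood change
#'   (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @return object of class `haplo_em`: list with `haplotypes` (data frame
#'   `a`, `b`, `freq`), `loglik`, `trace` (per-iteration log-likelihood),
#'   `n_iter`, `converged`, `subjects` (subject_id to genotype-group map),
#'   `configs` (per-group phase configurations with posterior probabilities
#'   `prob` and haplotype indices `h1`, `h2`), `geneA`, `geneB`,
#'   `n_subjects`.
#' @export
em_fit <- function(table, geneA = "DPA1", geneB = "DPB1", tol = 1e-8,
                   max_iter = 1000) {
  stopifnot(geneA %in% cohort_genes(table), geneB %in% cohort_genes(table))
  a1 <- table[[paste0(geneA, "_1")]]; a2 <- table[[paste0(geneA, "_2")]]
  b1 <- table[[paste0(geneB, "_1")]]; b2 <- table[[paste0(geneB, "_2")]]
  ok <- !is.na(a1) & !is.na(b1)
  if (!any(ok)) stop("no subjects typed at both genes", call. = FALSE)
  a1 <- a1[ok]; a2 <- a2[ok]; b1 <- b1[ok]; b2 <- b2[ok]
  ids <- table$subject_id[ok]
  n <- length(ids)

  gkey <- paste(a1, a2, b1, b2, sep = "|")
  groups <- unique(gkey)
  gidx <- match(gkey, groups)
  ng <- tabulate(gidx, length(groups))
  gdef <- do.call(rbind, strsplit(groups, "|", fixed = TRUE))

  # haplotype universe: all (a, b) pairs compatible with some subject
  hap_of <- function(a, b) paste(a, b, sep = "~")
  cfg <- do.call(rbind, lapply(seq_along(groups), function(g) {
    ga <- gdef[g, 1:2]; gb <- gdef[g, 3:4]
    c1 <- c(hap_of(ga[1], gb[1]), hap_of(ga[2], gb[2]))
    c2 <- c(hap_of(ga[1], gb[2]), hap_of(ga[2], gb[1]))
    if (identical(sort(c1), sort(c2)))
      data.frame(group = g, hap1 = c1[1], hap2 = c1[2],
                 stringsAsFactors = FALSE)
    else
      data.frame(group = g, hap1 = c(c1[1], c2[1]), hap2 = c(c1[2], c2[2]),
                 stringsAsFactors = FALSE)
  }))
  haps <- sort(unique(c(cfg$hap1, cfg$hap2)))
  h1 <- match(cfg$hap1, haps)
  h2 <- match(cfg$hap2, haps)
  mult <- ifelse(h1 == h2, 1, 2)  # HWE genotype probability multiplicity
  H <- length(haps)

  # deterministic start: product of marginal allele frequencies
  ab <- do.call(rbind, strsplit(haps, "~", fixed = TRUE))
  fa <- table(c(a1, a2)) / (2 * n)
  fb <- table(c(b1, b2)) / (2 * n)
  f <- as.numeric(fa[ab[, 1]]) * as.numeric(fb[ab[, 2]])
  f <- f / sum(f)

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    lik <- mult * f[h1] * f[h2]
    Lg <- as.numeric(rowsum(lik, cfg$group))
    ll <- sum(ng * log(Lg))
    if (length(trace) && ll < ll_old - 1e-9)
      stop("EM log-likelihood decreased; this indicates a bug")
    trace <- c(trace, ll)
    w <- lik / Lg[cfg$group]             # posterior per configuration
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    # M-step: expected chromosome counts
    contrib <- w * ng[cfg$group]
    s <- rowsum(c(contrib, contrib), c(h1, h2))
    f <- numeric(H)
    f[as.integer(rownames(s))] <- as.numeric(s) / (2 * n)
    ll_old <- ll
  }

  structure(list(
    haplotypes = data.frame(a = ab[, 1], b = ab[, 2], freq = f,
                            stringsAsFactors = FALSE),
    loglik = trace[length(trace)], trace = trace, n_iter = iter,
    converged = converged,
    subjects = data.frame(subject_id = ids, group = gidx,
                          stringsAsFactors = FALSE),
    configs = data.frame(group = cfg$group, h1 = h1, h2 = h2, prob = w),
    geneA = geneA, geneB = geneB, n_subjects = n), class = "haplo_em")
}

#' @export
print.haplo_em <- function(x, ...) {
  cat(sprintf("Two-locus EM fit %s~%s: %d subjects, %d haplotypes, loglik %.4f (%d iterations%s)\n",
              x$geneA, x$geneB, x$n_subjects, nrow(x$haplotypes), x$loglik,
              x$n_iter, if (x$converged) "" else ", NOT converged"))
  top <- x$haplotypes[order(-x$haplotypes$freq), ]
  print(utils::head(top, 10), row.names = FALSE)
  invisible(x)
}

# per-subject expected count of haplotypes in a qualifying set
# `qualifies`: logical over rows of em$haplotypes
em_expected_dosage <- function(em, qualifies) {
  q <- as.numeric(qualifies)
  per_cfg <- em$configs$prob * (q[em$configs$h1] + q[em$configs$h2])
  per_group <- as.numeric(rowsum(per_cfg, em$configs$group))
  stats::setNames(per_group[em$subjects$group], em$subjects$subject_id)
}

# expected chromosome counts per haplotype for a subject subset (logical over
# em$subjects rows)
em_expected_counts <- function(em, subset = NULL) {
  rows <- if (is.null(subset)) rep(TRUE, nrow(em$subjects)) else subset
  ng <- tabulate(em$subjects$group[rows],
                 nbins = max(em$configs$group))
  contrib <- em$configs$prob * ng[em$configs$group]
  out <- numeric(nrow(em$haplotypes))
  for (side in c("h1", "h2")) {
    s <- rowsum(contrib, em$configs[[side]], reorder = FALSE)
    out[as.integer(rownames(s))] <- out[as.integer(rownames(s))] +
      as.numeric(s)
  }
  out
}

#' Direct-count haplotype frequencies from phase-unambiguous subjects
#'
#' The sensitivity recoding that avoids the EM algorithm: double
#' heterozygotes are dropped and haplotypes are counted directly from the
#' remaining subjects, whose phase is determined by their genotypes.
#'
#' @inheritParams em_fit
#' @return data frame `a`, `b`, `freq` over the observed haplotypes.
#' @export
direct_count_frequencies <- function(table, geneA = "DPA1",
                                     geneB = "DPB1") {
  a1 <- table[[paste0(geneA, "_1")]]; a2 <- table[[paste0(geneA, "_2")]]
  b1 <- table[[paste0(geneB, "_1")]]; b2 <- table[[paste0(geneB, "_2")]]
  ok <- !is.na(a1) & !is.na(b1) & (a1 == a2 | b1 == b2)
  if (!any(ok)) stop("no phase-unambiguous subjects", call. = FALSE)
  h <- c(paste(a1[ok], b1[ok], sep = "~"), paste(a2[ok], b2[ok], sep = "~"))
  cnt <- table(h)
  ab <- do.call(rbind, strsplit(names(cnt), "~", fixed = TRUE))
  data.frame(a = ab[, 1], b = ab[, 2], freq = as.numeric(cnt) / sum(cnt),
             stringsAsFactors = FALSE)
}

#' Per-haplotype case-control association from EM-expected counts
#'
#' For each haplotype a 2x2 table of EM-expected chromosome counts (this
#' haplotype vs all others, cases vs controls) gives a 1-df chi-squared
#' test, an odds ratio and a Woolf (log-OR Wald) interval.  Haplotypes whose
#' expected count falls below `min_expected` in either phenotype group are
#' pooled into a `binned` pseudo-haplotype before testing.
#'
#' @param em a [em_fit()] result.
#' @param table the cohort the fit was run on (supplies case status by
#'   subject id).
#' @param min_expected binning threshold on expected chromosome counts
#'   (default 5).
#' @return data frame: `haplotype`, `case_count`, `control_count`, `or.`,
#'   `ci_lo`, `ci_hi`, `chisq`, `p`, `binned`.
#' @export
haplotype_test <- function(em, table, min_expected = 5) {
  st <- table$status[match(em$subjects$subject_id, table$subject_id)]
  if (anyNA(st)) stop("EM subjects missing from cohort table", call. = FALSE)
  case_counts <- em_expected_counts(em, st == "case")
  ctrl_counts <- em_expected_counts(em, st == "control")
  lab <- paste0(em$geneA, "*", em$haplotypes$a, "~",
                em$geneB, "*", em$haplotypes$b)
  keep <- case_counts >= min_expected & ctrl_counts >= min_expected
  if (!any(keep)) stop("all haplotypes fall below the binning threshold",
                       call. = FALSE)
  lab2 <- c(lab[keep], if (any(!keep)) "binned")
  cc <- c(case_counts[keep], if (any(!keep)) sum(case_counts[!keep]))
  kk <- c(ctrl_counts[keep], if (any(!keep)) sum(ctrl_counts[!keep]))
  tot_case <- sum(case_counts)
  tot_ctrl <- sum(ctrl_counts)
  out <- do.call(rbind, lapply(seq_along(lab2), function(i) {
    a <- cc[i]; b <- tot_case - cc[i]
    c_ <- kk[i]; d <- tot_ctrl - kk[i]
    or. <- (a * d) / (b * c_)
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    nn <- a + b + c_ + d
    chisq <- nn * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    data.frame(haplotype = lab2[i], case_count = a, control_count = c_,
               or. = or.,
               ci_lo = exp(log(or.) - 1.96 * se),
               ci_hi = exp(log(or.) + 1.96 * se),
               chisq = chisq,
               p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
               binned = lab2[i] == "binned", stringsAsFactors = FALSE)
  }))
  out
}
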