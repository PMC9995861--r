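# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately written without reusing the package's own
# code paths for the quantities it checks.

# --- Newton-Raphson logistic regression oracle -------------------------------
# Hand-coded maximum-likelihood fit of logit P(y=1) = b0 + b1 x.
newton_logistic <- function(x, y, tol = 1e-12, max_iter = 100) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- crossprod(X, y - mu)
    W <- mu * (1 - mu)
    H <- crossprod(X * W, X)
    step <- solve(H, grad)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# --- exhaustive two-locus likelihood oracle ----------------------------------
# Direct maximisation of the unphased-genotype log-likelihood over the
# haplotype frequency simplex (softmax parameterisation, multi-start BFGS).
# Genotypes: a1/a2 and b1/b2 are unordered allele pairs per subject.
em_oracle <- function(a1, a2, b1, b2, n_starts = 8, seed = 42) {
  haps <- unique(c(paste(a1, b1, sep = "~"), paste(a1, b2, sep = "~"),
                   paste(a2, b1, sep = "~"), paste(a2, b2, sep = "~")))
  haps <- sort(haps)
  H <- length(haps)
  # per subject, the list of phase configurations (pairs of hap indices)
  subj_cfg <- lapply(seq_along(a1), function(i) {
    c1 <- c(paste(a1[i], b1[i], sep = "~"), paste(a2[i], b2[i], sep = "~"))
    c2 <- c(paste(a1[i], b2[i], sep = "~"), paste(a2[i], b1[i], sep = "~"))
    cfgs <- list(match(c1, haps))
    if (!identical(sort(c1), sort(c2))) cfgs <- c(cfgs, list(match(c2, haps)))
    cfgs
  })
  negll <- function(theta) {
    f <- exp(c(theta, 0))
    f <- f / sum(f)
    -sum(vapply(subj_cfg, function(cfgs) {
      p <- sum(vapply(cfgs, function(h)
        (if (h[1] == h[2]) 1 else 2) * f[h[1]] * f[h[2]], numeric(1)))
      log(p)
    }, numeric(1)))
  }
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- if (s == 1) rep(0, H - 1) else stats::rnorm(H - 1)
    fit <- tryCatch(stats::optim(init, negll, method = "BFGS",
                                 control = list(maxit = 500, reltol = 1e-14)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  f <- exp(c(best$par, 0))
  f <- f / sum(f)
  data.frame(hap = haps, freq = f, stringsAsFactors = FALSE)
}

# --- cohort builders ----------------------------------------------------------
# quick in-memory cohort from per-gene genotype vectors
make_cohort <- function(status, ..., stratum = NULL) {
  genes <- list(...)
  n <- length(status)
  df <- data.frame(subject_id = sprintf("T%03d", seq_len(n)),
                   status = status, stringsAsFactors = FALSE)
  if (!is.null(stratum)) df$stratum <- stratum
  for (g in names(genes)) {
    df[[paste0(g, "_1")]] <- vapply(genes[[g]], `[`, character(1), 1)
    df[[paste0(g, "_2")]] <- vapply(genes[[g]], `[`, character(1), 2)
  }
  as_cohort(df, genes = names(genes))
}

# repeat a list of genotype pairs
rep_pairs <- function(pairs, times) {
  out <- list()
  for (i in seq_along(pairs))
    out <- c(out, rep(list(pairs[[i]]), times[i]))
  out
}

# a tiny registry over synthetic three-position alleles, written to temp TSVs
toy_registry <- function() {
  res <- data.frame(
    gene = "DPB1",
    allele = rep(c("01:01", "02:01"), each = 3),
    chain = "beta",
    position = rep(1:3, 2),
    residue = c("A", "A", "C", "A", "G", "C"),
    stringsAsFactors = FALSE)
  pk <- data.frame(pocket = "P1", chain = "beta", position = 1:3)
  sn <- data.frame(allele = c("01:01", "02:01"), class = c("A", "G"))
  tc <- data.frame(allele = c("01:01", "02:01"), group = c(1L, 2L))
  paths <- vapply(list(res, pk, sn, tc), function(df) {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("#provenance=toy", "#coordinate=mature"), f)
    suppressWarnings(write.table(df, f, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    f
  }, character(1))
  hla_registry(residues = paths[1], pockets = paths[2], snp = paths[3],
               tce = paths[4])
}

# small fast generator config used by the null-calibration studies: one
# stratum, four DPA1~DPB1 haplotypes at fixed frequencies
small_config <- function(n = 500, effects = data.frame(feature = character(0),
                                                       beta = numeric(0)),
                         baseline = 0, seed = 1) {
  haps <- data.frame(a = c("01:03", "01:03", "02:01", "02:02"),
                     b = c("04:01", "02:01", "17:01", "01:01"),
                     freq = c(0.35, 0.25, 0.25, 0.15),
                     stringsAsFactors = FALSE)
  generator_config(n_subjects = n, case_fraction = 0.5,
                   dp_haplotypes = list(all = haps),
                   effects = effects, baseline = baseline, seed = seed)
}
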