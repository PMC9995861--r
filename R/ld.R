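#' Linkage disequilibrium between two binary chromosome-level features
#'
#' The LD coefficient `D = p_AB - p_A * p_B`, where `p_AB` is the frequency
#' of chromosomes carrying both features, and the frequency-normalised
#' squared correlation `r2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`.  `r2` is
#' 1 exactly when the two features are in perfect correspondence.
#'
#' @param p_AB joint chromosome frequency of both features.
#' @param p_A,p_B marginal chromosome frequencies, both strictly inside
#'   (0, 1).
#' @return one-row data frame of class `ld_result`: `p_AB`, `p_A`, `p_B`,
#'   `D`, `r2`.
#' @examples
#' ld(0.4, 0.5, 0.5)  # D = 0.15, r2 = 0.36
#' @export
ld <- function(p_AB, p_A, p_B) {
  if (p_A <= 0 || p_A >= 1 || p_B <= 0 || p_B >= 1)
    stop("LD is undefined for a degenerate marginal frequency",
         call. = FALSE)
  if (p_AB < max(0, p_A + p_B - 1) - 1e-12 ||
      p_AB > min(p_A, p_B) + 1e-12)
    stop("p_AB is incompatible with the marginal frequencies",
         call. = FALSE)
  D <- p_AB - p_A * p_B
  structure(data.frame(p_AB = p_AB, p_A = p_A, p_B = p_B, D = D,
                       r2 = D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B))),
            class = c("ld_result", "data.frame"))
}

#' Chromosome-level feature for LD analysis
#'
#' A binary feature of one chromosome, resolvable from the allele call it
#' carries: a chain residue (`"b96:K"`, `"a31:M"`), an rs9277534 class
#' (`"snp:G"`), or a TCE group (`"tce:3"`).  Residue features may list
#' alternatives with `|`.
#'
#' @param text compact feature string.
#' @return list of class `ld_feature` with `kind`, carrying `gene`, and the
#'   kind-specific fields.
#' @export
ld_feature <- function(text) {
  t <- gsub(" ", "", text)
  if (grepl("^snp:", t)) {
    cl <- toupper(sub("^snp:", "", t))
    if (!cl %in% c("A", "G")) stop("SNP class must be A or G", call. = FALSE)
    return(structure(list(kind = "snp", gene = "DPB1", class = cl,
                          label = paste0("rs9277534:", cl)),
                     class = "ld_feature"))
  }
  if (grepl("^tce:", t)) {
    g <- as.integer(sub("^tce:", "", t))
    if (!g %in% 1:3) stop("TCE group must be 1, 2 or 3", call. = FALSE)
    return(structure(list(kind = "tce", gene = "DPB1", group = g,
                          label = paste0("TCE:", g)), class = "ld_feature"))
  }
  m <- regmatches(t, regexec("^([abAB])([0-9]+):([A-Za-z|]+)$", t))[[1]]
  if (length(m) == 0)
    stop(sprintf("cannot parse LD feature '%s'", text), call. = FALSE)
  chain <- if (tolower(m[2]) == "a") "alpha" else "beta"
  structure(list(kind = "residue", gene = chain_gene(chain), chain = chain,
                 position = as.integer(m[3]),
                 residues = toupper(strsplit(m[4], "|", fixed = TRUE)[[1]]),
                 label = t), class = "ld_feature")
}

# indicator of the feature over a vector of bare allele names of its gene
feature_indicator <- function(registry, feature, names) {
  switch(feature$kind,
         residue = residues_of(registry, names, feature$chain,
                               feature$position) %in% feature$residues,
         snp = expression_classes(registry, names) == feature$class,
         tce = tce_groups(registry, names) == feature$group)
}

#' LD between two features over a cohort's chromosomes
#'
#' Both features are resolved to per-chromosome indicators.  When both ride
#' the same gene (the usual case: any two DPB1-borne features, e.g. a beta
#' residue and the inferred rs9277534 class) no phasing is involved — the
#' joint frequency is counted directly over that gene's chromosomes.  A
#' cross-gene pair (alpha vs beta feature) takes marginal and joint
#' frequencies from the EM haplotype frequency estimate instead.
#'
#' @param table an `hla_cohort`.
#' @param feature_x,feature_y [ld_feature()] objects or compact strings.
#' @param registry an [hla_registry()].
#' @param em DPA1~DPB1 [em_fit()], required for cross-gene pairs.
#' @return an [ld()] result with `feature_x`/`feature_y` label columns.
#' @export
feature_ld <- function(table, feature_x, feature_y, registry, em = NULL) {
  if (is.character(feature_x)) feature_x <- ld_feature(feature_x)
  if (is.character(feature_y)) feature_y <- ld_feature(feature_y)
  if (feature_x$gene == feature_y$gene) {
    g <- feature_x$gene
    a <- c(table[[paste0(g, "_1")]], table[[paste0(g, "_2")]])
    a <- a[!is.na(a)]
    x <- feature_indicator(registry, feature_x, a)
    y <- feature_indicator(registry, feature_y, a)
    n <- as.numeric(length(a))
    kx <- as.numeric(sum(x)); ky <- as.numeric(sum(y))
    kxy <- as.numeric(sum(x & y))
    if (kx == 0 || kx == n || ky == 0 || ky == n)
      stop("degenerate feature on this cohort", call. = FALSE)
    # integer-count form: exact r2 = 1 under perfect correspondence
    D <- (n * kxy - kx * ky) / n^2
    r2 <- (n * kxy - kx * ky)^2 /
      (kx * (n - kx) * ky * (n - ky))
    out <- data.frame(p_AB = kxy / n, p_A = kx / n, p_B = ky / n,
                      D = D, r2 = r2)
  } else {
    if (is.null(em))
      stop("cross-gene LD needs a DPA1~DPB1 EM fit", call. = FALSE)
    fx <- if (feature_x$gene == em$geneA) "a" else "b"
    fy <- if (feature_y$gene == em$geneA) "a" else "b"
    x <- feature_indicator(registry, feature_x, em$haplotypes[[fx]])
    y <- feature_indicator(registry, feature_y, em$haplotypes[[fy]])
    f <- em$haplotypes$freq
    out <- ld(sum(f[x & y]), sum(f[x]), sum(f[y]))
  }
  out$feature_x <- feature_x$label
  out$feature_y <- feature_y$label
  class(out) <- c("ld_result", "data.frame")
  out
}

#' Residue / expression-SNP LD report
#'
#' For each tracked DPB1 position-residue feature, its LD with the
#' rs9277534 G class over the cohort's DPB1 chromosomes — the layout of the
#' published residue/SNP relationship table — plus optional residue-residue
#' pairs.
#'
#' @inheritParams feature_ld
#' @param positions beta positions to report (default: every tracked
#'   position).
#' @param pairs optional character vector of `"bX:R;bY:S"` residue pairs.
#' @return data frame of [ld()] rows with feature labels.
#' @export
ld_report <- function(table, registry, positions = NULL, pairs = NULL) {
  positions <- positions %||% tracked_positions(registry, "beta", "all")
  chroms <- c(table$DPB1_1, table$DPB1_2)
  chroms <- chroms[!is.na(chroms)]
  rows <- list()
  for (p in positions) {
    res <- sort(unique(residues_of(registry, chroms, "beta", p)))
    if (length(res) < 2) next   # monomorphic in this cohort
    for (r in res) {
      row <- tryCatch(
        feature_ld(table, sprintf("b%d:%s", p, r), "snp:G", registry),
        error = function(e) NULL)
      if (!is.null(row)) rows[[length(rows) + 1]] <- row
    }
  }
  for (pr in pairs) {
    # ';' separates the two features ('|' already separates residue
    # alternatives within a feature)
    fs <- strsplit(pr, ";", fixed = TRUE)[[1]]
    if (length(fs) == 2) {
      row <- tryCatch(feature_ld(table, fs[1], fs[2], registry),
                      error = function(e) NULL)
      if (!is.null(row)) rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}
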