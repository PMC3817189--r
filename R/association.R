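# Association testing of CGS summaries against phenotypes.
#
# Effect sizes are R^2 (squared Pearson correlation for quantitative
# phenotypes, eta^2 = between-group / total sum of squares for categorical
# ones) plus AUC for binary phenotypes; family-wise adjusted p-values come
# from single-step max-T permutation (Westfall-Young).  Because the CGS
# construction depends on the data only through permutation-invariant
# statistics, permuting the phenotype is a valid null even though the sets
# were built from the same expression matrix — this is what keeps the
# family-wise level exact despite the data-dependent set construction.

# Vectorised per-set statistic: squared correlation (quantitative y) or the
# one-way F statistic (categorical y).  Z is sets x samples, y has no NAs.
.assoc_stat <- function(Z, y) {
  if (is.numeric(y)) {
    as.vector(stats::cor(t(Z), y))^2
  } else {
    y <- factor(y)
    n <- length(y); g <- nlevels(y)
    tot <- rowSums((Z - rowMeans(Z))^2)
    gm <- t(rowsum(t(Z), y)) / matrix(tabulate(y), nrow(Z), g, byrow = TRUE)
    ssb <- rowSums(sweep((gm - rowMeans(Z))^2, 2, tabulate(y), `*`))
    (ssb / (g - 1)) / ((tot - ssb) / (n - g))
  }
}

#' R-squared ("beta statistic") of a summary against a phenotype
#'
#' Quantitative phenotypes give the squared Pearson correlation; categorical
#' phenotypes give eta-squared, the between-group over total sum of squares
#' of the one-way decomposition of `z` by the levels of `y`.  The raw p-value
#' comes from the corresponding F statistic.  Samples with missing `y` are
#' excluded pairwise.
#'
#' @param z numeric per-sample summary vector.
#' @param y phenotype vector (numeric, or factor/character for categorical).
#' @return list with `r_squared`, `p`, `n` (non-missing pairs used).
#' @export
beta_r_squared <- function(z, y) {
  keep <- !is.na(z) & !is.na(y)
  z <- z[keep]; y <- y[keep]
  n <- length(z)
  if (n < 3) stop("need at least 3 non-missing pairs")
  if (stats::var(z) == 0) stop("constant summary; effect size undefined")
  if (is.numeric(y)) {
    if (stats::var(y) == 0) stop("constant phenotype; effect size undefined")
    r2 <- stats::cor(z, y)^2
    df1 <- 1; df2 <- n - 2
  } else {
    y <- droplevels(factor(y))
    if (nlevels(y) < 2) stop("categorical phenotype needs >= 2 observed levels")
    gm <- tapply(z, y, mean)
    ssb <- sum(tabulate(y) * (gm - mean(z))^2)
    r2 <- ssb / sum((z - mean(z))^2)
    df1 <- nlevels(y) - 1; df2 <- n - nlevels(y)
  }
  Fstat <- (r2 / df1) / ((1 - r2) / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  list(r_squared = r2, p = p, n = n)
}

#' AUC of a summary for a binary phenotype
#'
#' The probability that a randomly chosen positive sample has a higher
#' summary value than a randomly chosen negative one, ties counted 1/2
#' (the rank-statistic form of the Mann-Whitney U).  `auc` is oriented so
#' that values >= 0.5 point toward the declared positive level; the raw
#' (unoriented) value is reported alongside.
#'
#' @param z numeric per-sample summary vector.
#' @param y binary labels (factor/character/logical).
#' @param positive the positive level (default: the last factor level).
#' @return list with `auc` (oriented), `auc_raw`, `n_pos`, `n_neg`.
#' @export
auc_binary <- function(z, y, positive = NULL) {
  keep <- !is.na(z) & !is.na(y)
  z <- z[keep]; y <- droplevels(factor(y[keep]))
  if (nlevels(y) != 2) stop("phenotype must have exactly 2 observed levels")
  if (is.null(positive)) positive <- levels(y)[2]
  pos <- y == positive
  if (!any(pos) || all(pos)) stop("one class is empty")
  r <- rank(z)                                     # midranks handle ties
  n1 <- sum(pos); n0 <- sum(!pos)
  auc_raw <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = max(auc_raw, 1 - auc_raw), auc_raw = auc_raw,
       n_pos = n1, n_neg = n0)
}

#' Single-step max-T family-wise adjustment by permutation
#'
#' For each of `B` permutations of the phenotype, all per-set statistics are
#' recomputed and their maximum recorded; the adjusted p-value of set s is
#' `(1 + #\{b : max_b >= T_s\}) / (B + 1)`.  The smallest attainable value is
#' `1/(B+1)` (0.001 at the default B = 999).  Permutations are drawn as
#' `sample.int(n)` after `set.seed(seed)`, so runs are reproducible
#' bit-for-bit.
#'
#' The per-set statistic is the one-way F for categorical phenotypes and the
#' squared correlation for quantitative ones, matching [beta_r_squared()];
#' both are monotone transforms of R^2, so the adjustment is monotone in the
#' effect size.
#'
#' @param Z summary matrix, sets x samples (no missing values; subset the
#'   columns to the phenotype's non-missing samples first).
#' @param y phenotype vector, length `ncol(Z)`.
#' @param B number of permutations (default 999; must be >= 99).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return named vector of adjusted p-values, one per set; attributes
#'   `statistic` (observed per-set values) and `B`.
#' @export
adjust_maxT <- function(Z, y, B = 999, seed) {
  if (missing(seed)) stop("a seed is mandatory for the permutation adjustment")
  if (B < 99) stop("B must be at least 99")
  if (B < 999)
    warning("B < 999: smallest attainable adjusted p is ", signif(1 / (B + 1), 3))
  if (anyNA(y)) stop("subset Z and y to non-missing samples before adjusting")
  n <- ncol(Z)
  t_obs <- .assoc_stat(Z, y)
  set.seed(seed)
  maxes <- numeric(B)
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    maxes[b] <- max(.assoc_stat(Z, y[perm]))
  }
  adj <- vapply(t_obs, function(t) (1 + sum(maxes >= t)) / (B + 1), numeric(1))
  names(adj) <- rownames(Z)
  structure(adj, statistic = stats::setNames(t_obs, rownames(Z)), B = B)
}

#' Test every CGS summary against every phenotype
#'
#' Long-form association results: per (set, phenotype), the R^2 effect size,
#' AUC for binary phenotypes, the raw parametric p and the max-T family-wise
#' adjusted p.  Missing phenotype entries are excluded pairwise per
#' phenotype (the n used is reported).  The reported adjusted p is
#' `max(maxT, raw)` so it can never undercut the raw p near the permutation
#' floor.
#'
#' @param S summary matrix, sets x samples.
#' @param pheno data.frame with `sample_id` plus phenotype columns (see
#'   [read_phenotype_table()]).
#' @param B permutations for the max-T adjustment (default 999).
#' @param seed RNG seed (mandatory).
#' @param variables which phenotype columns to test (default: all).
#' @return data.frame of class `cgs_association`: set_id, phenotype, n,
#'   r_squared, auc (NA unless binary), p_raw, p_adjusted.
#' @export
associate <- function(S, pheno, B = 999, seed, variables = NULL) {
  if (missing(seed)) stop("a seed is mandatory")
  ids <- intersect(colnames(S), pheno$sample_id)
  S <- S[, ids, drop = FALSE]
  pheno <- pheno[match(ids, pheno$sample_id), , drop = FALSE]
  if (is.null(variables)) variables <- setdiff(names(pheno), "sample_id")
  out <- list()
  for (v in variables) {
    y <- pheno[[v]]
    keep <- !is.na(y)
    if (sum(keep) < 3) { warning("phenotype '", v, "' has < 3 observations; skipped"); next }
    Zv <- S[, keep, drop = FALSE]; yv <- y[keep]
    adj <- adjust_maxT(Zv, if (is.character(yv)) factor(yv) else yv, B = B, seed = seed)
    res <- lapply(rownames(S), function(s) {
      b <- beta_r_squared(Zv[s, ], yv)
      auc <- NA_real_
      if (!is.numeric(yv) && nlevels(droplevels(factor(yv))) == 2)
        auc <- auc_binary(Zv[s, ], yv)$auc
      data.frame(set_id = s, phenotype = v, n = b$n, r_squared = b$r_squared,
                 auc = auc, p_raw = b$p,
                 p_adjusted = max(adj[[s]], b$p), stringsAsFactors = FALSE)
    })
    out[[v]] <- do.call(rbind, res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("cgs_association", "data.frame"),
            B = B, seed = seed)
}

#' Two-way ANOVA of a signature's first principal component
#'
#' The dependent variable is the first principal component of the signature
#' genes' expression across samples, sign-oriented to correlate positively
#' with the signature's mean profile; main effects of the two groupings are
#' tested without interaction using type-II sums of squares (each factor
#' adjusted for the other).
#'
#' @param X expression matrix.
#' @param signature_genes character vector of gene ids (>= 3 present).
#' @param factorA,factorB categorical vectors over the samples (>= 2 levels);
#'   a single gene signature uses that gene's standardized profile.
#' @return list with `p_factorA`, `p_factorB`, and `pc1` (the dependent
#'   variable, named by sample).
#' @export
signature_anova <- function(X, signature_genes, factorA, factorB) {
  genes <- intersect(signature_genes, rownames(X))
  if (!length(genes)) stop("no signature genes present in the matrix")
  sub <- X[genes, , drop = FALSE]
  if (length(genes) == 1) {
    pc1 <- as.vector(scale(sub[1, ]))
  } else {
    pc <- stats::prcomp(t(sub), center = TRUE, scale. = FALSE)
    pc1 <- pc$x[, 1]
    if (stats::cor(pc1, colMeans(sub)) < 0) pc1 <- -pc1
  }
  names(pc1) <- colnames(X)
  fA <- droplevels(factor(factorA)); fB <- droplevels(factor(factorB))
  if (nlevels(fA) < 2 || nlevels(fB) < 2) stop("both factors need >= 2 levels")
  cells <- table(fA, fB)
  if (any(rowSums(cells > 0) == 0) || any(colSums(cells > 0) == 0))
    stop("degenerate design: a factor level occurs in no cell")
  fit <- stats::lm(pc1 ~ fA + fB)
  dr <- stats::drop1(fit, scope = ~ fA + fB, test = "F")   # type-II main effects
  list(p_factorA = dr["fA", "Pr(>F)"], p_factorB = dr["fB", "Pr(>F)"],
       pc1 = pc1)
}
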