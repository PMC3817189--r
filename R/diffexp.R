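# Gene-wise generalized log-ratios, two-group differential expression with
# FDR control, and class-partitioned scaled density decompositions of
# fold-change distributions.

#' Gene-wise generalized log-ratios between two sample groups
#'
#' Per gene, the mean over group A minus the mean over group B on the input
#' (glog) scale — the variance-stabilised analogue of a log fold change.
#' Swapping the groups negates every entry.
#'
#' @param X expression matrix.
#' @param groupA,groupB disjoint character vectors of sample ids, each with
#'   at least 2 samples.
#' @return named numeric vector of log-ratios (contrast A minus B), with the
#'   contrast label attached as an attribute.
#' @export
group_log_ratios <- function(X, groupA, groupB) {
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  if (length(groupA) < 2 || length(groupB) < 2) stop("each group needs >= 2 samples")
  missing <- setdiff(c(groupA, groupB), colnames(X))
  if (length(missing)) stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  lr <- rowMeans(X[, groupA, drop = FALSE]) - rowMeans(X[, groupB, drop = FALSE])
  attr(lr, "contrast") <- "A_minus_B"
  lr
}

# Row-wise Welch t-test: means, variances and Welch-Satterthwaite df computed
# in vectorised form.  Genes constant in both groups with equal means get
# t = 0, p = 1 (not an error).
.welch_rows <- function(A, B) {
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  se2 <- vA / nA + vB / nB
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  degenerate <- se2 == 0
  t[degenerate] <- 0
  df[degenerate] <- nA + nB - 2
  p <- 2 * stats::pt(-abs(t), df)
  p[degenerate & (mA == mB)] <- 1
  list(t = t, df = df, p = p)
}

#' Two-group differential expression (Welch t + BH)
#'
#' Per gene: Welch two-sample t-test between the groups, Benjamini-Hochberg
#' adjustment across all tested genes, and up/down calls at the stated FDR
#' (up = q <= fdr and positive log-ratio).
#'
#' @param X expression matrix.
#' @param groupA,groupB disjoint sample id vectors, >= 3 samples each.
#' @param fdr FDR threshold for the up/down calls (default 0.05).
#' @return data.frame of class `cgs_de`: gene, log_ratio, t, df, p, q,
#'   direction ("up"/"down"/"ns"); attributes `n_up`, `n_down`, `fdr`.
#' @export
de_test <- function(X, groupA, groupB, fdr = 0.05) {
  if (length(groupA) < 3 || length(groupB) < 3)
    stop("each group needs >= 3 samples for the test")
  lr <- group_log_ratios(X, groupA, groupB)
  w <- .welch_rows(X[, groupA, drop = FALSE], X[, groupB, drop = FALSE])
  q <- stats::p.adjust(w$p, method = "BH")
  direction <- ifelse(q <= fdr & lr > 0, "up",
                      ifelse(q <= fdr & lr < 0, "down", "ns"))
  out <- data.frame(gene = rownames(X), log_ratio = as.numeric(lr),
                    t = w$t, df = w$df, p = w$p, q = q,
                    direction = direction, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(out, class = c("cgs_de", "data.frame"),
            n_up = sum(direction == "up"), n_down = sum(direction == "down"),
            fdr = fdr)
}

#' @export
print.cgs_de <- function(x, ...) {
  cat(sprintf("DE: %d genes, %d up / %d down at FDR %.3g\n",
              nrow(x), attr(x, "n_up"), attr(x, "n_down"), attr(x, "fdr")))
  invisible(x)
}

#' Class-partitioned scaled densities of log-ratios
#'
#' Gaussian-kernel density of the log-ratios per gene class, each scaled by
#' the class's share of the classified genes, so that the scaled class
#' densities sum pointwise to the density of all classified genes.  A single
#' bandwidth (Silverman's rule on the pooled classified genes) is shared by
#' all classes — additivity only holds with a shared bandwidth.  Genes in no
#' class are "unclassified" and excluded.
#'
#' @param ratios named numeric vector of log-ratios (names = gene ids).
#' @param classes named list of gene id vectors, e.g. `list(LE = ..., HE =
#'   ...)`; each included class must cover >= 10 genes with ratios.
#' @param grid evaluation points; default 512 points spanning the classified
#'   data range extended by 3 bandwidths.
#' @return list with `grid`, `total` (density of all classified genes),
#'   `by_class` (matrix grid x classes of scaled densities), `shares`,
#'   `bandwidth`.
#' @export
partitioned_density <- function(ratios, classes, grid = NULL) {
  vals <- lapply(classes, function(g) ratios[intersect(g, names(ratios))])
  empty <- lengths(vals) == 0
  if (any(empty)) {
    warning("empty class(es) omitted: ", paste(names(vals)[empty], collapse = ", "))
    vals <- vals[!empty]
  }
  small <- lengths(vals) < 10
  if (any(small))
    stop("class(es) with fewer than 10 genes: ",
         paste(names(vals)[small], collapse = ", "))
  pooled <- unlist(vals, use.names = FALSE)
  bw <- stats::bw.nrd0(pooled)
  if (is.null(grid))
    grid <- seq(min(pooled) - 3 * bw, max(pooled) + 3 * bw, length.out = 512)
  from <- min(grid); to <- max(grid); npt <- length(grid)
  dens <- function(x) stats::density(x, bw = bw, from = from, to = to,
                                     n = npt)$y
  shares <- lengths(vals) / length(pooled)
  by_class <- vapply(seq_along(vals), function(i) shares[i] * dens(vals[[i]]),
                     numeric(npt))
  colnames(by_class) <- names(vals)
  list(grid = grid, total = dens(pooled), by_class = by_class,
       shares = shares, bandwidth = bw)
}

#' Partition genes by membership across several up-regulated lists
#'
#' Set arithmetic behind a Venn diagram: every gene present in at least one
#' list is assigned to the region named by the sorted concatenation of the
#' lists containing it (e.g. `"A+B"`).
#'
#' @param lists named list of gene id vectors (2 or 3 lists, typically the
#'   "up" genes of several contrasts).
#' @return named list of gene id vectors, one per non-empty region.
#' @export
venn_partition <- function(lists, sep = "+") {
  stopifnot(length(lists) >= 2, !is.null(names(lists)))
  genes <- unique(unlist(lists))
  member <- vapply(lists, function(l) genes %in% l, logical(length(genes)))
  if (length(genes) == 1) member <- matrix(member, nrow = 1)
  region <- apply(member, 1, function(m) paste(names(lists)[m], collapse = sep))
  split(genes, region)
}
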