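# Annotation-term enrichment: hypergeometric over-representation of terms in
# a gene set, and PAGE-style parametric enrichment of terms in a per-gene
# score vector (e.g. log-ratios).

#' Hypergeometric over-representation of catalog terms in a query set
#'
#' Classic one-sided urn test: for each term, the upper-tail probability of
#' drawing at least the observed overlap when `|query|` genes are sampled
#' from the universe without replacement.  Terms are intersected with the
#' universe first and only terms with more than `min_term_size` genes are
#' tested.  P-values are reported unadjusted (the conventional practice for
#' descriptive set characterisation; pass them to [stats::p.adjust()] for a
#' BH variant).
#'
#' @param query character vector of gene ids (intersected with the universe).
#' @param catalog named list term -> member gene ids (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all considered gene ids.
#' @param min_term_size only terms with strictly more than this many genes in
#'   the universe are tested (default 10).
#' @return data.frame: term, term_size, overlap, expected, p, sorted by p.
#' @export
hypergeom_enrich <- function(query, catalog, universe, min_term_size = 10) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  N <- length(universe)
  query <- intersect(query, universe)
  k <- length(query)
  rows <- lapply(names(catalog), function(tm) {
    term <- intersect(catalog[[tm]], universe)
    m <- length(term)
    if (m <= min_term_size) return(NULL)
    x <- length(intersect(query, term))
    data.frame(term = tm, term_size = m, overlap = x,
               expected = k * m / N,
               p = stats::phyper(x - 1, m, N - m, k, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), term_size = integer(0),
                      overlap = integer(0), expected = numeric(0),
                      p = numeric(0)))
  out[order(out$p, out$term), , drop = FALSE]
}

#' PAGE parametric enrichment of terms in a score vector
#'
#' For a term with m genes and mean score S_m, the statistic is
#' `z = (S_m - mu) * sqrt(m) / delta` where mu and delta are the mean and SD
#' of all scores; p is two-sided normal.  The z score is invariant under
#' affine transformation of the scores.  A signed `-log10(p)` is reported for
#' heatmap-style matrices (positive = enriched above the global mean,
#' negative = depleted).
#'
#' @param scores named numeric vector of per-gene scores (>= 30 genes).
#' @param catalog named list term -> gene ids; terms are intersected with the
#'   score names and need at least `min_size` genes.
#' @param min_size minimum term size after intersection (default 10).
#' @return data.frame: term, m, mean_score, z, p, signed_log10p, sorted by p.
#' @export
page_enrich <- function(scores, catalog, min_size = 10) {
  if (length(scores) < 30) stop("PAGE needs a global score vector of >= 30 genes")
  if (is.null(names(scores))) stop("scores must be named by gene id")
  mu <- mean(scores); delta <- stats::sd(scores)
  if (delta == 0) stop("scores have zero variance")
  rows <- lapply(names(catalog), function(tm) {
    g <- intersect(catalog[[tm]], names(scores))
    m <- length(g)
    if (m < min_size) return(NULL)
    sm <- mean(scores[g])
    z <- (sm - mu) * sqrt(m) / delta
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(term = tm, m = m, mean_score = sm, z = z, p = p,
               signed_log10p = sign(z) * -log10(max(p, .Machine$double.xmin)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), m = integer(0),
                      mean_score = numeric(0), z = numeric(0), p = numeric(0),
                      signed_log10p = numeric(0)))
  out[order(out$p, out$term), , drop = FALSE]
}

#' PAGE enrichment matrix of catalog terms across gene subsets
#'
#' Runs PAGE once per subset with a 0/1 membership indicator as the score
#' vector over the whole universe: for each (subset, term) cell the z score
#' compares the term's share of subset members to the global share, giving
#' the familiar signed -log10 p heatmap (positive = term over-represented in
#' the subset, negative = depleted).
#'
#' @param partition named list subset -> gene ids (e.g. Venn regions from
#'   [venn_partition()]).
#' @param catalog named list term -> gene ids.
#' @param universe character vector of all genes the subsets were drawn from.
#' @param min_size minimum term size (default 10).
#' @return matrix terms x subsets of signed -log10 p values.
#' @export
page_matrix <- function(partition, catalog, universe, min_size = 10) {
  universe <- unique(universe)
  res <- lapply(names(partition), function(s) {
    scores <- stats::setNames(as.numeric(universe %in% partition[[s]]), universe)
    page_enrich(scores, catalog, min_size = min_size)
  })
  terms <- sort(unique(unlist(lapply(res, `[[`, "term"))))
  out <- matrix(NA_real_, length(terms), length(partition),
                dimnames = list(terms, names(partition)))
  for (i in seq_along(res))
    out[res[[i]]$term, i] <- res[[i]]$signed_log10p
  out
}
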