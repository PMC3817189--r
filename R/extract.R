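# Correlated gene set (CGS) extraction.
#
# Every gene is treated as the center of a candidate set containing all genes
# positively correlated with it above r_min.  Candidates are scored by
# s2_c * sum_j r_cj^2 (center variance times summed squared center
# correlations), sorted, and a top-K pairwise-disjoint collection is selected
# greedily.  All ingredients are functions of the total variances and
# covariances only, so the whole construction is invariant under permutation
# of the sample columns — the property that makes downstream permutation
# tests exact despite the data-dependent set construction.

#' Pearson correlations of every gene with a center gene
#'
#' @param X expression matrix (genes x samples, >= 3 samples).
#' @param center gene identifier (must have nonzero variance).
#' @return named vector of correlations, one per gene; genes with zero
#'   variance get 0 with a warning; the center's entry is 1.
#' @export
correlation_with_center <- function(X, center) {
  validate_expression(X)
  if (ncol(X) < 3L) stop("need at least 3 samples")
  if (!center %in% rownames(X)) stop("center gene '", center, "' not in matrix")
  xc <- X[center, ]
  if (stats::var(xc) == 0) stop("center gene '", center, "' has zero variance")
  sds <- apply(X, 1, stats::sd)
  r <- as.vector(stats::cor(xc, t(X[sds > 0, , drop = FALSE])))
  out <- stats::setNames(numeric(nrow(X)), rownames(X))
  out[sds > 0] <- r
  if (any(sds == 0))
    warning(sum(sds == 0), " zero-variance gene(s); correlation recorded as 0")
  out[center] <- 1
  out
}

#' Build the candidate set around a center gene
#'
#' Members are the genes whose correlation with the center is at least
#' `r_min`; the center is always a member.  Negatively correlated genes are
#' never included, whatever their magnitude.
#'
#' @param X expression matrix.
#' @param center gene identifier.
#' @param r_min correlation threshold in (0, 1).
#' @return object of class `cgs_set`: list with `center`, `members`, `score`
#'   (`NA` until scored).
#' @export
build_candidate_set <- function(X, center, r_min = 0.7) {
  stopifnot(r_min > 0, r_min < 1)
  r <- correlation_with_center(X, center)
  members <- names(r)[r >= r_min]
  if (!center %in% members) members <- c(center, members)
  structure(list(center = center, members = members, score = NA_real_),
            class = "cgs_set")
}

#' Score a candidate set
#'
#' Default score: `s2_c * sum_{j in members} r_cj^2`, the center gene's
#' sample variance times the summed squared correlations of the members with
#' the center (the center itself contributes r = 1).  The score grows with
#' set size, with the center's variance, and with how tightly members track
#' the center, and depends on the data only through variances and
#' covariances.
#'
#' @param X expression matrix.
#' @param set a `cgs_set` (or list with `center` and `members`).
#' @return non-negative scalar score.
#' @export
score_candidate_set <- function(X, set) {
  missing <- setdiff(set$members, rownames(X))
  if (length(missing))
    stop("set member(s) not in matrix: ", paste(missing, collapse = ", "))
  r <- correlation_with_center(X, set$center)
  s2 <- stats::var(X[set$center, ])
  s2 * sum(r[set$members]^2)
}

#' Extract a disjoint top-K collection of correlated gene sets
#'
#' Builds one candidate per gene, scores all candidates, sorts by score
#' (descending; ties broken by center gene id, ascending) and scans the list,
#' accepting a candidate iff it shares no member with any previously accepted
#' set and has at least `min_size` members, until `K` sets are accepted.
#'
#' @param X expression matrix.
#' @param K maximum number of sets (default 50).
#' @param r_min membership correlation threshold (default 0.7).
#' @param min_size minimum member count (default 2: a set must contain at
#'   least one non-center member to represent co-expression).
#' @return a `cgs_collection`: list of `cgs_set`s (fields `center`, `members`,
#'   `score`, `rank`) with the extraction parameters and a fingerprint of the
#'   input attached as attributes.  If fewer than `K` disjoint candidates
#'   exist, all accepted sets are returned with a warning.
#' @export
extract_cgs <- function(X, K = 50, r_min = 0.7, min_size = 2) {
  validate_expression(X)
  stopifnot(K >= 1, r_min > 0, r_min < 1, min_size >= 1)
  if (ncol(X) < 3L) stop("need at least 3 samples")
  genes <- rownames(X)
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0))
    warning(sum(sds == 0), " zero-variance gene(s) cannot center or join a set")
  ok <- sds > 0
  R <- stats::cor(t(X[ok, , drop = FALSE]))       # gene-gene correlations
  diag(R) <- 1
  member_mask <- R >= r_min                       # candidate membership
  scores <- (sds[ok]^2) * rowSums((R * member_mask)^2)
  sizes <- rowSums(member_mask)

  ord <- order(-scores, rownames(R))              # ties: center id ascending
  used <- stats::setNames(logical(sum(ok)), rownames(R))
  accepted <- list()
  for (i in ord) {
    if (length(accepted) >= K) break
    members <- rownames(R)[member_mask[i, ]]
    if (sizes[i] < min_size) next
    if (any(used[members])) next
    used[members] <- TRUE
    accepted[[length(accepted) + 1L]] <- structure(
      list(center = rownames(R)[i], members = members, score = scores[i],
           rank = length(accepted) + 1L),
      class = "cgs_set")
  }
  if (length(accepted) < K)
    warning(sprintf("only %d disjoint set(s) of size >= %d found (K = %d requested)",
                    length(accepted), min_size, K))
  structure(accepted, class = "cgs_collection",
            parameters = list(K = K, r_min = r_min, min_size = min_size,
                              score_formula = "var_center_x_sum_r2"),
            fingerprint = fingerprint_matrix(X))
}

# Permutation-invariant fingerprint of the input: dimensions, gene ids and
# column-sorted value digest would break permutation invariance, so hash the
# gene ids plus per-gene variance only.
fingerprint_matrix <- function(X) {
  v <- apply(X, 1, stats::var)
  f <- tempfile(); on.exit(unlink(f))
  writeLines(c(rownames(X), sprintf("%.12g", sort(v))), f)
  unname(tools::md5sum(f))
}

#' @export
print.cgs_collection <- function(x, ...) {
  p <- attr(x, "parameters")
  cat(sprintf("CGS collection: %d set(s) [K=%d, r_min=%g, min_size=%d, score=%s]\n",
              length(x), p$K, p$r_min, p$min_size, p$score_formula))
  for (s in utils::head(x, 10))
    cat(sprintf("  #%d %s: %d genes, score %.4g\n",
                s$rank, s$center, length(s$members), s$score))
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Convert a CGS collection to a GMT-style list
#'
#' The center gene is placed first among the members and the score is carried
#' in the description field as `score=<value>`.
#'
#' @param collection a `cgs_collection`.
#' @return named list of member vectors suitable for [write_gmt()].
#' @export
as_gmt <- function(collection) {
  out <- lapply(collection, function(s) {
    m <- c(s$center, setdiff(s$members, s$center))
    attr(m, "description") <- sprintf("score=%.10g", s$score)
    m
  })
  names(out) <- vapply(collection, function(s) s$center, character(1))
  out
}

#' Per-set metadata table of a collection
#'
#' @param collection a `cgs_collection`.
#' @return data.frame with center, size, score and rank per set.
#' @export
cgs_metadata <- function(collection) {
  data.frame(set_id = vapply(collection, `[[`, character(1), "center"),
             center = vapply(collection, `[[`, character(1), "center"),
             size = vapply(collection, function(s) length(s$members), integer(1)),
             score = vapply(collection, `[[`, numeric(1), "score"),
             rank = vapply(collection, `[[`, integer(1), "rank"),
             stringsAsFactors = FALSE)
}

#' Summarize a CGS collection into per-set, per-sample scores
#'
#' The summary for set S in sample i is `sum_{j in S} w_j x_ji` with weights
#' `w_j = 1/s_j`, the inverse total standard deviation of gene j.  Because
#' the weights depend only on total (phenotype-blind) variances, the summary
#' inherits the permutation invariance of the extraction.  Each summary row
#' is oriented to correlate positively with its center gene and, if
#' `standardize`, centered and scaled to unit variance.
#'
#' @param X expression matrix containing all member genes.
#' @param collection a `cgs_collection` (or GMT-style list whose first member
#'   is the center).
#' @param standardize center/scale each summary row (default `TRUE`).
#' @return matrix of class `cgs_summary`, sets x samples, with attributes
#'   `weights` (per-set named weight vectors), `signs` (orientation flags),
#'   `centers` and `scales` (the raw-summary statistics used, needed to place
#'   external samples on the same scale).
#' @export
summarize_cgs <- function(X, collection, standardize = TRUE) {
  validate_expression(X)
  if (!inherits(collection, "cgs_collection")) collection <- gmt_as_collection(collection)
  ids <- vapply(collection, `[[`, character(1), "center")
  S <- matrix(NA_real_, length(collection), ncol(X),
              dimnames = list(ids, colnames(X)))
  weights <- vector("list", length(collection)); names(weights) <- ids
  signs <- stats::setNames(rep(1, length(collection)), ids)
  for (k in seq_along(collection)) {
    set <- collection[[k]]
    missing <- setdiff(set$members, rownames(X))
    if (length(missing))
      stop("set '", set$center, "' member(s) not in matrix: ",
           paste(missing, collapse = ", "))
    sub <- X[set$members, , drop = FALSE]
    s <- apply(sub, 1, stats::sd)
    if (any(s == 0)) {
      warning("zero-variance member(s) excluded from summary of set '",
              set$center, "'")
      sub <- sub[s > 0, , drop = FALSE]; s <- s[s > 0]
    }
    w <- 1 / s
    z <- as.vector(w %*% sub)
    if (set$center %in% rownames(sub)) {
      rc <- stats::cor(z, X[set$center, ])
      if (!is.na(rc) && rc < 0) { z <- -z; w <- -w; signs[k] <- -1 }
    }
    weights[[k]] <- w
    S[k, ] <- z
  }
  centers <- rowMeans(S)
  scales <- apply(S, 1, stats::sd)
  if (standardize) {
    if (any(scales == 0)) stop("constant summary row; cannot standardize")
    S <- (S - centers) / scales
  }
  structure(S, class = c("cgs_summary", "matrix"),
            weights = weights, signs = signs,
            centers = centers, scales = scales, standardized = standardize)
}

# Accept a GMT-style list (center first) where a cgs_collection is expected.
gmt_as_collection <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  out <- lapply(seq_along(sets), function(i)
    structure(list(center = sets[[i]][1], members = as.character(sets[[i]]),
                   score = NA_real_, rank = i), class = "cgs_set"))
  structure(out, class = "cgs_collection",
            parameters = list(K = length(sets), r_min = NA, min_size = NA,
                              score_formula = "external"))
}

#' Write summary scores as TSV (sets in rows)
#'
#' @param S a `cgs_summary` matrix.
#' @param path output path.
#' @export
write_summary <- function(S, path) {
  df <- data.frame(set_id = rownames(S), unclass(S), check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read summary scores written by [write_summary()]
#'
#' @param path TSV path.
#' @return numeric matrix, sets x samples.
#' @export
read_summary <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}
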