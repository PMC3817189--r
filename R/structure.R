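# Unsupervised sample structure on CGS summaries: principal-plane
# coordinates, angular ordering, projection of external cohorts, mapping of
# set collections across platforms, and PAM clustering with silhouette-based
# selection of the number of clusters.

#' Principal-plane coordinates of the samples
#'
#' Treats each sample as a point in set-summary space and computes the
#' principal axes of the samples; returns the coordinates on the two
#' requested axes together with the per-set loadings.  Loadings are
#' sign-fixed so the largest-magnitude loading on each axis is positive,
#' making the output deterministic across eigensolvers.
#'
#' @param S summary matrix, sets x samples (>= 2 sets, >= 3 samples).
#' @param axes pair of principal-component indices (default `c(1, 2)`).
#' @return object of class `cgs_plane`: list with `coords` (samples x 2),
#'   `loadings` (sets x 2), `sdev`, plus the full rotation and centering
#'   needed to project external samples.
#' @export
principal_plane <- function(S, axes = c(1, 2)) {
  stopifnot(nrow(S) >= 2, ncol(S) >= 3, length(axes) == 2)
  pc <- stats::prcomp(t(S), center = TRUE, scale. = FALSE)
  if (max(axes) > ncol(pc$rotation))
    stop("axis index ", max(axes), " exceeds the rank of the summary matrix")
  flip <- vapply(axes, function(a) {
    l <- pc$rotation[, a]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  coords <- sweep(pc$x[, axes, drop = FALSE], 2, flip, `*`)
  loadings <- sweep(pc$rotation[, axes, drop = FALSE], 2, flip, `*`)
  colnames(coords) <- colnames(loadings) <- paste0("PC", axes)
  structure(list(coords = coords, loadings = loadings,
                 sdev = pc$sdev[axes], axes = axes, flip = flip,
                 rotation = pc$rotation, center = pc$center),
            class = "cgs_plane")
}

#' Order samples by angle on the principal plane
#'
#' Assigns each sample the counterclockwise angle of its coordinate vector
#' relative to a reference direction and orders samples by increasing angle.
#' The ordering is invariant under joint rotation or reflection of the
#' coordinates and the reference.  Samples at the exact origin have no angle
#' and are placed last, ordered by sample id; angle ties are broken by
#' sample id.
#'
#' @param coords samples x 2 coordinate matrix (rownames = sample ids), or a
#'   `cgs_plane`.
#' @param reference nonzero 2-vector; default: the direction of the first
#'   sample's coordinates (an arbitrary but recorded choice).
#' @return data.frame of class `sample_ordering` with sample, angle (radians
#'   in \[0, 2pi)), rank and the two coordinates, sorted by rank; the
#'   reference used is attached as an attribute.
#' @export
angular_order <- function(coords, reference = NULL) {
  if (inherits(coords, "cgs_plane")) coords <- coords$coords
  stopifnot(ncol(coords) == 2)
  if (is.null(rownames(coords))) stop("coordinates need sample ids as rownames")
  if (is.null(reference)) {
    reference <- coords[1, ]
    if (all(reference == 0)) stop("first sample lies at the origin; supply a reference")
  }
  if (all(reference == 0)) stop("reference vector must be nonzero")
  ang <- atan2(coords[, 2], coords[, 1]) - atan2(reference[2], reference[1])
  ang <- ang %% (2 * pi)
  zero <- rowSums(coords^2) == 0
  ang[zero] <- NA_real_
  ord <- order(is.na(ang), ang, rownames(coords))  # origin samples last, by id
  out <- data.frame(sample_id = rownames(coords)[ord],
                    angle = ang[ord],
                    rank = seq_len(nrow(coords)),
                    coord1 = coords[ord, 1], coord2 = coords[ord, 2],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("sample_ordering", "data.frame"),
            reference = reference)
}

#' Project external samples onto a reference principal plane
#'
#' External samples are summarised with the reference cohort's per-gene
#' weights and orientation, centred by the reference per-set means and scaled
#' by the reference per-set SDs, then rotated with the reference loadings.
#' The reference coordinates themselves are untouched; projecting the
#' reference cohort reproduces its own coordinates.
#'
#' Sets with more than half of their member genes absent from the external
#' matrix are marked missing; an external sample is dropped when more than
#' 20% of the sets are missing, otherwise missing set summaries are imputed
#' at the reference mean (0 on the standardized scale).
#'
#' @param S_ref `cgs_summary` of the reference cohort (standardized).
#' @param plane `cgs_plane` computed from `S_ref`.
#' @param X_ext external expression matrix sharing gene identifiers.
#' @param collection the `cgs_collection` behind `S_ref`.
#' @return samples x 2 coordinate matrix for the (retained) external samples;
#'   attribute `missing_sets` lists sets unavailable on the external platform.
#' @export
project_external <- function(S_ref, plane, X_ext, collection) {
  validate_expression(X_ext)
  ids <- rownames(S_ref)
  weights <- attr(S_ref, "weights")
  mu <- attr(S_ref, "centers"); sc <- attr(S_ref, "scales")
  Z <- matrix(NA_real_, length(ids), ncol(X_ext),
              dimnames = list(ids, colnames(X_ext)))
  missing_sets <- character(0)
  for (k in seq_along(collection)) {
    set <- collection[[k]]
    w <- weights[[k]]
    have <- intersect(names(w), rownames(X_ext))
    if (length(have) < length(set$members) / 2) {
      missing_sets <- c(missing_sets, ids[k])
      next
    }
    Z[k, ] <- (as.vector(w[have] %*% X_ext[have, , drop = FALSE]) - mu[k]) / sc[k]
  }
  if (length(missing_sets) > 0.2 * length(ids))
    stop(sprintf("%d/%d sets unavailable on the external platform; cannot project",
                 length(missing_sets), length(ids)))
  Z[is.na(Z)] <- 0                                  # reference mean on z-scale
  coords <- sweep((t(Z) - matrix(plane$center, ncol(Z), length(plane$center),
                                 byrow = TRUE)) %*%
                    plane$rotation[, plane$axes, drop = FALSE],
                  2, plane$flip, `*`)
  colnames(coords) <- paste0("PC", plane$axes)
  structure(coords, missing_sets = missing_sets)
}

#' Map a CGS collection onto a target platform's gene universe
#'
#' Per set, the retained members are the intersection with the target gene
#' list; sets whose retained fraction falls below `min_fraction` are flagged
#' unmapped and excluded from downstream summaries.  Mapping is idempotent.
#'
#' @param collection a `cgs_collection`.
#' @param target_genes character vector of gene ids on the target platform.
#' @param min_fraction minimum retained fraction to keep a set (default 0.5).
#' @return a `cgs_collection` of the mapped (retained-member) sets, with a
#'   `mapping` attribute: data.frame of set_id, n_original, n_retained,
#'   retained_fraction, mapped flag for every input set.
#' @export
map_gene_sets <- function(collection, target_genes, min_fraction = 0.5) {
  if (!length(target_genes)) stop("empty target gene list")
  target_genes <- unique(target_genes)
  info <- do.call(rbind, lapply(collection, function(s) {
    kept <- intersect(s$members, target_genes)
    data.frame(set_id = s$center, n_original = length(s$members),
               n_retained = length(kept),
               retained_fraction = length(kept) / length(s$members),
               stringsAsFactors = FALSE)
  }))
  info$mapped <- info$retained_fraction >= min_fraction
  mapped <- list()
  for (i in seq_along(collection)) {
    if (!info$mapped[i]) next
    s <- collection[[i]]
    s$members <- intersect(s$members, target_genes)
    # center may itself be absent on the target; keep it as the set label
    s$rank <- length(mapped) + 1L
    mapped[[length(mapped) + 1L]] <- s
  }
  structure(mapped, class = "cgs_collection",
            parameters = attr(collection, "parameters"),
            mapping = info)
}

# ---- PAM clustering ---------------------------------------------------------

#' PAM clustering of samples on standardized summaries
#'
#' Euclidean distances are computed between samples after standardizing each
#' set row (z-scores across samples), then classical partitioning around
#' medoids (BUILD + SWAP, deterministic, via [cluster::pam()]) is run.
#'
#' @param S summary matrix, sets x samples.
#' @param k number of clusters, `2 <= k < n`.
#' @param standardize re-standardize rows before distances (default `TRUE`;
#'   a no-op if `S` is already row-standardized).
#' @return object of class `cgs_clusters`: list with `k`, `labels` (named
#'   integer vector in input sample order), `medoids` (sample ids),
#'   `silhouette` (named widths), `asw` (average silhouette width), `cost`
#'   (total distance of samples to their medoids).
#' @export
pam_cluster <- function(S, k, standardize = TRUE) {
  n <- ncol(S)
  stopifnot(k >= 2, k < n)
  Z <- if (standardize) t(scale(t(S))) else S
  d <- stats::dist(t(Z))
  fit <- cluster::pam(d, k = k, diss = TRUE, keep.diss = FALSE)
  labels <- fit$clustering[colnames(S)]
  sil <- fit$silinfo$widths
  silw <- stats::setNames(sil[, "sil_width"], rownames(sil))[colnames(S)]
  structure(list(k = k, labels = labels, medoids = fit$medoids,
                 silhouette = silw, asw = fit$silinfo$avg.width,
                 cost = sum(fit$clusinfo[, "size"] * fit$clusinfo[, "av_diss"])),
            class = "cgs_clusters")
}

#' @export
print.cgs_clusters <- function(x, ...) {
  cat(sprintf("PAM clustering: k=%d, ASW=%.3f, sizes: %s\n", x$k, x$asw,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Choose the number of clusters by average silhouette width
#'
#' Runs [pam_cluster()] for every k in `k_range` and returns the result with
#' the largest average silhouette width, ties broken toward smaller k.  If
#' even the best ASW is below 0.25 the data show little cluster structure and
#' a warning is raised.
#'
#' @param S summary matrix, sets x samples.
#' @param k_range candidate cluster numbers (default `2:10`, clipped to n-1).
#' @param standardize passed to [pam_cluster()].
#' @return the winning `cgs_clusters`, with an `asw_table` attribute holding
#'   every (k, ASW) pair.
#' @export
choose_k <- function(S, k_range = 2:10, standardize = TRUE) {
  k_range <- k_range[k_range >= 2 & k_range < ncol(S)]
  if (!length(k_range)) stop("no feasible k in range")
  fits <- lapply(k_range, function(k) pam_cluster(S, k, standardize))
  asw <- vapply(fits, `[[`, numeric(1), "asw")
  best <- which.max(asw)                       # first max -> smaller k on ties
  if (asw[best] < 0.25)
    warning(sprintf("little cluster structure: best ASW %.3f < 0.25", asw[best]))
  out <- fits[[best]]
  attr(out, "asw_table") <- data.frame(k = k_range, asw = asw)
  out
}

#' Correlations between cluster centroids of two cohorts
#'
#' Centroids are per-cluster mean summary profiles over the sets shared by
#' both cohorts; the result is the Pearson correlation between every centroid
#' of A and every centroid of B.
#'
#' @param A,B matrices sets x clusters (centroids), rownames = set ids.
#' @return matrix clusters(A) x clusters(B) of correlations.
#' @export
centroid_correlation <- function(A, B) {
  shared <- intersect(rownames(A), rownames(B))
  if (length(shared) < 3)
    stop("fewer than 3 shared sets; centroid correlation is unstable")
  stats::cor(A[shared, , drop = FALSE], B[shared, , drop = FALSE])
}

#' Per-cluster centroids of a summary matrix
#'
#' @param S summary matrix, sets x samples.
#' @param labels cluster assignment per sample (named or in column order).
#' @return matrix sets x clusters of per-cluster mean summaries.
#' @export
cluster_centroids <- function(S, labels) {
  if (!is.null(names(labels))) labels <- labels[colnames(S)]
  g <- split(seq_len(ncol(S)), labels)
  out <- vapply(g, function(idx) rowMeans(S[, idx, drop = FALSE]),
                numeric(nrow(S)))
  rownames(out) <- rownames(S)
  out
}

#' Circularly aligned Spearman agreement of two angular orderings
#'
#' Orderings on a circle are defined up to rotation and reflection; this
#' helper computes the Spearman correlation of the two rank vectors maximized
#' over all circular offsets of the second ordering and over its reflection,
#' which is the natural agreement measure for split-half stability analyses.
#'
#' @param o1,o2 `sample_ordering` objects over the same samples.
#' @return maximal absolute Spearman correlation across alignments.
#' @export
ordering_agreement <- function(o1, o2) {
  ids <- o1$sample_id
  stopifnot(setequal(ids, o2$sample_id))
  n <- length(ids)
  r1 <- stats::setNames(o1$rank, o1$sample_id)[ids]
  r2 <- stats::setNames(o2$rank, o2$sample_id)[ids]
  best <- 0
  for (r2v in list(r2, (n + 1) - r2)) {          # identity and reflection
    for (off in 0:(n - 1)) {
      rr <- ((r2v - 1 + off) %% n) + 1
      best <- max(best, abs(stats::cor(r1, rr, method = "spearman")))
    }
  }
  best
}
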