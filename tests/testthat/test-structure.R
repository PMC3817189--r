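test_that("principal plane reproduces a direct eigendecomposition", {
  set.seed(31)
  S <- matrix(rnorm(5 * 20), 5, 20,
              dimnames = list(sprintf("set%d", 1:5), sprintf("s%02d", 1:20)))
  pl <- principal_plane(S)
  # eigensolver oracle on the sample covariance
  C <- cov(t(S))
  ev <- eigen(C, symmetric = TRUE)
  for (a in 1:2) {
    v <- ev$vectors[, a]
    if (v[which.max(abs(v))] < 0) v <- -v     # same sign convention
    want <- as.vector(t(S - rowMeans(S)) %*% v)
    expect_equal(unname(pl$coords[, a]), want, tolerance = 1e-10)
  }
  expect_gte(var(pl$coords[, 1]), var(pl$coords[, 2]))
})

test_that("rank-1 data collapse onto the first axis", {
  f <- rnorm(20)
  S <- rbind(a = 2 * f, b = -f, c = 0.5 * f)
  colnames(S) <- sprintf("s%02d", 1:20)
  pl <- principal_plane(S)
  expect_equal(unname(pl$coords[, 2]), rep(0, 20), tolerance = 1e-10)
  expect_error(principal_plane(S, axes = c(1, 10)), "rank|axis")
})

test_that("angular ordering matches axis-aligned geometry and is rotation invariant", {
  coords <- rbind(e = c(1, 0), n = c(0, 1), w = c(-1, 0), s = c(0, -1))
  ord <- angular_order(coords, reference = c(1, 0))
  expect_identical(ord$sample_id, c("e", "n", "w", "s"))
  expect_equal(ord$angle, c(0, pi / 2, pi, 3 * pi / 2))

  set.seed(5)
  pts <- matrix(rnorm(40), 20, 2,
                dimnames = list(sprintf("p%02d", 1:20), NULL))
  ref <- c(1, 2)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  o1 <- angular_order(pts, ref)
  o2 <- angular_order(pts %*% t(R), as.vector(R %*% ref))
  expect_identical(o1$sample_id, o2$sample_id)

  expect_error(angular_order(pts, c(0, 0)), "nonzero")

  # origin points go last, ordered by id
  pts2 <- rbind(pts, zzz = c(0, 0), aaa = c(0, 0))
  o3 <- angular_order(pts2, ref)
  expect_identical(tail(o3$sample_id, 2), c("aaa", "zzz"))
})

test_that("external projection is idempotent on the reference cohort", {
  co <- toy_cohort(seed = 41)
  coll <- suppressWarnings(extract_cgs(co$expr, K = 2, r_min = 0.6))
  S <- summarize_cgs(co$expr, coll)
  pl <- principal_plane(S)
  proj <- project_external(S, pl, co$expr, coll)
  expect_equal(unname(proj), unname(pl$coords), tolerance = 1e-10,
               ignore_attr = TRUE)

  # a sample at the reference per-gene mean lands at the origin
  Xm <- cbind(ext1 = rowMeans(co$expr))
  proj0 <- project_external(S, pl, Xm, coll)
  expect_equal(unname(proj0[1, ]), c(0, 0), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("externals drawn from a planted cluster land near that cluster", {
  design <- synthetic_design(n_samples = 120, n_background = 100,
                             module_sizes = rep(10, 3), k_clusters = 3,
                             phenotypes = list())
  co <- simulate_cohort(design, seed = 51)
  coll <- suppressWarnings(extract_cgs(co$expr, K = 3, r_min = 0.6))
  S <- summarize_cgs(co$expr, coll)
  pl <- principal_plane(S)
  cent <- sapply(split(seq_len(ncol(S)), co$truth$clusters[colnames(S)]),
                 function(i) colMeans(pl$coords[i, , drop = FALSE]))
  # draw fresh samples from cluster 2's distribution
  d <- co$truth$design
  set.seed(99)
  hits <- 0; n_draw <- 200
  mu_g <- rowMeans(co$expr)  # not exact baselines, but shared across clusters
  gm <- co$truth$gene_module
  for (rep in seq_len(n_draw)) {
    f <- rnorm(3) + d$cluster_shifts[2, ]
    x <- rnorm(nrow(co$expr), sd = d$sigma) + mu_g
    for (m in 1:3) {
      g <- which(!is.na(gm) & gm == m)
      x[g] <- x[g] + d$loading[m] * (f[m] - mean(co$truth$factors[, m]))
    }
    Xe <- cbind(ext = x)
    rownames(Xe) <- rownames(co$expr)
    p <- project_external(S, pl, Xe, coll)
    dist2 <- colSums((t(cent) - as.vector(p))^2)
    if (which.min(dist2) == 2) hits <- hits + 1
  }
  expect_gte(hits / n_draw, 0.95)
})

test_that("gene set mapping is exact set arithmetic and idempotent", {
  co <- toy_cohort(seed = 61)
  coll <- suppressWarnings(extract_cgs(co$expr, K = 2, r_min = 0.6))
  all_genes <- rownames(co$expr)
  m_all <- map_gene_sets(coll, all_genes)
  expect_true(all(attr(m_all, "mapping")$retained_fraction == 1))

  m_none <- map_gene_sets(coll, c("absent1", "absent2"))
  expect_length(m_none, 0)
  expect_true(all(!attr(m_none, "mapping")$mapped))

  set.seed(7)
  target <- sample(all_genes, length(all_genes) %/% 2)
  m_half <- map_gene_sets(coll, target, min_fraction = 0.2)
  info <- attr(m_half, "mapping")
  for (i in seq_along(coll)) {
    expect_equal(info$n_retained[i],
                 length(intersect(coll[[i]]$members, target)))
  }
  # idempotence
  m_twice <- map_gene_sets(m_half, target, min_fraction = 0.2)
  expect_equal(length(m_twice), length(m_half))
  for (i in seq_along(m_half))
    expect_setequal(m_twice[[i]]$members, m_half[[i]]$members)

  expect_error(map_gene_sets(coll, character(0)), "empty")
})

test_that("PAM recovers well-separated pairs with the hand-computed silhouette", {
  # 4 points: two tight pairs far apart
  S <- rbind(x = c(0, 0.5, 10, 10.5), y = c(0, 0, 0, 0.2))
  colnames(S) <- c("a", "b", "c", "d")
  res <- pam_cluster(S, 2, standardize = FALSE)
  expect_equal(unname(res$labels[c("a", "b")]), rep(res$labels[["a"]], 2))
  expect_equal(unname(res$labels[c("c", "d")]), rep(res$labels[["c"]], 2))
  D <- as.matrix(dist(t(S)))
  sil <- silhouette_direct(D, res$labels)
  expect_equal(unname(res$silhouette), sil, tolerance = 1e-10)
  expect_equal(res$asw, mean(sil), tolerance = 1e-10)
})

test_that("k = n-1 on distinct points yields exactly one pair cluster", {
  set.seed(3)
  S <- matrix(rnorm(2 * 8), 2, 8, dimnames = list(NULL, letters[1:8]))
  res <- pam_cluster(S, 7, standardize = FALSE)
  expect_equal(sum(table(res$labels) == 2), 1)
  expect_equal(sum(table(res$labels) == 1), 6)
})

test_that("PAM cost equals exhaustive medoid search on tiny clustered instances", {
  # separated blobs: the optimizer must find the obvious global optimum.
  # (On structureless data the swap neighbourhood can stop short of the
  # global optimum — an inherent property of local search, documented in the
  # methods vignette — so the brute-force check uses clustered instances.)
  for (seed in 1:8) {
    set.seed(seed)
    for (k in 2:3) {
      cl <- rep(1:k, each = 4)
      centers <- matrix(c(0, 0, 0, 6, 6, 0, 0, 6, 6), 3, 3)[, 1:k, drop = FALSE]
      S <- sapply(cl, function(j) centers[, j] + rnorm(3))
      colnames(S) <- sprintf("s%02d", seq_along(cl))
      res <- pam_cluster(S, k, standardize = FALSE)
      expect_equal(res$cost, exhaustive_pam_cost(dist(t(S)), k),
                   tolerance = 1e-10)
    }
  }
})

test_that("silhouette-based k selection recovers separated blobs and flags no structure", {
  set.seed(17)
  hits <- 0
  for (rep in 1:20) {
    centers <- matrix(c(0, 0, 8, 0, 0, 8), 2, 3)
    S <- sapply(sample(1:3, 45, replace = TRUE),
                function(k) centers[, k] + rnorm(2))
    colnames(S) <- sprintf("s%02d", 1:45)
    res <- choose_k(S, k_range = 2:6, standardize = FALSE)
    if (res$k == 3) hits <- hits + 1
    tab <- attr(res, "asw_table")
    expect_true(all(res$asw >= tab$asw))
  }
  expect_gte(hits, 19)

  set.seed(18)
  S1 <- matrix(rnorm(10 * 40), 10, 40, dimnames = list(NULL, sprintf("s%02d", 1:40)))
  expect_warning(res1 <- choose_k(S1, k_range = 2:5, standardize = FALSE),
                 "ASW")
  expect_lt(res1$asw, 0.25)
})

test_that("silhouette widths from choose_k match the direct formula", {
  co <- toy_cohort(seed = 71)
  S <- summarize_cgs(co$expr, suppressWarnings(extract_cgs(co$expr, K = 2, r_min = 0.6)))
  res <- suppressWarnings(choose_k(S, k_range = 2:4))
  D <- as.matrix(dist(scale(t(S))))
  sil <- silhouette_direct(D, res$labels)
  expect_equal(unname(res$silhouette), sil, tolerance = 1e-10)
})

test_that("centroid correlations are exact Pearson correlations on shared sets", {
  set.seed(23)
  A <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(sprintf("set%d", 1:5), NULL))
  expect_equal(unname(diag(centroid_correlation(A, A))), rep(1, 3))
  B <- 2 * A + 1                              # proportional profiles
  expect_equal(unname(diag(centroid_correlation(A, B))), rep(1, 3))
  B2 <- matrix(rnorm(5 * 2), 5, 2, dimnames = list(rownames(A), NULL))
  expect_equal(centroid_correlation(A, B2), cor(A, B2), tolerance = 1e-12)
  expect_error(centroid_correlation(A[1:2, , drop = FALSE], B2[1:2, , drop = FALSE]),
               "3 shared")
})
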