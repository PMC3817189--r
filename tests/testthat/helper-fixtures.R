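# Shared fixtures built in code.

# Small random expression matrix with unique gene/sample ids.
random_expr <- function(G = 10, n = 8, seed = 1) {
  set.seed(seed)
  matrix(rnorm(G * n, mean = 8), G, n,
         dimnames = list(sprintf("g%02d", 1:G), sprintf("s%02d", 1:n)))
}

# Two-module toy cohort used across extraction/structure tests.
toy_cohort <- function(seed = 11, n = 60) {
  simulate_cohort(
    synthetic_design(n_samples = n, n_background = 40,
                     module_sizes = c(8, 8), k_clusters = 1,
                     phenotypes = list(
                       list(name = "group", type = "categorical", factor = 1),
                       list(name = "score", type = "quantitative",
                            factor = 2, effect = 1))),
    seed = seed)
}

# Direct (loop-based) silhouette widths from a distance matrix and labels —
# the test-side oracle, independent of cluster::pam.
silhouette_direct <- function(D, labels) {
  D <- as.matrix(D)
  n <- length(labels)
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) == 1) return(0) else mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(k) mean(D[i, labels == k]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# Exhaustive PAM cost: minimal total distance to medoids over all k-subsets.
exhaustive_pam_cost <- function(D, k) {
  D <- as.matrix(D)
  n <- nrow(D)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(D[, med, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# Reference BH step-up, coded independently of stats::p.adjust.
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}
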