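# Latent-factor cohort simulator.
#
# Gene g in module m:  x_gi = mu_g + lambda_m * f_{m,i} + eps_gi,
# eps ~ N(0, sigma^2); factors f are standard normal per sample with
# per-cluster mean shifts; background genes are mu_g + eps.  The within-
# module correlation (within a cluster) is lambda^2 / (lambda^2 + sigma^2),
# so loadings can be chosen for a target correlation.  Phenotypes are
# derived from chosen factors (thresholding for categorical, linear plus
# noise for quantitative) or generated as pure noise.

#' Describe a synthetic cohort design
#'
#' Defaults describe the package's reference cohort: 150 samples, 10 modules
#' of 10 to 20 genes on top of 1850 background genes (2000 total), module
#' loading `sqrt(3)` with unit noise (within-cluster module correlation
#' 0.75), and 3 equally mixed sample clusters, cluster c shifting factor c by
#' 4 SD.  One factor per cluster keeps the between-module covariance
#' non-positive, so planted modules remain separable by positive-correlation
#' extraction while the clusters stay recoverable.
#'
#' @param n_samples number of samples.
#' @param n_background number of background (module-free) genes.
#' @param module_sizes integer vector, one entry per module.
#' @param loading factor loading lambda, scalar or per-module vector.
#' @param sigma residual SD (> 0).
#' @param k_clusters number of planted sample clusters (1 = no structure).
#' @param cluster_shifts k x n_modules matrix of factor-mean shifts; default
#'   `shift` at `[c, c]` for c up to `min(k, n_modules)`, 0 elsewhere.
#' @param shift default shift magnitude used to build `cluster_shifts`.
#' @param mixing cluster mixing proportions (default equal; must sum to 1).
#' @param baseline_mean,baseline_sd distribution of per-gene baselines mu_g.
#' @param bimodal_baseline draw baselines from a two-component mixture
#'   (mimicking the low/high global expression classes); off by default.
#' @param phenotypes list of phenotype descriptors, each a list with `name`,
#'   `type` ("categorical", "quantitative" or "null_categorical"/
#'   "null_quantitative"), `factor` (module index it tracks) and `effect`
#'   (slope for quantitative; categorical thresholds at the factor median).
#' @return list of class `cgsa_design`.
#' @export
synthetic_design <- function(n_samples = 150,
                             n_background = 1850,
                             module_sizes = round(seq(10, 20, length.out = 10)),
                             loading = sqrt(3),
                             sigma = 1,
                             k_clusters = 3,
                             cluster_shifts = NULL,
                             shift = 4,
                             mixing = NULL,
                             baseline_mean = 8, baseline_sd = 1.5,
                             bimodal_baseline = FALSE,
                             phenotypes = list(
                               list(name = "group", type = "categorical", factor = 1),
                               list(name = "activity", type = "quantitative",
                                    factor = 2, effect = 1),
                               list(name = "noise", type = "null_categorical"))) {
  M <- length(module_sizes)
  stopifnot(n_samples >= 3, all(module_sizes > 0), sigma > 0, k_clusters >= 1)
  if (is.null(mixing)) mixing <- rep(1 / k_clusters, k_clusters)
  stopifnot(length(mixing) == k_clusters, abs(sum(mixing) - 1) < 1e-8)
  if (is.null(cluster_shifts)) {
    cluster_shifts <- matrix(0, k_clusters, M)
    for (c in seq_len(min(k_clusters, M)))
      if (k_clusters > 1) cluster_shifts[c, c] <- shift
  }
  stopifnot(nrow(cluster_shifts) == k_clusters, ncol(cluster_shifts) == M)
  if (k_clusters > n_samples) stop("more clusters than samples")
  loading <- rep_len(loading, M)
  structure(list(n_samples = n_samples, n_background = n_background,
                 module_sizes = module_sizes, loading = loading, sigma = sigma,
                 k_clusters = k_clusters, cluster_shifts = cluster_shifts,
                 mixing = mixing, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, bimodal_baseline = bimodal_baseline,
                 phenotypes = phenotypes),
            class = "cgsa_design")
}

#' Simulate a cohort from a design
#'
#' Fully reproducible from the seed (R's default Mersenne-Twister generator;
#' the seed and generator are recorded in the truth object).
#'
#' @param design a `cgsa_design`.
#' @param seed integer RNG seed.
#' @return list of class `cgsa_cohort`: `expr` (genes x samples matrix),
#'   `pheno` (data.frame with sample_id and phenotype columns), `truth`
#'   (list: `modules` named list module -> gene ids, `gene_module` named
#'   vector, `clusters` named integer vector, `factors` samples x modules
#'   matrix, `seed`, `design`).
#' @export
simulate_cohort <- function(design, seed) {
  stopifnot(inherits(design, "cgsa_design"))
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  d <- design
  M <- length(d$module_sizes)
  n <- d$n_samples
  G <- sum(d$module_sizes) + d$n_background
  gene_ids <- sprintf("g%04d", seq_len(G))
  sample_ids <- sprintf("s%03d", seq_len(n))

  clusters <- sample(seq_len(d$k_clusters), n, replace = TRUE, prob = d$mixing)
  F <- matrix(stats::rnorm(n * M), n, M)
  if (d$k_clusters > 1) F <- F + d$cluster_shifts[clusters, , drop = FALSE]

  if (d$bimodal_baseline) {
    comp <- sample(1:2, G, replace = TRUE, prob = c(0.35, 0.65))
    mu <- stats::rnorm(G, mean = c(d$baseline_mean - 2.5,
                                   d$baseline_mean + 0.5)[comp],
                       sd = d$baseline_sd)
  } else {
    mu <- stats::rnorm(G, d$baseline_mean, d$baseline_sd)
  }

  gene_module <- rep(NA_integer_, G)
  idx <- 0L
  X <- matrix(stats::rnorm(G * n, sd = d$sigma), G, n)
  for (m in seq_len(M)) {
    g <- idx + seq_len(d$module_sizes[m])
    X[g, ] <- X[g, ] + d$loading[m] * matrix(F[, m], length(g), n, byrow = TRUE)
    gene_module[g] <- m
    idx <- idx + d$module_sizes[m]
  }
  X <- X + mu
  dimnames(X) <- list(gene_ids, sample_ids)

  pheno <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  for (ph in d$phenotypes) {
    y <- switch(ph$type,
      categorical = {
        f <- F[, ph$factor]
        factor(ifelse(f > stats::median(f), "high", "low"), c("low", "high"))
      },
      quantitative = ph$effect * F[, ph$factor] + stats::rnorm(n),
      null_categorical = factor(sample(c("a", "b"), n, replace = TRUE)),
      null_quantitative = stats::rnorm(n),
      stop("unknown phenotype type '", ph$type, "'"))
    pheno[[ph$name]] <- y
  }

  modules <- split(gene_ids[!is.na(gene_module)],
                   gene_module[!is.na(gene_module)])
  names(modules) <- sprintf("module%02d", as.integer(names(modules)))
  structure(list(expr = X, pheno = pheno,
                 truth = list(modules = modules,
                              gene_module = stats::setNames(gene_module, gene_ids),
                              clusters = stats::setNames(clusters, sample_ids),
                              factors = `dimnames<-`(F, list(sample_ids, names(modules))),
                              seed = seed, generator = RNGkind()[1],
                              design = d)),
            class = "cgsa_cohort")
}

#' @export
print.cgsa_cohort <- function(x, ...) {
  d <- x$truth$design
  cat(sprintf("Synthetic cohort: %d genes x %d samples, %d module(s), %d cluster(s), seed %d\n",
              nrow(x$expr), ncol(x$expr), length(d$module_sizes),
              d$k_clusters, x$truth$seed))
  invisible(x)
}

#' Truth-recovery metrics for an extracted collection
#'
#' Each planted module is matched one-to-one to the found set maximizing the
#' Jaccard index, greedily on the sorted list of (module, set, Jaccard)
#' pairs; unmatched modules score 0.  Cluster label agreement is the
#' adjusted Rand index (chance-corrected).
#'
#' @param found a `cgs_collection` (may be empty).
#' @param truth the `truth` element of a `cgsa_cohort`.
#' @param found_clusters optional cluster labels (named by sample) to compare
#'   with the planted clusters.
#' @return list with `jaccard` (named per-module vector), `mean_jaccard`,
#'   `matching` (data.frame module/set_id/jaccard), and when labels given:
#'   `ari` and `confusion` (table planted x found).
#' @export
recovery_metrics <- function(found, truth, found_clusters = NULL) {
  modules <- truth$modules
  jac <- stats::setNames(numeric(length(modules)), names(modules))
  match_set <- stats::setNames(rep(NA_character_, length(modules)), names(modules))
  if (length(found)) {
    J <- matrix(0, length(modules), length(found),
                dimnames = list(names(modules), seq_along(found)))
    for (i in seq_along(modules)) for (j in seq_along(found)) {
      a <- modules[[i]]; b <- found[[j]]$members
      J[i, j] <- length(intersect(a, b)) / length(union(a, b))
    }
    ord <- order(-J)
    used_m <- logical(length(modules)); used_s <- logical(length(found))
    for (pos in ord) {
      if (J[pos] == 0) break
      i <- (pos - 1) %% length(modules) + 1
      j <- (pos - 1) %/% length(modules) + 1
      if (used_m[i] || used_s[j]) next
      used_m[i] <- TRUE; used_s[j] <- TRUE
      jac[i] <- J[i, j]
      match_set[i] <- found[[j]]$center
    }
  }
  out <- list(jaccard = jac, mean_jaccard = mean(jac),
              matching = data.frame(module = names(modules), set_id = match_set,
                                    jaccard = jac, row.names = NULL,
                                    stringsAsFactors = FALSE))
  if (!is.null(found_clusters)) {
    planted <- truth$clusters
    ids <- intersect(names(planted), names(found_clusters))
    out$ari <- mclust::adjustedRandIndex(planted[ids], found_clusters[ids])
    out$confusion <- table(planted = planted[ids], found = found_clusters[ids])
  }
  out
}

#' Write a cohort to disk in the package's standard formats
#'
#' Emits the expression TSV, phenotype TSV, and truth tables (gene-module and
#' sample-cluster maps) under a common path prefix.
#'
#' @param cohort a `cgsa_cohort`.
#' @param prefix output path prefix.
#' @return invisibly, the named vector of files written.
#' @export
write_cohort <- function(cohort, prefix) {
  files <- c(expr = paste0(prefix, "_expr.tsv"),
             pheno = paste0(prefix, "_pheno.tsv"),
             gene_module = paste0(prefix, "_gene_module.tsv"),
             clusters = paste0(prefix, "_clusters.tsv"))
  write_expression_table(cohort$expr, files["expr"])
  utils::write.table(cohort$pheno, files["pheno"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(cohort$truth$gene_module),
               module = cohort$truth$gene_module),
    files["gene_module"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(cohort$truth$clusters),
               cluster = cohort$truth$clusters),
    files["clusters"], sep = "\t", quote = FALSE, row.names = FALSE)
  cgsa_log("cohort written to %s_* (seed %d, generator %s)", prefix,
           cohort$truth$seed, cohort$truth$generator)
  invisible(files)
}
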