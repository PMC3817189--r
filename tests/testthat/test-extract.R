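test_that("center correlations match the textbook formula and handle degeneracy", {
  X <- random_expr(5, 8, seed = 7)
  X["g02", ] <- 2 * X["g01", ] - 3        # exact collinearity
  X["g03", ] <- -X["g01", ] + 10          # exact anti-collinearity
  r <- correlation_with_center(X, "g01")
  expect_equal(unname(r["g01"]), 1)
  expect_equal(unname(r["g02"]), 1)
  expect_equal(unname(r["g03"]), -1)
  expect_true(all(r >= -1 & r <= 1))

  # two-pass covariance/SD oracle
  oracle <- apply(X, 1, function(x) {
    cv <- sum((x - mean(x)) * (X["g01", ] - mean(X["g01", ]))) / (ncol(X) - 1)
    cv / (sd(x) * sd(X["g01", ]))
  })
  expect_equal(unname(r), unname(oracle), tolerance = 1e-12)

  X["g04", ] <- 5                          # zero variance
  expect_error(correlation_with_center(X, "g04"), "zero variance")
  expect_warning(r2 <- correlation_with_center(X, "g01"), "zero-variance")
  expect_equal(unname(r2["g04"]), 0)
})

test_that("candidate sets include exactly the positively correlated genes", {
  X <- random_expr(4, 10, seed = 2)
  rownames(X) <- c("A", "B", "C", "D")
  X["B", ] <- 2 * X["A", ]
  X["C", ] <- -X["A", ]
  s <- build_candidate_set(X, "A", r_min = 0.7)
  expect_setequal(s$members, c("A", "B"))

  # near-1 threshold leaves the center essentially alone on noisy data
  Y <- random_expr(30, 20, seed = 5)
  s2 <- build_candidate_set(Y, "g01", r_min = 0.999)
  expect_identical(s2$members, "g01")
})

test_that("the score formula is s2_c times summed squared correlations", {
  # singleton with unit center variance scores 1; an exact double scores 2
  X <- random_expr(4, 12, seed = 9)
  rownames(X) <- c("A", "B", "C", "D")
  X["A", ] <- as.vector(scale(X["A", ])) * sqrt(1)   # unit variance
  X["B", ] <- 2 * X["A", ]
  expect_equal(score_candidate_set(X, list(center = "A", members = "A")), 1)
  expect_equal(score_candidate_set(X, list(center = "A", members = c("A", "B"))), 2)

  # term-wise oracle on a random 4-gene candidate
  Z <- random_expr(6, 15, seed = 13)
  set <- list(center = "g02", members = c("g02", "g04", "g05", "g06"))
  oracle <- var(Z["g02", ]) *
    sum(sapply(set$members, function(g) cor(Z["g02", ], Z[g, ])^2))
  expect_equal(score_candidate_set(Z, set), oracle, tolerance = 1e-12)

  expect_error(score_candidate_set(Z, list(center = "g02", members = c("g02", "nope"))),
               "nope")

  # monotonicity: adding a positively correlated member never lowers the score
  set.seed(21)
  for (i in 1:20) {
    W <- random_expr(8, 12, seed = 100 + i)
    r <- correlation_with_center(W, "g01")
    pos <- setdiff(names(r)[r > 0], "g01")
    if (length(pos) < 2) next
    base <- list(center = "g01", members = c("g01", pos[1]))
    bigger <- list(center = "g01", members = c("g01", pos[1:2]))
    expect_gte(score_candidate_set(W, bigger), score_candidate_set(W, base))
  }
})

test_that("greedy selection accepts by score, skips overlaps, and caps at K", {
  # hand-enumerable trace: S1={A,B} 5, S2={B,C} 4, S3={D,E} 3, K=2
  X <- matrix(rnorm(5 * 30), 5, 30,
              dimnames = list(c("A", "B", "C", "D", "E"), sprintf("s%02d", 1:30)))
  fA <- rnorm(30); fD <- rnorm(30)
  X["A", ] <- 3 * fA + 0.1 * rnorm(30)
  X["B", ] <- 2.5 * fA + 0.3 * rnorm(30)
  X["C", ] <- 1.5 * fA + 1.2 * rnorm(30)   # correlated with B via fA but below A,B
  X["D", ] <- 2 * fD + 0.2 * rnorm(30)
  X["E", ] <- 1.8 * fD + 0.3 * rnorm(30)
  coll <- extract_cgs(X, K = 2, r_min = 0.7, min_size = 2)
  expect_equal(length(coll), 2)
  centers <- vapply(coll, `[[`, character(1), "center")
  members <- lapply(coll, `[[`, "members")
  expect_length(intersect(members[[1]], members[[2]]), 0)
  expect_true(coll[[1]]$score >= coll[[2]]$score)
  expect_equal(vapply(coll, `[[`, integer(1), "rank"), 1:2)
})

test_that("fast greedy equals a naive rescan reference on small instances", {
  naive_select <- function(X, K, r_min, min_size) {
    R <- cor(t(X)); v <- apply(X, 1, var)
    cand <- lapply(rownames(X), function(g) {
      members <- rownames(X)[R[g, ] >= r_min]
      list(center = g, members = members,
           score = v[g] * sum(R[g, members]^2))
    })
    accepted <- list()
    repeat {
      ok <- Filter(function(s) {
        length(s$members) >= min_size &&
          !any(s$members %in% unlist(lapply(accepted, `[[`, "members")))
      }, cand)
      if (!length(ok) || length(accepted) >= K) break
      scores <- vapply(ok, `[[`, numeric(1), "score")
      ids <- vapply(ok, `[[`, character(1), "center")
      best <- ok[[order(-scores, ids)[1]]]
      accepted[[length(accepted) + 1]] <- best
    }
    accepted
  }
  for (seed in 1:10) {
    X <- random_expr(12, 10, seed = seed)
    got <- suppressWarnings(extract_cgs(X, K = 4, r_min = 0.5, min_size = 2))
    want <- naive_select(X, 4, 0.5, 2)
    expect_equal(length(got), length(want))
    for (i in seq_along(got)) {
      expect_identical(got[[i]]$center, want[[i]]$center)
      expect_setequal(got[[i]]$members, want[[i]]$members)
      expect_equal(got[[i]]$score, want[[i]]$score, tolerance = 1e-12)
    }
  }
})

test_that("identical candidates collapse to one set and K caps the output", {
  # all genes perfectly collinear -> one candidate membership, one set
  base <- rnorm(20)
  X <- t(sapply(1:6, function(i) i * base + i))
  dimnames(X) <- list(sprintf("g%d", 1:6), sprintf("s%02d", 1:20))
  coll <- suppressWarnings(extract_cgs(X, K = 3, r_min = 0.7))
  expect_equal(length(coll), 1)
  expect_setequal(coll[[1]]$members, rownames(X))

  co <- toy_cohort(seed = 3)
  expect_lte(length(suppressWarnings(extract_cgs(co$expr, K = 50, r_min = 0.6))), 50)
})

test_that("extraction is permutation invariant and deterministic", {
  co <- toy_cohort(seed = 8)
  X <- co$expr
  coll1 <- suppressWarnings(extract_cgs(X, K = 5, r_min = 0.6))
  set.seed(1); perm <- sample(ncol(X))
  coll2 <- suppressWarnings(extract_cgs(X[, perm], K = 5, r_min = 0.6))
  expect_equal(length(coll1), length(coll2))
  for (i in seq_along(coll1)) {
    expect_identical(coll1[[i]]$center, coll2[[i]]$center)
    expect_setequal(coll1[[i]]$members, coll2[[i]]$members)
    expect_equal(coll1[[i]]$score, coll2[[i]]$score, tolerance = 1e-12)
  }
  # byte-identical GMT across two runs on identical input
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gmt(suppressWarnings(extract_cgs(X, K = 5, r_min = 0.6)), f1)
  write_gmt(suppressWarnings(extract_cgs(X, K = 5, r_min = 0.6)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("summaries are inverse-SD weighted sums, oriented and standardized", {
  co <- toy_cohort(seed = 15)
  X <- co$expr
  coll <- suppressWarnings(extract_cgs(X, K = 2, r_min = 0.6))
  S <- summarize_cgs(X, coll, standardize = TRUE)
  expect_equal(unname(rowMeans(S)), rep(0, nrow(S)), tolerance = 1e-8)
  expect_equal(unname(apply(S, 1, sd)), rep(1, nrow(S)), tolerance = 1e-8)
  for (i in seq_along(coll))
    expect_gt(cor(S[i, ], X[coll[[i]]$center, ]), 0)

  # term-wise oracle on the raw (unstandardized) summary
  Sraw <- summarize_cgs(X, coll, standardize = FALSE)
  set <- coll[[1]]
  w <- 1 / apply(X[set$members, ], 1, sd)
  oracle <- colSums(X[set$members, ] * w)
  sgn <- attr(Sraw, "signs")[1]
  expect_equal(unname(Sraw[1, ]), unname(sgn * oracle), tolerance = 1e-12)

  # two identical standardized genes -> summary equals that profile
  z <- rnorm(30)
  Y <- rbind(g1 = z, g2 = z)
  colnames(Y) <- sprintf("s%02d", 1:30)
  coll2 <- gmt_as_collection(list(g1 = c("g1", "g2")))
  S2 <- summarize_cgs(Y, coll2, standardize = TRUE)
  expect_equal(unname(S2[1, ]), unname(as.vector(scale(z))), tolerance = 1e-10)
})
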