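two_blobs <- function(n_per = 6, p = 20, sep = 10, sd = 1, seed = 1) {
  set.seed(seed)
  centre <- rbind(rep(0, p), c(rep(sep, 3), rep(0, p - 3)))
  X <- rbind(
    matrix(rnorm(n_per * p, 0, sd), n_per, p),
    sweep(matrix(rnorm(n_per * p, 0, sd), n_per, p), 2, centre[2, ], "+"))
  rownames(X) <- paste0("it", seq_len(2 * n_per))
  X
}

test_that("consensus separates well-separated blobs at k = 2", {
  X <- two_blobs(sep = 10)
  cm <- consensus_matrix(X, 2, reps = 200, seed = 3)
  within <- c(cm[1:6, 1:6][upper.tri(diag(6))],
              cm[7:12, 7:12][upper.tri(diag(6))])
  across <- cm[1:6, 7:12]
  expect_true(all(within >= 0.95))
  expect_true(all(across <= 0.05))
})

test_that("consensus matrices are symmetric with unit diagonal", {
  set.seed(9)
  X <- matrix(rnorm(12 * 8), 12)
  cm <- consensus_matrix(X, 3, reps = 300, seed = 1)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 12))
  expect_true(all(cm >= 0 & cm <= 1))
  # identical duplicated items always co-cluster
  X[2, ] <- X[1, ]
  cm2 <- consensus_matrix(X, 2, reps = 300, seed = 2)
  expect_equal(cm2[1, 2], 1)
  expect_error(consensus_matrix(X[1:3, ], 5),
               class = "actinospec_domain_error")
})

test_that("the inner k-means agrees with stats::kmeans on separated data", {
  X <- two_blobs(sep = 10, seed = 4)
  set.seed(1)
  ours <- actinospec:::.cpp_kmeans_assign(X, 2L, 10L, 25L, TRUE)
  ref <- stats::kmeans(X, 2, nstart = 10)$cluster
  # same partition up to label switching
  expect_equal(length(unique(paste(ours, ref))), 2)
})

test_that("PAC counts exactly the ambiguous consensus mass", {
  stable <- diag(12)
  stable[1:6, 1:6] <- 1; stable[7:12, 7:12] <- 1
  expect_equal(pac_score(stable), 0)
  total <- matrix(0.5, 10, 10); diag(total) <- 1
  expect_equal(pac_score(total), 1)
  # counting oracle: 10 upper-triangle entries, 4 inside (0.1, 0.9]
  cm <- diag(5)
  vals <- c(0.05, 0.1, 0.95, 1, 0, 0.2, 0.5, 0.9, 0.11, 0.04)
  cm[upper.tri(cm)] <- vals
  cm <- cm + t(cm); diag(cm) <- 1
  expect_equal(pac_score(cm), 0.4)
  expect_error(pac_score(cm, 0.9, 0.1), class = "actinospec_domain_error")
})

test_that("null references preserve shape and covariance eigenvalues", {
  set.seed(30)
  X <- matrix(rnorm(12 * 40), 12) %*% diag(c(8, 5, 3, rep(0.5, 37)))
  rownames(X) <- paste0("w", 1:12)
  refs <- simulate_null_references(X, B = 200, seed = 5)
  expect_length(refs, 200)
  expect_equal(dim(refs[[1]]), dim(X))
  expect_equal(rownames(refs[[1]]), rownames(X))
  ev <- function(M) {
    d <- svd(sweep(M, 2, colMeans(M)), nu = 0, nv = 0)$d
    d[1:3]^2 / (nrow(M) - 1)   # the dominant structure-carrying directions
  }
  mean_ref_ev <- Reduce(`+`, lapply(refs, ev)) / length(refs)
  expect_true(all(abs(mean_ref_ev / ev(X) - 1) < 0.1))
  # deterministic under a fixed seed
  r1 <- simulate_null_references(X, B = 2, seed = 7)
  r2 <- simulate_null_references(X, B = 2, seed = 7)
  expect_identical(r1, r2)
  expect_error(simulate_null_references(matrix(1, 5, 3)),
               class = "actinospec_domain_error")
})

test_that("select_k recovers planted two- and three-group structures", {
  # groups are driven by disjoint feature subsets, as in the generator
  mk_groups <- function(sizes, p = 120, delta = 0.6, sd = 0.12, seed) {
    set.seed(seed)
    n <- sum(sizes)
    g <- rep(seq_along(sizes), sizes)
    driver <- sample(seq_along(sizes), p, replace = TRUE)
    X <- matrix(rnorm(n * p, 0, sd), n, p) - delta * outer(g, driver, "==")
    rownames(X) <- paste0("it", 1:n)
    X
  }
  ok2 <- 0; ok3 <- 0; split_ok <- TRUE
  for (s in 1:5) {
    # a lone two-group contrast leaves the null quasi-one-dimensional, so
    # the two-group case needs a sizeable within-group noise floor
    sc2 <- select_k(mk_groups(c(6, 6), sd = 0.3, seed = s),
                    k_range = 2:5, reps = 300, B = 40, seed = s + 50)
    ok2 <- ok2 + (sc2$selected_k == 2L)
    if (sc2$selected_k == 2L)
      split_ok <- split_ok &&
        length(unique(sc2$assignments[1:6])) == 1 &&
        length(unique(sc2$assignments[7:12])) == 1
    sc3 <- select_k(mk_groups(c(4, 4, 4), seed = s),
                    k_range = 2:5, reps = 300, B = 40, seed = s + 70)
    ok3 <- ok3 + (sc3$selected_k == 3L)
  }
  expect_gte(ok2, 4)
  expect_gte(ok3, 4)
  expect_true(split_ok)
})

test_that("p-values on unimodal data are rarely significant", {
  # K = 1 Gaussian input: the scan should usually declare no significant K
  hits <- 0
  for (trial in 1:15) {
    set.seed(100 + trial)
    X <- matrix(rnorm(12 * 30), 12) %*% diag(runif(30, 0.5, 2))
    sc <- select_k(X, k_range = 2:5, reps = 200, B = 40,
                   seed = 200 + trial)
    hits <- hits + (sc$selected_k == 1L)
  }
  expect_gte(hits, 13)  # >= ~90% of trials
})

test_that("a consensus scan is reproducible under a fixed seed", {
  X <- two_blobs(sep = 5, seed = 21)
  a <- select_k(X, k_range = 2:4, reps = 200, B = 20, seed = 33)
  b <- select_k(X, k_range = 2:4, reps = 200, B = 20, seed = 33)
  expect_identical(a$scores, b$scores)
  expect_identical(a$consensus, b$consensus)
  expect_identical(a$assignments, b$assignments)
})

test_that("cluster assignments map to contiguous wavelength bands", {
  wl <- seq(290, 400, by = 10)
  asg <- setNames(c(rep(1, 4), rep(2, 4), rep(3, 4)), wl)
  bands <- map_clusters(asg)
  expect_equal(bands$band, c("290-320", "330-360", "370-400"))
  expect_equal(bands$cluster, c(1, 2, 3))
  # single cluster spans everything
  expect_equal(map_clusters(setNames(rep(1, 12), wl))$band, "290-400")
  # a non-contiguous cluster is reported as separate runs
  split <- map_clusters(setNames(c(1, 2, 1, 2), c(290, 300, 310, 320)))
  expect_equal(nrow(split), 4)
  # blank is reported apart from the wavelength runs
  withb <- map_clusters(setNames(c(1, 1, 2, 3), c(290, 300, 310, "blank")))
  expect_equal(nrow(withb), 2)
  expect_equal(attr(withb, "blank_cluster"), 3)
})
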