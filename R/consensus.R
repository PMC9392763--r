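# Monte-Carlo reference-based consensus clustering: consensus matrices from
# subsampled k-means, PAC scores, simulated K=1 null references, K selection.

#' @noRd
pc_project <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nv = 0)
  keep <- sv$d > max(sv$d) * 1e-12
  if (!any(keep))
    as_error("degenerate (zero-variance) data", "actinospec_domain_error")
  S <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  rownames(S) <- rownames(X)
  S
}

#' Consensus matrix from subsampled k-means
#'
#' Over `reps` resampling runs: subsample items without replacement, cluster
#' the subsample with k-means (Lloyd, `nstart` random restarts), and record
#' pairwise co-assignment. Entry (i, j) is the fraction of runs in which i
#' and j were assigned to the same cluster among runs where both were
#' sampled; the diagonal is 1. Items are internally projected onto their
#' principal-component row space, which leaves all pairwise Euclidean
#' distances (and hence the k-means objective) unchanged.
#'
#' @param X numeric items x features matrix (items >= k).
#' @param k number of clusters (>= 2).
#' @param reps number of resampling runs (default 100; with ~12 items use
#'   500 so every pair is co-sampled).
#' @param subsample_fraction fraction of items per run (default 0.8).
#' @param nstart,iter_max k-means initialisations per run and iteration cap.
#' @param init `"pp"` (default): k-means++ seeding, whose data-adaptive
#'   randomness keeps the consensus near-deterministic on well-separated
#'   clusters yet variable on unimodal data, which the Monte-Carlo null
#'   comparison relies on at small item counts; `"random"`: distinct random
#'   points.
#' @param seed optional seed (`set.seed` is called when non-`NULL`).
#' @return symmetric items x items matrix with entries in [0, 1] and unit
#'   diagonal. Errors if an item pair is never co-sampled.
#' @export
consensus_matrix <- function(X, k, reps = 100, subsample_fraction = 0.8,
                             nstart = 1, iter_max = 25,
                             init = c("pp", "random"), seed = NULL) {
  init <- match.arg(init)
  X <- as.matrix(X)
  if (k < 2 || k > nrow(X))
    as_error("need items >= k >= 2", "actinospec_domain_error")
  if (ncol(X) < 1) as_error("need at least one feature",
                            "actinospec_domain_error")
  if (!is.null(seed)) set.seed(seed)
  cm <- .cpp_consensus_matrix(pc_project(X), as.integer(k), as.integer(reps),
                              subsample_fraction, as.integer(nstart),
                              as.integer(iter_max), init == "pp")
  dimnames(cm) <- list(rownames(X), rownames(X))
  cm
}

#' Proportion of ambiguous clustering (PAC)
#'
#' The mass of the empirical CDF of the upper-triangle consensus entries
#' falling in the ambiguous window: `CDF(upper) - CDF(lower)`, i.e. the
#' fraction of entries in `(lower, upper]`. 0 for a perfectly stable
#' clustering (all entries 0 or 1), 1 for total ambiguity.
#'
#' @param cm consensus matrix.
#' @param lower,upper window cut-offs, `0 <= lower < upper <= 1`
#'   (defaults 0.1, 0.9).
#' @return PAC in [0, 1].
#' @export
pac_score <- function(cm, lower = 0.1, upper = 0.9) {
  if (!(lower >= 0 && lower < upper && upper <= 1))
    as_error("require 0 <= lower < upper <= 1", "actinospec_domain_error")
  e <- cm[upper.tri(cm)]
  mean(e > lower & e <= upper)
}

#' Simulate K = 1 null reference data sets
#'
#' Each reference is drawn from a single multivariate Gaussian whose
#' feature-covariance eigen-structure matches the data
#' (principal-component-preserving sampling): unimodal K = 1 data with the
#' real data's correlation structure, used as the null when testing higher
#' K.
#'
#' @param X numeric items x features matrix (items >= 3).
#' @param B number of references (default 100).
#' @param seed optional seed.
#' @return list of B matrices with the shape (and dimnames) of `X`.
#' @export
simulate_null_references <- function(X, B = 100, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) as_error("need at least 3 items", "actinospec_domain_error")
  if (!is.null(seed)) set.seed(seed)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0)
  keep <- sv$d > max(sv$d) * 1e-12
  if (!any(keep))
    as_error("degenerate (zero-variance) data", "actinospec_domain_error")
  sds <- sv$d[keep] / sqrt(n - 1)
  V <- sv$v[, keep, drop = FALSE]
  mu <- colMeans(X)
  lapply(seq_len(B), function(b) {
    Z <- matrix(rnorm(n * length(sds)), n) %*% (sds * t(V))
    ref <- sweep(Z, 2, mu, "+")
    dimnames(ref) <- dimnames(X)
    ref
  })
}

#' Monte-Carlo consensus scan and K selection
#'
#' For each K in `k_range`: the real consensus matrix and PAC, and the PAC
#' of the same pipeline on B simulated K = 1 references. The p-value for
#' each K is the add-one permutation estimator
#' `(1 + #\{null PAC <= real PAC\}) / (B + 1)`; the relative cluster
#' stability index is `RCSI = mean(ln null PAC) - ln(real PAC)` with PAC
#' floored at 1/n_pairs. The selected K maximises RCSI among K with
#' p < `alpha`; if none is significant the data are taken as unimodal
#' (selected K = 1).
#'
#' @param X numeric items x features matrix (rownames label the items, e.g.
#'   wavelengths).
#' @param k_range candidate K values (default 2:8).
#' @param reps resampling runs per consensus matrix (default 500).
#' @param B number of null references (default 100).
#' @param subsample_fraction,nstart,iter_max,init passed to
#'   [consensus_matrix()].
#' @param pac_window `c(lower, upper)` PAC cut-offs (default 0.1, 0.9).
#' @param alpha significance level for K (default 0.05).
#' @param seed optional seed governing the whole scan.
#' @return a list of class `consensus_scan`: `scores` (tibble `k, pac,
#'   p_value, rcsi`), `null_pac` (B x K matrix), `consensus` (list of real
#'   consensus matrices), `selected_k`, `assignments` (named integer vector
#'   for the selected K; all 1 when K = 1).
#' @export
select_k <- function(X, k_range = 2:8, reps = 500, B = 100,
                     subsample_fraction = 0.8, nstart = 1, iter_max = 25,
                     init = c("pp", "random"), pac_window = c(0.1, 0.9),
                     alpha = 0.05, seed = NULL) {
  init <- match.arg(init)
  pp <- init == "pp"
  X <- as.matrix(X)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rownames(X))) rownames(X) <- seq_len(nrow(X))
  k_range <- sort(unique(as.integer(k_range)))
  floor_pac <- 1 / choose(nrow(X), 2)
  Xp <- pc_project(X)

  scan_one <- function(M) {
    vapply(k_range, function(k) {
      cm <- .cpp_consensus_matrix(M, as.integer(k), as.integer(reps),
                                  subsample_fraction, as.integer(nstart),
                                  as.integer(iter_max), pp)
      pac_score(cm, pac_window[1], pac_window[2])
    }, numeric(1))
  }

  cons <- lapply(k_range, function(k) {
    cm <- .cpp_consensus_matrix(Xp, as.integer(k), as.integer(reps),
                                subsample_fraction, as.integer(nstart),
                                as.integer(iter_max), pp)
    dimnames(cm) <- list(rownames(X), rownames(X))
    cm
  })
  names(cons) <- as.character(k_range)
  real_pac <- vapply(cons, pac_score, numeric(1),
                     lower = pac_window[1], upper = pac_window[2])

  refs <- simulate_null_references(X, B)
  null_pac <- t(vapply(refs, function(ref) scan_one(pc_project(ref)),
                       numeric(length(k_range))))
  colnames(null_pac) <- as.character(k_range)

  p_value <- vapply(seq_along(k_range), function(j) {
    (1 + sum(null_pac[, j] <= real_pac[j])) / (B + 1)
  }, numeric(1))
  rcsi <- vapply(seq_along(k_range), function(j) {
    mean(log(pmax(null_pac[, j], floor_pac))) -
      log(max(real_pac[j], floor_pac))
  }, numeric(1))

  sig <- which(p_value < alpha)
  selected_k <- if (length(sig) == 0) 1L else k_range[sig[which.max(rcsi[sig])]]
  assignments <- if (selected_k == 1L) {
    setNames(rep(1L, nrow(X)), rownames(X))
  } else {
    setNames(.cpp_kmeans_assign(Xp, as.integer(selected_k), 100L,
                                as.integer(iter_max), pp), rownames(X))
  }
  structure(list(
    scores = tibble::tibble(k = k_range, pac = unname(real_pac),
                            p_value = p_value, rcsi = rcsi),
    null_pac = null_pac, consensus = cons,
    selected_k = selected_k, assignments = assignments),
    class = "consensus_scan")
}

#' @export
print.consensus_scan <- function(x, ...) {
  cat(sprintf("<consensus_scan> selected K = %d\n", x$selected_k))
  print(x$scores)
  invisible(x)
}

#' Map cluster assignments to contiguous wavelength bands
#'
#' Reports each cluster as runs of contiguous wavelengths (no silent
#' merging of non-contiguous runs). An item labelled `"blank"` (the blank
#' filter-position control) is reported separately.
#'
#' @param assignments named integer vector (names = wavelength in nm, or
#'   `"blank"`), e.g. from [select_k()].
#' @return tibble `cluster, band, n_items` sorted by band start; the blank
#'   item's cluster (if present) is attached as attribute `blank_cluster`.
#' @export
map_clusters <- function(assignments) {
  labs <- names(assignments)
  if (is.null(labs))
    as_error("assignments must be named by wavelength",
             "actinospec_domain_error")
  blank <- assignments[labs == "blank"]
  wl_i <- labs != "blank"
  wl <- as.numeric(labs[wl_i])
  cl <- assignments[wl_i]
  o <- order(wl)
  wl <- wl[o]; cl <- cl[o]
  r <- rle(as.vector(cl))
  stop_i <- cumsum(r$lengths)
  start_i <- stop_i - r$lengths + 1L
  out <- tibble::tibble(
    cluster = r$values,
    band = sprintf("%g-%g", wl[start_i], wl[stop_i]),
    n_items = r$lengths)
  if (length(blank) > 0) attr(out, "blank_cluster") <- unname(blank)
  out
}
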