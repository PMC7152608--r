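#' Permutation Mahalanobis test on GCoE cluster sizes
#'
#' Asks whether the size distribution of a pattern set's subclusters
#' deviates from what independent transcripts would give. Each permutation
#' shuffles every transcript's per-line profile across lines independently
#' (destroying transcript-transcript co-association while preserving each
#' transcript's multiset of values), reclusters into `k` groups, sorts the
#' sizes in descending order and drops the smallest, yielding a
#' `(k-1)`-vector. The observed vector's squared Mahalanobis distance from
#' the permutation mean, under the permutation covariance, is referred to
#' chi-squared with `k - 1` degrees of freedom (7 when `k = 8`).
#'
#' @param lsm lines x transcripts lsmean matrix of the pattern set
#' @param k number of clusters (default 8)
#' @param n_perm number of permutations (default 1000)
#' @param seed integer seed
#' @param linkage passed to [subcluster()]
#' @return object of class `cluster_size_test`: `observed` (size vector),
#'   `d2`, `df`, `p`, `null_mean`, `null_cov`, `n_perm`
#' @export
mahalanobis_test <- function(lsm, k = 8, n_perm = 1000, seed = 1L,
                             linkage = "ward.D2") {
  stopifnot(k >= 2, ncol(lsm) >= k)
  if (n_perm < k) abort("`n_perm` must be at least `k` for an estimable covariance")
  # same distance/linkage as subcluster(); cluster sizes do not depend on
  # transcript order, so the lean path skips the ordering bookkeeping
  size_vector <- function(M) {
    M <- scale(M)
    M[, attr(M, "scaled:scale") == 0] <- 0
    cl <- cutree(hclust(dist(t(M)), method = linkage), k = k)
    sort(tabulate(cl, nbins = k), decreasing = TRUE)[seq_len(k - 1)]
  }
  obs <- size_vector(lsm)
  set.seed(seed)
  n_l <- nrow(lsm)
  null <- t(vapply(seq_len(n_perm), function(b) {
    M <- apply(lsm, 2, function(col) col[sample.int(n_l)])
    rownames(M) <- rownames(lsm)
    size_vector(M)
  }, numeric(k - 1)))
  mu <- colMeans(null)
  S <- cov(null)
  d2 <- tryCatch(
    mahalanobis(obs, mu, S),
    error = function(e) {
      warn("singular permutation covariance; using pseudo-inverse")
      drop(t(obs - mu) %*% MASS::ginv(S) %*% (obs - mu))
    }
  )
  structure(
    list(
      observed = obs, d2 = unname(d2), df = k - 1,
      p = pchisq(unname(d2), df = k - 1, lower.tail = FALSE),
      null_mean = mu, null_cov = S, n_perm = n_perm, k = k
    ),
    class = "cluster_size_test"
  )
}

#' @export
print.cluster_size_test <- function(x, ...) {
  cat(sprintf(
    "cluster-size test (k = %d, %d permutations): D2 = %.3f on %d df, p = %.4g\n",
    x$k, x$n_perm, x$d2, x$df, x$p
  ))
  cat("observed sizes (smallest dropped):", x$observed, "\n")
  invisible(x)
}

#' @export
tidy.cluster_size_test <- function(x, ...) {
  tibble(
    position = seq_along(x$observed),
    observed_size = x$observed, null_mean = x$null_mean
  )
}

#' @export
glance.cluster_size_test <- function(x, ...) {
  tibble(
    statistic = x$d2, df = x$df, p.value = x$p,
    k = x$k, n_perm = x$n_perm
  )
}

#' Bonferroni significance screen over a family of tests
#'
#' @param p numeric p-values in `[0, 1]`
#' @param alpha family-wise level (default 0.05)
#' @return logical flags: `p < alpha / length(p)`
#' @export
bonferroni_screen <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p < alpha / length(p)
}

#' Run the cluster-size test for every TCoE set
#'
#' @param codes tibble from [encode_patterns()]
#' @param lsm lines x transcripts lsmean matrix
#' @param min_set_size smallest set to test (must be >= `k`)
#' @param alpha family-wise level for the Bonferroni screen
#' @inheritParams mahalanobis_test
#' @return tibble: `tcoe_id`, `n_members`, `d2`, `df`, `p`, `flagged`
#' @export
cluster_size_screen <- function(codes, lsm, k = 8, n_perm = 1000, seed = 1L,
                                min_set_size = max(k, 10), alpha = 0.05) {
  sets <- split(codes$transcript_id, codes$code)
  sets <- sets[lengths(sets) >= min_set_size]
  if (!length(sets)) abort("no TCoE set reaches `min_set_size`")
  out <- purrr::imap(sets, function(members, code) {
    t <- mahalanobis_test(lsm[, members, drop = FALSE],
      k = k,
      n_perm = n_perm, seed = seed
    )
    tibble(
      tcoe_id = code, n_members = length(members),
      d2 = t$d2, df = t$df, p = t$p
    )
  }) %>% bind_rows()
  out$flagged <- bonferroni_screen(out$p, alpha)
  out
}
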