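gcoe_factors <- function(metadata) {
  data.frame(
    line = factor(metadata$line),
    location = factor(metadata$location),
    replicate = factor(metadata$replicate),
    time = factor(metadata$daa, levels = sort(unique(metadata$daa)))
  )
}

gcoe_formula <- function(fac) {
  terms <- c("line")
  if (nlevels(fac$location) > 1) terms <- c(terms, "location")
  if (nlevels(fac$replicate) > 1) {
    terms <- c(
      terms,
      if (nlevels(fac$location) > 1) "location:replicate" else "replicate"
    )
  }
  if (nlevels(fac$time) > 1) terms <- c(terms, "time")
  stats::as.formula(paste("~", paste(terms, collapse = " + ")))
}

gcoe_design <- function(fac, grid = fac) {
  X <- model.matrix(gcoe_formula(fac), grid)
  if (nrow(grid) == nrow(fac) && qr(X)$rank < ncol(X)) {
    abort("design (~ line + location + location/replicate + time) is rank-deficient")
  }
  X
}

#' Remove one latent factor of unwanted variation
#'
#' Residualises every transcript on the known design effects (line,
#' location, replicate within location, time), takes the first principal
#' component of the residual matrix across samples as the latent factor
#' (the leading surrogate variable under an SVA-type model), and subtracts
#' its rank-1 contribution from the normalised values. Because the factor
#' lives in the residual space, the design effects are untouched.
#'
#' @param vst transcripts x samples normalised matrix
#' @param metadata sample metadata (`line`, `location`, `replicate`, `daa`)
#' @return list with `adjusted` (same shape as `vst`), `factor` (per-sample
#'   latent scores) and `loadings` (per-transcript)
#' @export
adjust_latent <- function(vst, metadata) {
  stopifnot(ncol(vst) == nrow(metadata))
  fac <- gcoe_factors(metadata)
  X <- gcoe_design(fac)
  Y <- t(vst) # samples x transcripts
  qx <- qr(X)
  R <- Y - qr.fitted(qx, Y)
  s <- svd(R, nu = 1, nv = 1)
  f <- s$u[, 1] * s$d[1]
  lam <- s$v[, 1]
  adjusted <- t(Y - outer(f, lam))
  dimnames(adjusted) <- dimnames(vst)
  list(
    adjusted = adjusted,
    factor = setNames(f, colnames(vst)),
    loadings = setNames(lam, rownames(vst))
  )
}

#' Per-line least-squares means of expression
#'
#' Fits, per transcript, the fixed-effects model
#' `~ line + location + location/replicate + time` and predicts each line
#' at equal weight over all levels of the other factors — the model-
#' adjusted line mean. On a balanced complete design this equals the
#' arithmetic mean of the line's samples. All transcripts share one design
#' matrix, so the fit is a single multivariate least-squares solve.
#'
#' @param vst transcripts x samples matrix (typically latent-adjusted)
#' @param metadata sample metadata
#' @return lines x transcripts numeric matrix (lsmean expression matrix)
#' @export
lsmeans <- function(vst, metadata) {
  stopifnot(ncol(vst) == nrow(metadata))
  fac <- gcoe_factors(metadata)
  missing_lines <- setdiff(levels(fac$line), unique(as.character(fac$line)))
  if (length(missing_lines)) {
    warn(paste("lines with no samples:", paste(missing_lines, collapse = ", ")))
  }
  X <- gcoe_design(fac)
  B <- qr.coef(qr(X), t(vst))
  grid <- expand.grid(
    line = levels(fac$line), location = levels(fac$location),
    replicate = levels(fac$replicate), time = levels(fac$time),
    KEEP.OUT.ATTRS = FALSE
  )
  Xg <- gcoe_design(fac, grid)
  pred <- Xg %*% B
  lsm <- rowsum(pred, grid$line) / as.vector(table(grid$line))
  rownames(lsm) <- levels(fac$line)
  colnames(lsm) <- rownames(vst)
  lsm
}

#' Subcluster a pattern set into genetic co-expression sets
#'
#' Agglomerative (Ward) clustering of transcripts on the Euclidean
#' distance between their per-line lsmean profiles, standardised per
#' transcript so the partition reflects profile shape rather than
#' expression magnitude. Deterministic: no randomness, and the result is
#' invariant to transcript input order.
#'
#' @param lsm lines x transcripts lsmean matrix (the members to cluster)
#' @param k number of clusters, `2 <= k <=` number of transcripts
#' @param linkage hclust agglomeration method (default `"ward.D2"`)
#' @param standardize centre and scale each transcript profile first
#' @return tibble: `transcript_id`, `cluster` (integer in `1..k`)
#' @export
subcluster <- function(lsm, k, linkage = "ward.D2", standardize = TRUE) {
  if (k > ncol(lsm)) abort("`k` exceeds the number of member transcripts")
  stopifnot(k >= 1)
  M <- lsm
  if (standardize) {
    M <- scale(M)
    M[, attr(M, "scaled:scale") == 0] <- 0
  }
  ord <- order(colnames(M))
  hc <- hclust(dist(t(M[, ord, drop = FALSE])), method = linkage)
  cl <- cutree(hc, k = k)
  tibble(transcript_id = colnames(M)[ord], cluster = unname(cl)) %>%
    arrange(match(.data$transcript_id, colnames(lsm)))
}

#' PC1 eigengene scores of a GCoE set
#'
#' PCA with the panel lines as observations and the member transcripts as
#' (centred) variables; the first component's per-line scores summarise
#' the set. The sign is fixed so the scores correlate positively with the
#' mean member profile, making downstream regressions reproducible.
#'
#' @param lsm lines x transcripts lsmean matrix restricted to the members
#' @return list with `scores` (named per-line vector) and `var_explained`
#' @export
pc1_scores <- function(lsm) {
  if (ncol(lsm) < 1) abort("empty member set")
  if (is.null(rownames(lsm))) abort("`lsm` must carry line IDs as rownames")
  C <- scale(lsm, center = TRUE, scale = FALSE)
  if (all(apply(C, 2, sd) == 0)) abort("all member transcripts have zero variance")
  if (ncol(C) == 1) {
    sc <- C[, 1]
    ve <- 1
  } else {
    pc <- prcomp(C, center = FALSE, scale. = FALSE)
    sc <- pc$x[, 1]
    ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  mp <- rowMeans(C)
  if (cor(sc, mp) < 0) sc <- -sc
  list(scores = setNames(sc, rownames(lsm)), var_explained = ve)
}

#' Choose the number of GCoE subclusters by heritability profile
#'
#' For each candidate `k`, partitions the set, computes every subcluster's
#' PC1 heritability under the kinship `K`, and scores the partition as
#' `median(h2) - lambda * IQR(h2)` — high and homogeneous heritabilities
#' win. Ties go to the smaller `k`.
#'
#' @param lsm lines x transcripts lsmean matrix of the pattern set
#' @param K lines x lines relationship matrix (rows aligned to `lsm`)
#' @param k_range candidate cluster numbers (default 4:20, truncated to
#'   the member count)
#' @param lambda penalty weight on the heritability IQR (default 1)
#' @param linkage passed to [subcluster()]
#' @return list with `k` (chosen), `by_k` (tibble: `k`, `median_h2`,
#'   `iqr_h2`, `score`) and `h2` (tibble: `k`, `cluster`, `n_members`,
#'   `h2`)
#' @export
choose_k <- function(lsm, K, k_range = 4:20, lambda = 1, linkage = "ward.D2") {
  if (!inherits(K, "grm_eigen")) K <- grm_eigen(K)
  k_range <- k_range[k_range >= 2 & k_range <= ncol(lsm)]
  if (!length(k_range)) abort("no admissible k in `k_range`")
  all_h2 <- list()
  by_k <- purrr::map(k_range, function(k) {
    part <- subcluster(lsm, k, linkage = linkage)
    h2s <- vapply(seq_len(k), function(cl) {
      members <- part$transcript_id[part$cluster == cl]
      sc <- pc1_scores(lsm[, members, drop = FALSE])$scores
      estimate_h2(sc, K)$h2
    }, numeric(1))
    sizes <- tabulate(part$cluster, nbins = k)
    cl_id <- seq_len(k)
    all_h2[[as.character(k)]] <<- tibble(
      k = rep(k, k), cluster = cl_id, n_members = sizes, h2 = h2s
    )
    tibble(
      k = k, median_h2 = median(h2s), iqr_h2 = IQR(h2s),
      score = median(h2s) - lambda * IQR(h2s)
    )
  }) %>% bind_rows()
  best <- by_k$k[order(-by_k$score, by_k$k)][1]
  list(k = best, by_k = by_k, h2 = bind_rows(all_h2))
}

#' Build all GCoE sets of a study
#'
#' Groups DETs by pattern code (TCoE sets), optionally drops small sets,
#' chooses each set's subcluster count by [choose_k()], and returns per-set
#' memberships and PC1 scores.
#'
#' @param codes tibble from [encode_patterns()]
#' @param lsm lines x transcripts lsmean matrix covering the coded
#'   transcripts
#' @param K lines x lines relationship matrix
#' @param min_set_size smallest TCoE set to subcluster (default 10)
#' @param k_range,lambda,linkage passed to [choose_k()]
#' @return list with `membership` (tibble: `tcoe_id`, `gcoe_id`,
#'   `transcript_id`), `pc1` (tibble: `tcoe_id`, `gcoe_id`, `line`,
#'   `score`) and `chosen_k` (tibble: `tcoe_id`, `k`)
#' @export
build_gcoe_sets <- function(codes, lsm, K, min_set_size = 10,
                            k_range = 4:20, lambda = 1, linkage = "ward.D2") {
  if (!inherits(K, "grm_eigen")) K <- grm_eigen(K)
  sets <- split(codes$transcript_id, codes$code)
  sets <- sets[lengths(sets) >= min_set_size]
  if (!length(sets)) abort("no TCoE set reaches `min_set_size`")
  res <- purrr::imap(sets, function(members, code) {
    sub_lsm <- lsm[, members, drop = FALSE]
    ck <- choose_k(sub_lsm, K, k_range = k_range, lambda = lambda, linkage = linkage)
    part <- subcluster(sub_lsm, ck$k, linkage = linkage)
    pc1 <- purrr::map(seq_len(ck$k), function(cl) {
      mem <- part$transcript_id[part$cluster == cl]
      sc <- pc1_scores(sub_lsm[, mem, drop = FALSE])
      tibble(
        tcoe_id = code, gcoe_id = paste0(code, ".", cl),
        line = names(sc$scores), score = unname(sc$scores),
        var_explained = sc$var_explained
      )
    }) %>% bind_rows()
    list(
      membership = tibble(
        tcoe_id = code, gcoe_id = paste0(code, ".", part$cluster),
        transcript_id = part$transcript_id
      ),
      pc1 = pc1,
      chosen_k = tibble(tcoe_id = code, k = ck$k)
    )
  })
  list(
    membership = bind_rows(purrr::map(res, "membership")),
    pc1 = bind_rows(purrr::map(res, "pc1")),
    chosen_k = bind_rows(purrr::map(res, "chosen_k"))
  )
}
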