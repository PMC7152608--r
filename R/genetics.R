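#' Genomic relationship matrix (VanRaden method 1)
#'
#' Centres each marker by twice its allele frequency and scales the
#' cross-product by `sum(2 p (1-p))`, so the diagonal averages about 1
#' for a panel in Hardy-Weinberg proportions.
#'
#' @param genotypes lines x markers dosage matrix in {0, 1, 2}
#' @return symmetric lines x lines matrix with line IDs as dimnames
#' @export
grm_vanraden <- function(genotypes) {
  p <- colMeans(genotypes) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) abort("need at least 2 polymorphic markers")
  Z <- sweep(genotypes[, poly, drop = FALSE], 2, 2 * p[poly])
  K <- tcrossprod(Z) / sum(2 * p[poly] * (1 - p[poly]))
  dimnames(K) <- list(rownames(genotypes), rownames(genotypes))
  (K + t(K)) / 2
}

#' Pre-decompose a relationship matrix for repeated REML fits
#'
#' @param K symmetric PSD lines x lines matrix
#' @return object of class `grm_eigen` caching the eigendecomposition
#' @export
grm_eigen <- function(K) {
  stopifnot(isSymmetric(unname(K), tol = 1e-8))
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8) abort("K has a clearly negative eigenvalue; not a relationship matrix")
  if (min(e$values) < 1e-10) {
    warn("K is singular; adding ridge 1e-6 to the diagonal")
    e <- eigen((K + t(K)) / 2 + diag(1e-6, nrow(K)), symmetric = TRUE)
  }
  structure(
    list(values = e$values, vectors = e$vectors, ids = rownames(K)),
    class = "grm_eigen"
  )
}

# restricted log-likelihood of y = mu + u + e, u ~ N(0, sigma_u2 K),
# in the eigenbasis of K; lambda = sigma_u2 / sigma_e2
reml_profile <- function(lambda, d, yt, xt, n) {
  v <- lambda * d + 1
  xvx <- sum(xt^2 / v)
  ypy <- sum(yt^2 / v) - sum(xt * yt / v)^2 / xvx
  se2 <- ypy / (n - 1)
  if (se2 <= 0) {
    return(list(rll = -Inf, se2 = 0))
  }
  rll <- -0.5 * ((n - 1) * log(2 * pi * se2) + sum(log(v)) + log(xvx) + (n - 1))
  list(rll = rll, se2 = se2)
}

#' REML heritability of per-line scores under a relationship matrix
#'
#' Fits `y = mu + u + e` with `u ~ N(0, K sigma_u2)`, `e ~ N(0, I
#' sigma_e2)` by restricted maximum likelihood, using the
#' eigendecomposition of `K` and a one-dimensional profile over the
#' variance ratio (log-scale grid over `[1e-6, 1e6]` refined by golden-
#' section search). The reduced model drops `u`; the likelihood-ratio
#' statistic is referred to the boundary mixture `0.5 chi2_0 + 0.5 chi2_1`
#' (or plain `chi2_1` with `boundary_mixture = FALSE`). Heritability is
#' `sigma_u2 / (sigma_u2 + sigma_e2)`.
#'
#' @param y per-line numeric vector (e.g. GCoE PC1 scores), names matching
#'   the rows of `K` if both are named
#' @param K lines x lines relationship matrix, or a [grm_eigen()] object
#' @param boundary_mixture use the 50:50 boundary-corrected LRT reference
#' @return object of class `h2_fit`: `sigma_u2`, `sigma_e2`, `h2`,
#'   `lrt_stat`, `p`, `loglik_full`, `loglik_reduced`
#' @export
estimate_h2 <- function(y, K, boundary_mixture = TRUE) {
  eK <- if (inherits(K, "grm_eigen")) K else grm_eigen(K)
  n <- length(y)
  stopifnot(n == length(eK$values), n >= 3)
  if (!is.null(names(y)) && !is.null(eK$ids)) {
    stopifnot(all(names(y) %in% eK$ids))
    y <- y[eK$ids]
  }
  if (sd(y) == 0) {
    warn("constant response; heritability undefined, returning 0")
    return(structure(
      list(
        sigma_u2 = 0, sigma_e2 = 0, h2 = 0, lrt_stat = 0, p = 1,
        loglik_full = NA_real_, loglik_reduced = NA_real_
      ),
      class = "h2_fit"
    ))
  }
  d <- eK$values
  yt <- drop(crossprod(eK$vectors, y))
  xt <- drop(crossprod(eK$vectors, rep(1, n)))

  obj <- function(loglam) reml_profile(exp(loglam), d, yt, xt, n)$rll
  grid <- seq(log(1e-6), log(1e6), length.out = 121)
  vals <- vapply(grid, obj, numeric(1))
  tol <- 1e-8
  # smallest ratio within tolerance of the grid optimum: a flat restricted
  # likelihood (e.g. K = I) must not drift to a large genetic variance
  i <- which(vals >= max(vals) - tol)[1]
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-10)
  # reduced model: lambda = 0
  red <- reml_profile(0, d, yt, xt, n)
  cand <- if (opt$objective > vals[i] + tol) opt$maximum else grid[i]
  full <- reml_profile(exp(cand), d, yt, xt, n)
  if (red$rll >= full$rll - tol) { # boundary optimum
    cand <- -Inf
    full <- red
  }
  lam <- exp(cand)
  if (!is.finite(lam)) lam <- 0
  se2 <- full$se2
  su2 <- lam * se2
  stat <- max(0, 2 * (full$rll - red$rll))
  p <- if (stat <= 1e-12) {
    1
  } else if (boundary_mixture) {
    0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(
    list(
      sigma_u2 = su2, sigma_e2 = se2, h2 = su2 / (su2 + se2),
      lrt_stat = stat, p = p,
      loglik_full = full$rll, loglik_reduced = red$rll
    ),
    class = "h2_fit"
  )
}

#' @export
print.h2_fit <- function(x, ...) {
  cat(sprintf(
    "h2 = %.3f (sigma_u2 = %.4g, sigma_e2 = %.4g), LRT = %.3f, p = %.3g\n",
    x$h2, x$sigma_u2, x$sigma_e2, x$lrt_stat, x$p
  ))
  invisible(x)
}

#' @export
tidy.h2_fit <- function(x, ...) {
  tibble(
    term = c("sigma_u2", "sigma_e2", "h2"),
    estimate = c(x$sigma_u2, x$sigma_e2, x$h2)
  )
}

#' @export
glance.h2_fit <- function(x, ...) {
  tibble(
    h2 = x$h2, sigma_u2 = x$sigma_u2, sigma_e2 = x$sigma_e2,
    lrt_stat = x$lrt_stat, p.value = x$p
  )
}

#' Heritability of every GCoE set's PC1 scores
#'
#' @param pc1 tibble from [build_gcoe_sets()] (`$pc1`)
#' @param K relationship matrix or [grm_eigen()] object
#' @return tibble: `tcoe_id`, `gcoe_id`, `sigma_u2`, `sigma_e2`, `h2`,
#'   `lrt_stat`, `p`
#' @export
gcoe_h2 <- function(pc1, K) {
  eK <- if (inherits(K, "grm_eigen")) K else grm_eigen(K)
  pc1 %>%
    group_by(.data$tcoe_id, .data$gcoe_id) %>%
    summarise(
      {
        fit <- estimate_h2(setNames(.data$score, .data$line), eK)
        tibble(
          sigma_u2 = fit$sigma_u2, sigma_e2 = fit$sigma_e2,
          h2 = fit$h2, lrt_stat = fit$lrt_stat, p = fit$p
        )
      },
      .groups = "drop"
    )
}

#' Permutation null for GCoE heritability
#'
#' Each permutation shuffles the line labels of the lsmean matrix relative
#' to the kinship `K` — expression covariance among transcripts is
#' preserved, the genetic alignment is destroyed — and re-runs the whole
#' GCoE procedure (subcluster-number choice, subclustering, PC1,
#' heritability).
#'
#' @param codes tibble from [encode_patterns()]
#' @param lsm lines x transcripts lsmean matrix
#' @param K relationship matrix
#' @param n_perm number of permuted data sets (default 50)
#' @param seed integer seed
#' @param ... passed to [build_gcoe_sets()]
#' @return list of class `h2_null` with `real` and `null` h2 tibbles
#'   (`null` has a `perm` column)
#' @export
h2_permutation_null <- function(codes, lsm, K, n_perm = 50, seed = 1L, ...) {
  stopifnot(n_perm >= 1)
  eK <- grm_eigen(K)
  real_sets <- build_gcoe_sets(codes, lsm, K = eK, ...)
  real <- gcoe_h2(real_sets$pc1, eK)
  set.seed(seed)
  null <- purrr::map(seq_len(n_perm), function(b) {
    perm <- sample.int(nrow(lsm))
    lsm_b <- lsm[perm, , drop = FALSE]
    rownames(lsm_b) <- rownames(lsm)
    sets_b <- build_gcoe_sets(codes, lsm_b, K = eK, ...)
    gcoe_h2(sets_b$pc1, eK) %>% mutate(perm = b)
  }) %>% bind_rows()
  structure(list(real = real, null = null, sets = real_sets), class = "h2_null")
}

#' @export
print.h2_null <- function(x, ...) {
  cat(sprintf(
    "GCoE heritability: %d real sets (median h2 %.3f) vs %d permuted fits (median h2 %.3f)\n",
    nrow(x$real), median(x$real$h2), nrow(x$null), median(x$null$h2)
  ))
  invisible(x)
}

#' Design-based heritability of a metabolite
#'
#' Fits the all-random RCBD model
#' `value ~ (1|line) + (1|location) + (1|location:replicate) +
#' (1|line:location)` by REML and computes line-mean heritability
#' `sigma2_L / (sigma2_L + sigma2_LxLoc / n_loc + sigma2_e / (n_loc *
#' n_rep))`; with two locations and two replicates the denominators are 2
#' and 4.
#'
#' @param df tibble with columns `line`, `location`, `replicate`, `value`
#'   for one metabolite
#' @return list of class `met_h2`: `h2`, `sigma2_line`, `sigma2_loc_line`,
#'   `sigma2_e`, `n_loc`, `n_rep`
#' @export
metabolite_h2 <- function(df) {
  n_loc <- length(unique(df$location))
  n_rep <- length(unique(df$replicate))
  n_line <- length(unique(df$line))
  if (n_line < 2 || n_loc < 2) {
    abort("need at least 2 lines and 2 locations for the RCBD model")
  }
  if (n_line * n_loc >= nrow(df)) {
    abort("line and location:replicate structure completely confounded with plots")
  }
  d <- data.frame(
    line = factor(df$line), location = factor(df$location),
    replicate = factor(df$replicate), value = df$value
  )
  fit <- suppressMessages(suppressWarnings(lme4::lmer(
    value ~ (1 | line) + (1 | location) + (1 | location:replicate) +
      (1 | line:location),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  )))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) max(0, v) else 0
  }
  vL <- get_vc("line")
  vLL <- get_vc("line:location")
  ve <- get_vc("Residual")
  h2 <- if (vL + vLL / n_loc + ve / (n_loc * n_rep) == 0) {
    0
  } else {
    vL / (vL + vLL / n_loc + ve / (n_loc * n_rep))
  }
  structure(
    list(
      h2 = h2, sigma2_line = vL, sigma2_loc_line = vLL, sigma2_e = ve,
      n_loc = n_loc, n_rep = n_rep
    ),
    class = "met_h2"
  )
}

#' @export
tidy.met_h2 <- function(x, ...) {
  tibble(
    term = c("sigma2_line", "sigma2_loc_line", "sigma2_e", "h2"),
    estimate = c(x$sigma2_line, x$sigma2_loc_line, x$sigma2_e, x$h2)
  )
}

#' @export
glance.met_h2 <- function(x, ...) {
  tibble(
    h2 = x$h2, sigma2_line = x$sigma2_line,
    sigma2_loc_line = x$sigma2_loc_line, sigma2_e = x$sigma2_e
  )
}
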