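#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a vector of p-values; missing values stay
#' missing and do not perturb their neighbours.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA/NaN allowed)
#' @return adjusted p-values, capped at 1
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

# design cells = unique rows of the design matrix
design_cells <- function(X) {
  match(
    apply(X, 1, paste, collapse = "\r"),
    unique(apply(X, 1, paste, collapse = "\r"))
  )
}

#' Per-transcript NB dispersion estimates with trend shrinkage
#'
#' Per transcript, the dispersion is estimated by maximising the Cox-Reid
#' adjusted profile likelihood over `alpha` given the design's replicate
#' cells (cell means are the NB maximum-likelihood fitted values; the
#' adjustment `-0.5 * sum(log W_c)`, with `W_c` the summed NB working
#' weights of cell `c`, compensates the degrees of freedom spent on the
#' means and removes the downward bias of the plain profile MLE). A
#' gamma-GLM mean-dispersion trend `alpha(mu) = a0 + a1 / mu` is then
#' fitted across transcripts and each estimate is shrunk toward it on the
#' log scale with an adaptive empirical-Bayes weight: the weight on the
#' per-transcript value is the estimated population spread of true
#' dispersions around the trend relative to the total (spread plus
#' sampling noise, the latter approximated by `2 / residual df`). When
#' transcripts hug the trend the trend dominates; when true dispersions
#' genuinely vary, per-transcript estimates are left nearly unshrunk —
#' shrinkage never buys calibration it did not pay for.
#' Transcripts whose raw estimate sits far above the trend (more than 1.5
#' robust SDs on the log scale) are dispersion outliers and keep their raw
#' estimate: shrinking them down would understate their variance and
#' inflate the tests. All estimates are floored at `1e-8`.
#'
#' @param counts transcripts x samples matrix
#' @param sf per-sample size factors
#' @param design a design matrix (samples x terms) or a data frame of
#'   factors; identical rows define replicate cells
#' @return named per-transcript dispersion vector (>= 1e-8)
#' @export
estimate_dispersions <- function(counts, sf, design) {
  X <- if (is.data.frame(design)) {
    model.matrix(~., data = design)
  } else {
    design
  }
  stopifnot(nrow(X) == ncol(counts))
  if (qr(X)$rank < ncol(X)) {
    abort("design matrix is rank-deficient; remove aliased terms")
  }
  cells <- design_cells(X)
  if (ncol(counts) - length(unique(cells)) < 2) {
    abort("fewer than 2 residual degrees of freedom for dispersion estimation")
  }
  floor_d <- 1e-8
  cell_idx <- split(seq_len(ncol(counts)), cells)
  sf_cell <- vapply(cell_idx, function(i) sum(sf[i]), numeric(1))

  apl <- function(y, log_alpha) {
    alpha <- exp(log_alpha)
    mu_c <- vapply(cell_idx, function(i) sum(y[i]), numeric(1)) / sf_cell
    mu <- unlist(lapply(seq_along(cell_idx), function(c) sf[cell_idx[[c]]] * mu_c[c]))
    yy <- unlist(lapply(cell_idx, function(i) y[i]))
    ll <- sum(dnbinom(yy, size = 1 / alpha, mu = mu, log = TRUE))
    w_c <- vapply(seq_along(cell_idx), function(c) {
      m <- sf[cell_idx[[c]]] * mu_c[c]
      sum(m / (1 + alpha * m))
    }, numeric(1))
    ll - 0.5 * sum(log(w_c[w_c > 0]))
  }
  raw <- vapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    if (sum(y) == 0) {
      return(floor_d)
    }
    opt <- optimize(function(la) apl(y, la),
      interval = log(c(1e-8, 30)), maximum = TRUE, tol = 1e-4
    )
    # boundary tie-break: prefer the floor when the likelihood is flat
    if (apl(y, log(1e-8)) >= opt$objective - 1e-8) {
      return(floor_d)
    }
    exp(opt$maximum)
  }, numeric(1))
  raw <- pmax(raw, floor_d)

  base_mean <- rowMeans(t(t(counts) / sf))
  use <- raw > floor_d & base_mean > 0
  if (!any(use)) { # e.g. constant counts everywhere: nothing to shrink
    return(setNames(raw, rownames(counts)))
  }
  trend <- rep(max(median(raw[use]), floor_d), nrow(counts))
  if (sum(use) >= 10) {
    fit <- tryCatch(
      suppressWarnings(stats::glm(raw[use] ~ I(1 / base_mean[use]),
        family = stats::Gamma(link = "identity"),
        start = c(median(raw[use]), 1)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit) && all(is.finite(coef(fit)))) {
      trend <- pmax(coef(fit)[1] + coef(fit)[2] / base_mean, floor_d)
    }
  }
  resid_log <- log(raw) - log(trend)
  s_samp2 <- 2 / (ncol(counts) - length(cell_idx))
  s_pop2 <- if (sum(use) < 2) 0 else max(var(resid_log[use]) - s_samp2, 0)
  w <- if (s_pop2 + s_samp2 == 0) 0.5 else s_pop2 / (s_pop2 + s_samp2)
  disp <- exp(w * log(raw) + (1 - w) * log(trend))
  spread <- max(stats::mad(resid_log[use]), 0.1)
  outlier <- is.finite(resid_log) & resid_log > 1.5 * spread
  disp[outlier] <- raw[outlier]
  disp[!is.finite(disp)] <- floor_d
  setNames(pmax(disp, floor_d), rownames(counts))
}

#' Fit one negative-binomial GLM with log link
#'
#' IRLS fit of counts on a design matrix with log size factors as offsets
#' and a fixed dispersion (convergence when the deviance change is below
#' `1e-8`, at most 100 iterations). The log-likelihood is the direct NB
#' log-density sum at the fitted means.
#'
#' @param y non-negative integer counts for one transcript
#' @param X design matrix (samples x terms)
#' @param offsets log size factors (finite)
#' @param dispersion positive NB dispersion (`Var = mu + dispersion*mu^2`)
#' @return object of class `nb_fit`: list with `coefficients` (log scale),
#'   `vcov`, `fitted`, `dispersion`, `loglik`, `converged`
#' @export
fit_nb_glm <- function(y, X, offsets = rep(0, length(y)), dispersion) {
  stopifnot(all(y >= 0), all(is.finite(offsets)), dispersion > 0)
  fam <- MASS::negative.binomial(theta = 1 / dispersion)
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = fam, offset = offsets, control = ctrl)),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) {
    # IRLS can overshoot for highly dispersed counts; restart from the
    # log-linear fit of shifted counts
    start <- tryCatch(
      qr.coef(qr(X), log(pmax(y, 0.5)) - offsets),
      error = function(e) NULL
    )
    if (!is.null(start) && all(is.finite(start))) {
      fit2 <- tryCatch(
        suppressWarnings(glm.fit(X, y,
          family = fam, offset = offsets,
          start = start, control = ctrl
        )),
        error = function(e) NULL
      )
      if (!is.null(fit2)) fit <- fit2
    }
  }
  if (is.null(fit)) {
    return(structure(
      list(
        coefficients = rep(NA_real_, ncol(X)),
        vcov = matrix(NA_real_, ncol(X), ncol(X)),
        fitted = rep(NA_real_, length(y)),
        dispersion = dispersion, loglik = NA_real_, converged = FALSE
      ),
      class = "nb_fit"
    ))
  }
  w <- fit$weights
  XtWX <- crossprod(X * w, X)
  vc <- tryCatch(solve(XtWX), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vc) <- list(colnames(X), colnames(X))
  ll <- sum(dnbinom(y, size = 1 / dispersion, mu = fit$fitted.values, log = TRUE))
  structure(
    list(
      coefficients = coef(fit), vcov = vc, fitted = fit$fitted.values,
      dispersion = dispersion, loglik = ll, converged = fit$converged
    ),
    class = "nb_fit"
  )
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf(
    "NB GLM fit: %d coefficients, dispersion %.4g, loglik %.3f, %s\n",
    length(x$coefficients), x$dispersion, x$loglik,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

de_factors <- function(metadata) {
  data.frame(
    line = factor(metadata$line),
    time = factor(metadata$daa, levels = sort(unique(metadata$daa)))
  )
}

#' Genotype-by-time interaction screen (likelihood-ratio test)
#'
#' Per transcript, compares the full NB model `~ genotype + time +
#' genotype:time` against the reduced `~ genotype + time` with a LRT
#' against chi-squared with `(G-1)(T-1)` degrees of freedom. Transcripts
#' significant at BH-FDR `alpha` show genotype-specific temporal behaviour
#' and are flagged for removal before global pattern analysis.
#'
#' @param counts transcripts x samples matrix (post QC)
#' @param sf per-sample size factors
#' @param metadata sample metadata (`line`, `daa` columns)
#' @param alpha FDR level of the screen (default 0.1)
#' @param dispersions optional per-transcript dispersions; estimated from
#'   the additive design when missing
#' @return tibble: `transcript_id`, `stat`, `df`, `p`, `padj`, `flagged`
#' @export
interaction_lrt <- function(counts, sf, metadata, alpha = 0.1,
                            dispersions = NULL) {
  fac <- de_factors(metadata)
  G <- nlevels(fac$line)
  Tn <- nlevels(fac$time)
  if (Tn < 2) abort("need at least 2 time levels")
  if (G < 2) {
    # a single genotype: interaction and additive models coincide
    return(tibble(
      transcript_id = rownames(counts), stat = 0, df = 0L,
      p = 1, padj = 1, flagged = FALSE
    ))
  }
  X_red <- model.matrix(~ line + time, fac)
  X_full <- model.matrix(~ line * time, fac)
  # empty genotype x time cells alias interaction columns; the LRT df is
  # the realised rank difference, not the nominal (G-1)(T-1)
  df <- qr(X_full)$rank - qr(X_red)$rank
  if (df == 0) {
    # full and reduced models coincide (e.g. a single genotype)
    return(tibble(
      transcript_id = rownames(counts), stat = 0, df = 0L,
      p = 1, padj = 1, flagged = FALSE
    ))
  }
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts, sf, X_red)
  off <- log(sf)
  stat <- vapply(seq_len(nrow(counts)), function(i) {
    f1 <- fit_nb_glm(counts[i, ], X_full, off, dispersions[i])
    f0 <- fit_nb_glm(counts[i, ], X_red, off, dispersions[i])
    if (!f1$converged || !f0$converged) {
      return(NA_real_)
    }
    max(0, 2 * (f1$loglik - f0$loglik))
  }, numeric(1))
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  padj <- bh_adjust(p)
  tibble(
    transcript_id = rownames(counts), stat = stat, df = df,
    p = p, padj = padj, flagged = !is.na(padj) & padj < alpha
  )
}

#' Differential expression between adjacent time points
#'
#' Per transcript, fits the NB model `~ genotype + time` (controlling for
#' genotype) once, then Wald-tests the difference of consecutive time-level
#' coefficients for each of the adjacent intervals. Signs follow later
#' minus earlier time. p-values are BH-adjusted within each interval.
#'
#' @inheritParams interaction_lrt
#' @param alpha FDR level used downstream for calling DETs (default 0.05);
#'   recorded, not applied here
#' @return tibble: `transcript_id`, `contrast` (e.g. `"8-13"`), `log2fc`,
#'   `se`, `stat`, `p`, `padj`
#' @export
adjacent_contrasts <- function(counts, sf, metadata, alpha = 0.05,
                               dispersions = NULL) {
  fac <- de_factors(metadata)
  times <- levels(fac$time)
  if (length(times) < 2) abort("need at least 2 time levels")
  X <- model.matrix(~ line + time, fac)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts, sf, X)
  off <- log(sf)
  time_cols <- paste0("time", times)
  col_idx <- match(time_cols, colnames(X)) # NA for the baseline level
  labels <- paste0(times[-length(times)], "-", times[-1])

  rows <- lapply(seq_len(nrow(counts)), function(i) {
    f <- fit_nb_glm(counts[i, ], X, off, dispersions[i])
    est <- se <- rep(NA_real_, length(labels))
    if (f$converged && all(is.finite(f$vcov))) {
      b <- ifelse(is.na(col_idx), 0, f$coefficients[col_idx])
      for (j in seq_along(labels)) {
        est[j] <- b[j + 1] - b[j]
        cv <- function(a, b2) {
          ia <- col_idx[a]
          ib <- col_idx[b2]
          if (is.na(ia) || is.na(ib)) 0 else f$vcov[ia, ib]
        }
        se[j] <- sqrt(cv(j + 1, j + 1) + cv(j, j) - 2 * cv(j, j + 1))
      }
    }
    z <- est / se
    tibble(
      transcript_id = rownames(counts)[i], contrast = labels,
      log2fc = est / log(2), se = se / log(2), stat = z,
      p = 2 * pnorm(-abs(z))
    )
  })
  out <- bind_rows(rows)
  out %>%
    group_by(.data$contrast) %>%
    mutate(padj = bh_adjust(.data$p)) %>%
    ungroup() %>%
    arrange(match(.data$contrast, labels), .data$transcript_id)
}
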