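test_that("BH adjustment reproduces the step-up formula", {
  # direct formula: p_(i) * m / i, cumulative minimum from the largest
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, NA, 0.04, 0.9)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[-2], bh_adjust(p[-2]))
  # random vector against an independent implementation
  set.seed(1)
  q <- runif(50)
  m <- length(q)
  o <- order(q)
  brute <- numeric(m)
  brute[o] <- rev(cummin(rev(q[o] * m / seq_len(m))))
  expect_equal(bh_adjust(q), pmin(brute, 1))
})

test_that("the NB GLM engine matches closed forms and the direct likelihood", {
  f <- fit_nb_glm(rep(7L, 12), matrix(1, 12, 1), rep(0, 12), dispersion = 0.5)
  expect_equal(unname(f$coefficients[1]), log(7), tolerance = 1e-8)
  expect_true(f$converged)
  expect_equal(
    f$loglik,
    sum(dnbinom(rep(7L, 12), size = 2, mu = 7, log = TRUE)),
    tolerance = 1e-8
  )

  set.seed(2)
  y <- c(rnbinom(300, mu = 10, size = 10), rnbinom(300, mu = 40, size = 10))
  X <- cbind(1, rep(0:1, each = 300))
  f2 <- fit_nb_glm(y, X, rep(0, 600), dispersion = 0.1)
  expect_equal(unname(f2$coefficients[2]) / log(2), 2, tolerance = 0.1)
  expect_equal(
    f2$loglik,
    sum(dnbinom(y, size = 10, mu = f2$fitted, log = TRUE))
  )
})

test_that("dispersion estimation floors Poisson data and recovers NB truth", {
  fac <- data.frame(g = factor(rep(1:10, each = 4)))
  set.seed(3)
  pois <- matrix(rnbinom(200 * 40, mu = 100, size = 1e8), 200,
    dimnames = list(sprintf("T%03d", 1:200), sprintf("S%02d", 1:40))
  )
  dp <- estimate_dispersions(pois, rep(1, 40), fac)
  expect_lt(median(dp), 0.05)

  nb <- matrix(rnbinom(500 * 40, mu = 500, size = 1 / 0.4), 500,
    dimnames = list(sprintf("T%03d", 1:500), sprintf("S%02d", 1:40))
  )
  dn <- estimate_dispersions(nb, rep(1, 40), fac)
  expect_gt(median(dn), 0.25)
  expect_lt(median(dn), 0.6)

  const <- matrix(5L, 3, 40, dimnames = list(c("a", "b", "c"), colnames(nb)))
  dc <- estimate_dispersions(const, rep(1, 40), fac)
  expect_true(all(dc < 1e-6))

  bad <- cbind(fac, g2 = fac$g) # aliased copy
  expect_error(
    estimate_dispersions(nb, rep(1, 40), model.matrix(~ g + g2, bad)),
    "rank-deficient"
  )
})

test_that("the interaction screen degenerates gracefully and finds planted reversals", {
  d <- fixture_de_design(n_lines = 4, n_reps = 3)
  truth <- simulation_truth(d,
    n_transcripts = 30, patterns = "00000",
    line_sd = 0, latent_fraction = 0,
    dispersion_range = c(0.02, 0.1), seed = 4
  )
  sim <- simulate_counts(d, truth, seed = 4)
  sf <- size_factors(sim$counts)

  # plant a genotype-specific temporal reversal in transcript 1
  cm <- sim$counts
  first_line <- sim$metadata$line == "L01"
  late <- sim$metadata$daa >= 23
  cm[1, first_line & late] <- cm[1, first_line & late] * 16L
  cm[1, !first_line & late] <- pmax(1L, cm[1, !first_line & late] %/% 16L)
  lrt <- interaction_lrt(cm, sf, sim$metadata, alpha = 0.1)
  expect_true(lrt$flagged[1])
  expect_equal(lrt$df[1], (4 - 1) * (6 - 1))

  # single genotype: full and reduced models coincide
  one <- sim$metadata$line == "L01"
  lrt1 <- interaction_lrt(sim$counts[1:5, one], sf[one], sim$metadata[one, ])
  expect_equal(lrt1$stat, rep(0, 5))
  expect_equal(lrt1$p, rep(1, 5))
})

test_that("adjacent contrasts find a planted first-interval step and nothing else", {
  d <- fixture_de_design()
  truth <- simulation_truth(d,
    n_transcripts = 40,
    patterns = c("u0000", "d0000", "00000", "00000", "00000"),
    step_log2 = 2,
    line_sd = 0.1, latent_fraction = 0,
    dispersion_range = c(0.01, 0.05), seed = 5
  )
  sim <- simulate_counts(d, truth, seed = 5)
  sf <- size_factors(sim$counts)
  de <- adjacent_contrasts(sim$counts, sf, sim$metadata)
  planted <- truth$transcripts$transcript_id[truth$transcripts$pattern == "u0000"]
  hit <- de[de$transcript_id %in% planted & de$contrast == "8-13", ]
  expect_true(all(hit$padj < 0.05))
  expect_equal(mean(hit$log2fc), 2, tolerance = 0.25)
  rest <- de[de$transcript_id %in% planted & de$contrast != "8-13", ]
  expect_lt(mean(rest$padj < 0.05, na.rm = TRUE), 0.05)
})

test_that("relabelling the two times of an interval flips its log2fc exactly", {
  d <- fixture_de_design(n_lines = 4, n_reps = 2)
  truth <- simulation_truth(d,
    n_transcripts = 10, seed = 6,
    latent_fraction = 0
  )
  sim <- simulate_counts(d, truth, seed = 6)
  sf <- size_factors(sim$counts)
  disp <- rep(0.1, 10)
  names(disp) <- rownames(sim$counts)
  de <- adjacent_contrasts(sim$counts, sf, sim$metadata, dispersions = disp)

  swapped <- sim$metadata
  swapped$daa[sim$metadata$daa == 8] <- 13
  swapped$daa[sim$metadata$daa == 13] <- 8
  de2 <- adjacent_contrasts(sim$counts, sf, swapped, dispersions = disp)
  a <- de[de$contrast == "8-13", ]
  b <- de2[de2$contrast == "8-13", ]
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-6)
  expect_equal(a$p, b$p, tolerance = 1e-6)
})

test_that("Wald and LRT agree on order of magnitude for a large planted effect", {
  d <- fixture_de_design(n_lines = 3, n_reps = 4)
  truth <- simulation_truth(d,
    n_transcripts = 5, patterns = "u0000",
    step_log2 = 1.5, line_sd = 0, latent_fraction = 0,
    dispersion_range = c(0.02, 0.02), seed = 7
  )
  sim <- simulate_counts(d, truth, seed = 7)
  sf <- size_factors(sim$counts)
  fac <- data.frame(
    line = factor(sim$metadata$line),
    time = factor(sim$metadata$daa)
  )
  X_full <- model.matrix(~ line + time, fac)
  X_red <- X_full[, !grepl("time13", colnames(X_full))]
  disp <- estimate_dispersions(sim$counts, sf, fac)
  for (i in 1:3) {
    f1 <- fit_nb_glm(sim$counts[i, ], X_full, log(sf), disp[i])
    f0 <- fit_nb_glm(sim$counts[i, ], X_red, log(sf), disp[i])
    lrt_p <- pchisq(2 * (f1$loglik - f0$loglik), 1, lower.tail = FALSE)
    z <- f1$coefficients["time13"] / sqrt(f1$vcov["time13", "time13"])
    wald_p <- 2 * pnorm(-abs(z))
    expect_lt(abs(log10(lrt_p + 1e-300) - log10(wald_p + 1e-300)), 1.5)
  }
})
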