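sim_vst_study <- function(latent_sd, latent_fraction, n_transcripts = 150,
                          seed = 11) {
  d <- study_design(
    n_lines = 8, n_locations = 2, n_reps = 2,
    missing_fraction = 0
  )
  truth <- simulation_truth(d,
    n_transcripts = n_transcripts,
    latent_sd = latent_sd, latent_fraction = latent_fraction,
    dispersion_range = c(0.02, 0.1), seed = seed
  )
  sim <- simulate_counts(d, truth, seed = seed)
  vst <- variance_stabilize(sim$counts, size_factors(sim$counts))
  list(design = d, truth = truth, sim = sim, vst = vst)
}

test_that("latent-factor adjustment recovers a planted factor and spares clean data", {
  st <- sim_vst_study(latent_sd = 4, latent_fraction = 0.8, n_transcripts = 200)
  adj <- adjust_latent(st$vst, st$sim$metadata)
  # the factor is identifiable only in the residual space of the design,
  # so compare against the design-residualised truth
  X <- model.matrix(
    ~ line + location + location:replicate + time,
    data.frame(
      line = factor(st$sim$metadata$line),
      location = factor(st$sim$metadata$location),
      replicate = factor(st$sim$metadata$replicate),
      time = factor(st$sim$metadata$daa)
    )
  )
  f_resid <- qr.resid(qr(X), st$sim$latent_factor[names(adj$factor)])
  expect_gt(abs(cor(adj$factor, f_resid)), 0.95)

  # without any latent signal the adjustment removes only a noise sliver
  st0 <- sim_vst_study(latent_sd = 0, latent_fraction = 0, seed = 12)
  adj0 <- adjust_latent(st0$vst, st0$sim$metadata)
  rel <- sum((adj0$adjusted - st0$vst)^2) / sum((st0$vst - mean(st0$vst))^2)
  expect_lt(rel, 0.05)

  # a second pass removes less than the first (diminishing effect)
  adj1 <- adjust_latent(st$vst, st$sim$metadata)
  adj2 <- adjust_latent(adj1$adjusted, st$sim$metadata)
  expect_lt(
    sum((adj2$adjusted - adj1$adjusted)^2),
    sum((adj1$adjusted - st$vst)^2)
  )
})

test_that("lsmeans equal line means on balanced data and normal equations otherwise", {
  st <- sim_vst_study(latent_sd = 0, latent_fraction = 0, n_transcripts = 30)
  lsm <- lsmeans(st$vst, st$sim$metadata)
  line_means <- t(apply(st$vst, 1, function(v) {
    tapply(v, st$sim$metadata$line, mean)
  }))
  expect_equal(lsm, t(line_means), tolerance = 1e-8)

  # equivariance under a constant shift
  lsm_shift <- lsmeans(st$vst + 3, st$sim$metadata)
  expect_equal(lsm_shift, lsm + 3, tolerance = 1e-8)

  # unbalanced: drop a third of the samples, compare to emmeans
  skip_if_not_installed("emmeans")
  set.seed(13)
  keep <- sort(sample(ncol(st$vst), round(ncol(st$vst) * 2 / 3)))
  v2 <- st$vst[, keep]
  m2 <- st$sim$metadata[keep, ]
  lsm2 <- lsmeans(v2, m2)
  df <- data.frame(
    y = v2[1, ],
    line = factor(m2$line), location = factor(m2$location),
    replicate = factor(m2$replicate), time = factor(m2$daa)
  )
  fit <- stats::lm(y ~ line + location + location:replicate + time, df)
  em <- summary(emmeans::emmeans(fit, "line"))
  expect_equal(unname(lsm2[, 1]), em$emmean, tolerance = 1e-6)
})

test_that("subclustering is deterministic, order-invariant and separates planted groups", {
  kin <- fixture_kinship(n_lines = 10, n_families = 2, n_markers = 60)
  set.seed(14)
  prof <- drop(kin$L %*% rnorm(10))
  lsm <- cbind(
    vapply(1:12, function(i) prof + rnorm(10, 0, .1), numeric(10)),
    vapply(1:12, function(i) -prof + rnorm(10, 0, .1), numeric(10))
  )
  dimnames(lsm) <- list(rownames(kin$K), sprintf("T%03d", 1:24))
  part <- subcluster(lsm, 2)
  expect_length(unique(part$cluster[1:12]), 1)
  expect_length(unique(part$cluster[13:24]), 1)
  expect_false(part$cluster[1] == part$cluster[13])

  shuffled <- lsm[, sample(24)]
  part2 <- subcluster(shuffled, 2)
  joined <- dplyr::left_join(part, part2,
    by = "transcript_id",
    suffix = c("", "_shuf")
  )
  expect_equal(
    length(unique(paste(joined$cluster, joined$cluster_shuf))), 2
  )

  singl <- subcluster(lsm, ncol(lsm))
  expect_equal(sort(unique(singl$cluster)), 1:24)
  expect_error(subcluster(lsm, 30), "exceeds")
})

test_that("PC1 eigengene scores match the eigendecomposition and the sign rule", {
  kin <- fixture_kinship(n_lines = 12, n_families = 3, n_markers = 80)
  set.seed(15)
  base <- drop(kin$L %*% rnorm(12))
  lsm <- vapply(1:9, function(i) base + rnorm(12, 0, .05), numeric(12))
  dimnames(lsm) <- list(rownames(kin$K), sprintf("T%03d", 1:9))
  pc <- pc1_scores(lsm)
  expect_gt(pc$var_explained, 0.98)
  C <- scale(lsm, center = TRUE, scale = FALSE)
  eg <- eigen(crossprod(C))
  sc_oracle <- C %*% eg$vectors[, 1]
  expect_equal(abs(cor(pc$scores, drop(sc_oracle))), 1, tolerance = 1e-8)
  expect_gt(cor(pc$scores, rowMeans(C)), 0) # fixed sign

  single <- lsm[, 1, drop = FALSE]
  pcs <- pc1_scores(single)
  expect_equal(
    unname(abs(pcs$scores)),
    as.numeric(abs(scale(single, scale = FALSE))),
    tolerance = 1e-12
  )
  flat <- matrix(1, 12, 2, dimnames = list(rownames(kin$K), c("a", "b")))
  expect_error(pc1_scores(flat), "zero variance")
})

test_that("the subcluster count is chosen where heritabilities are high and even", {
  kin <- fixture_kinship()
  picks <- vapply(1:10, function(r) {
    pl <- fixture_planted_lsm(kin, seed = 100 + r)
    choose_k(pl$lsm, kin$eK, k_range = 2:8)$k
  }, numeric(1))
  expect_equal(as.integer(names(which.max(table(picks)))), 3L)

  # a single admissible k is returned as-is
  pl <- fixture_planted_lsm(kin, seed = 1)
  expect_equal(choose_k(pl$lsm, kin$eK, k_range = 5)$k, 5)

  # pure noise: boundary heritabilities tie and the smallest k usually wins
  set.seed(16)
  noise_k <- vapply(1:5, function(r) {
    noise <- matrix(rnorm(22 * 30), 22,
      dimnames = list(rownames(kin$K), sprintf("T%03d", 1:30))
    )
    ck <- choose_k(noise, kin$eK, k_range = 2:6)
    expect_lt(ck$by_k$median_h2[ck$by_k$k == ck$k], 0.5)
    ck$k
  }, numeric(1))
  expect_equal(as.integer(names(which.max(table(noise_k)))), 2L)
})

test_that("within-module line profiles correlate more than between modules", {
  kin <- fixture_kinship()
  pl <- fixture_planted_lsm(kin, seed = 3)
  cors <- cor(pl$lsm)
  same <- outer(pl$module, pl$module, "==") & upper.tri(cors)
  diff <- outer(pl$module, pl$module, "!=") & upper.tri(cors)
  expect_gt(mean(cors[same]), mean(cors[diff]))
})

test_that("build_gcoe_sets assembles consistent memberships and scores", {
  kin <- fixture_kinship()
  pl <- fixture_planted_lsm(kin, seed = 21)
  codes <- tibble::tibble(
    transcript_id = colnames(pl$lsm),
    code = rep(c("u0000", "d0000"), length.out = ncol(pl$lsm))
  )
  sets <- build_gcoe_sets(codes, pl$lsm, kin$eK,
    min_set_size = 5, k_range = 2:4
  )
  expect_setequal(unique(sets$membership$tcoe_id), c("u0000", "d0000"))
  expect_equal(nrow(sets$membership), ncol(pl$lsm))
  per_set <- table(sets$pc1$gcoe_id)
  expect_true(all(per_set == 22))
  expect_true(all(sets$chosen_k$k %in% 2:4))
})
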