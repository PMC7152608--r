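# Shared fixtures, all generated in code under fixed seeds.

# structured kinship: families give the GRM enough off-diagonal structure
# for additive variance to be identifiable from line-level scores
fixture_kinship <- function(n_lines = 22, n_markers = 300, n_families = 6,
                            fst = 0.5, seed = 2) {
  geno <- simulate_markers(n_lines, n_markers,
    n_families = n_families,
    fst = fst, seed = seed
  )
  K <- grm_vanraden(geno)
  eK <- suppressWarnings(grm_eigen(K))
  list(
    K = K, eK = eK,
    L = eK$vectors %*% diag(sqrt(pmax(eK$values, 0))),
    top = eK$vectors[, seq_len(n_families)]
  )
}

# lines x transcripts lsmean-like matrix with two correlated genetic
# modules and one coherent non-heritable module (its direction carries no
# family-structure variance); true module count is 3
fixture_planted_lsm <- function(kin, n_per_module = 15, seed = 101,
                                include_env = TRUE) {
  set.seed(seed)
  n <- nrow(kin$K)
  gA <- drop(kin$L %*% rnorm(n))
  gB <- 0.7 * gA + 0.7 * drop(kin$L %*% rnorm(n))
  e0 <- rnorm(n)
  env <- drop(e0 - kin$top %*% crossprod(kin$top, e0))
  env <- env / sd(env)
  lsm <- cbind(
    vapply(seq_len(n_per_module), function(i) gA + rnorm(n, 0, 0.3), numeric(n)),
    vapply(seq_len(n_per_module), function(i) gB + rnorm(n, 0, 0.3), numeric(n)),
    if (include_env) {
      vapply(seq_len(n_per_module), function(i) env + rnorm(n, 0, 0.8), numeric(n))
    }
  )
  dimnames(lsm) <- list(
    rownames(kin$K),
    sprintf("T%03d", seq_len(ncol(lsm)))
  )
  list(
    lsm = lsm, gA = gA, gB = gB, env = env,
    module = rep(c("A", "B", "env")[seq_len(2 + include_env)],
      each = n_per_module
    )
  )
}

# small time-course study for the DE path: one location keeps the GLM cheap
fixture_de_design <- function(n_lines = 8, n_reps = 2) {
  study_design(
    n_lines = n_lines, n_locations = 1, n_reps = n_reps,
    missing_fraction = 0
  )
}

# counts with planted pattern codes at large effect and low dispersion so
# the encode round trip is near-deterministic; u/d balanced to avoid
# compositional bias in the size factors
fixture_planted_study <- function(n_transcripts = 100,
                                  patterns = c(
                                    "u0000", "d0000", "0u000", "0d000",
                                    "00u00", "00d00", "000u0", "000d0",
                                    "0000u", "0000d", "uu000", "dd000",
                                    rep("00000", 12)
                                  ),
                                  step_log2 = 2.5, seed = 5) {
  d <- fixture_de_design()
  truth <- simulation_truth(d,
    n_transcripts = n_transcripts, patterns = patterns,
    step_log2 = step_log2, line_sd = 0.15,
    dispersion_range = c(0.01, 0.05), latent_fraction = 0, seed = seed
  )
  sim <- simulate_counts(d, truth, depth_range = c(0.8, 1.25), seed = seed)
  list(design = d, truth = truth, sim = sim)
}
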