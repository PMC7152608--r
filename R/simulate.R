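#' Simulate biallelic marker dosages for a diversity panel
#'
#' Draws markers with ancestral allele frequencies uniform on `maf_range`
#' and Hardy-Weinberg genotype dosages in {0, 1, 2}. With `fst = 0`
#' (default) the lines are unrelated and, with many markers, the VanRaden
#' relationship matrix is close to diagonal — the near-diagonal kinship of
#' a diverse panel. With `n_families > 1` and `fst > 0`, lines are grouped
#' into families whose allele frequencies drift from the ancestral ones by
#' a Balding-Nichols model, giving the GRM a block structure under which
#' additive variance is identifiable.
#'
#' @param n_lines number of lines (rows)
#' @param n_markers number of markers (columns); must be at least `n_lines`
#' @param maf_range minor-allele-frequency interval, a subset of (0, 0.5]
#' @param n_families number of equally sized line families (default 1)
#' @param fst Balding-Nichols differentiation of family allele frequencies
#'   (default 0, unrelated lines)
#' @param seed integer seed; identical seeds give identical matrices
#' @return integer matrix `n_lines` x `n_markers` with line IDs as rownames
#' @seealso [grm_vanraden()]
#' @export
simulate_markers <- function(n_lines, n_markers, maf_range = c(0.05, 0.5),
                             n_families = 1, fst = 0, seed = 1L) {
  stopifnot(n_lines >= 1, n_families >= 1, fst >= 0, fst < 1)
  if (n_markers < n_lines) abort("`n_markers` must be >= `n_lines`")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
    maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an interval within (0, 0.5]")
  }
  set.seed(seed)
  p <- runif(n_markers, maf_range[1], maf_range[2])
  fam <- rep_len(seq_len(n_families), n_lines)
  geno <- vapply(seq_len(n_markers), function(m) {
    pf <- if (fst > 0 && n_families > 1) {
      stats::rbeta(
        n_families, p[m] * (1 - fst) / fst, (1 - p[m]) * (1 - fst) / fst
      )
    } else {
      rep(p[m], n_families)
    }
    rbinom(n_lines, 2L, pf[fam])
  }, integer(n_lines))
  rownames(geno) <- sprintf("L%02d", seq_len(n_lines))
  colnames(geno) <- sprintf("m%05d", seq_len(n_markers))
  geno
}

#' Ground truth for a synthetic seed-development study
#'
#' Fixes everything the generator needs and the tests recover: each
#' transcript's temporal pattern code (a string over {u, d, 0}, one
#' character per adjacent time interval), its genetic module (a GCoE set
#' nested in the TCoE pattern set), module heritabilities, per-line
#' additive genetic values drawn from the kinship `K`, NB dispersions, one
#' latent batch factor, and metabolite-module links.
#'
#' @param design a [study_design()]
#' @param n_transcripts number of transcripts to simulate
#' @param K lines x lines relationship matrix (defaults to identity);
#'   row order defines line order
#' @param patterns optional character vector of pattern codes to assign
#'   (recycled); if `NULL`, per-interval states are drawn i.i.d. with
#'   probabilities `state_probs`, so inter-interval independence holds by
#'   construction
#' @param state_probs named probabilities for states `u`, `d`, `0` when
#'   sampling codes
#' @param n_gcoe_per_pattern genetic modules nested within each pattern set
#' @param h2_module heritability of every module, or a range to draw from
#' @param step_log2 log2 step size of an `u`/`d` move between adjacent times
#' @param line_sd total per-transcript line-offset standard deviation
#'   (log2 units); the genetic share of its variance is `h2_module`
#' @param dispersion_range NB dispersions drawn log-uniform in this interval
#' @param latent_fraction fraction of transcripts loaded on the latent factor
#' @param latent_sd standard deviation of non-zero latent loadings (log2)
#' @param n_metabolites metabolites to link later via [simulate_metabolites()]
#' @param linked_fraction fraction of metabolites causally linked to a module
#' @param beta_range absolute effect sizes for linked metabolites
#' @param seed integer seed
#' @return a list of class `sim_truth` with elements `transcripts` (tibble:
#'   `transcript_id`, `pattern`, `tcoe_id`, `gcoe_id`, `dispersion`,
#'   `latent_loading`, `baseline_log2`), `modules` (tibble: `gcoe_id`,
#'   `tcoe_id`, `h2`), `line_genetic_values` (modules x lines matrix),
#'   `metabolite_links` (tibble: `metabolite_id`, `gcoe_id`, `beta`) and
#'   the simulation parameters
#' @export
simulation_truth <- function(design, n_transcripts = 1000, K = NULL,
                             patterns = NULL,
                             state_probs = c(u = 0.15, d = 0.15, `0` = 0.70),
                             n_gcoe_per_pattern = 2,
                             h2_module = c(0.6, 0.9),
                             step_log2 = 1.0,
                             line_sd = 0.5,
                             dispersion_range = c(0.01, 1),
                             latent_fraction = 0.3,
                             latent_sd = 1.0,
                             n_metabolites = 0,
                             linked_fraction = 0.5,
                             beta_range = c(0.5, 2),
                             seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  set.seed(seed)
  k_int <- length(design$time_points) - 1L
  if (is.null(K)) {
    K <- diag(design$n_lines)
    dimnames(K) <- list(design$lines, design$lines)
  }
  stopifnot(nrow(K) == design$n_lines)
  if (is.null(rownames(K))) rownames(K) <- colnames(K) <- design$lines

  if (is.null(patterns)) {
    states <- names(state_probs)
    codes <- replicate(
      n_transcripts,
      paste(sample(states, k_int, replace = TRUE, prob = state_probs),
        collapse = ""
      )
    )
  } else {
    if (any(nchar(patterns) != k_int)) {
      abort(sprintf("pattern codes must have length %d for this design", k_int))
    }
    codes <- rep_len(patterns, n_transcripts)
  }

  tcoe <- codes
  gcoe_idx <- sample.int(n_gcoe_per_pattern, n_transcripts, replace = TRUE)
  gcoe <- paste0(tcoe, ".g", gcoe_idx)

  module_ids <- sort(unique(gcoe))
  h2 <- if (length(h2_module) == 2 && h2_module[1] != h2_module[2]) {
    runif(length(module_ids), h2_module[1], h2_module[2])
  } else {
    rep_len(h2_module[1], length(module_ids))
  }
  stopifnot(all(h2 >= 0 & h2 <= 1))

  # per-module line genetic values ~ MVN(0, K)
  ek <- eigen(K, symmetric = TRUE)
  L <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0)), nrow(K))
  G <- matrix(rnorm(length(module_ids) * nrow(K)), length(module_ids)) %*% t(L)
  dimnames(G) <- list(module_ids, rownames(K))

  transcripts <- tibble(
    transcript_id = sprintf("T%05d", seq_len(n_transcripts)),
    pattern = codes, tcoe_id = tcoe, gcoe_id = gcoe,
    dispersion = exp(runif(
      n_transcripts, log(dispersion_range[1]),
      log(dispersion_range[2])
    )),
    latent_loading = ifelse(
      runif(n_transcripts) < latent_fraction,
      rnorm(n_transcripts, 0, latent_sd), 0
    ),
    baseline_log2 = runif(n_transcripts, 4, 8)
  )
  modules <- tibble(
    gcoe_id = module_ids,
    tcoe_id = sub("\\.g[0-9]+$", "", module_ids),
    h2 = h2
  )

  links <- tibble(
    metabolite_id = character(), gcoe_id = character(), beta = double()
  )
  if (n_metabolites > 0) {
    linked <- runif(n_metabolites) < linked_fraction
    links <- tibble(
      metabolite_id = sprintf("M%04d", seq_len(n_metabolites)),
      gcoe_id = ifelse(linked,
        sample(module_ids, n_metabolites, replace = TRUE), NA_character_
      ),
      beta = ifelse(linked,
        sample(c(-1, 1), n_metabolites, TRUE) *
          runif(n_metabolites, beta_range[1], beta_range[2]), 0
      )
    )
  }

  structure(
    list(
      transcripts = transcripts, modules = modules,
      line_genetic_values = G, metabolite_links = links,
      step_log2 = step_log2, line_sd = line_sd, K = K, seed = seed
    ),
    class = "sim_truth"
  )
}

# cumulative log2 profile of a pattern code across the time points
pattern_profile <- function(code, n_times, step_log2) {
  steps <- c(u = 1, d = -1, `0` = 0)[strsplit(code, "")[[1]]]
  if (length(steps) != n_times - 1L || anyNA(steps)) {
    abort(sprintf("invalid pattern code '%s' for %d time points", code, n_times))
  }
  cumsum(c(0, steps)) * step_log2
}

#' Simulate a 3' tag RNA-seq count matrix for a study design
#'
#' Counts are NB draws whose log2 mean follows the transcript's assigned
#' pattern code across adjacent time intervals (a `step_log2` move per `u`
#' or `d`, flat for `0`), plus a per-line offset whose genetic fraction of
#' variance equals the module heritability, plus one latent batch factor on
#' a subset of transcripts, scaled by a per-sample sequencing-depth factor.
#' A `missing_fraction` of the potential samples is dropped at random,
#' emulating field losses.
#'
#' @param design a [study_design()]
#' @param truth a [simulation_truth()] built for the same design
#' @param depth_range relative sequencing depths drawn log-uniform in this
#'   positive interval
#' @param seed integer seed
#' @return list with `counts` (transcripts x samples integer matrix),
#'   `metadata` (tibble: `sample_id`, `line`, `location`, `replicate`,
#'   `daa`), `depth_factors` (named per-sample truth depths),
#'   `latent_factor` (named per-sample truth scores) and `offsets`
#'   (transcripts x lines realized line offsets, log2 scale)
#' @export
simulate_counts <- function(design, truth, depth_range = c(0.5, 2),
                            seed = 1L) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "sim_truth"))
  if (any(depth_range <= 0)) abort("`depth_range` must be positive")
  set.seed(seed)
  tr <- truth$transcripts
  n_times <- length(design$time_points)

  meta <- design$samples
  if (design$missing_fraction > 0) {
    keep <- sort(sample.int(
      nrow(meta),
      round(nrow(meta) * (1 - design$missing_fraction))
    ))
    meta <- meta[keep, ]
  }
  n_s <- nrow(meta)
  time_idx <- match(meta$daa, design$time_points)
  line_idx <- match(meta$line, design$lines)

  depth <- exp(runif(n_s, log(depth_range[1]), log(depth_range[2])))
  depth <- depth / exp(mean(log(depth)))
  names(depth) <- meta$sample_id
  f <- rnorm(n_s)
  names(f) <- meta$sample_id

  profiles <- t(vapply(
    tr$pattern, pattern_profile, numeric(n_times),
    n_times = n_times, step_log2 = truth$step_log2
  ))

  # line offsets: shared genetic value (module) + transcript-level line noise
  G <- truth$line_genetic_values
  h2 <- setNames(truth$modules$h2, truth$modules$gcoe_id)[tr$gcoe_id]
  sd_g <- truth$line_sd * sqrt(h2)
  sd_e <- truth$line_sd * sqrt(1 - h2)
  noise <- matrix(rnorm(nrow(tr) * design$n_lines), nrow(tr))
  offsets <- G[tr$gcoe_id, , drop = FALSE] * sd_g + noise * sd_e

  mu_log2 <- tr$baseline_log2 + profiles[, time_idx, drop = FALSE] +
    offsets[, line_idx, drop = FALSE] +
    outer(tr$latent_loading, f)
  mu <- t(t(2^mu_log2) * depth)

  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = rep(1 / tr$dispersion, n_s)),
    nrow = nrow(tr)
  )
  dimnames(counts) <- list(tr$transcript_id, meta$sample_id)
  dimnames(offsets) <- list(tr$transcript_id, design$lines)
  list(
    counts = counts, metadata = meta,
    depth_factors = depth, latent_factor = f, offsets = offsets
  )
}

#' Simulate mature-seed metabolite measurements linked to GCoE modules
#'
#' Each metabolite is measured once per line x location x replicate.
#' A linked metabolite's line-level signal is `beta` times the module's
#' per-line PC1 truth; design noise adds a location main effect, a
#' replicate-within-location block effect, a location-by-line interaction
#' and a plot residual, each with its stated variance.
#'
#' @param truth a [simulation_truth()] carrying `metabolite_links`
#' @param design the [study_design()]
#' @param pc1_truth modules x lines matrix of true module scores; defaults
#'   to `truth$line_genetic_values`
#' @param noise_variances named variances: `loc` (location main effect),
#'   `rep` (replicate within location), `loc_line` (location x line) and
#'   `residual` (plot error)
#' @param seed integer seed
#' @return tibble with columns `metabolite_id`, `line`, `location`,
#'   `replicate`, `value`
#' @export
simulate_metabolites <- function(truth, design,
                                 pc1_truth = NULL,
                                 noise_variances = c(
                                   loc = 0.5, rep = 0.25,
                                   loc_line = 0.25, residual = 0.5
                                 ),
                                 seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"), inherits(design, "study_design"))
  if (any(noise_variances < 0)) abort("noise variances must be non-negative")
  links <- truth$metabolite_links
  if (nrow(links) == 0) abort("`truth` carries no metabolite links; set `n_metabolites`")
  if (is.null(pc1_truth)) pc1_truth <- truth$line_genetic_values
  miss <- setdiff(na.omit(links$gcoe_id), rownames(pc1_truth))
  if (length(miss) > 0) {
    abort(paste("linked modules absent from `pc1_truth`:", paste(miss, collapse = ", ")))
  }
  set.seed(seed)
  grid <- expand.grid(
    line = design$lines, location = design$locations,
    replicate = design$replicates,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  sv <- sqrt(noise_variances)
  out <- lapply(seq_len(nrow(links)), function(i) {
    g <- if (is.na(links$gcoe_id[i])) {
      rep(0, design$n_lines)
    } else {
      pc1_truth[links$gcoe_id[i], design$lines]
    }
    loc_eff <- setNames(rnorm(design$n_locations, 0, sv["loc"]), design$locations)
    rep_eff <- matrix(rnorm(design$n_locations * design$n_reps, 0, sv["rep"]),
      design$n_locations,
      dimnames = list(design$locations, design$replicates)
    )
    ll_eff <- matrix(rnorm(design$n_locations * design$n_lines, 0, sv["loc_line"]),
      design$n_locations,
      dimnames = list(design$locations, design$lines)
    )
    value <- links$beta[i] * g[match(grid$line, design$lines)] +
      loc_eff[grid$location] +
      rep_eff[cbind(grid$location, grid$replicate)] +
      ll_eff[cbind(grid$location, grid$line)] +
      rnorm(nrow(grid), 0, sv["residual"])
    tibble(
      metabolite_id = links$metabolite_id[i],
      line = grid$line, location = grid$location,
      replicate = grid$replicate, value = value
    )
  })
  bind_rows(out)
}
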