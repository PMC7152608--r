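#' Write / read a labelled numeric matrix as TSV
#'
#' Rows carry their names in the first column (`id`); the header holds the
#' column names. The round-trip is exact to the printed precision.
#'
#' @param m matrix with dimnames
#' @param path file path
#' @return `read_tsv_matrix` returns the matrix
#' @export
write_tsv_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @export
read_tsv_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

write_tsv_tbl <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_tbl <- function(path) {
  as_tibble(read.delim(path, check.names = FALSE, stringsAsFactors = FALSE))
}

stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% (.Machine$integer.max - 1) + 1)
}

#' Validate pipeline input files
#'
#' Cross-checks sample and line ID alignment (counts columns vs metadata,
#' metadata lines vs GRM vs metabolites), integer-ness of counts, and GRM
#' symmetry; fails fast with a message naming the offenders.
#'
#' @param counts_path,metadata_path TSV paths (counts as
#'   [write_tsv_matrix()] layout, metadata with `sample_id`, `line`,
#'   `location`, `replicate`, `daa`)
#' @param grm_path optional GRM TSV path
#' @param metabolites_path optional long metabolite TSV path
#' @return invisibly `TRUE`; aborts on the first problem
#' @export
validate_inputs <- function(counts_path, metadata_path, grm_path = NULL,
                            metabolites_path = NULL) {
  counts <- read_tsv_matrix(counts_path)
  meta <- read_tsv_tbl(metadata_path)
  need <- setdiff(c("sample_id", "line", "location", "replicate", "daa"), names(meta))
  if (length(need)) abort(paste("metadata missing columns:", paste(need, collapse = ", ")))
  if (!setequal(colnames(counts), meta$sample_id)) {
    off <- union(
      setdiff(colnames(counts), meta$sample_id),
      setdiff(meta$sample_id, colnames(counts))
    )
    abort(paste("sample IDs differ between counts and metadata:", paste(off, collapse = ", ")))
  }
  bad <- which(counts != round(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "non-integer or negative count at row %s, column %s",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]
    ))
  }
  if (!is.null(grm_path)) {
    K <- read_tsv_matrix(grm_path)
    if (!isSymmetric(unname(K), tol = 1e-6)) abort("GRM is not symmetric")
    miss <- setdiff(unique(meta$line), rownames(K))
    if (length(miss)) abort(paste("GRM missing line(s):", paste(miss, collapse = ", ")))
  }
  if (!is.null(metabolites_path)) {
    mt <- read_tsv_tbl(metabolites_path)
    miss <- setdiff(unique(mt$line), unique(meta$line))
    if (length(miss)) abort(paste("metabolite line(s) absent from metadata:", paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Default pipeline configuration
#'
#' Every tunable of every stage with its default; unknown keys passed to
#' [run_pipeline()] are rejected.
#'
#' @param ... overrides as `name = value`
#' @return named list of class `run_config`
#' @export
run_config <- function(...) {
  cfg <- list(
    n_transcripts = 400, n_metabolites = 40, patterns = NULL,
    n_markers = 2000, maf_range = c(0.05, 0.5),
    depth_range = c(0.5, 2),
    min_mapped = 0, min_count = 2, min_samples = 10, top_n = 500,
    min_minor_fraction = 0.05,
    alpha_interaction = 0.1, alpha_de = 0.05,
    min_set_size = 10, k_range = 4:20, lambda = 1, linkage = "ward.D2",
    n_perm_patterns = 200, top_k = 20,
    n_perm_h2 = 10, k_test = 8, n_perm_sizetest = 200,
    h2_threshold = 0.4, n_perm_metab = 100
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg[names(ov)] <- ov
  structure(cfg, class = "run_config")
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulate, qc, de, patterns, gcoe, h2, sizetest and metabolites
#' in dependency order, writing each stage's outputs as TSV under
#' `output_dir`. A stage whose output files already exist is skipped
#' unless an upstream stage reran; the manifest records every file with
#' its MD5 checksum, so a run is reproducible from (config, seed) and
#' resumable after deleting any stage's outputs. Each stage draws from its
#' own deterministic sub-stream of `seed`.
#'
#' @param output_dir directory for stage outputs (created if needed)
#' @param design a [study_design()]
#' @param config a [run_config()]
#' @param seed master integer seed
#' @param force rerun all stages even when outputs exist
#' @return tibble manifest: `stage`, `file`, `md5`, `status`
#' @export
run_pipeline <- function(output_dir, design = study_design(),
                         config = run_config(), seed = 1L, force = FALSE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  pp <- function(...) file.path(output_dir, paste0(...))
  cfg <- config
  writeLines(
    c(
      sprintf("seed\t%d", seed),
      vapply(names(cfg), function(k) {
        sprintf("%s\t%s", k, paste(format(cfg[[k]]), collapse = ","))
      }, character(1))
    ),
    pp("config.tsv")
  )

  stages <- list(
    simulate = c("counts.tsv", "metadata.tsv", "grm.tsv", "metabolites.tsv", "truth_transcripts.tsv", "truth_modules.tsv"),
    qc = c("vst.tsv", "size_factors.tsv", "pca_scores.tsv", "qc_metadata.tsv"),
    de = c("de_results.tsv", "interaction.tsv"),
    patterns = c("codes.tsv", "pattern_table.tsv", "pattern_null.tsv"),
    gcoe = c("lsmeans.tsv", "gcoe_membership.tsv", "gcoe_pc1.tsv", "chosen_k.tsv"),
    h2 = c("gcoe_h2.tsv", "h2_null.tsv"),
    sizetest = c("cluster_size_test.tsv"),
    metabolites = c("metabolite_h2.tsv", "met_observed.tsv", "met_summary.tsv")
  )
  ran <- character()
  status <- setNames(rep("skipped", length(stages)), names(stages))
  must_run <- function(stage) {
    force || length(ran) > 0 || !all(file.exists(pp(stages[[stage]])))
  }
  log_stage <- function(stage) {
    inform(sprintf("[%s] seed %d: running", stage, stage_seed(seed, stage)))
  }

  if (must_run("simulate")) {
    log_stage("simulate")
    s <- stage_seed(seed, "simulate")
    geno <- simulate_markers(design$n_lines, cfg$n_markers, cfg$maf_range, seed = s)
    K <- grm_vanraden(geno)
    truth <- simulation_truth(design,
      n_transcripts = cfg$n_transcripts, K = K,
      patterns = cfg$patterns,
      n_metabolites = cfg$n_metabolites, seed = s
    )
    sim <- simulate_counts(design, truth, depth_range = cfg$depth_range, seed = s)
    met <- simulate_metabolites(truth, design, seed = s)
    write_tsv_matrix(sim$counts, pp("counts.tsv"))
    write_tsv_tbl(sim$metadata, pp("metadata.tsv"))
    write_tsv_matrix(K, pp("grm.tsv"))
    write_tsv_tbl(met, pp("metabolites.tsv"))
    write_tsv_tbl(truth$transcripts, pp("truth_transcripts.tsv"))
    write_tsv_tbl(truth$modules, pp("truth_modules.tsv"))
    ran <- c(ran, "simulate")
    status["simulate"] <- "ran"
  }

  if (must_run("qc")) {
    log_stage("qc")
    counts <- read_tsv_matrix(pp("counts.tsv"))
    meta <- read_tsv_tbl(pp("metadata.tsv"))
    qc <- qc_pipeline(counts, meta,
      min_mapped = cfg$min_mapped,
      min_count = cfg$min_count, min_samples = cfg$min_samples,
      top_n = cfg$top_n, min_minor_fraction = cfg$min_minor_fraction
    )
    write_tsv_matrix(qc$vst, pp("vst.tsv"))
    write_tsv_tbl(
      tibble(sample_id = names(qc$size_factors), size_factor = qc$size_factors),
      pp("size_factors.tsv")
    )
    write_tsv_tbl(qc$pca$scores, pp("pca_scores.tsv"))
    write_tsv_tbl(qc$metadata, pp("qc_metadata.tsv"))
    ran <- c(ran, "qc")
    status["qc"] <- "ran"
  }

  meta_q <- read_tsv_tbl(pp("qc_metadata.tsv"))
  counts_q <- function() {
    counts <- read_tsv_matrix(pp("counts.tsv"))
    vst <- read_tsv_matrix(pp("vst.tsv"))
    counts[rownames(vst), colnames(vst), drop = FALSE]
  }

  if (must_run("de")) {
    log_stage("de")
    cm <- counts_q()
    sfa <- read_tsv_tbl(pp("size_factors.tsv"))
    sf <- setNames(sfa$size_factor, sfa$sample_id)[colnames(cm)]
    disp <- estimate_dispersions(cm, sf, de_factors(meta_q))
    lrt <- interaction_lrt(cm, sf, meta_q, alpha = cfg$alpha_interaction, dispersions = disp)
    keep <- lrt$transcript_id[!lrt$flagged]
    de <- adjacent_contrasts(cm[keep, , drop = FALSE], sf, meta_q,
      alpha = cfg$alpha_de, dispersions = disp[keep]
    )
    write_tsv_tbl(de, pp("de_results.tsv"))
    write_tsv_tbl(lrt, pp("interaction.tsv"))
    ran <- c(ran, "de")
    status["de"] <- "ran"
  }

  if (must_run("patterns")) {
    log_stage("patterns")
    de <- read_tsv_tbl(pp("de_results.tsv"))
    codes <- encode_patterns(de, alpha = cfg$alpha_de)
    en <- enumerate_patterns(codes)
    pn <- permutation_null(codes,
      n_perm = cfg$n_perm_patterns, top_k = cfg$top_k,
      seed = stage_seed(seed, "patterns")
    )
    write_tsv_tbl(codes, pp("codes.tsv"))
    write_tsv_tbl(en$table, pp("pattern_table.tsv"))
    write_tsv_tbl(pn$summary, pp("pattern_null.tsv"))
    ran <- c(ran, "patterns")
    status["patterns"] <- "ran"
  }

  if (must_run("gcoe")) {
    log_stage("gcoe")
    vst <- read_tsv_matrix(pp("vst.tsv"))
    adj <- adjust_latent(vst, meta_q)
    lsm <- lsmeans(adj$adjusted, meta_q)
    codes <- read_tsv_tbl(pp("codes.tsv"))
    K <- read_tsv_matrix(pp("grm.tsv"))
    sets <- build_gcoe_sets(codes, lsm, K,
      min_set_size = cfg$min_set_size,
      k_range = cfg$k_range, lambda = cfg$lambda, linkage = cfg$linkage
    )
    write_tsv_matrix(lsm, pp("lsmeans.tsv"))
    write_tsv_tbl(sets$membership, pp("gcoe_membership.tsv"))
    write_tsv_tbl(sets$pc1, pp("gcoe_pc1.tsv"))
    write_tsv_tbl(sets$chosen_k, pp("chosen_k.tsv"))
    ran <- c(ran, "gcoe")
    status["gcoe"] <- "ran"
  }

  if (must_run("h2")) {
    log_stage("h2")
    codes <- read_tsv_tbl(pp("codes.tsv"))
    lsm <- read_tsv_matrix(pp("lsmeans.tsv"))
    K <- read_tsv_matrix(pp("grm.tsv"))
    hn <- h2_permutation_null(codes, lsm, K,
      n_perm = cfg$n_perm_h2,
      seed = stage_seed(seed, "h2"),
      min_set_size = cfg$min_set_size, k_range = cfg$k_range,
      lambda = cfg$lambda, linkage = cfg$linkage
    )
    write_tsv_tbl(hn$real, pp("gcoe_h2.tsv"))
    write_tsv_tbl(hn$null, pp("h2_null.tsv"))
    ran <- c(ran, "h2")
    status["h2"] <- "ran"
  }

  if (must_run("sizetest")) {
    log_stage("sizetest")
    codes <- read_tsv_tbl(pp("codes.tsv"))
    lsm <- read_tsv_matrix(pp("lsmeans.tsv"))
    st <- cluster_size_screen(codes, lsm,
      k = cfg$k_test,
      n_perm = cfg$n_perm_sizetest,
      seed = stage_seed(seed, "sizetest"),
      min_set_size = max(cfg$k_test, cfg$min_set_size)
    )
    write_tsv_tbl(st, pp("cluster_size_test.tsv"))
    ran <- c(ran, "sizetest")
    status["sizetest"] <- "ran"
  }

  if (must_run("metabolites")) {
    log_stage("metabolites")
    met <- read_tsv_tbl(pp("metabolites.tsv"))
    met$replicate <- as.character(met$replicate)
    pc1 <- read_tsv_tbl(pp("gcoe_pc1.tsv"))
    fh <- filter_heritable(met, threshold = cfg$h2_threshold)
    if (any(fh$h2$kept)) {
      cmp <- permutation_compare(fh$metabolites, pc1,
        n_perm = cfg$n_perm_metab, seed = stage_seed(seed, "metabolites")
      )
      write_tsv_tbl(cmp$observed, pp("met_observed.tsv"))
      write_tsv_tbl(glance(cmp), pp("met_summary.tsv"))
    } else {
      write_tsv_tbl(tibble(), pp("met_observed.tsv"))
      write_tsv_tbl(tibble(), pp("met_summary.tsv"))
    }
    write_tsv_tbl(fh$h2, pp("metabolite_h2.tsv"))
    ran <- c(ran, "metabolites")
    status["metabolites"] <- "ran"
  }

  manifest <- purrr::imap(stages, function(files, stage_name) {
    sums <- unname(tools::md5sum(pp(files)))
    st <- rep(status[[stage_name]], length(files))
    tibble(stage = stage_name, file = files, md5 = sums, status = st)
  }) %>% bind_rows()
  write_tsv_tbl(manifest, pp("manifest.tsv"))
  manifest
}
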