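#' Heritability filter for metabolites
#'
#' Computes (or reuses) the design-based heritability of every metabolite
#' and keeps those strictly above the threshold.
#'
#' @param metabolites long tibble: `metabolite_id`, `line`, `location`,
#'   `replicate`, `value`
#' @param threshold keep metabolites with `h2 > threshold` (default 0.4,
#'   strict)
#' @param h2 optional precomputed tibble (`metabolite_id`, `h2`); computed
#'   with [metabolite_h2()] when missing
#' @return list with `metabolites` (filtered long tibble) and `h2` (tibble
#'   of all metabolites with their heritabilities and a `kept` flag)
#' @export
filter_heritable <- function(metabolites, threshold = 0.4, h2 = NULL) {
  if (is.null(h2)) {
    h2 <- metabolites %>%
      group_by(.data$metabolite_id) %>%
      summarise(
        h2 = metabolite_h2(dplyr::pick(dplyr::everything()))$h2,
        .groups = "drop"
      )
  }
  h2$kept <- h2$h2 > threshold
  if (!any(h2$kept)) warn("no metabolite passes the heritability filter")
  list(
    metabolites = metabolites[
      metabolites$metabolite_id %in% h2$metabolite_id[h2$kept],
    ],
    h2 = h2
  )
}

# per-line response: mean across locations and replicates
line_means <- function(metabolites) {
  metabolites %>%
    group_by(.data$metabolite_id, .data$line) %>%
    summarise(value = mean(.data$value), .groups = "drop")
}

#' Regress metabolites on GCoE eigengene scores
#'
#' Simple linear regression of each metabolite's per-line mean on each
#' GCoE set's PC1 scores; the slope's two-sided p-value comes from the t
#' distribution with `n_lines - 2` degrees of freedom. No multiple-testing
#' correction is applied on the metabolite x GCoE grid: inference rests on
#' the permutation comparison, not per-test significance.
#'
#' @param metabolites long metabolite tibble (typically filtered)
#' @param pc1 tibble from [build_gcoe_sets()] (`$pc1`)
#' @return tibble: `metabolite_id`, `gcoe_id`, `slope`, `r2`, `df`, `p`
#' @export
regress_on_pc1 <- function(metabolites, pc1) {
  lm_df <- line_means(metabolites)
  met_wide <- lm_df %>% pivot_wider(names_from = "metabolite_id", values_from = "value")
  pc_wide <- pc1 %>%
    select("gcoe_id", "line", "score") %>%
    pivot_wider(names_from = "gcoe_id", values_from = "score")
  common <- intersect(met_wide$line, pc_wide$line)
  if (length(common) < 3) abort("fewer than 3 lines shared between metabolites and PC1 scores")
  M <- as.matrix(met_wide[match(common, met_wide$line), -1, drop = FALSE])
  P <- as.matrix(pc_wide[match(common, pc_wide$line), -1, drop = FALSE])
  n <- length(common)
  df <- n - 2
  out <- purrr::map(seq_len(ncol(P)), function(j) {
    x <- P[, j]
    sx <- sd(x)
    if (sx == 0) {
      return(tibble(
        metabolite_id = colnames(M), gcoe_id = colnames(P)[j],
        slope = NA_real_, r2 = NA_real_, df = df, p = NA_real_
      ))
    }
    r <- drop(cor(x, M))
    slope <- r * apply(M, 2, sd) / sx
    tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    tibble(
      metabolite_id = colnames(M), gcoe_id = colnames(P)[j],
      slope = slope, r2 = r^2, df = df,
      p = 2 * pt(-abs(tstat), df = df)
    )
  }) %>% bind_rows()
  out
}

#' Compare observed metabolite-PC1 p-values with a permutation null
#'
#' Permutes each GCoE set's PC1 scores across lines `n_perm` times,
#' recomputes every metabolite regression, and contrasts the observed
#' p-value collection with the permuted one: per-GCoE quantiles and a
#' one-sided rank-sum test of whether observed p-values are stochastically
#' smaller.
#'
#' @inheritParams regress_on_pc1
#' @param n_perm permutations of the PC1 scores (default 100)
#' @param seed integer seed
#' @return object of class `met_link`: `observed` (regression tibble),
#'   `permuted` (with `perm` column), `by_gcoe` (quantile comparison),
#'   `rank_sum_p` (one-sided)
#' @export
permutation_compare <- function(metabolites, pc1, n_perm = 100, seed = 1L) {
  stopifnot(n_perm >= 1)
  observed <- regress_on_pc1(metabolites, pc1)
  set.seed(seed)
  permuted <- purrr::map(seq_len(n_perm), function(b) {
    pc_b <- pc1 %>%
      group_by(.data$gcoe_id) %>%
      mutate(score = .data$score[sample.int(dplyr::n())]) %>%
      ungroup()
    regress_on_pc1(metabolites, pc_b) %>% mutate(perm = b)
  }) %>% bind_rows()
  by_gcoe <- dplyr::bind_rows(
    observed %>% mutate(source = "observed"),
    permuted %>% select(-"perm") %>% mutate(source = "permuted")
  ) %>%
    group_by(.data$gcoe_id, .data$source) %>%
    summarise(
      q10 = quantile(.data$p, 0.10, na.rm = TRUE),
      median_p = median(.data$p, na.rm = TRUE),
      .groups = "drop"
    )
  rs <- wilcox.test(observed$p, permuted$p, alternative = "less")$p.value
  structure(
    list(
      observed = observed, permuted = permuted,
      by_gcoe = by_gcoe, rank_sum_p = rs
    ),
    class = "met_link"
  )
}

#' @export
print.met_link <- function(x, ...) {
  cat(sprintf(
    "metabolite-GCoE association: %d observed tests, %d permuted; one-sided rank-sum p = %.3g\n",
    nrow(x$observed), nrow(x$permuted), x$rank_sum_p
  ))
  invisible(x)
}

#' @export
glance.met_link <- function(x, ...) {
  tibble(
    n_tests = nrow(x$observed),
    n_perm = max(x$permuted$perm),
    median_p_observed = median(x$observed$p, na.rm = TRUE),
    median_p_permuted = median(x$permuted$p, na.rm = TRUE),
    rank_sum_p = x$rank_sum_p
  )
}
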