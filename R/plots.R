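#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of the most populous temporal patterns
#'
#' @param pattern_table `$table` from [enumerate_patterns()]
#' @param top_k how many patterns to show (default 20)
#' @return a ggplot
#' @export
plot_pattern_table <- function(pattern_table, top_k = 20) {
  df <- head(pattern_table[order(pattern_table$rank), ], top_k)
  ggplot(df, aes(
    x = stats::reorder(.data$code, .data$rank),
    y = .data$n_transcripts
  )) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(
      x = "pattern code (u = up, d = down, 0 = no change)",
      y = "transcripts",
      title = sprintf("Top %d temporal co-expression patterns", nrow(df))
    ) +
    theme_minimal()
}

#' Sample PCA scatter, coloured by a metadata variable
#'
#' @param pca result of [sample_pca()]
#' @param metadata sample metadata tibble
#' @param colour metadata column to colour by (default `"daa"`)
#' @return a ggplot
#' @export
plot_sample_pca <- function(pca, metadata, colour = "daa") {
  df <- dplyr::left_join(pca$scores, metadata, by = "sample_id")
  ve <- pca$var_explained
  ggplot(df, aes(.data$PC1, .data$PC2, colour = factor(.data[[colour]]))) +
    geom_point(alpha = 0.8) +
    labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
      colour = colour
    ) +
    theme_minimal()
}

#' Box plots of real vs permuted GCoE heritabilities per TCoE set
#'
#' @param object an `h2_null` object from [h2_permutation_null()]
#' @param ... unused
#' @return a ggplot
#' @method autoplot h2_null
#' @export
autoplot.h2_null <- function(object, ...) {
  df <- bind_rows(
    object$real %>% mutate(source = "real"),
    object$null %>% select(-"perm") %>% mutate(source = "permuted")
  )
  ggplot(df, aes(.data$tcoe_id, .data$h2, fill = .data$source)) +
    geom_boxplot(outlier.size = 0.5, position = "dodge") +
    labs(x = "TCoE set (pattern code)", y = "GCoE PC1 heritability") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
}

#' Observed vs permuted p-value distributions of metabolite links
#'
#' @param object a `met_link` object from [permutation_compare()]
#' @param ... unused
#' @return a ggplot (empirical CDFs)
#' @method autoplot met_link
#' @export
autoplot.met_link <- function(object, ...) {
  df <- bind_rows(
    object$observed %>% mutate(source = "observed"),
    object$permuted %>% select(-"perm") %>% mutate(source = "permuted")
  )
  ggplot(df, aes(.data$p, colour = .data$source)) +
    stat_ecdf() +
    labs(
      x = "regression p-value", y = "empirical CDF",
      title = sprintf("rank-sum p = %.3g", object$rank_sum_p)
    ) +
    theme_minimal()
}

#' Permutation-null summary plot for pattern statistics
#'
#' @param object a `pattern_null` object from [permutation_null()]
#' @param ... unused
#' @return a ggplot with null ranges and the observed value per statistic
#' @method autoplot pattern_null
#' @export
autoplot.pattern_null <- function(object, ...) {
  ggplot(object$summary, aes(x = .data$statistic)) +
    geom_linerange(aes(ymin = .data$null_min, ymax = .data$null_max),
      linewidth = 3, colour = "grey70"
    ) +
    geom_point(aes(y = .data$observed), colour = "firebrick", size = 2) +
    facet_wrap(~ .data$statistic, scales = "free") +
    labs(y = "value (grey = null range, red = observed)", x = NULL) +
    theme_minimal()
}
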