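#' Code transcripts as temporal patterns over {u, d, 0}
#'
#' Each adjacent-interval result contributes one character: `u` when the
#' transcript is significantly up (BH-adjusted p below `alpha`, positive
#' log2 fold change), `d` when significantly down, `0` otherwise.
#' Transcripts coded all-`0` are not differentially expressed anywhere and
#' are excluded from the DET universe; transcripts missing any interval
#' result are excluded with a message.
#'
#' @param de_results tibble from [adjacent_contrasts()]
#' @param alpha significance level on the adjusted p-value (default 0.05)
#' @return tibble: `transcript_id`, `code` (one row per DET)
#' @export
encode_patterns <- function(de_results, alpha = 0.05) {
  intervals <- unique(de_results$contrast)
  st <- de_results %>%
    mutate(state = dplyr::case_when(
      is.na(.data$padj) ~ NA_character_,
      .data$padj < alpha & .data$log2fc > 0 ~ "u",
      .data$padj < alpha & .data$log2fc < 0 ~ "d",
      TRUE ~ "0"
    )) %>%
    select("transcript_id", "contrast", "state") %>%
    pivot_wider(names_from = "contrast", values_from = "state")
  mat <- as.matrix(st[, intervals, drop = FALSE])
  incomplete <- rowSums(is.na(mat)) > 0
  if (any(incomplete)) {
    inform(sprintf(
      "%d transcript(s) excluded: missing interval results", sum(incomplete)
    ))
  }
  codes <- apply(mat[!incomplete, , drop = FALSE], 1, paste, collapse = "")
  out <- tibble(
    transcript_id = st$transcript_id[!incomplete],
    code = codes
  )
  out[out$code != strrep("0", length(intervals)), ]
}

#' Tabulate observed pattern codes
#'
#' Frequency table of codes sorted by descending transcript count
#' (lexicographic code order breaks ties), plus the theoretical pattern
#' count `3^k` for `k` intervals.
#'
#' @param codes character vector of pattern codes, or the tibble from
#'   [encode_patterns()]
#' @return list with `table` (tibble: `code`, `n_transcripts`, `rank`) and
#'   `theoretical_n` (`3^k`)
#' @export
enumerate_patterns <- function(codes) {
  if (is.data.frame(codes)) codes <- codes$code
  k <- if (length(codes)) nchar(codes[1]) else 5L
  tab <- tibble(code = codes) %>%
    count(.data$code, name = "n_transcripts") %>%
    arrange(desc(.data$n_transcripts), .data$code) %>%
    mutate(rank = row_number())
  list(table = tab, theoretical_n = 3L^k)
}

#' Share of DETs captured by the k most populous patterns
#'
#' @param pattern_table the `$table` tibble from [enumerate_patterns()]
#' @param k how many top patterns to pool (default 20)
#' @return real in `[0, 1]`; 1 when `k` exceeds the number of patterns
#' @export
top_mass <- function(pattern_table, k = 20) {
  stopifnot(k >= 1)
  total <- sum(pattern_table$n_transcripts)
  if (total == 0) {
    return(NaN)
  }
  sum(head(
    pattern_table$n_transcripts[order(-pattern_table$n_transcripts)], k
  )) / total
}

#' Monotonicity and reversal-direction statistics of pattern codes
#'
#' A code is monotone when its non-`0` characters are all the same
#' direction. Among reversers (codes containing both `u` and `d`),
#' down-then-up means the first non-`0` character is `d`.
#'
#' @param codes character vector of codes or [encode_patterns()] output
#' @return tibble with `monotone_fraction`,
#'   `down_then_up_fraction_among_reversers`, `n_det`, `n_reversers`
#' @export
direction_stats <- function(codes) {
  if (is.data.frame(codes)) codes <- codes$code
  dirs <- lapply(strsplit(codes, ""), function(ch) ch[ch != "0"])
  has_u <- vapply(dirs, function(d) "u" %in% d, logical(1))
  has_d <- vapply(dirs, function(d) "d" %in% d, logical(1))
  monotone <- xor(has_u, has_d)
  rev <- has_u & has_d
  dtu <- vapply(dirs[rev], function(d) d[1] == "d", logical(1))
  tibble(
    monotone_fraction = mean(monotone),
    down_then_up_fraction_among_reversers =
      if (any(rev)) mean(dtu) else NaN,
    n_det = length(codes), n_reversers = sum(rev)
  )
}

#' Mirror a pattern code (swap up and down)
#'
#' @param code character vector of codes
#' @return codes with `u` and `d` swapped per character
#' @export
mirror_code <- function(code) {
  chartr("ud", "du", code)
}

#' Pair symmetric patterns and compare their transcript counts
#'
#' For every observed code whose first non-`0` character is `u`, reports
#' the mirrored (u-d swapped) code and the transcript counts of both; a
#' similar count in the two members of a pair is the symmetry signature of
#' the global pattern distribution.
#'
#' @param pattern_table `$table` from [enumerate_patterns()]
#' @return tibble: `code`, `mirror`, `n_up`, `n_down`
#' @export
symmetry_pairs <- function(pattern_table) {
  lead_dir <- vapply(strsplit(pattern_table$code, ""), function(ch) {
    nz <- ch[ch != "0"]
    if (length(nz)) nz[1] else "0"
  }, character(1))
  up <- pattern_table[lead_dir == "u", c("code", "n_transcripts")]
  lookup <- setNames(pattern_table$n_transcripts, pattern_table$code)
  tibble(
    code = up$code,
    mirror = mirror_code(up$code),
    n_up = up$n_transcripts,
    n_down = as.integer(unname(lookup[mirror_code(up$code)])) %>%
      tidyr::replace_na(0L)
  )
}

pattern_summary_stats <- function(codes, top_k) {
  en <- enumerate_patterns(codes)
  ds <- direction_stats(codes)
  c(
    n_distinct_patterns = nrow(en$table),
    top_k_mass = top_mass(en$table, top_k),
    monotone_fraction = ds$monotone_fraction,
    down_then_up_fraction = ds$down_then_up_fraction_among_reversers
  )
}

#' Permutation null of inter-interval independence
#'
#' Simulates the null that expression change in one time interval is
#' independent of change in the others: each permutation shuffles every
#' interval's character column independently across transcripts, which
#' preserves each interval's (u, d, 0) marginal counts while destroying
#' inter-interval dependence. Codes that become all-`0` are dropped from
#' that permutation's DET universe, exactly as observed all-`0` codes are.
#'
#' @param codes character vector of observed DET codes
#' @param n_perm number of permutations (default 1000)
#' @param top_k top-pattern pool size for the mass statistic (default 20)
#' @param seed integer seed
#' @return list of class `pattern_null` with `observed` (named statistics),
#'   `null` (tibble, one row per permutation) and `summary` (tibble with
#'   null min/mean/max and the empirical two-sided p per statistic)
#' @export
permutation_null <- function(codes, n_perm = 1000, top_k = 20, seed = 1L) {
  if (is.data.frame(codes)) codes <- codes$code
  stopifnot(n_perm >= 1)
  set.seed(seed)
  mat <- do.call(rbind, strsplit(codes, ""))
  observed <- pattern_summary_stats(codes, top_k)
  null <- purrr::map(seq_len(n_perm), function(b) {
    perm <- apply(mat, 2, sample)
    pc <- apply(perm, 1, paste, collapse = "")
    pc <- pc[pc != strrep("0", ncol(mat))]
    as_tibble(as.list(pattern_summary_stats(pc, top_k)))
  }) %>% bind_rows()
  summary <- tibble(
    statistic = names(observed),
    observed = unname(observed),
    null_min = vapply(null, min, numeric(1), na.rm = TRUE),
    null_mean = vapply(null, mean, numeric(1), na.rm = TRUE),
    null_max = vapply(null, max, numeric(1), na.rm = TRUE),
    p_emp = vapply(seq_along(observed), function(i) {
      x <- null[[i]]
      lo <- (1 + sum(x <= observed[i], na.rm = TRUE)) / (n_perm + 1)
      hi <- (1 + sum(x >= observed[i], na.rm = TRUE)) / (n_perm + 1)
      min(1, 2 * min(lo, hi))
    }, numeric(1))
  )
  structure(
    list(observed = observed, null = null, summary = summary),
    class = "pattern_null"
  )
}

#' @export
print.pattern_null <- function(x, ...) {
  cat("Permutation null of inter-interval independence\n")
  print(x$summary)
  invisible(x)
}
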