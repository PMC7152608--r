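#' Drop samples with too few mapped reads
#'
#' Retains samples whose total counts (column sums) meet `min_mapped`,
#' preserving column order. The companion metadata, if given, is subset to
#' the retained samples.
#'
#' @param counts transcripts x samples non-negative integer matrix
#' @param min_mapped minimum column sum to retain a sample (default 5e5,
#'   the half-million mapped-read threshold)
#' @param metadata optional sample metadata tibble with a `sample_id` column
#' @return the filtered matrix, or a list `(counts, metadata)` when
#'   metadata is supplied
#' @export
filter_samples <- function(counts, min_mapped = 5e5, metadata = NULL) {
  stopifnot(min_mapped >= 0)
  keep <- colSums(counts) >= min_mapped
  if (!any(keep)) {
    abort(sprintf("no sample reaches min_mapped = %g mapped reads", min_mapped))
  }
  out <- counts[, keep, drop = FALSE]
  if (is.null(metadata)) {
    return(out)
  }
  list(counts = out, metadata = metadata[metadata$sample_id %in% colnames(out), ])
}

#' Drop weakly expressed transcripts
#'
#' Default reading: retain transcripts with at least `min_count` reads in
#' at least `min_samples` samples (standard expression filtering). The
#' complementary literal reading — remove transcripts that have fewer than
#' `min_count` reads in `min_samples` or more samples — is available with
#' `literal = TRUE`.
#'
#' @param counts transcripts x samples matrix
#' @param min_count count threshold (default 2)
#' @param min_samples sample threshold (default 10)
#' @param literal use the complementary removal-rule reading
#' @return the filtered matrix
#' @export
filter_transcripts <- function(counts, min_count = 2, min_samples = 10,
                               literal = FALSE) {
  stopifnot(min_count >= 0, min_samples >= 1)
  if (min_samples > ncol(counts)) {
    abort("`min_samples` exceeds the number of samples")
  }
  keep <- if (literal) {
    rowSums(counts < min_count) < min_samples
  } else {
    rowSums(counts >= min_count) >= min_samples
  }
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' The per-sample sequencing-depth normaliser: each sample's size factor is
#' the median, over transcripts with a positive geometric mean across
#' samples, of the ratio of the sample's count to that geometric mean.
#'
#' @param counts transcripts x samples matrix
#' @return named positive numeric vector of size factors
#' @export
size_factors <- function(counts) {
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) {
    abort(paste(
      "no transcript has positive counts in every sample;",
      "consider a pseudo-reference fallback (e.g. add a pseudocount)"
    ))
  }
  gm <- exp(log_gm[use])
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnt) {
    median(cnt / gm)
  })
  setNames(sf, colnames(counts))
}

#' Variance-stabilising transform of normalised counts
#'
#' Shifted log2 of size-factor-normalised counts:
#' `value = log2(count / sf + 1)`. Monotone in counts at fixed size factor
#' and invariant to jointly rescaling counts and size factors; downstream
#' stages use the matrix only through variance ranking, linear models and
#' PCA, for which the shifted log is an accepted stabiliser.
#'
#' @param counts transcripts x samples matrix
#' @param sf per-sample positive size factors (default [size_factors()])
#' @return transcripts x samples numeric matrix on the log2-like scale,
#'   with `size_factors` attached as an attribute
#' @export
variance_stabilize <- function(counts, sf = size_factors(counts)) {
  stopifnot(all(sf > 0), length(sf) == ncol(counts))
  v <- log2(t(t(counts) / sf) + 1)
  attr(v, "size_factors") <- sf
  v
}

#' PCA of samples on the most variable transcripts
#'
#' Centres (without scaling) the `top_n` highest-variance transcripts and
#' runs PCA with samples as observations, the standard global QC view of
#' an expression matrix.
#'
#' @param vst transcripts x samples matrix ([variance_stabilize()] output)
#' @param top_n number of top-variance transcripts to use (default 500)
#' @return list with `scores` (tibble: `sample_id`, `PC1`, `PC2`, ...) and
#'   `var_explained` (non-increasing fractions summing to <= 1)
#' @export
sample_pca <- function(vst, top_n = 500) {
  if (ncol(vst) < 2) abort("need at least 2 samples for a PCA")
  top_n <- min(top_n, nrow(vst))
  rv <- apply(vst, 1, var)
  sel <- order(rv, decreasing = TRUE)[seq_len(top_n)]
  pc <- prcomp(t(vst[sel, , drop = FALSE]), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x, .name_repair = "minimal")
  scores <- bind_cols(tibble(sample_id = colnames(vst)), scores)
  list(scores = scores, var_explained = ve)
}

#' Split samples into a major and an outlier cluster on PC1-PC2
#'
#' Two-means on the first two principal components with deterministic
#' initial centres (the two samples farthest apart). A split is accepted
#' only when it looks like two genuinely distinct clouds: the minor group
#' must hold at least `min_minor_fraction` of the samples and the two
#' centres must be separated by more than `min_separation` pooled
#' within-cluster standard deviations (2-means cuts even a unimodal cloud
#' roughly in half, so balance alone cannot certify a split). Otherwise
#' the data are declared unimodal and the minor set is returned empty.
#' Downstream analyses use the major set.
#'
#' @param scores tibble from [sample_pca()] (`$scores`)
#' @param min_minor_fraction smallest minor-cluster share that counts as a
#'   real split (default 0.05)
#' @param min_separation minimum centre distance in pooled within-cluster
#'   standard deviations (default 3)
#' @return list with `major` and `minor` character vectors of sample IDs
#' @export
split_outlier_cluster <- function(scores, min_minor_fraction = 0.05,
                                  min_separation = 3) {
  if (nrow(scores) < 4) abort("need at least 4 samples to look for a split")
  X <- as.matrix(scores[, c("PC1", "PC2")])
  d <- as.matrix(dist(X))
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  km <- suppressWarnings(
    kmeans(X, centers = X[c(far[1], far[2]), , drop = FALSE], iter.max = 100)
  )
  ids <- split(scores$sample_id, km$cluster)
  sizes <- lengths(ids)
  major_i <- if (sizes[1] != sizes[2]) {
    which.max(sizes)
  } else {
    # tie: the group holding the lexicographically first sample is major
    which(vapply(ids, function(s) min(scores$sample_id) %in% s, logical(1)))
  }
  major <- ids[[major_i]]
  minor <- ids[[setdiff(1:2, major_i)]]
  within_sd <- sqrt(km$tot.withinss / max(1, nrow(X) - 2) / ncol(X))
  separation <- sqrt(sum((km$centers[1, ] - km$centers[2, ])^2)) /
    max(within_sd, .Machine$double.eps)
  if (length(minor) < min_minor_fraction * nrow(scores) ||
    separation < min_separation) {
    return(list(major = scores$sample_id, minor = character()))
  }
  list(major = sort(major), minor = sort(minor))
}

#' Run the full count-matrix QC path
#'
#' Samples first (mapped-read threshold), then transcripts, then
#' size-factor normalisation, variance stabilisation, top-variance PCA and
#' outlier-cluster removal; returns the analysis-ready matrix restricted to
#' the major cluster.
#'
#' @param counts transcripts x samples integer matrix
#' @param metadata sample metadata tibble (`sample_id` column required)
#' @param min_mapped,min_count,min_samples,top_n,min_minor_fraction,min_separation
#'   thresholds, see the individual steps
#' @return list with `vst` (major-cluster matrix), `metadata`,
#'   `size_factors`, `pca` and the dropped `minor` sample IDs
#' @export
qc_pipeline <- function(counts, metadata, min_mapped = 5e5, min_count = 2,
                        min_samples = 10, top_n = 500,
                        min_minor_fraction = 0.05, min_separation = 3) {
  fs <- filter_samples(counts, min_mapped, metadata)
  cm <- filter_transcripts(fs$counts, min_count, min_samples)
  sf <- size_factors(cm)
  vst <- variance_stabilize(cm, sf)
  pca <- sample_pca(vst, top_n)
  split <- split_outlier_cluster(pca$scores, min_minor_fraction, min_separation)
  keep <- colnames(vst) %in% split$major
  list(
    vst = vst[, keep, drop = FALSE],
    counts = cm[, keep, drop = FALSE],
    metadata = fs$metadata[fs$metadata$sample_id %in% split$major, ],
    size_factors = sf[keep], pca = pca, minor = split$minor
  )
}
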