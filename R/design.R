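#' Describe the sampling design of a seed-development time course
#'
#' The study layout is a diversity panel sampled repeatedly through grain
#' fill: `n_lines` genotypes crossed with an ordered set of sampling times
#' (days after anthesis, DAA), grown at `n_locations` sites with `n_reps`
#' replicates per site. The default reproduces a 22-line panel sampled at
#' 8, 13, 18, 23, 28 and 33 DAA in two locations with two replicates, i.e.
#' 528 potential samples, of which a fraction may be missing in the field.
#'
#' @param n_lines number of genotypes (lines) in the panel
#' @param time_points strictly increasing integer vector of sampling times
#'   in days after anthesis
#' @param n_locations number of growing sites
#' @param n_reps replicates per site
#' @param missing_fraction fraction of potential samples lost (in `[0, 1)`);
#'   the default mirrors losing 109 of 528 field samples
#' @return an object of class `study_design`: a list with the design
#'   parameters and `$samples`, a tibble of all potential samples with
#'   columns `sample_id`, `line`, `location`, `replicate`, `daa`
#' @examples
#' d <- study_design()
#' potential_samples(d) # 528
#' @export
study_design <- function(n_lines = 22,
                         time_points = c(8L, 13L, 18L, 23L, 28L, 33L),
                         n_locations = 2,
                         n_reps = 2,
                         missing_fraction = 109 / 528) {
  stopifnot(n_lines >= 1, n_locations >= 1, n_reps >= 1)
  if (any(diff(time_points) <= 0)) {
    abort("`time_points` must be strictly increasing")
  }
  if (missing_fraction < 0 || missing_fraction >= 1) {
    abort("`missing_fraction` must be in [0, 1)")
  }
  lines <- sprintf("L%02d", seq_len(n_lines))
  locs <- sprintf("loc%d", seq_len(n_locations))
  reps <- sprintf("r%d", seq_len(n_reps))
  grid <- expand.grid(
    daa = as.integer(time_points), replicate = reps,
    location = locs, line = lines,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  samples <- as_tibble(grid[, c("line", "location", "replicate", "daa")])
  samples$sample_id <- sprintf(
    "%s_%s_%s_d%02d", samples$line, samples$location,
    samples$replicate, samples$daa
  )
  samples <- samples[, c("sample_id", "line", "location", "replicate", "daa")]
  structure(
    list(
      n_lines = n_lines, time_points = as.integer(time_points),
      n_locations = n_locations, n_reps = n_reps,
      missing_fraction = missing_fraction,
      lines = lines, locations = locs, replicates = reps,
      samples = samples
    ),
    class = "study_design"
  )
}

#' Number of potential samples implied by a design
#'
#' @param design a [study_design()] object
#' @return integer: lines x times x locations x replicates
#' @export
potential_samples <- function(design) {
  stopifnot(inherits(design, "study_design"))
  as.integer(design$n_lines * length(design$time_points) *
    design$n_locations * design$n_reps)
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "study_design: %d lines x %d times (%s DAA) x %d locations x %d reps = %d potential samples (missing fraction %.3f)\n",
    x$n_lines, length(x$time_points), paste(x$time_points, collapse = ","),
    x$n_locations, x$n_reps, potential_samples(x), x$missing_fraction
  ))
  invisible(x)
}

#' Labels of the adjacent time intervals of a design
#'
#' @param design a [study_design()] object
#' @return character vector like `"8-13"`, one per adjacent pair of times
#' @export
interval_labels <- function(design) {
  tp <- design$time_points
  paste0(tp[-length(tp)], "-", tp[-1])
}
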