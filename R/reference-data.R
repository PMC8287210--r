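# Packaged reference tables from a published 3T g-ratio study of 25
# healthy adults (21 high-SNR white-matter ROIs, two sessions). They are
# inputs to the internal-consistency checks: the dynamic ranges and the
# relative bias/error columns can be recomputed from the printed
# absolute values with this package's own statistics.

#' Published per-ROI reference statistics
#'
#' Group-averaged mean and SD of the reference-corrected g-ratio, axon
#' volume fraction and myelin volume fraction in 21 high-SNR
#' white-matter ROIs, as published for a 25-subject 3T cohort.
#'
#' @return data.frame with columns `name`, `acronym`, `g_mean`, `g_sd`,
#'   `avf_mean`, `avf_sd`, `mvf_mean`, `mvf_sd`.
#' @export
reference_roi_stats <- function() {
  utils::read.delim(system.file("extdata", "roi_reference_stats.tsv",
                                package = "gratiomap"),
                    stringsAsFactors = FALSE)
}

#' Published agreement statistics
#'
#' Bland-Altman bias and error (absolute and as a percentage of the
#' metric's dynamic range) for the test-retest comparison and for the
#' between-method comparisons (reference correction vs. none, reference
#' vs. data-driven), as published. The `whole_wm` rows use a dynamic
#' range that was not published, so only the `high_snr` rows can be
#' checked against recomputed relatives. The relative bias of the
#' g-ratio `DATA_DRIVEN` row is a documented half-ulp rounding exception
#' (the printed absolute bias was rounded before the relative column was
#' formed).
#'
#' @return data.frame with columns `comparison`, `metric`, `test`,
#'   `roi_set`, `bias`, `error`, `rel_bias_pct`, `rel_error_pct`.
#' @export
reference_agreement <- function() {
  utils::read.delim(system.file("extdata", "agreement_reference.tsv",
                                package = "gratiomap"),
                    stringsAsFactors = FALSE)
}

#' Published dynamic ranges of the reference metrics
#'
#' Dynamic range (max minus min of the 21 per-ROI group means) of the
#' reference-corrected g-ratio, AVF and MVF. These equal
#' [dynamic_range()] applied to the columns of
#' [reference_roi_stats()].
#'
#' @return named numeric vector with elements `g`, `avf`, `mvf`.
#' @export
reference_dynamic_range <- function() {
  c(g = 0.046, avf = 0.076, mvf = 0.037)
}
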