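# ROI aggregation and Bland-Altman bias/error machinery, with bias and
# error expressed as percentages of the reference metric's dynamic range
# across ROIs.

#' Per-ROI means of a map
#'
#' Mean of the map over the defined (non-`NaN`) voxels of each requested
#' ROI, optionally intersected with a restriction mask.
#'
#' @param map a [volume_map].
#' @param atlas a [label_atlas].
#' @param roi_ids integer ROI ids; default all nonzero labels.
#' @param restrict_mask optional binary [volume_map]; ROI voxels outside
#'   it are dropped.
#' @return data.frame with columns `roi_id`, `mean`.
#' @export
roi_means <- function(map, atlas, roi_ids = NULL, restrict_mask = NULL) {
  stopifnot(inherits(map, "volume_map"), inherits(atlas, "label_atlas"))
  if (!identical(dim(map$values), dim(atlas$labels)))
    stop("map and atlas grids differ")
  lab <- as.vector(atlas$labels)
  vals <- as.vector(map$values)
  keep <- rep(TRUE, length(lab))
  if (!is.null(restrict_mask))
    keep <- as.vector(.as_logical_mask(restrict_mask))
  if (is.null(roi_ids)) roi_ids <- sort(unique(lab[lab != 0L]))
  means <- vapply(roi_ids, function(i) {
    v <- vals[lab == i & keep]
    v <- v[is.finite(v)]
    if (length(v) == 0L)
      stop("ROI ", i, " is empty after restriction")
    mean(v)
  }, numeric(1))
  data.frame(roi_id = roi_ids, mean = means)
}

#' Build a ROI statistics table over subjects and sessions
#'
#' One row per (ROI, subject, session): the ROI mean of that
#' subject/session's map.
#'
#' @param maps nested list: `maps[[subject]][[session]]` is a
#'   [volume_map].
#' @param atlas a [label_atlas].
#' @param roi_ids ROI ids to aggregate.
#' @param restrict_mask optional binary [volume_map].
#' @param metric,variant optional tags stored as attributes.
#' @return data.frame of class `roi_stats_table` with columns `roi_id`,
#'   `subject`, `session`, `mean`.
#' @export
roi_stats_table <- function(maps, atlas, roi_ids = NULL,
                            restrict_mask = NULL, metric = NULL,
                            variant = NULL) {
  rows <- list()
  for (s in seq_along(maps)) {
    for (ses in seq_along(maps[[s]])) {
      rm <- roi_means(maps[[s]][[ses]], atlas, roi_ids, restrict_mask)
      rm$subject <- s
      rm$session <- ses
      rows[[length(rows) + 1L]] <- rm
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("roi_id", "subject", "session", "mean")]
  attr(out, "metric") <- metric
  attr(out, "variant") <- variant
  class(out) <- c("roi_stats_table", "data.frame")
  out
}

#' Group summary of a ROI statistics table
#'
#' Per-ROI group mean and SD across subjects. With `by_session = FALSE`
#' (the default) the two sessions of each subject are first averaged, so
#' the SD is an across-subject SD; with `by_session = TRUE` summaries are
#' returned per session (for test-retest analysis).
#'
#' @param stats a [roi_stats_table()].
#' @param by_session keep sessions separate.
#' @return data.frame with columns `roi_id`, (`session`,) `mean`, `sd`,
#'   `n`.
#' @export
roi_group_summary <- function(stats, by_session = FALSE) {
  df <- as.data.frame(stats)
  if (by_session) {
    out <- do.call(rbind, lapply(split(df, df[c("roi_id", "session")]),
      function(d) data.frame(roi_id = d$roi_id[1], session = d$session[1],
                             mean = mean(d$mean), sd = stats::sd(d$mean),
                             n = nrow(d))))
  } else {
    per_subj <- stats::aggregate(mean ~ roi_id + subject, data = df,
                                 FUN = mean)
    out <- do.call(rbind, lapply(split(per_subj, per_subj$roi_id),
      function(d) data.frame(roi_id = d$roi_id[1], mean = mean(d$mean),
                             sd = stats::sd(d$mean), n = nrow(d))))
  }
  rownames(out) <- NULL
  out[order(out$roi_id), , drop = FALSE]
}

#' Dynamic range of per-ROI group means
#'
#' `max - min` of the per-ROI group means: the span of meaningful signal
#' variation used to normalize Bland-Altman bias and error.
#'
#' @param group_means numeric vector of per-ROI group means (>= 2).
#' @return scalar dynamic range.
#' @export
dynamic_range <- function(group_means) {
  group_means <- group_means[is.finite(group_means)]
  if (length(group_means) < 2L)
    stop("dynamic range needs at least 2 ROI means")
  max(group_means) - min(group_means)
}

#' Bland-Altman agreement between paired per-ROI values
#'
#' For paired reference/test values over the same ROIs (same order),
#' computes per-ROI differences \eqn{\delta_i = ref_i - test_i} and pair
#' means, the bias \eqn{\bar\delta = \frac{1}{N}\sum \delta_i}, the error
#' \eqn{\epsilon = 1.96 \cdot SD(\delta_i)} (sample SD, N-1 denominator),
#' and, when a dynamic range is supplied, the relative bias and error
#' \eqn{100 \cdot \{\bar\delta, \epsilon\}/\Delta_{DR}}.
#'
#' @param reference,test numeric vectors of equal length >= 2, same ROI
#'   order.
#' @param dr dynamic range of the reference metric (> 0), or `NULL` to
#'   skip relative quantities.
#' @return A list of class `agreement_result`: `delta`, `pair_mean`,
#'   `bias`, `error`, `dr`, `bias_dr_pct`, `error_dr_pct`, `n`.
#' @export
bland_altman <- function(reference, test, dr = NULL) {
  if (length(reference) != length(test))
    stop("reference and test lengths differ")
  if (length(reference) < 2L) stop("need at least 2 paired values")
  delta <- reference - test
  bias <- mean(delta)
  error <- 1.96 * stats::sd(delta)
  rel_b <- rel_e <- NA_real_
  if (!is.null(dr)) {
    if (!is.finite(dr) || dr <= 0)
      stop("'dr' must be positive for relative quantities")
    rel_b <- 100 * bias / dr
    rel_e <- 100 * error / dr
  }
  structure(list(delta = delta, pair_mean = (reference + test) / 2,
                 bias = bias, error = error,
                 dr = if (is.null(dr)) NA_real_ else dr,
                 bias_dr_pct = rel_b, error_dr_pct = rel_e,
                 n = length(delta)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> n = %d\n", x$n))
  cat(sprintf("  bias  = %+.4g   error (1.96*SD) = %.4g\n", x$bias, x$error))
  if (is.finite(x$dr))
    cat(sprintf("  vs dynamic range %.4g: bias %+.2f%%, error %.2f%%\n",
                x$dr, x$bias_dr_pct, x$error_dr_pct))
  invisible(x)
}

#' Test-retest agreement between two sessions
#'
#' Bland-Altman comparison of per-ROI group means of session 1
#' (reference) against session 2 (test). Group means are across-subject
#' means within each session.
#'
#' @param session1,session2 [roi_stats_table()]s containing one session
#'   each (or tables filtered to one session).
#' @param dr dynamic range used for the relative quantities.
#' @return An `agreement_result`.
#' @export
test_retest <- function(session1, session2, dr = NULL) {
  g1 <- stats::aggregate(mean ~ roi_id, data = as.data.frame(session1),
                         FUN = mean)
  g2 <- stats::aggregate(mean ~ roi_id, data = as.data.frame(session2),
                         FUN = mean)
  if (!identical(sort(g1$roi_id), sort(g2$roi_id)))
    stop("the two sessions cover different ROI sets")
  g1 <- g1[order(g1$roi_id), ]
  g2 <- g2[order(g2$roi_id), ]
  res <- bland_altman(g1$mean, g2$mean, dr)
  res$roi_id <- g1$roi_id
  res
}
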