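# End-to-end orchestration: phantom generation, the three correction
# variants, calibration, map computation, masking, ROI statistics,
# agreement analyses and CoV comparison, mirroring the study design
# (measured-field correction as reference vs. no correction vs.
# data-driven correction).

#' Analysis configuration
#'
#' Bundles every tunable of [run_full_analysis()] with its default. All
#' method constants surface here: the correction constant `C`, the
#' histology assumptions (`unmyelinated_frac`, `evf_frac`), the SNR/WM
#' mask settings, and the smoothing FWHM.
#'
#' @param phantom a [phantom_config()] describing the synthetic dataset.
#' @param C transmit-correction constant (default 0.4).
#' @param mvf_hist histological myelin volume fraction anchoring the
#'   calibration; `NULL` (default) uses the phantom's true MVF inside
#'   the calibration region, a [fiber_table] computes it via
#'   [mvf_from_histology()], a scalar is used as-is.
#' @param unmyelinated_frac,evf_frac histology assumptions passed to
#'   [mvf_from_histology()] when `mvf_hist` is a fiber table.
#' @param snr an [snr_mask_config()].
#' @param fwhm_mm smoothing FWHM for the CoV analysis (default 6 mm).
#' @param clip clamp MVF into `[0, 1]` before forming AVF and g
#'   (default `TRUE`: with noisy MTsat, non-tissue voxels can otherwise
#'   go negative and make the g-ratio undefined).
#' @param do_cov run the CoV stage (default `TRUE`).
#' @param out_dir optional directory; when set, all result tables are
#'   written there as TSV.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(phantom = phantom_config(), C = 0.4,
                            mvf_hist = NULL, unmyelinated_frac = 0.43,
                            evf_frac = 0.25, snr = snr_mask_config(),
                            fwhm_mm = 6, clip = TRUE, do_cov = TRUE,
                            out_dir = NULL) {
  stopifnot(inherits(phantom, "phantom_config"), C >= 0, C < 1,
            inherits(snr, "snr_mask_config"), fwhm_mm >= 0)
  structure(list(phantom = phantom, C = C, mvf_hist = mvf_hist,
                 unmyelinated_frac = unmyelinated_frac,
                 evf_frac = evf_frac, snr = snr, fwhm_mm = fwhm_mm,
                 clip = clip, do_cov = do_cov, out_dir = out_dir),
            class = "analysis_config")
}

#' Write an analysis configuration to YAML
#'
#' Serializes every scalar/tabular field. The phantom's
#' `ceiling_prob_fn` is a function and is stored as `"default"` when it
#' is the default; custom functions are not serializable and are noted
#' as such (reading restores the default).
#'
#' @param config an [analysis_config()].
#' @param path YAML output path.
#' @return `path`, invisibly.
#' @export
write_analysis_config <- function(config, path) {
  ph <- config$phantom
  ph_l <- list(grid_shape = ph$grid_shape, n_subjects = ph$n_subjects,
               n_sessions = ph$n_sessions,
               roi_layout = lapply(seq_len(nrow(ph$roi_layout)),
                                   function(i) as.list(ph$roi_layout[i, ])),
               mvf_true = as.list(ph$mvf_true),
               avf_true = as.list(ph$avf_true),
               alpha_true = ph$alpha_true, c_factor = ph$c_factor,
               b1_amplitude = ph$b1_amplitude,
               b1_poly_order = ph$b1_poly_order,
               un_error_amplitude = ph$un_error_amplitude,
               map_noise_sd = as.list(ph$map_noise_sd),
               nu_iso_range = ph$nu_iso_range,
               snr_high = ph$snr_high, snr_low = ph$snr_low,
               sigma_noise = ph$sigma_noise, n_b0 = ph$n_b0,
               wm_background_mvf = ph$wm_background_mvf,
               wm_background_avf = ph$wm_background_avf,
               seed = ph$seed)
  obj <- list(phantom = ph_l, C = config$C,
              mvf_hist = config$mvf_hist,
              unmyelinated_frac = config$unmyelinated_frac,
              evf_frac = config$evf_frac,
              snr = unclass(config$snr), fwhm_mm = config$fwhm_mm,
              clip = config$clip, do_cov = config$do_cov,
              out_dir = config$out_dir)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file written by [write_analysis_config()].
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  obj <- yaml::read_yaml(path)
  ph <- obj$phantom
  roi_layout <- do.call(rbind, lapply(ph$roi_layout, as.data.frame))
  cfg <- phantom_config(
    grid_shape = unlist(ph$grid_shape),
    n_subjects = ph$n_subjects, n_sessions = ph$n_sessions,
    roi_layout = roi_layout,
    mvf_true = unlist(ph$mvf_true), avf_true = unlist(ph$avf_true),
    alpha_true = ph$alpha_true, c_factor = ph$c_factor,
    b1_amplitude = ph$b1_amplitude, b1_poly_order = ph$b1_poly_order,
    un_error_amplitude = ph$un_error_amplitude,
    map_noise_sd = unlist(ph$map_noise_sd),
    nu_iso_range = unlist(ph$nu_iso_range),
    snr_high = ph$snr_high, snr_low = ph$snr_low,
    sigma_noise = ph$sigma_noise, n_b0 = ph$n_b0,
    wm_background_mvf = ph$wm_background_mvf,
    wm_background_avf = ph$wm_background_avf,
    seed = ph$seed)
  analysis_config(phantom = cfg, C = obj$C, mvf_hist = obj$mvf_hist,
                  unmyelinated_frac = obj$unmyelinated_frac,
                  evf_frac = obj$evf_frac,
                  snr = do.call(snr_mask_config,
                                lapply(obj$snr, unlist)),
                  fwhm_mm = obj$fwhm_mm, clip = obj$clip,
                  do_cov = obj$do_cov, out_dir = obj$out_dir)
}

.variant_tags <- c("REFERENCE_B1", "NONE", "DATA_DRIVEN")

# MTsat maps per variant: nested list variant -> subject -> session.
.variant_mtsat <- function(phantom, C) {
  lapply(stats::setNames(.variant_tags, .variant_tags), function(tag) {
    lapply(phantom$subjects, function(sub) {
      b1 <- switch(tag, REFERENCE_B1 = sub$b1_true,
                   DATA_DRIVEN = sub$b1_surrogate, NONE = NULL)
      lapply(sub$sessions, function(ses) {
        if (is.null(b1)) ses$mtsat_no else correct_mtsat(ses$mtsat_no, b1, C)
      })
    })
  })
}

#' Run the full phantom comparison analysis
#'
#' Reproduces the study's comparison design on a synthetic phantom:
#' \enumerate{
#'   \item generate the phantom (or accept a pre-generated one);
#'   \item build the three MTsat variants (reference-field corrected,
#'     uncorrected, data-driven corrected);
#'   \item calibrate one alpha per variant against the histology anchor
#'     in the calibration region (pooling all subjects and sessions);
#'   \item compute MVF/AVF/g maps per subject, session and variant;
#'   \item build the group WM mask, optimize the SNR threshold against
#'     the nu_icvf ceiling artifact, build the high-SNR mask, and select
#'     whole-WM and high-SNR ROI sets;
#'   \item aggregate per-ROI statistics, dynamic ranges, test-retest
#'     agreement (reference variant, session 1 vs 2), and between-method
#'     agreement (reference vs uncorrected and vs data-driven) for g,
#'     AVF and MVF on the high-SNR ROIs, plus MVF on whole-WM ROIs;
#'   \item optionally smooth (tissue-weighted) and compare CoV maps
#'     across variants.
#' }
#'
#' @param config an [analysis_config()].
#' @param phantom optional pre-generated `phantom_dataset`; default
#'   generates one from `config$phantom`.
#' @return A list of class `analysis_report`; see the elements
#'   `calibration`, `roi_summary`, `dynamic_range`, `retest`,
#'   `method_agreement`, `cov_agreement`, `snr_threshold`, `roi_sets`.
#' @export
run_full_analysis <- function(config = analysis_config(), phantom = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(phantom)) phantom <- generate_phantom(config$phantom)
  stopifnot(inherits(phantom, "phantom_dataset"))
  C <- config$C
  cfg_snr <- config$snr

  # --- variants and calibration ----------------------------------------
  mtsat <- .variant_mtsat(phantom, C)
  mvf_hist <- config$mvf_hist
  if (is.null(mvf_hist)) {
    mvf_hist <- masked_mean(phantom$truth$mvf, phantom$calib_mask)
  } else if (inherits(mvf_hist, "fiber_table")) {
    mvf_hist <- mvf_from_histology(mvf_hist, config$unmyelinated_frac,
                                   config$evf_frac)$mvf_hist
  }
  calib <- lapply(.variant_tags, function(tag) {
    flat <- unlist(mtsat[[tag]], recursive = FALSE)
    calibrate_alpha(mvf_hist, flat, phantom$calib_mask, variant_tag = tag)
  })
  names(calib) <- .variant_tags
  calib_tab <- data.frame(
    variant = .variant_tags,
    mvf_hist = mvf_hist,
    mean_mtsat = vapply(calib, function(x) x$mean_mtsat, numeric(1)),
    alpha = vapply(calib, function(x) x$alpha, numeric(1)))

  # --- g-ratio maps -----------------------------------------------------
  sets <- lapply(stats::setNames(.variant_tags, .variant_tags), function(tag)
    lapply(seq_along(phantom$subjects), function(s)
      lapply(seq_along(phantom$subjects[[s]]$sessions), function(ses) {
        maps <- phantom$subjects[[s]]$sessions[[ses]]
        compute_gratio_set(mtsat[[tag]][[s]][[ses]], calib[[tag]]$alpha,
                           maps$nu_icvf, maps$nu_iso,
                           clip = isTRUE(config$clip), variant_tag = tag)
      })))

  # --- masks and ROI sets ----------------------------------------------
  tpms <- lapply(phantom$subjects, function(s) phantom$wm_tpm)
  wm_mask <- group_wm_mask(tpms, cfg_snr$wm_group_threshold)
  snr_maps <- lapply(phantom$subjects, function(s)
    snr_map(s$sessions[[1]]$mean_b0, s$sessions[[1]]$sigma, cfg_snr$n_b0))
  icvf_maps <- lapply(phantom$subjects, function(s)
    s$sessions[[1]]$nu_icvf)
  search <- optimize_snr_threshold(snr_maps, icvf_maps, wm_mask, cfg_snr)
  hs_mask <- high_snr_mask(wm_mask, snr_maps[[1]], search$chosen_threshold)
  rois <- select_rois(phantom$atlas, wm_mask, hs_mask,
                      cfg_snr$roi_overlap_min)

  # --- ROI statistics ---------------------------------------------------
  metrics <- c("g", "avf", "mvf")
  metric_maps <- function(tag, metric)
    lapply(sets[[tag]], function(sub) lapply(sub, function(x) x[[metric]]))
  stats_hs <- list()
  for (tag in .variant_tags) for (met in metrics) {
    stats_hs[[paste(tag, met, sep = ".")]] <- roi_stats_table(
      metric_maps(tag, met), phantom$atlas, rois$high_snr_ids,
      restrict_mask = wm_mask, metric = met, variant = tag)
  }
  stats_wm_mvf <- lapply(stats::setNames(.variant_tags, .variant_tags),
    function(tag) roi_stats_table(metric_maps(tag, "mvf"), phantom$atlas,
                                  rois$whole_wm_ids,
                                  restrict_mask = wm_mask,
                                  metric = "mvf", variant = tag))

  ref_summ <- lapply(stats::setNames(metrics, metrics), function(met)
    roi_group_summary(stats_hs[[paste("REFERENCE_B1", met, sep = ".")]]))
  dr <- vapply(ref_summ, function(s) dynamic_range(s$mean), numeric(1))
  dr_wm_mvf <- dynamic_range(
    roi_group_summary(stats_wm_mvf$REFERENCE_B1)$mean)

  # --- test-retest (reference variant) ---------------------------------
  retest <- lapply(stats::setNames(metrics, metrics), function(met) {
    tab <- stats_hs[[paste("REFERENCE_B1", met, sep = ".")]]
    df <- as.data.frame(tab)
    if (max(df$session) < 2L) return(NULL)
    test_retest(df[df$session == 1L, ], df[df$session == 2L, ],
                dr = dr[[met]])
  })

  # --- between-method agreement ----------------------------------------
  method_rows <- list()
  method_results <- list()
  for (met in metrics) for (tag in c("NONE", "DATA_DRIVEN")) {
    ref <- roi_group_summary(stats_hs[[paste("REFERENCE_B1", met,
                                             sep = ".")]])
    tst <- roi_group_summary(stats_hs[[paste(tag, met, sep = ".")]])
    res <- bland_altman(ref$mean, tst$mean, dr = dr[[met]])
    key <- paste(met, tag, sep = ".")
    method_results[[key]] <- res
    method_rows[[key]] <- data.frame(
      metric = met, test_variant = tag, roi_set = "high_snr",
      bias = res$bias, error = res$error, dr = res$dr,
      bias_dr_pct = res$bias_dr_pct, error_dr_pct = res$error_dr_pct)
  }
  for (tag in c("NONE", "DATA_DRIVEN")) {
    ref <- roi_group_summary(stats_wm_mvf$REFERENCE_B1)
    tst <- roi_group_summary(stats_wm_mvf[[tag]])
    res <- bland_altman(ref$mean, tst$mean, dr = dr_wm_mvf)
    key <- paste("mvf_whole_wm", tag, sep = ".")
    method_results[[key]] <- res
    method_rows[[key]] <- data.frame(
      metric = "mvf", test_variant = tag, roi_set = "whole_wm",
      bias = res$bias, error = res$error, dr = res$dr,
      bias_dr_pct = res$bias_dr_pct, error_dr_pct = res$error_dr_pct)
  }
  method_tab <- do.call(rbind, method_rows)
  rownames(method_tab) <- NULL

  # --- CoV analysis -----------------------------------------------------
  cov_tab <- NULL
  cov_results <- NULL
  if (isTRUE(config$do_cov)) {
    covs <- list()
    for (tag in .variant_tags) for (met in metrics) {
      maps <- unlist(metric_maps(tag, met), recursive = FALSE)
      sm <- lapply(maps, tissue_weighted_smooth, tpm = phantom$wm_tpm,
                   fwhm_mm = config$fwhm_mm)
      covs[[paste(tag, met, sep = ".")]] <-
        cov_map(sm, mask = wm_mask, metric = met, variant = tag,
                fwhm_mm = config$fwhm_mm)
    }
    cov_rows <- list()
    cov_results <- list()
    for (met in metrics) for (tag in c("NONE", "DATA_DRIVEN")) {
      res <- cov_bland_altman(covs[[paste("REFERENCE_B1", met, sep = ".")]],
                              covs[[paste(tag, met, sep = ".")]])
      key <- paste(met, tag, sep = ".")
      cov_results[[key]] <- res
      cov_rows[[key]] <- data.frame(
        metric = met, test_variant = tag, bias = res$bias,
        error = res$error, normalizer = res$normalizer,
        bias_pct = res$bias_dr_pct, error_pct = res$error_dr_pct)
    }
    cov_tab <- do.call(rbind, cov_rows)
    rownames(cov_tab) <- NULL
  }

  report <- structure(list(
    calibration = calib_tab,
    alphas = calib,
    roi_summary = ref_summ,
    dynamic_range = c(dr, mvf_whole_wm = dr_wm_mvf),
    retest = retest,
    method_agreement = method_tab,
    method_results = method_results,
    cov_agreement = cov_tab,
    cov_results = cov_results,
    snr_threshold = search$chosen_threshold,
    snr_search = search$table,
    roi_sets = rois,
    stats = stats_hs,
    config = config),
    class = "analysis_report")

  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(report$calibration, "calibration.tsv")
  for (met in names(report$roi_summary))
    wt(report$roi_summary[[met]], sprintf("roi_summary_%s.tsv", met))
  wt(data.frame(metric = names(report$dynamic_range),
                dr = unname(report$dynamic_range)), "dynamic_range.tsv")
  retest_rows <- Filter(Negate(is.null), report$retest)
  if (length(retest_rows))
    wt(do.call(rbind, lapply(names(retest_rows), function(met) {
      r <- retest_rows[[met]]
      data.frame(metric = met, bias = r$bias, error = r$error, dr = r$dr,
                 bias_dr_pct = r$bias_dr_pct,
                 error_dr_pct = r$error_dr_pct)
    })), "retest.tsv")
  wt(report$method_agreement, "method_agreement.tsv")
  if (!is.null(report$cov_agreement))
    wt(report$cov_agreement, "cov_agreement.tsv")
  wt(report$snr_search, "snr_threshold_search.tsv")
  wt(report$roi_sets$table, "roi_selection.tsv")
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat("  alphas:",
      paste(sprintf("%s=%.4f", x$calibration$variant, x$calibration$alpha),
            collapse = ", "), "\n")
  cat(sprintf("  SNR threshold: %g; %d whole-WM / %d high-SNR ROI(s)\n",
              x$snr_threshold, length(x$roi_sets$whole_wm_ids),
              length(x$roi_sets$high_snr_ids)))
  cat(sprintf("  dynamic range: g=%.4g AVF=%.4g MVF=%.4g\n",
              x$dynamic_range[["g"]], x$dynamic_range[["avf"]],
              x$dynamic_range[["mvf"]]))
  cat("  method agreement (relative %):\n")
  ma <- x$method_agreement
  for (i in seq_len(nrow(ma)))
    cat(sprintf("    %-4s vs %-12s [%s]: bias %+7.2f%%  error %6.2f%%\n",
                ma$metric[i], ma$test_variant[i], ma$roi_set[i],
                ma$bias_dr_pct[i], ma$error_dr_pct[i]))
  invisible(x)
}
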