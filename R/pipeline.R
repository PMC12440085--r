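#' Pipeline configuration
#'
#' Central container for the analysis constants: the FDR level alpha
#' (default 0.05), the noise-band half-width (default 0.05 on the Fisher-z
#' scale), the edge-level test, the FDR family, the ribbon weight scheme,
#' and the master seed. Every run derives all randomness from the master
#' seed; no stage reads ambient entropy.
#'
#' @param alpha FDR level in (0, 1).
#' @param threshold Noise-band half-width, positive.
#' @param test `"student"` or `"welch"`.
#' @param fdr_family `"all_edges"` or `"per_lobe_pair"`.
#' @param weight_scheme `"one_minus_q"` or `"neglog10q"`.
#' @param seed Master seed (integer).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05, threshold = 0.05,
                            test = c("student", "welch"),
                            fdr_family = c("all_edges", "per_lobe_pair"),
                            weight_scheme = c("one_minus_q", "neglog10q"),
                            seed = 1L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be positive", call. = FALSE)
  }
  structure(list(alpha = alpha, threshold = threshold,
                 test = match.arg(test), fdr_family = match.arg(fdr_family),
                 weight_scheme = match.arg(weight_scheme),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Run manifest: enough to regenerate the outputs exactly (config + seed +
# input sizes + headline counts). Deliberately free of timestamps so a
# rerun with the same inputs is byte-identical.
write_manifest <- function(path, config, extra) {
  jsonlite::write_json(
    c(list(package = "fccontrast",
           version = as.character(utils::packageVersion("fccontrast")),
           alpha = config$alpha, threshold = config$threshold,
           test = config$test, fdr_family = config$fdr_family,
           weight_scheme = config$weight_scheme, seed = config$seed),
      extra),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Run the cross-sectional connectivity analysis end to end
#'
#' Computes per-subject FC matrices, contrasts condition A against
#' condition B edge-wise (convention: A = the case group, e.g. insulin
#' resistant; B = controls, so positive `delta_z` means stronger
#' connectivity in the cases), classifies the significant edges against the
#' noise band, and aggregates them into hemisphere, lobe and network pair
#' tables plus a hub table. When `out_dir` is given, all tables, chord
#' exports and a reproducibility manifest are written as TSV/JSON.
#'
#' @param ts_a,ts_b Lists of [bold_time_series()] (or precomputed
#'   `fc_matrix`) objects for conditions A and B.
#' @param meta A `region_meta` table.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List of class `fc_run`: `contrast`, `classified`, `tally`,
#'   `pairs` (per level), `hubs`, `manifest`.
#' @export
run_cross_sectional <- function(ts_a, ts_b, meta, config = pipeline_config(),
                                out_dir = NULL) {
  meta <- validate_region_meta(meta)
  as_fc <- function(x) if (inherits(x, "fc_matrix")) x else compute_fc_matrix(x)
  fc_a <- lapply(ts_a, as_fc)
  fc_b <- lapply(ts_b, as_fc)
  contrast <- edgewise_group_contrast(
    fc_a, fc_b, alpha = config$alpha, test = config$test,
    fdr_family = config$fdr_family, weight_scheme = config$weight_scheme,
    meta = meta, contrast_kind = "cross_sectional")
  classified <- classify_edges(contrast, meta, threshold = config$threshold,
                               kind = "cross_sectional")
  tally <- count_categories(classified$category,
                            levels = CROSS_SECTIONAL_CATEGORIES)
  pairs <- lapply(c(hemisphere = "hemisphere", lobe = "lobe",
                    network = "network"),
                  function(lv) aggregate_pairs(classified, meta, lv))
  hubs <- hub_table(classified, meta)
  manifest <- list(kind = "cross_sectional", n_a = length(fc_a),
                   n_b = length(fc_b), n_regions = nrow(meta),
                   n_edges = nrow(contrast),
                   n_significant = sum(contrast$significant))
  out <- structure(list(contrast = contrast, classified = classified,
                        tally = tally, pairs = pairs, hubs = hubs,
                        manifest = manifest),
                   class = "fc_run")
  if (!is.null(out_dir)) export_run(out, config, out_dir)
  out
}

#' Run the randomized pre/post treatment analysis end to end
#'
#' Placebo-subtracted longitudinal analysis: per-subject change matrices,
#' treated-minus-control edge-wise contrast on the change scores (positive
#' `delta_z` = greater connectivity change under treatment), and
#' longitudinal four-bar classification of the treatment-significant edges
#' within each arm using that arm's mean pre and post z values, followed by
#' the same aggregation layers as the cross-sectional run.
#'
#' @param treated_pre,treated_post,control_pre,control_post Lists of
#'   [bold_time_series()] or `fc_matrix` objects, paired by subject within
#'   arm.
#' @inheritParams run_cross_sectional
#' @return List of class `fc_run`: `contrast`, per-arm `classified_treated`
#'   / `classified_control` and tallies, `pairs`, `hubs`, `manifest`.
#' @export
run_rct <- function(treated_pre, treated_post, control_pre, control_post,
                    meta, config = pipeline_config(), out_dir = NULL) {
  meta <- validate_region_meta(meta)
  as_fc <- function(x) if (inherits(x, "fc_matrix")) x else compute_fc_matrix(x)
  fc <- lapply(list(tp = treated_pre, tq = treated_post,
                    cp = control_pre, cq = control_post),
               function(l) lapply(l, as_fc))
  contrast <- treatment_contrast(
    fc$tp, fc$tq, fc$cp, fc$cq, alpha = config$alpha, test = config$test,
    fdr_family = config$fdr_family, weight_scheme = config$weight_scheme,
    meta = meta)
  mean_edges <- function(fc_list) colMeans(stack_edges(fc_list))
  classified_treated <- classify_edges(
    contrast, meta, threshold = config$threshold, kind = "longitudinal",
    mean_pre = mean_edges(fc$tp), mean_post = mean_edges(fc$tq))
  classified_control <- classify_edges(
    contrast, meta, threshold = config$threshold, kind = "longitudinal",
    mean_pre = mean_edges(fc$cp), mean_post = mean_edges(fc$cq))
  tally_treated <- count_categories(classified_treated$category,
                                    levels = LONGITUDINAL_CATEGORIES)
  tally_control <- count_categories(classified_control$category,
                                    levels = LONGITUDINAL_CATEGORIES)
  pairs <- lapply(c(hemisphere = "hemisphere", lobe = "lobe",
                    network = "network"),
                  function(lv) aggregate_pairs(classified_treated, meta, lv))
  hubs <- hub_table(classified_treated, meta)
  manifest <- list(kind = "rct", n_per_arm = length(fc$tp),
                   n_regions = nrow(meta), n_edges = nrow(contrast),
                   n_significant = sum(contrast$significant))
  out <- structure(list(contrast = contrast,
                        classified_treated = classified_treated,
                        classified_control = classified_control,
                        tally_treated = tally_treated,
                        tally_control = tally_control,
                        pairs = pairs, hubs = hubs, manifest = manifest),
                   class = "fc_run")
  if (!is.null(out_dir)) export_run(out, config, out_dir)
  out
}

# Write every table of a run to out_dir, plus chord exports and manifest.
export_run <- function(run, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_contrast(run$contrast, file.path(out_dir, "contrast.tsv"))
  for (nm in intersect(c("classified", "classified_treated",
                         "classified_control"), names(run))) {
    write_tsv(run[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  for (nm in intersect(c("tally", "tally_treated", "tally_control"),
                       names(run))) {
    write_tsv(run[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  for (lv in names(run$pairs)) {
    export_chord_table(run$pairs[[lv]],
                       file.path(out_dir, paste0("pairs_", lv, ".tsv")))
  }
  write_tsv(run$hubs, file.path(out_dir, "hubs.tsv"))
  write_manifest(file.path(out_dir, "manifest.json"), config, run$manifest)
  invisible(out_dir)
}
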