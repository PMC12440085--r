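#' Standardized uptake value ratio
#'
#' Regional tracer uptake normalized to a reference region's uptake
#' (conventionally the pons for whole-brain FDG-PET), giving a
#' dimensionless, scanner-scale-free ratio.
#'
#' @param regional_uptake Positive regional uptake (vectorized).
#' @param reference_uptake Positive reference (pons) uptake.
#' @return `regional_uptake / reference_uptake`.
#' @export
suvr <- function(regional_uptake, reference_uptake) {
  if (any(!is.finite(reference_uptake)) || any(reference_uptake <= 0)) {
    stop("reference (pons) uptake must be positive", call. = FALSE)
  }
  if (any(!is.finite(regional_uptake)) || any(regional_uptake < 0)) {
    stop("regional uptake must be nonnegative and finite", call. = FALSE)
  }
  regional_uptake / reference_uptake
}

#' Normalize a regional volume to estimated intracranial volume
#'
#' Dividing by eTIV removes head-size (and hence most sex-based)
#' differences in brain volume before group comparison.
#'
#' @param volume Regional volume (mm^3), nonnegative.
#' @param etiv Estimated total intracranial volume (mm^3), positive.
#' @return Dimensionless `volume / etiv`.
#' @export
normalize_to_etiv <- function(volume, etiv) {
  if (any(!is.finite(etiv)) || any(etiv <= 0)) {
    stop("eTIV must be positive", call. = FALSE)
  }
  if (any(!is.finite(volume)) || any(volume < 0)) {
    stop("volume must be nonnegative and finite", call. = FALSE)
  }
  volume / etiv
}

# Reshape a long (subject_id, region, value) table to subjects x regions,
# erroring on missing subject-region combinations.
wide_by_region <- function(values) {
  stopifnot(all(c("subject_id", "region", "value") %in% names(values)))
  subjects <- unique(values$subject_id)
  regions <- unique(values$region)
  m <- matrix(NA_real_, length(subjects), length(regions),
              dimnames = list(subjects, regions))
  m[cbind(match(values$subject_id, subjects), match(values$region, regions))] <-
    values$value
  if (anyNA(m)) {
    gaps <- which(is.na(m), arr.ind = TRUE)
    gap_txt <- paste(subjects[gaps[, 1L]], regions[gaps[, 2L]],
                     sep = ":", collapse = ", ")
    stop("missing value(s) for subject:region ", gap_txt, call. = FALSE)
  }
  m
}

#' Per-region two-group comparison with within-lobe FDR
#'
#' Pooled-variance two-sided t-test of group A against group B for every
#' region, with Benjamini-Hochberg adjustment applied within each
#' anatomical division (lobe) independently.
#'
#' @param values Long data frame `subject_id`, `region`, `value` (one value
#'   per subject-region; normalized metrics such as SUVr or volume ratios).
#' @param group Named vector (names = subject ids) with two levels; the
#'   first sorted level unique value order defines condition A, or pass a
#'   factor whose first level is condition A.
#' @param lobe_map Named vector mapping region name to lobe label.
#' @param alpha FDR level.
#' @return Data frame: `region`, `lobe`, `mean_a`, `mean_b`, `delta`,
#'   `statistic`, `p`, `q`, `significant`.
#' @export
compare_groups_by_region <- function(values, group, lobe_map, alpha = 0.05) {
  m <- wide_by_region(values)
  g <- group[rownames(m)]
  if (anyNA(g)) {
    stop("missing group assignment for subject(s): ",
         paste(rownames(m)[is.na(g)], collapse = ", "), call. = FALSE)
  }
  g <- factor(g)
  if (nlevels(g) != 2L) stop("group must have exactly 2 levels", call. = FALSE)
  a <- m[g == levels(g)[1L], , drop = FALSE]
  b <- m[g == levels(g)[2L], , drop = FALSE]
  tt <- two_sample_t(a, b)
  lobe <- unname(lobe_map[colnames(m)])
  if (anyNA(lobe)) {
    stop("no lobe label for region(s): ",
         paste(colnames(m)[is.na(lobe)], collapse = ", "), call. = FALSE)
  }
  adj <- grouped_bh_fdr(tt$p, lobe, alpha)
  data.frame(region = colnames(m), lobe = lobe, mean_a = tt$mean_a,
             mean_b = tt$mean_b, delta = tt$delta, statistic = tt$statistic,
             p = tt$p, q = adj$q, significant = adj$significant,
             row.names = NULL)
}

#' Per-region simple linear regression on a subject-level marker
#'
#' Ordinary least squares of each region's value on a fasting-marker
#' covariate (e.g. fasting glucose), pooled across subjects, with the
#' two-sided slope p-value adjusted by Benjamini-Hochberg within each lobe.
#' Regions whose adjusted p passes `alpha` are flagged (the heatmap
#' asterisk analogue). Exact fits produce the smallest representable
#' positive p rather than 0.
#'
#' @param values Long data frame `subject_id`, `region`, `value`.
#' @param marker Named numeric vector (names = subject ids) with nonzero
#'   variance.
#' @param lobe_map Named vector mapping region to lobe.
#' @param alpha FDR level.
#' @return Data frame: `region`, `lobe`, `slope`, `intercept`, `r`, `p`,
#'   `q`, `n`, `significant`.
#' @export
regress_marker <- function(values, marker, lobe_map, alpha = 0.05) {
  m <- wide_by_region(values)
  x <- marker[rownames(m)]
  if (anyNA(x)) {
    stop("missing marker value for subject(s): ",
         paste(rownames(m)[is.na(x)], collapse = ", "), call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 subjects for regression", call. = FALSE)
  if (stats::var(x) == 0) stop("marker has zero variance", call. = FALSE)
  rows <- lapply(colnames(m), function(region) {
    y <- m[, region]
    fit <- stats::lm(y ~ x)
    # exact fits trip summary.lm's perfect-fit warning; their p is floored below
    sm <- suppressWarnings(summary(fit))
    slope <- stats::coef(fit)[[2L]]
    p <- sm$coefficients[2L, 4L]
    if (!is.finite(p) || p <= 0) p <- .Machine$double.xmin
    r <- if (stats::var(y) == 0) 0 else stats::cor(x, y)
    data.frame(region = region, slope = slope,
               intercept = stats::coef(fit)[[1L]], r = r, p = p,
               n = length(y))
  })
  out <- do.call(rbind, rows)
  out$lobe <- unname(lobe_map[out$region])
  if (anyNA(out$lobe)) {
    stop("no lobe label for region(s): ",
         paste(out$region[is.na(out$lobe)], collapse = ", "), call. = FALSE)
  }
  adj <- grouped_bh_fdr(out$p, out$lobe, alpha)
  out$q <- adj$q
  out$significant <- adj$significant
  rownames(out) <- NULL
  out[, c("region", "lobe", "slope", "intercept", "r", "p", "q", "n",
          "significant")]
}

#' Per-region treatment-by-time interaction on pre/post scalars
#'
#' For every region, computes each subject's change score (post - pre) and
#' tests the arm difference in mean change with [interaction_delta_test()]
#' — equivalent to the group-by-time interaction of the 2 x 2
#' repeated-measures ANOVA. Reports the mean change per arm alongside the
#' interaction p-value.
#'
#' @param pre,post Long data frames `subject_id`, `region`, `value` with
#'   identical subject-region coverage.
#' @param arm Named vector (names = subject ids) with two levels; first
#'   level = treated arm (condition A).
#' @return Data frame: `region`, `mean_delta_a`, `mean_delta_b`,
#'   `delta_diff`, `statistic`, `p`.
#' @export
delta_interaction_by_region <- function(pre, post, arm) {
  m_pre <- wide_by_region(pre)
  m_post <- wide_by_region(post)
  if (!identical(dimnames(m_pre), dimnames(m_post))) {
    missing <- c(setdiff(rownames(m_pre), rownames(m_post)),
                 setdiff(rownames(m_post), rownames(m_pre)))
    stop("pre/post subject or region mismatch",
         if (length(missing)) paste0(": ", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  delta <- m_post - m_pre
  g <- arm[rownames(delta)]
  if (anyNA(g)) {
    stop("missing arm assignment for subject(s): ",
         paste(rownames(delta)[is.na(g)], collapse = ", "), call. = FALSE)
  }
  g <- factor(g)
  if (nlevels(g) != 2L) stop("arm must have exactly 2 levels", call. = FALSE)
  da <- delta[g == levels(g)[1L], , drop = FALSE]
  db <- delta[g == levels(g)[2L], , drop = FALSE]
  tt <- two_sample_t(da, db)
  data.frame(region = colnames(delta), mean_delta_a = tt$mean_a,
             mean_delta_b = tt$mean_b, delta_diff = tt$delta,
             statistic = tt$statistic, p = tt$p, row.names = NULL)
}
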