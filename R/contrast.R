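#' Vectorized two-sided two-sample t-test
#'
#' Column-wise unpaired t-tests of `a` (rows = subjects in condition A)
#' against `b`. The pooled-variance Student test is the default; Welch's
#' unequal-variance test is available as an option. Degenerate columns with
#' zero standard error are reported as `p = 1` when the means are equal and
#' as the smallest representable positive p-value (with a warning) when they
#' differ, so vectorized pipelines stay total.
#'
#' @param a,b Numeric matrices with one column per variable and one row per
#'   subject (`>= 2` rows each).
#' @param test `"student"` (pooled variance) or `"welch"`.
#' @return List with per-column `mean_a`, `mean_b`, `delta` (A - B),
#'   `statistic`, `df`, `p`, `degenerate`.
#' @keywords internal
two_sample_t <- function(a, b, test = c("student", "welch")) {
  test <- match.arg(test)
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("a and b must have the same number of columns", call. = FALSE)
  na <- nrow(a); nb <- nrow(b)
  if (na < 2L || nb < 2L) stop("need at least 2 subjects per condition", call. = FALSE)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums((a - rep(ma, each = na))^2) / (na - 1)
  vb <- colSums((b - rep(mb, each = nb))^2) / (nb - 1)
  delta <- ma - mb
  if (test == "student") {
    s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(s2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    df[!is.finite(df)] <- na + nb - 2
  }
  statistic <- delta / se
  p <- 2 * stats::pt(-abs(statistic), df)
  degenerate <- se == 0
  if (any(degenerate)) {
    zero_delta <- degenerate & delta == 0
    p[zero_delta] <- 1
    statistic[zero_delta] <- 0
    nz <- degenerate & delta != 0
    if (any(nz)) {
      warning(sum(nz), " variable(s) with zero pooled variance but unequal means; ",
              "p set to smallest representable positive value", call. = FALSE)
      p[nz] <- .Machine$double.xmin
      statistic[nz] <- sign(delta[nz]) * Inf
    }
  }
  list(mean_a = ma, mean_b = mb, delta = delta, statistic = statistic,
       df = df, p = p, degenerate = degenerate)
}

#' Significance-weighted effect magnitude for an edge
#'
#' Converts an edge's connectivity difference and adjusted p-value into the
#' nonnegative ribbon weight used for chord-diagram export. The default
#' scheme is `|delta_z| * (1 - q)`: bounded, monotone in both the effect
#' magnitude and its significance. An alternative `|delta_z| * -log10(q)`
#' scaling is available.
#'
#' @param delta_z Numeric vector of mean Fisher-z differences.
#' @param q Adjusted p-values in `[0, 1]`.
#' @param scheme `"one_minus_q"` (default) or `"neglog10q"`.
#' @return Nonnegative numeric weights.
#' @export
significance_weight <- function(delta_z, q, scheme = c("one_minus_q", "neglog10q")) {
  scheme <- match.arg(scheme)
  bad <- which(!is.finite(q) | q < 0 | q > 1)
  if (length(bad) > 0L) {
    stop("invalid q value: ", format(q[bad[1L]]), call. = FALSE)
  }
  switch(scheme,
    one_minus_q = abs(delta_z) * (1 - q),
    neglog10q = abs(delta_z) * -log10(pmax(q, .Machine$double.xmin))
  )
}

# Stack the upper triangles of a list of fc_matrix/change objects into a
# subjects x edges matrix (edge_index order).
stack_edges <- function(fc_list) {
  if (length(fc_list) == 0L) stop("empty matrix list", call. = FALSE)
  dims <- vapply(fc_list, function(f) nrow(f$z), integer(1L))
  if (length(unique(dims)) != 1L) {
    stop("all matrices must have the same number of regions", call. = FALSE)
  }
  do.call(rbind, lapply(fc_list, function(f) upper_tri_vector(f$z)))
}

#' Edge-wise group contrast with BH-FDR
#'
#' For every unordered region pair (edge), tests the difference in mean
#' Fisher-z connectivity between condition A and condition B with a
#' two-sided unpaired t-test, adjusts the resulting p-values by
#' Benjamini-Hochberg across the edge family, and attaches the
#' significance-weighted effect magnitude. Raw (unthresholded) z values are
#' always used here; the noise band applies only to downstream categorical
#' interpretation.
#'
#' @param fc_a,fc_b Lists of [fc_matrix()] (or change-matrix) objects, one
#'   per subject, at least 2 per condition. Condition A minus condition B is
#'   the reported effect direction (cross-sectional convention: A = IR,
#'   B = HC; longitudinal convention: A = treated-arm changes, B = placebo
#'   changes).
#' @param alpha FDR level (default 0.05).
#' @param test `"student"` (pooled variance, default) or `"welch"`.
#' @param fdr_family `"all_edges"` (default): one BH family over all
#'   `R(R-1)/2` edges; `"per_lobe_pair"`: BH within each lobe-pair stratum
#'   (requires `meta`).
#' @param weight_scheme Passed to [significance_weight()].
#' @param meta Optional `region_meta` table; required for
#'   `fdr_family = "per_lobe_pair"`.
#' @param contrast_kind `"cross_sectional"` or `"longitudinal"`; recorded as
#'   an attribute.
#' @return A data frame of class `group_contrast` with one row per edge in
#'   [edge_index()] order: `edge_i`, `edge_j`, `mean_a`, `mean_b`,
#'   `delta_z`, `statistic`, `p`, `q`, `significant`, `weight`. Attributes:
#'   `alpha`, `contrast_kind`, `n_a`, `n_b`, `n_regions`, `test`,
#'   `fdr_family`, `weight_scheme`.
#' @export
edgewise_group_contrast <- function(fc_a, fc_b, alpha = 0.05,
                                    test = c("student", "welch"),
                                    fdr_family = c("all_edges", "per_lobe_pair"),
                                    weight_scheme = c("one_minus_q", "neglog10q"),
                                    meta = NULL,
                                    contrast_kind = c("cross_sectional", "longitudinal")) {
  test <- match.arg(test)
  fdr_family <- match.arg(fdr_family)
  weight_scheme <- match.arg(weight_scheme)
  contrast_kind <- match.arg(contrast_kind)
  A <- stack_edges(fc_a)
  B <- stack_edges(fc_b)
  if (ncol(A) != ncol(B)) stop("conditions have different region counts", call. = FALSE)
  R <- nrow(fc_a[[1L]]$z)
  tt <- two_sample_t(A, B, test)
  edges <- edge_table(R)
  if (fdr_family == "per_lobe_pair") {
    if (is.null(meta)) stop("per_lobe_pair FDR family requires region metadata", call. = FALSE)
    meta <- validate_region_meta(meta)
    li <- meta$lobe[edges$edge_i + 1L]
    lj <- meta$lobe[edges$edge_j + 1L]
    lab <- paste(pmin(li, lj), pmax(li, lj), sep = "|")
    adj <- grouped_bh_fdr(tt$p, lab, alpha)
  } else {
    adj <- bh_fdr(tt$p, alpha)
  }
  out <- data.frame(
    edge_i = edges$edge_i,
    edge_j = edges$edge_j,
    mean_a = tt$mean_a,
    mean_b = tt$mean_b,
    delta_z = tt$delta,
    statistic = tt$statistic,
    p = tt$p,
    q = adj$q,
    significant = adj$significant,
    weight = significance_weight(tt$delta, adj$q, weight_scheme)
  )
  structure(out,
            class = c("group_contrast", "data.frame"),
            alpha = alpha, contrast_kind = contrast_kind,
            n_a = length(fc_a), n_b = length(fc_b), n_regions = R,
            test = test, fdr_family = fdr_family,
            weight_scheme = weight_scheme)
}

#' Per-subject connectivity change matrix
#'
#' Entry-wise `post - pre` difference of a subject's Fisher-z connectivity,
#' the within-subject treatment effect used by the difference-in-differences
#' contrast.
#'
#' @param pre,post [fc_matrix()] objects for the same subject and
#'   parcellation.
#' @return An `fc_matrix`-compatible object of class
#'   `c("change_matrix", "fc_matrix")` whose `z` holds the change scores.
#' @export
subject_change <- function(pre, post) {
  stopifnot(inherits(pre, "fc_matrix"), inherits(post, "fc_matrix"))
  if (!identical(pre$subject_id, post$subject_id)) {
    stop("pre/post subject mismatch: ", pre$subject_id, " vs ",
         post$subject_id, call. = FALSE)
  }
  if (!identical(dim(pre$z), dim(post$z))) {
    stop("pre/post dimension mismatch for subject ", pre$subject_id, call. = FALSE)
  }
  out <- fc_matrix(pre$subject_id, post$z - pre$z)
  class(out) <- c("change_matrix", class(out))
  out
}

# Pair pre/post lists by subject_id; error naming any unpaired subject.
pair_changes <- function(pre, post, arm) {
  ids_pre <- vapply(pre, `[[`, character(1L), "subject_id")
  ids_post <- vapply(post, `[[`, character(1L), "subject_id")
  unpaired <- c(setdiff(ids_pre, ids_post), setdiff(ids_post, ids_pre))
  if (length(unpaired) > 0L) {
    stop("unpaired subject in ", arm, " arm: ",
         paste(unpaired, collapse = ", "), call. = FALSE)
  }
  post <- post[match(ids_pre, ids_post)]
  Map(subject_change, pre, post)
}

#' Placebo-subtracted longitudinal treatment contrast
#'
#' Difference-in-differences analysis of a two-arm pre/post design: the
#' per-subject change matrices (post - pre) are computed within each arm,
#' and the treated-arm changes are contrasted edge-wise against the
#' placebo-arm changes. A positive `delta_z` means a greater connectivity
#' change under treatment (metformin - placebo convention); shared time
#' trends and baseline offsets cancel.
#'
#' @param treated_pre,treated_post,control_pre,control_post Lists of
#'   [fc_matrix()] objects; pre/post are paired by `subject_id` within each
#'   arm.
#' @inheritParams edgewise_group_contrast
#' @return A `group_contrast` data frame (`contrast_kind = "longitudinal"`).
#' @export
treatment_contrast <- function(treated_pre, treated_post,
                               control_pre, control_post,
                               alpha = 0.05, test = c("student", "welch"),
                               fdr_family = c("all_edges", "per_lobe_pair"),
                               weight_scheme = c("one_minus_q", "neglog10q"),
                               meta = NULL) {
  d_treated <- pair_changes(treated_pre, treated_post, "treated")
  d_control <- pair_changes(control_pre, control_post, "control")
  edgewise_group_contrast(d_treated, d_control, alpha = alpha,
                          test = match.arg(test),
                          fdr_family = match.arg(fdr_family),
                          weight_scheme = match.arg(weight_scheme),
                          meta = meta, contrast_kind = "longitudinal")
}

#' Interaction test for a two-arm pre/post design via change scores
#'
#' Two-sided pooled-variance t-test on the per-subject change scores
#' (post - pre) of two arms. For a balanced (or unbalanced) 2 x 2 design
#' with one within-subject factor (time) and one between-subject factor
#' (arm), this p-value equals the group-by-time interaction p of the
#' repeated-measures ANOVA, which the test suite asserts against
#' [stats::aov()].
#'
#' @param deltas_a,deltas_b Numeric vectors of per-subject change scores,
#'   at least 2 per arm.
#' @return List with `p`, `statistic`, `df`, `mean_delta_a`, `mean_delta_b`.
#' @export
interaction_delta_test <- function(deltas_a, deltas_b) {
  tt <- two_sample_t(matrix(deltas_a, ncol = 1L), matrix(deltas_b, ncol = 1L))
  list(p = unname(tt$p[1L]), statistic = unname(tt$statistic[1L]),
       df = unname(tt$df[1L]), mean_delta_a = unname(tt$mean_a[1L]),
       mean_delta_b = unname(tt$mean_b[1L]))
}

#' Write a group contrast as TSV
#'
#' One row per edge in deterministic [edge_index()] order, with columns
#' `edge_i, edge_j, mean_a, mean_b, delta_z, p, q, significant, weight`.
#'
#' @param contrast A `group_contrast` data frame.
#' @param path Output file path.
#' @export
write_contrast <- function(contrast, path) {
  stopifnot(inherits(contrast, "group_contrast"))
  cols <- c("edge_i", "edge_j", "mean_a", "mean_b", "delta_z", "p", "q",
            "significant", "weight")
  out <- as.data.frame(contrast)[, cols]
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
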