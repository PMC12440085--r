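#' Monte-Carlo calibration studies for the edge-wise contrast pipeline
#'
#' These functions run the package's own generator and contrast engine over
#' many replicated synthetic cohorts to measure its operating
#' characteristics: the realized false-discovery rate under a global null,
#' and sensitivity/FDR/classification accuracy when effects of known size
#' are injected. They are the basis of the package's validation suite and
#' of the reproduction script.
#'
#' @param n_replicates Number of simulated cohorts.
#' @param n_regions Parcellation size (default 30 regions, 435 edges).
#' @param n_per_group Subjects per condition (default 20).
#' @param n_timepoints Series length (default 116 volumes).
#' @param base_z Background Fisher-z connectivity level (default 0.1).
#' @param alpha FDR level (default 0.05).
#' @param seed Master seed; replicate seeds derive from it.
#' @return `null_fdr_study`: list with `fdr_per_replicate`, `realized_fdr`,
#'   `mc_se`, `n_edges`, `n_replicates`.
#' @name calibration
NULL

#' @rdname calibration
#' @export
null_fdr_study <- function(n_replicates = 200L, n_regions = 30L,
                           n_per_group = 20L, n_timepoints = 116L,
                           base_z = 0.1, alpha = 0.05, seed = 1L) {
  meta <- make_parcellation(n_regions, seed = seed)
  fdr <- vapply(seq_len(n_replicates), function(rep) {
    d <- synthetic_design(
      meta = meta, base_z = base_z, injections = NULL,
      arms = list(kind = "cross_sectional", n_a = n_per_group,
                  n_b = n_per_group),
      n_timepoints = n_timepoints, seed = derive_seed(seed, rep, 900L))
    coh <- simulate_cohort(d)
    con <- edgewise_group_contrast(lapply(coh$ts_a, compute_fc_matrix),
                                   lapply(coh$ts_b, compute_fc_matrix),
                                   alpha = alpha)
    n_sig <- sum(con$significant)
    if (n_sig == 0L) 0 else 1  # every discovery is false under the null
  }, numeric(1L))
  list(fdr_per_replicate = fdr, realized_fdr = mean(fdr),
       mc_se = stats::sd(fdr) / sqrt(n_replicates),
       n_edges = n_regions * (n_regions - 1L) / 2L,
       n_replicates = n_replicates)
}

# Disjoint injected edges (0,1), (2,3), ... keep the condition-A matrix
# positive definite without repair distortion.
default_injections <- function(n_injected, delta_z) {
  data.frame(edge_i = as.integer(2L * (seq_len(n_injected) - 1L)),
             edge_j = as.integer(2L * (seq_len(n_injected) - 1L) + 1L),
             delta_z = delta_z)
}

#' @rdname calibration
#' @param n_injected Number of injected edges (default 10, disjoint pairs).
#' @param delta_z Injected condition-A-minus-B z gap (default 0.5).
#' @return `recovery_study`: list with per-replicate `sensitivity` and
#'   `fdr` vectors, their means, `prop_expected_category` (fraction of
#'   recovered injected edges classified `stronger_positive_in_A`), and the
#'   injected edge table.
#' @export
recovery_study <- function(n_replicates = 50L, n_regions = 30L,
                           n_per_group = 20L, n_timepoints = 116L,
                           base_z = 0.1, n_injected = 10L, delta_z = 0.5,
                           alpha = 0.05, seed = 1L) {
  meta <- make_parcellation(n_regions, seed = seed)
  inj <- default_injections(n_injected, delta_z)
  truth_key <- paste(inj$edge_i, inj$edge_j)
  sens <- numeric(n_replicates)
  fdr <- numeric(n_replicates)
  n_expected_cat <- 0L
  n_recovered <- 0L
  for (rep in seq_len(n_replicates)) {
    d <- synthetic_design(
      meta = meta, base_z = base_z, injections = inj,
      arms = list(kind = "cross_sectional", n_a = n_per_group,
                  n_b = n_per_group),
      n_timepoints = n_timepoints, seed = derive_seed(seed, rep, 901L))
    coh <- simulate_cohort(d)
    con <- edgewise_group_contrast(lapply(coh$ts_a, compute_fc_matrix),
                                   lapply(coh$ts_b, compute_fc_matrix),
                                   alpha = alpha)
    sig_key <- paste(con$edge_i[con$significant], con$edge_j[con$significant])
    true_pos <- sum(sig_key %in% truth_key)
    sens[rep] <- true_pos / n_injected
    fdr[rep] <- if (length(sig_key) == 0L) 0 else
      (length(sig_key) - true_pos) / length(sig_key)
    cats <- classify_cross_sectional(con$mean_a, con$mean_b, con$significant)
    hit <- con$significant & paste(con$edge_i, con$edge_j) %in% truth_key
    n_recovered <- n_recovered + sum(hit)
    n_expected_cat <- n_expected_cat +
      sum(cats[hit] == "stronger_positive_in_A")
  }
  list(sensitivity = sens, fdr = fdr,
       mean_sensitivity = mean(sens), mean_fdr = mean(fdr),
       prop_expected_category = if (n_recovered == 0L) NA_real_ else
         n_expected_cat / n_recovered,
       injections = inj, n_replicates = n_replicates)
}

#' @rdname calibration
#' @param n_subjects Subjects per condition for the fidelity check
#'   (default 200).
#' @return `fidelity_study`: list with `target_delta_z`,
#'   `realized_delta_z` (mean sample z gap at each injected edge across
#'   subjects) and `max_abs_error`.
#' @export
fidelity_study <- function(n_subjects = 200L, n_regions = 30L,
                           n_timepoints = 116L, base_z = 0.1,
                           n_injected = 10L, delta_z = 0.5, seed = 1L) {
  inj <- default_injections(n_injected, delta_z)
  both <- build_condition_matrices(base_z, inj, n_regions)
  idx <- cbind(inj$edge_i + 1L, inj$edge_j + 1L)
  mean_edge_z <- function(cov, offset) {
    acc <- matrix(0, n_subjects, n_injected)
    for (k in seq_len(n_subjects)) {
      fc <- compute_fc_matrix(
        simulate_subject(cov, n_timepoints,
                         seed = derive_seed(seed, k, offset)))
      acc[k, ] <- fc$z[idx]
    }
    colMeans(acc)
  }
  za <- mean_edge_z(both$A, 902L)
  zb <- mean_edge_z(both$B, 903L)
  realized <- za - zb
  list(target_delta_z = inj$delta_z, realized_delta_z = realized,
       max_abs_error = max(abs(realized - inj$delta_z)))
}
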