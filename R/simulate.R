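#' Nearest positive-definite correlation matrix by eigenvalue clipping
#'
#' Clips the eigenvalues of a symmetric matrix at a small positive floor,
#' reconstructs, and renormalizes the diagonal to 1 so the result is a valid
#' correlation matrix. The output is verified with a Cholesky factorization.
#'
#' @param m Symmetric numeric matrix.
#' @param eig_floor Eigenvalue floor (default `1e-6`).
#' @return Positive-definite correlation matrix (unit diagonal).
#' @export
nearest_positive_definite <- function(m, eig_floor = 1e-6) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    stop("input must be a symmetric square matrix", call. = FALSE)
  }
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eig_floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  # renormalization can nudge an eigenvalue back under the floor; ridge it
  ok <- FALSE
  ridge <- 0
  for (attempt in 1:6) {
    ok <- !inherits(try(chol(out), silent = TRUE), "try-error")
    if (ok) break
    ridge <- if (ridge == 0) eig_floor else ridge * 10
    out <- (1 - ridge) * out
    diag(out) <- 1
  }
  if (!ok) stop("could not repair matrix to positive definite", call. = FALSE)
  dimnames(out) <- dimnames(m)
  out
}

#' Designed group correlation matrix with injected edge effects
#'
#' Builds the population correlation matrix for one study condition.
#' Condition B is the base structure: `tanh(base_z)` off the diagonal (or a
#' full base correlation matrix). Condition A additionally carries the
#' injected effects: at each injected edge the correlation is shifted in the
#' Fisher-z domain so that `fisher_z(r_A) - fisher_z(r_B) = delta_z`, then
#' mapped back through `tanh`. If the injection breaks positive
#' definiteness the matrix is repaired with [nearest_positive_definite()],
#' and the realized z-gaps at the injected edges are re-checked against the
#' targets (tolerance `1e-3`); a repair that distorts an injection beyond
#' tolerance is an error advising smaller effects or sparser injections.
#'
#' @param base Either a single base Fisher-z level or a full base
#'   correlation matrix.
#' @param injections Data frame with 0-based columns `edge_i < edge_j` and
#'   `delta_z` (condition A minus condition B target z gap); may be empty.
#' @param condition `"A"` (carries the injections) or `"B"` (base).
#' @param n_regions Number of regions (required when `base` is scalar).
#' @return Positive-definite correlation matrix.
#' @export
build_group_covariance <- function(base, injections = NULL,
                                   condition = c("A", "B"), n_regions = NULL) {
  condition <- match.arg(condition)
  both <- build_condition_matrices(base, injections, n_regions)
  if (condition == "A") both$A else both$B
}

# Build both condition matrices, repair, and verify realized injections.
build_condition_matrices <- function(base, injections, n_regions) {
  if (is.matrix(base)) {
    r_base <- base
    n_regions <- nrow(base)
    if (any(abs(r_base[row(r_base) != col(r_base)]) >= 1)) {
      stop("base correlation entries must be in (-1, 1)", call. = FALSE)
    }
    diag(r_base) <- 1
  } else {
    if (is.null(n_regions)) stop("n_regions required with a scalar base level", call. = FALSE)
    r <- tanh(base)
    r_base <- matrix(r, n_regions, n_regions)
    diag(r_base) <- 1
  }
  r_b <- nearest_positive_definite(r_base)
  r_a <- r_b
  if (!is.null(injections) && nrow(injections) > 0L) {
    for (k in seq_len(nrow(injections))) {
      i <- injections$edge_i[k] + 1L
      j <- injections$edge_j[k] + 1L
      if (i >= j || i < 1L || j > n_regions) {
        stop("invalid injected edge (", injections$edge_i[k], ", ",
             injections$edge_j[k], ")", call. = FALSE)
      }
      shifted <- tanh(fisher_z(r_b[i, j]) + injections$delta_z[k])
      if (abs(shifted) >= 1) stop("injected effect pushes |r| to 1", call. = FALSE)
      r_a[i, j] <- r_a[j, i] <- shifted
    }
    r_a <- nearest_positive_definite(r_a)
    realized <- fisher_z(r_a[cbind(injections$edge_i + 1L, injections$edge_j + 1L)]) -
      fisher_z(r_b[cbind(injections$edge_i + 1L, injections$edge_j + 1L)])
    off <- abs(realized - injections$delta_z)
    if (any(off > 1e-3)) {
      stop("positive-definite repair distorted an injected effect by ",
           format(max(off), digits = 3),
           "; use smaller delta_z or fewer injected edges", call. = FALSE)
    }
  }
  list(A = r_a, B = r_b)
}

#' Simulate one subject's parcellated BOLD-like time series
#'
#' Draws a stationary Gaussian series with the requested contemporaneous
#' correlation structure and AR(1) temporal smoothness:
#' `x_t = phi * x_{t-1} + sqrt(1 - phi^2) * L %*% eps_t`, with `L` the
#' Cholesky factor of `cov` and `x_1 = L %*% eps_1`, so every marginal
#' timepoint has covariance `cov` exactly and the sample correlation
#' converges to `cov` as `T` grows. The AR(1) component stands in for the
#' temporal smoothness of band-limited BOLD noise.
#'
#' @param cov Positive-definite correlation matrix (`R x R`).
#' @param n_timepoints Series length `T` (default 116 volumes).
#' @param ar_coef AR(1) coefficient `phi` in `[0, 0.95]`.
#' @param noise_sd Marginal standard deviation scale.
#' @param seed Integer seed; the draw is bitwise reproducible.
#' @param subject_id Label for the returned series.
#' @param tr_seconds Repetition time (default 3.0 s).
#' @return A [bold_time_series()] object (`T x R`).
#' @export
simulate_subject <- function(cov, n_timepoints = 116L, ar_coef = 0,
                             noise_sd = 1, seed = 1L, subject_id = "sim",
                             tr_seconds = 3.0) {
  cov <- as.matrix(cov)
  if (ar_coef < 0 || ar_coef >= 1) stop("ar_coef must be in [0, 1)", call. = FALSE)
  Lt <- try(chol(cov), silent = TRUE)
  if (inherits(Lt, "try-error")) {
    stop("covariance is not positive definite; repair it first", call. = FALSE)
  }
  R <- nrow(cov)
  x <- with_seed(seed, {
    eps <- matrix(stats::rnorm(n_timepoints * R), n_timepoints, R)
    innov <- eps %*% Lt            # row t = t(L %*% eps_t), Lt = chol upper
    if (ar_coef == 0) {
      innov
    } else {
      out <- innov
      scale <- sqrt(1 - ar_coef^2)
      for (t in 2:n_timepoints) {
        out[t, ] <- ar_coef * out[t - 1L, ] + scale * innov[t, ]
      }
      out
    }
  })
  x <- x * noise_sd
  colnames(x) <- if (!is.null(colnames(cov))) colnames(cov) else
    sprintf("region_%03d", seq_len(R) - 1L)
  bold_time_series(subject_id, x, tr_seconds)
}

#' Specify a synthetic cohort design
#'
#' Bundles everything [simulate_cohort()] needs: a parcellation, the base
#' connectivity level, the injected edge effects (the ground-truth
#' condition-A-minus-B z gaps), the arm structure, and the noise model. The
#' defaults mirror the study conditions the package emulates: 116 volumes
#' at TR 3 s, a cross-sectional comparison of 18 controls vs 56 cases, and
#' a two-arm randomized pre/post design of 20 subjects per arm.
#'
#' @param meta A `region_meta` table (default: [make_parcellation()] with 32
#'   regions).
#' @param base_z Base Fisher-z level (scalar) or base correlation matrix.
#' @param injections Data frame `edge_i`, `edge_j`, `delta_z` (may be NULL).
#' @param arms Either `list(kind = "cross_sectional", n_a = 56, n_b = 18)`
#'   or `list(kind = "rct", n_per_arm = 20)`.
#' @param n_timepoints,tr_seconds,ar_coef,noise_sd Noise model; see
#'   [simulate_subject()].
#' @param seed Master seed; all per-subject seeds derive from it.
#' @return List of class `synthetic_design`.
#' @export
synthetic_design <- function(meta = make_parcellation(32L, seed = 1L),
                             base_z = 0.1, injections = NULL,
                             arms = list(kind = "cross_sectional",
                                         n_a = 56L, n_b = 18L),
                             n_timepoints = 116L, tr_seconds = 3.0,
                             ar_coef = 0, noise_sd = 1, seed = 1L) {
  meta <- validate_region_meta(meta)
  if (!arms$kind %in% c("cross_sectional", "rct")) {
    stop("arms$kind must be cross_sectional or rct", call. = FALSE)
  }
  ns <- if (arms$kind == "cross_sectional") c(arms$n_a, arms$n_b) else arms$n_per_arm
  if (any(ns < 2L)) stop("every arm needs at least 2 subjects", call. = FALSE)
  if (n_timepoints < 3L) stop("n_timepoints must be >= 3", call. = FALSE)
  if (!is.null(injections) && nrow(injections) > 0L) {
    stopifnot(all(c("edge_i", "edge_j", "delta_z") %in% names(injections)))
  }
  structure(list(meta = meta, base_z = base_z, injections = injections,
                 arms = arms, n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds, ar_coef = ar_coef,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_design")
}

# Deterministic per-subject seed derived from the master seed, the subject
# index and a timepoint code; kept below 2^31 - 1.
derive_seed <- function(master, index, time_code = 0L) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 7919 +
                as.numeric(time_code) * 104729 + 12345) %% 2147483647)
}

#' Simulate a full synthetic cohort with known ground truth
#'
#' Cross-sectional designs draw `n_a` subjects from the condition-A
#' correlation matrix (carrying the injected effects) and `n_b` from the
#' base condition-B matrix. RCT designs draw paired pre/post series per
#' subject in two arms: both arms' pre (and the control arm's post) come
#' from the base matrix, while the treated arm's post carries the injected
#' effects. Per-subject seeds are derived deterministically from the master
#' seed, so regeneration with the same design is identical.
#'
#' @param design A [synthetic_design()].
#' @param out_dir Optional directory; when given, every subject's series is
#'   written as `<subject_id>.tsv`, the parcellation as `region_meta.tsv`,
#'   and the ground truth as `ground_truth.json`.
#' @return List of class `synthetic_cohort`. Cross-sectional: lists `ts_a`,
#'   `ts_b` of `bold_ts`. RCT: lists `treated_pre`, `treated_post`,
#'   `control_pre`, `control_post`. Always: `design` and `truth`
#'   (injections plus the two condition correlation matrices).
#' @export
simulate_cohort <- function(design, out_dir = NULL) {
  stopifnot(inherits(design, "synthetic_design"))
  R <- nrow(design$meta)
  cond <- build_condition_matrices(design$base_z, design$injections, R)
  colnames(cond$A) <- rownames(cond$A) <- design$meta$name
  colnames(cond$B) <- rownames(cond$B) <- design$meta$name
  sim_one <- function(cov, idx, time_code, id) {
    simulate_subject(cov, design$n_timepoints, design$ar_coef,
                     design$noise_sd, seed = derive_seed(design$seed, idx, time_code),
                     subject_id = id, tr_seconds = design$tr_seconds)
  }
  truth <- list(
    injections = if (is.null(design$injections)) {
      data.frame(edge_i = integer(0L), edge_j = integer(0L), delta_z = numeric(0L))
    } else design$injections,
    cor_a = cond$A, cor_b = cond$B
  )
  if (design$arms$kind == "cross_sectional") {
    n_a <- design$arms$n_a; n_b <- design$arms$n_b
    ts_a <- lapply(seq_len(n_a), function(k)
      sim_one(cond$A, k, 0L, sprintf("A_%03d", k)))
    ts_b <- lapply(seq_len(n_b), function(k)
      sim_one(cond$B, n_a + k, 0L, sprintf("B_%03d", k)))
    cohort <- list(kind = "cross_sectional", ts_a = ts_a, ts_b = ts_b,
                   design = design, truth = truth)
  } else {
    n <- design$arms$n_per_arm
    treated_pre <- lapply(seq_len(n), function(k)
      sim_one(cond$B, k, 1L, sprintf("T_%03d", k)))
    treated_post <- lapply(seq_len(n), function(k)
      sim_one(cond$A, k, 2L, sprintf("T_%03d", k)))
    control_pre <- lapply(seq_len(n), function(k)
      sim_one(cond$B, n + k, 1L, sprintf("C_%03d", k)))
    control_post <- lapply(seq_len(n), function(k)
      sim_one(cond$B, n + k, 2L, sprintf("C_%03d", k)))
    cohort <- list(kind = "rct", treated_pre = treated_pre,
                   treated_post = treated_post, control_pre = control_pre,
                   control_post = control_post, design = design, truth = truth)
  }
  class(cohort) <- "synthetic_cohort"
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

# Serialize a cohort: one TSV per series (pre/post suffixed), region
# metadata, and ground truth as JSON + condition matrices as TSV.
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_series <- function(ts_list, suffix = "") {
    for (ts in ts_list) {
      write_time_series(ts, file.path(out_dir, paste0(ts$subject_id, suffix, ".tsv")))
    }
  }
  if (cohort$kind == "cross_sectional") {
    write_series(cohort$ts_a); write_series(cohort$ts_b)
  } else {
    write_series(cohort$treated_pre, "_pre")
    write_series(cohort$treated_post, "_post")
    write_series(cohort$control_pre, "_pre")
    write_series(cohort$control_post, "_post")
  }
  write_region_meta(cohort$design$meta, file.path(out_dir, "region_meta.tsv"))
  jsonlite::write_json(
    list(kind = cohort$kind, seed = cohort$design$seed,
         n_timepoints = cohort$design$n_timepoints,
         injections = cohort$truth$injections),
    file.path(out_dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  utils::write.table(format_num(cohort$truth$cor_a),
                     file.path(out_dir, "cor_condition_a.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(format_num(cohort$truth$cor_b),
                     file.path(out_dir, "cor_condition_b.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(out_dir)
}
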