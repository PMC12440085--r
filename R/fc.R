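#' Fisher z-transform of a correlation coefficient
#'
#' Applies the variance-stabilizing map `z = atanh(r)`. Correlations with
#' `|r| = 1` (e.g. duplicated time series) are clamped to `1 - 1e-6` in
#' magnitude before the transform so that perfectly correlated columns yield
#' a finite, extreme z rather than infinity; ranking among extreme values is
#' preserved.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @return Numeric vector of Fisher z values.
#' @seealso [inverse_fisher_z()]
#' @export
fisher_z <- function(r) {
  if (!is.numeric(r)) stop("r must be numeric", call. = FALSE)
  bad <- which(!is.finite(r) | abs(r) > 1)
  if (length(bad) > 0L) {
    stop("invalid correlation value: ", format(r[bad[1L]]),
         " (must be finite with |r| <= 1)", call. = FALSE)
  }
  cap <- 1 - 1e-6
  atanh(sign(r) * pmin(abs(r), cap))
}

#' Inverse Fisher z-transform
#'
#' @param z Numeric vector of finite Fisher z values.
#' @return Correlations `tanh(z)` in `(-1, 1)`.
#' @export
inverse_fisher_z <- function(z) {
  if (!is.numeric(z)) stop("z must be numeric", call. = FALSE)
  bad <- which(!is.finite(z))
  if (length(bad) > 0L) {
    stop("invalid z value: ", format(z[bad[1L]]), " (must be finite)",
         call. = FALSE)
  }
  tanh(z)
}

#' Construct a parcellated BOLD time-series object
#'
#' @param subject_id Subject label.
#' @param values `T x R` numeric matrix: `T` timepoints (rows) by `R`
#'   regions (columns). Column names, if present, are region names.
#' @param tr_seconds Repetition time in seconds (default 3.0, i.e. TR
#'   3000 ms).
#' @return An object of class `bold_ts`.
#' @export
bold_time_series <- function(subject_id, values, tr_seconds = 3.0) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("time-series values must be numeric", call. = FALSE)
  if (nrow(values) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  if (any(!is.finite(values))) {
    stop("non-finite values in time series for subject ", subject_id, call. = FALSE)
  }
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) {
    stop("tr_seconds must be positive", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), values = values,
         tr_seconds = tr_seconds),
    class = "bold_ts"
  )
}

#' Per-subject functional-connectivity matrix
#'
#' Computes the `R x R` matrix of Fisher z-transformed Pearson correlations
#' between all pairs of regional BOLD time series. The diagonal is not a
#' connection and is stored as `NA`; it is excluded from every downstream
#' computation.
#'
#' @param ts A [bold_time_series()] object.
#' @return An object of class `fc_matrix`: a list with `subject_id` and the
#'   symmetric `z` matrix (diagonal `NA`).
#' @export
compute_fc_matrix <- function(ts) {
  if (!inherits(ts, "bold_ts")) ts <- bold_time_series("subject", ts)
  x <- ts$values
  v <- apply(x, 2L, stats::var)
  if (any(v == 0)) {
    region <- colnames(x)[which(v == 0)[1L]]
    if (is.null(region)) region <- paste0("column ", which(v == 0)[1L])
    stop("zero-variance time series for region ", region,
         ": correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x)
  z <- fisher_z(r)
  diag(z) <- NA_real_
  z <- (z + t(z)) / 2
  fc_matrix(ts$subject_id, z)
}

#' @rdname compute_fc_matrix
#' @param subject_id Subject label.
#' @param z Symmetric `R x R` Fisher-z matrix, diagonal `NA`.
#' @export
fc_matrix <- function(subject_id, z) {
  z <- as.matrix(z)
  if (nrow(z) != ncol(z)) stop("z must be square", call. = FALSE)
  diag(z) <- NA_real_
  off <- z[row(z) != col(z)]
  if (any(!is.finite(off))) {
    stop("non-finite off-diagonal z values for subject ", subject_id, call. = FALSE)
  }
  if (max(abs(z - t(z)), na.rm = TRUE) > 1e-8) {
    stop("z matrix is not symmetric", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), z = z),
            class = "fc_matrix")
}

#' Linear index of an edge in row-major upper-triangle order
#'
#' Maps an unordered region pair `(i, j)` with `0 <= i < j < R` to its
#' position in `0..R(R-1)/2 - 1`, enumerating `(0,1), (0,2), ...,
#' (0,R-1), (1,2), ...` This is the deterministic row order of every edge
#' table the package writes.
#'
#' @param i,j 0-based region indices with `i < j` (vectorized).
#' @param n_regions Number of regions `R`.
#' @return 0-based integer edge positions.
#' @export
edge_index <- function(i, j, n_regions) {
  i <- as.integer(i); j <- as.integer(j); R <- as.integer(n_regions)
  bad <- which(i < 0L | j >= R | i >= j)
  if (length(bad) > 0L) {
    stop(sprintf("invalid edge (%d, %d) for R = %d: need 0 <= i < j < R",
                 i[bad[1L]], j[bad[1L]], R), call. = FALSE)
  }
  as.integer(i * R - (i * (i + 1L)) %/% 2L + (j - i - 1L))
}

#' Enumerate all edges of an R-region parcellation
#'
#' @param n_regions Number of regions.
#' @return Data frame with 0-based columns `edge_i < edge_j`, one row per
#'   unordered pair, in [edge_index()] order.
#' @export
edge_table <- function(n_regions) {
  R <- as.integer(n_regions)
  i <- rep.int(seq_len(R) - 1L, times = rev(seq_len(R) - 1L))
  j <- unlist(lapply(seq_len(R - 1L) - 1L, function(k) seq.int(k + 1L, R - 1L)),
              use.names = FALSE)
  data.frame(edge_i = i, edge_j = as.integer(j))
}

# Row-major upper-triangle vector of a symmetric matrix, matching
# edge_index() order. (Column-major lower triangle of the transpose.)
upper_tri_vector <- function(m) {
  tm <- t(m)
  tm[lower.tri(tm)]
}

# Rebuild a symmetric matrix (diagonal NA) from an upper-triangle vector in
# edge_index() order.
matrix_from_upper_tri <- function(v, n_regions) {
  m <- matrix(NA_real_, n_regions, n_regions)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Read and write per-subject inputs and FC matrices as TSV
#'
#' Time-series files are tab-separated with `T` rows by `R` columns and a
#' header row of region names; the filename stem is the subject id. FC
#' matrix files are `R x R` with header and row labels and `NA` on the
#' diagonal.
#'
#' @param path File path.
#' @param tr_seconds Repetition time recorded on the returned object.
#' @return `read_time_series` returns a `bold_ts`; `read_fc_matrix` an
#'   `fc_matrix`; the writers return `path` invisibly.
#' @export
read_time_series <- function(path, tr_seconds = 3.0) {
  if (!file.exists(path)) stop("time-series file not found: ", path, call. = FALSE)
  values <- as.matrix(utils::read.delim(path, check.names = FALSE))
  subject_id <- sub("\\.[^.]*$", "", basename(path))
  bold_time_series(subject_id, values, tr_seconds)
}

#' @rdname read_time_series
#' @param ts A `bold_ts` object.
#' @export
write_time_series <- function(ts, path) {
  stopifnot(inherits(ts, "bold_ts"))
  utils::write.table(format_num(ts$values), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname read_time_series
#' @export
read_fc_matrix <- function(path) {
  if (!file.exists(path)) stop("FC matrix file not found: ", path, call. = FALSE)
  m <- as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
  fc_matrix(sub("\\.[^.]*$", "", basename(path)), m)
}

#' @rdname read_time_series
#' @param fc An `fc_matrix` object.
#' @export
write_fc_matrix <- function(fc, path) {
  stopifnot(inherits(fc, "fc_matrix"))
  z <- fc$z
  if (is.null(rownames(z))) {
    rownames(z) <- colnames(z) <- sprintf("region_%03d", seq_len(nrow(z)) - 1L)
  }
  out <- cbind(region = rownames(z), as.data.frame(format_num(z)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Fixed-width significant-digit formatting so rewritten files are
# byte-identical across runs regardless of options(digits).
format_num <- function(x) {
  out <- format(x, digits = 15, trim = TRUE, scientific = FALSE)
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}
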