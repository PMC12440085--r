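#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up procedure: with sorted p-values `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{k >= i} p_(k) * m / k`, capped at 1 and mapped back to the
#' input order. Implemented via [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level used for the significance mask (default 0.05).
#' @return List with `q` (adjusted p-values) and `significant`
#'   (`q <= alpha`).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  bad <- which(!is.finite(p) | p < 0 | p > 1)
  if (length(bad) > 0L) {
    stop("invalid p-value: ", format(p[bad[1L]]), " (must be in [0, 1])",
         call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0, 1)", call. = FALSE)
  }
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = q <= alpha)
}

#' Grouped Benjamini-Hochberg adjustment
#'
#' Applies [bh_fdr()] independently within each level of `group_label`
#' (e.g. the anatomical division of each region, so the FDR is controlled
#' within each lobe) and reassembles the results in input order.
#'
#' @param p Numeric vector of p-values.
#' @param group_label Vector of group labels, same length as `p`.
#' @inheritParams bh_fdr
#' @return List with `q` and `significant` in input order.
#' @export
grouped_bh_fdr <- function(p, group_label, alpha = 0.05) {
  if (length(group_label) != length(p)) {
    stop("group_label must have the same length as p", call. = FALSE)
  }
  q <- numeric(length(p))
  for (g in unique(group_label)) {
    idx <- which(group_label == g)
    q[idx] <- bh_fdr(p[idx], alpha)$q
  }
  list(q = q, significant = q <= alpha)
}
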