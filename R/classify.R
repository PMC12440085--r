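#' Banded sign of a Fisher-z connectivity value
#'
#' Connectivity values inside the noise band (default `(-0.05, +0.05)`) are
#' treated as effectively zero: correlations of that magnitude represent
#' negligible functional relationships regardless of sign, so categorical
#' interpretation should not read noise-level fluctuation as a transition
#' between positive and negative connectivity. Values at or beyond the band
#' boundary count as meaningful (`P` or `N`); the band is an open interval.
#'
#' @param z Numeric vector of finite Fisher-z values.
#' @param threshold Positive half-width of the band (default 0.05).
#' @return Character vector: `"P"` (`z >= +threshold`), `"N"`
#'   (`z <= -threshold`), `"Z"` (inside the band).
#' @export
band_sign <- function(z, threshold = 0.05) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive value", call. = FALSE)
  }
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  ifelse(z >= threshold, "P", ifelse(z <= -threshold, "N", "Z"))
}

CROSS_SECTIONAL_CATEGORIES <- c(
  "stronger_positive_in_A", "stronger_positive_in_B",
  "stronger_negative_in_A", "stronger_negative_in_B", "indeterminate"
)

LONGITUDINAL_CATEGORIES <- c(
  "more_positive", "less_positive", "more_negative", "less_negative",
  "sign_transition", "indeterminate"
)

#' Directional classification of a significant cross-sectional edge
#'
#' Given the two group mean Fisher-z values at a significant edge, decides
#' which group carries the stronger meaningful (out-of-band) connectivity
#' and in which sign. With `d = mean_a - mean_b`:
#' * `stronger_positive_in_A` if `d > 0` and A's mean is meaningfully
#'   positive;
#' * `stronger_negative_in_B` if `d > 0` and B's mean is meaningfully
#'   negative (and symmetrically for `d < 0`);
#' * when both hold (one group clearly positive, the other clearly
#'   negative) the tie is broken toward the group with the larger absolute
#'   mean, preferring the positive category on an exact tie;
#' * both means inside the band yield `indeterminate`.
#'
#' Non-significant edges receive the `not_classified` sentinel.
#'
#' @param mean_a,mean_b Numeric vectors of group mean z values.
#' @param significant Logical vector.
#' @param threshold Noise-band half-width (default 0.05).
#' @return Character vector of categories.
#' @export
classify_cross_sectional <- function(mean_a, mean_b, significant,
                                     threshold = 0.05) {
  n <- length(mean_a)
  stopifnot(length(mean_b) == n, length(significant) == n)
  sa <- band_sign(mean_a, threshold)
  sb <- band_sign(mean_b, threshold)
  d <- mean_a - mean_b
  out <- character(n)
  for (k in seq_len(n)) {
    if (!significant[k]) { out[k] <- "not_classified"; next }
    if (sa[k] == "Z" && sb[k] == "Z") { out[k] <- "indeterminate"; next }
    if (d[k] > 0) {
      pos_a <- sa[k] == "P"
      neg_b <- sb[k] == "N"
      out[k] <- if (pos_a && neg_b) {
        if (abs(mean_b[k]) > abs(mean_a[k])) "stronger_negative_in_B"
        else "stronger_positive_in_A"
      } else if (pos_a) "stronger_positive_in_A"
      else if (neg_b) "stronger_negative_in_B"
      else "indeterminate"
    } else if (d[k] < 0) {
      pos_b <- sb[k] == "P"
      neg_a <- sa[k] == "N"
      out[k] <- if (pos_b && neg_a) {
        if (abs(mean_a[k]) > abs(mean_b[k])) "stronger_negative_in_A"
        else "stronger_positive_in_B"
      } else if (pos_b) "stronger_positive_in_B"
      else if (neg_a) "stronger_negative_in_A"
      else "indeterminate"
    } else {
      out[k] <- "indeterminate"
    }
  }
  out
}

#' Directional classification of a significant longitudinal edge
#'
#' Classifies the pre-to-post evolution of an edge's mean Fisher-z into the
#' four-bar scheme (connections becoming more/less positively or more/less
#' negatively connected), using banded pre/post signs so noise-level
#' fluctuations are never read as sign changes. A genuine crossing from
#' meaningful positive to meaningful negative connectivity (or vice versa)
#' is labelled `sign_transition`; both means inside the band yield
#' `indeterminate`.
#'
#' @param mean_pre,mean_post Numeric vectors of mean z values.
#' @param significant Logical vector.
#' @param threshold Noise-band half-width (default 0.05).
#' @return Character vector of categories.
#' @export
classify_longitudinal <- function(mean_pre, mean_post, significant,
                                  threshold = 0.05) {
  n <- length(mean_pre)
  stopifnot(length(mean_post) == n, length(significant) == n)
  sp <- band_sign(mean_pre, threshold)
  sq <- band_sign(mean_post, threshold)
  d <- mean_post - mean_pre
  out <- character(n)
  for (k in seq_len(n)) {
    if (!significant[k]) { out[k] <- "not_classified"; next }
    out[k] <- if ((sp[k] == "P" && sq[k] == "N") ||
                  (sp[k] == "N" && sq[k] == "P")) "sign_transition"
    else if (sq[k] == "P" && d[k] > 0 && sp[k] %in% c("P", "Z")) "more_positive"
    else if (sp[k] == "P" && d[k] < 0 && sq[k] %in% c("P", "Z")) "less_positive"
    else if (sq[k] == "N" && d[k] < 0 && sp[k] %in% c("N", "Z")) "more_negative"
    else if (sp[k] == "N" && d[k] > 0 && sq[k] %in% c("N", "Z")) "less_negative"
    else "indeterminate"
  }
  out
}

#' Tally classified edge categories
#'
#' @param categories Character vector of edge categories (sentinel
#'   `not_classified` entries are dropped).
#' @param levels Category vocabulary; defaults to the union of the
#'   cross-sectional and longitudinal sets restricted to what is present.
#' @return Data frame with `category`, `count` and `proportion`
#'   (count / total classified; zero when the input is empty).
#' @export
count_categories <- function(categories, levels = NULL) {
  categories <- categories[categories != "not_classified"]
  if (is.null(levels)) {
    known <- c(CROSS_SECTIONAL_CATEGORIES, LONGITUDINAL_CATEGORIES)
    levels <- unique(c(intersect(known, categories), setdiff(categories, known)))
    if (length(levels) == 0L) levels <- character(0L)
  }
  counts <- table(factor(categories, levels = levels))
  total <- sum(counts)
  data.frame(
    category = names(counts),
    count = as.integer(counts),
    proportion = if (total > 0) as.numeric(counts) / total else rep(0, length(counts))
  )
}

#' Attach region labels and categories to the significant edges of a contrast
#'
#' Convenience layer joining a [edgewise_group_contrast()] result with a
#' region metadata table: keeps the significant edges, classifies them
#' (cross-sectionally by default), and adds the lobe and network of both
#' endpoints — the long table behind chord, bubble and hub displays.
#'
#' @param contrast A `group_contrast` data frame.
#' @param meta A `region_meta` table.
#' @param threshold Noise-band half-width.
#' @param kind `"cross_sectional"` or `"longitudinal"`. For
#'   `"longitudinal"`, supply `mean_pre`/`mean_post` (per-edge vectors in
#'   [edge_index()] order, e.g. an arm's mean pre and post z) — the
#'   contrast's own columns are change-score means and carry no banded sign.
#' @param mean_pre,mean_post Optional per-edge mean z vectors for
#'   longitudinal classification.
#' @return Data frame of significant edges with columns `edge_i`, `edge_j`,
#'   `category`, `delta_z`, `q`, `weight`, `lobe_i`, `lobe_j`, `network_i`,
#'   `network_j`, `hemisphere_i`, `hemisphere_j`.
#' @export
classify_edges <- function(contrast, meta, threshold = 0.05,
                           kind = c("cross_sectional", "longitudinal"),
                           mean_pre = NULL, mean_post = NULL) {
  stopifnot(inherits(contrast, "group_contrast"))
  kind <- match.arg(kind)
  meta <- validate_region_meta(meta)
  if (kind == "cross_sectional") {
    category <- classify_cross_sectional(contrast$mean_a, contrast$mean_b,
                                         contrast$significant, threshold)
  } else {
    if (is.null(mean_pre) || is.null(mean_post)) {
      stop("longitudinal classification needs mean_pre and mean_post", call. = FALSE)
    }
    category <- classify_longitudinal(mean_pre, mean_post,
                                      contrast$significant, threshold)
  }
  keep <- contrast$significant
  idx_i <- contrast$edge_i[keep] + 1L
  idx_j <- contrast$edge_j[keep] + 1L
  data.frame(
    edge_i = contrast$edge_i[keep],
    edge_j = contrast$edge_j[keep],
    category = category[keep],
    delta_z = contrast$delta_z[keep],
    q = contrast$q[keep],
    weight = contrast$weight[keep],
    lobe_i = meta$lobe[idx_i],
    lobe_j = meta$lobe[idx_j],
    network_i = meta$network[idx_i],
    network_j = meta$network[idx_j],
    hemisphere_i = meta$hemisphere[idx_i],
    hemisphere_j = meta$hemisphere[idx_j]
  )
}

#' Aggregate classified edges into a label-pair table
#'
#' Sums edge counts and weights into a symmetric matrix over hemisphere,
#' lobe or network labels; edges joining two regions with the same label
#' land on the diagonal. The aggregation conserves both the number of edges
#' and the total weight.
#'
#' @param edges Data frame with `edge_i`, `edge_j` and `weight` columns
#'   (e.g. from [classify_edges()]).
#' @param meta A `region_meta` table covering every region id in `edges`.
#' @param level `"hemisphere"`, `"lobe"` or `"network"`.
#' @return List of class `pair_table` with `level`, `labels`, `count`
#'   (integer matrix) and `weight` (numeric matrix).
#' @export
aggregate_pairs <- function(edges, meta,
                            level = c("hemisphere", "lobe", "network")) {
  level <- match.arg(level)
  meta <- validate_region_meta(meta)
  labels <- switch(level, hemisphere = HEMISPHERES, lobe = LOBES,
                   network = NETWORKS)
  L <- length(labels)
  count <- matrix(0L, L, L, dimnames = list(labels, labels))
  weight <- matrix(0, L, L, dimnames = list(labels, labels))
  if (nrow(edges) > 0L) {
    bad <- setdiff(c(edges$edge_i, edges$edge_j), meta$region_id)
    if (length(bad) > 0L) {
      stop("unknown region_id in edge table: ", bad[1L], call. = FALSE)
    }
    lab_i <- meta[[level]][edges$edge_i + 1L]
    lab_j <- meta[[level]][edges$edge_j + 1L]
    for (k in seq_len(nrow(edges))) {
      a <- lab_i[k]; b <- lab_j[k]
      count[a, b] <- count[a, b] + 1L
      weight[a, b] <- weight[a, b] + edges$weight[k]
      if (a != b) {
        count[b, a] <- count[b, a] + 1L
        weight[b, a] <- weight[b, a] + edges$weight[k]
      }
    }
  }
  structure(list(level = level, labels = labels, count = count,
                 weight = weight),
            class = "pair_table")
}

#' Per-region hub summary of significant edges
#'
#' Degree and weight summary per region over a set of significant classified
#' edges: number of touching edges, total edge weight, and the partner
#' region of the maximum-weight edge. Sorted by degree (descending), weight
#' (descending), then region id — a deterministic order suitable for hub
#' maps where node size tracks degree and line width tracks weight.
#'
#' @inheritParams aggregate_pairs
#' @return Data frame with `region_id`, `name`, `n_connections`,
#'   `total_weight`, `strongest_partner`; empty for an empty edge list.
#' @export
hub_table <- function(edges, meta) {
  meta <- validate_region_meta(meta)
  if (nrow(edges) == 0L) {
    return(data.frame(region_id = integer(0L), name = character(0L),
                      n_connections = integer(0L), total_weight = numeric(0L),
                      strongest_partner = integer(0L)))
  }
  long <- data.frame(
    region = c(edges$edge_i, edges$edge_j),
    partner = c(edges$edge_j, edges$edge_i),
    weight = rep(edges$weight, 2L)
  )
  ids <- sort(unique(long$region))
  rows <- lapply(ids, function(id) {
    sub <- long[long$region == id, , drop = FALSE]
    best <- sub$partner[which.max(sub$weight)]
    data.frame(region_id = id, name = meta$name[id + 1L],
               n_connections = nrow(sub), total_weight = sum(sub$weight),
               strongest_partner = best)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_connections, -out$total_weight, out$region_id), ]
  rownames(out) <- NULL
  out
}

#' Export a pair table in chord-diagram long format
#'
#' Writes one row per unordered label pair with a nonzero count:
#' `from_label`, `to_label`, `count`, `weight`. An empty table produces a
#' header-only file. Ribbon width in a chord renderer maps naturally onto
#' `weight` (the summed significance-weighted effect magnitudes).
#'
#' @param pair_table A [aggregate_pairs()] result.
#' @param path Output TSV path.
#' @export
export_chord_table <- function(pair_table, path) {
  stopifnot(inherits(pair_table, "pair_table"))
  L <- length(pair_table$labels)
  rows <- list()
  for (a in seq_len(L)) {
    for (b in a:L) {
      if (pair_table$count[a, b] > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          from_label = pair_table$labels[a],
          to_label = pair_table$labels[b],
          count = pair_table$count[a, b],
          weight = pair_table$weight[a, b]
        )
      }
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(from_label = character(0L), to_label = character(0L),
               count = integer(0L), weight = numeric(0L))
  }
  if (nrow(out) > 0L) out$weight <- format(out$weight, digits = 15, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
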