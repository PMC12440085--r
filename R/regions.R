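#' Label vocabularies for brain parcellations
#'
#' The parcellation metadata used throughout the package tags every region
#' with a hemisphere, an anatomical division ("lobe") and a resting-state
#' functional network. These constants enumerate the admissible labels:
#' two hemispheres, eight anatomical divisions and nine functional networks.
#'
#' @format Character vectors.
#' @name region_labels
NULL

#' @rdname region_labels
#' @export
HEMISPHERES <- c("Left", "Right")

#' @rdname region_labels
#' @export
LOBES <- c("Frontal", "Temporal", "Parietal", "Occipital", "Limbic",
           "Cerebellum", "Subcortical", "Insular")

#' @rdname region_labels
#' @export
NETWORKS <- c("Auditory", "Cerebellar", "Default Mode", "Dorsal Attention",
              "Executive Control", "Salience", "Sensorimotor", "Subcortical",
              "Visual")

#' Construct and validate a region metadata table
#'
#' A region metadata table has one row per parcellation region with columns
#' `region_id` (0-based, contiguous), `name`, `hemisphere`, `lobe` and
#' `network`. Labels must come from [HEMISPHERES], [LOBES] and [NETWORKS].
#'
#' @param region_id Integer vector of 0-based region indices, contiguous
#'   `0..R-1` after sorting.
#' @param name Character vector of region names (unique).
#' @param hemisphere,lobe,network Character vectors of labels.
#' @return A `data.frame` of class `region_meta`, ordered by `region_id`.
#' @export
region_meta <- function(region_id, name, hemisphere, lobe, network) {
  meta <- data.frame(
    region_id = as.integer(region_id),
    name = as.character(name),
    hemisphere = as.character(hemisphere),
    lobe = as.character(lobe),
    network = as.character(network),
    stringsAsFactors = FALSE
  )
  validate_region_meta(meta)
}

#' @rdname region_meta
#' @param meta A data frame with the columns listed above.
#' @export
validate_region_meta <- function(meta) {
  required <- c("region_id", "name", "hemisphere", "lobe", "network")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop("region metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  meta <- meta[order(meta$region_id), required, drop = FALSE]
  rownames(meta) <- NULL
  ids <- meta$region_id
  if (anyDuplicated(ids)) {
    stop("duplicate region_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (!identical(as.integer(ids), seq_len(nrow(meta)) - 1L)) {
    stop("region_id must be contiguous 0..R-1", call. = FALSE)
  }
  check_labels <- function(values, allowed, what) {
    bad <- which(!(values %in% allowed))
    if (length(bad) > 0L) {
      stop(sprintf("unknown %s label %s in row %d",
                   what, dQuote(values[bad[1L]]), bad[1L]), call. = FALSE)
    }
  }
  check_labels(meta$hemisphere, HEMISPHERES, "hemisphere")
  check_labels(meta$lobe, LOBES, "lobe")
  check_labels(meta$network, NETWORKS, "network")
  class(meta) <- c("region_meta", "data.frame")
  meta
}

#' Read or write a region metadata table as TSV
#'
#' @param path Path to a tab-separated file with columns `region_id`,
#'   `name`, `hemisphere`, `lobe`, `network`.
#' @return `read_region_meta` returns a validated `region_meta` data frame;
#'   `write_region_meta` writes the file and returns `path` invisibly.
#' @export
read_region_meta <- function(path) {
  if (!file.exists(path)) stop("region metadata file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_region_meta(raw)
}

#' @rdname read_region_meta
#' @param meta A `region_meta` table.
#' @export
write_region_meta <- function(meta, path) {
  meta <- validate_region_meta(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Generate a balanced synthetic parcellation
#'
#' Builds a region metadata table for `n_regions` regions whose hemisphere,
#' lobe and network labels cover both hemispheres, all eight anatomical
#' divisions and all nine functional networks as evenly as possible. The
#' assignment is a seeded permutation of balanced label pools, so the table
#' is reproducible for a fixed seed.
#'
#' @param n_regions Number of regions; must be at least 8 so every lobe can
#'   be represented.
#' @param seed Integer seed controlling the label permutation.
#' @return A `region_meta` data frame with `n_regions` rows.
#' @export
make_parcellation <- function(n_regions, seed = 1L) {
  if (n_regions < 8L) {
    stop("n_regions must be >= 8 to cover all anatomical divisions", call. = FALSE)
  }
  balanced <- function(pool, n) rep(pool, length.out = n)
  perm <- with_seed(as.integer(seed), {
    list(
      lobe = sample(balanced(LOBES, n_regions)),
      network = sample(balanced(NETWORKS, n_regions)),
      hemisphere = sample(balanced(HEMISPHERES, n_regions))
    )
  })
  name <- sprintf("%s_%s_%03d",
                  abbreviate(gsub(" ", "", perm$lobe), 6),
                  substr(perm$hemisphere, 1, 1),
                  seq_len(n_regions) - 1L)
  region_meta(
    region_id = seq_len(n_regions) - 1L,
    name = name,
    hemisphere = perm$hemisphere,
    lobe = perm$lobe,
    network = perm$network
  )
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. All randomness in the package flows through
# this helper so no operation reads ambient entropy.
with_seed <- function(seed, expr) {
  if (!is.finite(seed)) stop("seed must be a finite integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
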