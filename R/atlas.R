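#' Generate a synthetic cortical + striatal parcellation table
#'
#' Builds an atlas with `2 * n_cortical_per_hemisphere` cortical regions and
#' four striatal nodes (left/right caudate and putamen). Cortical centroids
#' are drawn uniformly in a right-hemisphere box (positive first coordinate,
#' millimetres) with a minimum pairwise separation, and mirrored through the
#' midsagittal plane so left/right homologues sit at (-x, y, z) / (x, y, z).
#' The separation guarantee keeps nearest-centroid sample matching
#' well-posed at the default donor jitter.
#'
#' @param n_cortical_per_hemisphere Number of cortical regions per hemisphere
#'   (>= 2); the default emulates a 34-per-hemisphere (68 cortical ROI)
#'   Desikan-style parcellation.
#' @param seed Integer seed; the atlas is a pure function of its arguments.
#' @param min_separation Minimum Euclidean distance (mm) between cortical
#'   centroids within a hemisphere.
#' @return A data.frame of class `atlas_table` with columns `roi_id`, `name`,
#'   `hemisphere` (`"L"`/`"R"`), `node_class` (`"cortical"`/`"striatal"`),
#'   `x`, `y`, `z`.
#' @examples
#' atlas <- generate_atlas(34, seed = 1)
#' table(atlas$node_class)
#' @export
generate_atlas <- function(n_cortical_per_hemisphere = 34L, seed = 1L,
                           min_separation = 12) {
  n <- assert_count(n_cortical_per_hemisphere, "n_cortical_per_hemisphere",
                    min = 2L)
  pts <- with_seed(seed, sample_separated_points(
    n, min_separation,
    lo = c(12, -100, -40), hi = c(70, 70, 80)))
  cortical_R <- data.frame(
    name = sprintf("ctx_R_%03d", seq_len(n)), hemisphere = "R",
    node_class = "cortical", x = pts[, 1], y = pts[, 2], z = pts[, 3],
    stringsAsFactors = FALSE)
  cortical_L <- cortical_R
  cortical_L$name <- sprintf("ctx_L_%03d", seq_len(n))
  cortical_L$hemisphere <- "L"
  cortical_L$x <- -cortical_L$x
  striatal <- data.frame(
    name = c("caudate_L", "caudate_R", "putamen_L", "putamen_R"),
    hemisphere = c("L", "R", "L", "R"),
    node_class = "striatal",
    x = c(-15, 15, -26, 26), y = c(10, 10, 0, 0), z = c(15, 15, 0, 0),
    stringsAsFactors = FALSE)
  atlas <- rbind(cortical_L, cortical_R, striatal)
  atlas <- cbind(roi_id = seq_len(nrow(atlas)), atlas)
  rownames(atlas) <- NULL
  class(atlas) <- c("atlas_table", "data.frame")
  atlas
}

# Rejection-sample n points in a box with pairwise min distance.
sample_separated_points <- function(n, min_sep, lo, hi) {
  pts <- matrix(NA_real_, n, 3L)
  k <- 0L
  tries <- 0L
  while (k < n) {
    cand <- stats::runif(3L, lo, hi)
    ok <- k == 0L ||
      min(sqrt(colSums((t(pts[seq_len(k), , drop = FALSE]) - cand)^2))) >=
        min_sep
    if (ok) {
      k <- k + 1L
      pts[k, ] <- cand
    }
    tries <- tries + 1L
    if (tries > 10000L * n)
      stop("could not place centroids at the requested separation")
  }
  pts
}

#' @export
print.atlas_table <- function(x, ...) {
  cat(sprintf("atlas_table: %d ROIs (%d cortical, %d striatal)\n",
              nrow(x), sum(x$node_class == "cortical"),
              sum(x$node_class == "striatal")))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' @keywords internal
cortical_names <- function(atlas) atlas$name[atlas$node_class == "cortical"]

#' @keywords internal
striatal_names <- function(atlas) atlas$name[atlas$node_class == "striatal"]

#' @keywords internal
validate_atlas <- function(atlas) {
  stopifnot(is.data.frame(atlas))
  need <- c("roi_id", "name", "hemisphere", "node_class", "x", "y", "z")
  miss <- setdiff(need, names(atlas))
  if (length(miss))
    stop("atlas is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(atlas$roi_id) || !identical(sort(atlas$roi_id),
                                                seq_len(nrow(atlas))))
    stop("atlas roi_ids must be unique and contiguous from 1")
  if (!all(atlas$hemisphere %in% c("L", "R")))
    stop("atlas hemisphere must be 'L' or 'R'")
  if (!all(atlas$node_class %in% c("cortical", "striatal")))
    stop("atlas node_class must be 'cortical' or 'striatal'")
  str_names <- atlas$name[atlas$node_class == "striatal"]
  if (!all(grepl("^(caudate|putamen)", str_names)))
    stop("striatal nodes must be caudate or putamen")
  invisible(atlas)
}

#' Read / write an atlas table
#'
#' Plain TSV with columns roi_id, name, hemisphere, node_class, x, y, z.
#' @param atlas An `atlas_table`.
#' @param path File path.
#' @return `read_atlas` returns an `atlas_table`; `write_atlas` its path,
#'   invisibly.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  write_tsv(as.data.frame(atlas), path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  atlas <- read_tsv(path)
  validate_atlas(atlas)
  class(atlas) <- c("atlas_table", "data.frame")
  atlas
}
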