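#' Collapse probe-level expression to gene level
#'
#' Unweighted mean over the probes mapped to each gene; sample order is
#' preserved.
#'
#' @param probe_matrix Probe x sample numeric matrix with probe ids as
#'   rownames.
#' @param probe_map Data frame with columns `probe_id`, `gene`.
#' @return Gene x sample matrix.
#' @export
collapse_probes <- function(probe_matrix, probe_map) {
  probe_matrix <- as.matrix(probe_matrix)
  if (is.null(rownames(probe_matrix))) stop("probe_matrix needs rownames")
  unmapped <- setdiff(rownames(probe_matrix), probe_map$probe_id)
  if (length(unmapped))
    stop("unmapped probes: ", paste(utils::head(unmapped, 10), collapse = ", "))
  gene <- probe_map$gene[match(rownames(probe_matrix), probe_map$probe_id)]
  sums <- rowsum(probe_matrix, gene)
  counts <- as.vector(table(gene)[rownames(sums)])
  out <- sums / counts
  out[order(rownames(out)), , drop = FALSE]
}

#' Assign donor samples to atlas regions by nearest centroid
#'
#' Each sample is matched to the cortical ROI with the nearest centroid
#' (Euclidean distance, shared coordinate frame assumed). Samples farther
#' than `radius` from every cortical centroid are left unassigned; exact
#' ties go to the lowest roi_id.
#'
#' @param sample_coords Data frame with columns `sample_id`, `x`, `y`, `z`.
#' @param atlas An `atlas_table`.
#' @param radius Rejection radius in mm.
#' @return Data frame `sample_id`, `roi` (NA when unmatched), `distance`.
#' @export
match_regions <- function(sample_coords, atlas, radius = 20) {
  validate_atlas(atlas)
  if (!nrow(sample_coords)) stop("empty sample set")
  cort <- atlas[atlas$node_class == "cortical", ]
  cent <- as.matrix(cort[, c("x", "y", "z")])
  pts <- as.matrix(sample_coords[, c("x", "y", "z")])
  # n_samples x n_rois distance matrix
  d2 <- outer(rowSums(pts^2), rep(1, nrow(cent))) +
    outer(rep(1, nrow(pts)), rowSums(cent^2)) - 2 * pts %*% t(cent)
  d2[d2 < 0] <- 0
  best <- max.col(-d2, ties.method = "first")   # lowest roi index on ties
  dist <- sqrt(d2[cbind(seq_len(nrow(pts)), best)])
  roi <- cort$name[best]
  roi[dist > radius] <- NA_character_
  data.frame(sample_id = sample_coords$sample_id, roi = roi,
             distance = dist, stringsAsFactors = FALSE)
}

#' Build the regional gene x ROI expression matrix
#'
#' Two-stage averaging: gene values are averaged over a region's samples
#' within each donor, then across the donors that sampled that region, so
#' donors with more samples do not dominate. Probe collapse and region
#' matching are applied per donor. Regions with no samples in any donor are
#' dropped with a warning.
#'
#' @param dset A `donor_expression_set`.
#' @param atlas An `atlas_table`.
#' @param assignments Optional list (one data.frame per donor, as returned
#'   by [match_regions()]); computed from sample coordinates when `NULL`.
#' @param radius Matching radius passed to [match_regions()].
#' @return An `expression_matrix`: gene x ROI matrix with attributes
#'   `excluded_rois` (unsampled regions) and `provenance` (donor indices).
#' @export
regional_expression <- function(dset, atlas, assignments = NULL,
                                radius = 20) {
  stopifnot(inherits(dset, "donor_expression_set"))
  validate_atlas(atlas)
  if (!length(dset$donors)) stop("need >= 1 donor")
  rois <- cortical_names(atlas)
  if (is.null(assignments))
    assignments <- lapply(dset$donors, function(d)
      match_regions(d$samples, atlas, radius = radius))
  donor_means <- lapply(seq_along(dset$donors), function(i) {
    don <- dset$donors[[i]]
    genes_x_sample <- collapse_probes(don$values, dset$probe_map)
    asg <- assignments[[i]]
    asg <- asg[match(colnames(genes_x_sample), asg$sample_id), ]
    keep <- !is.na(asg$roi)
    if (!any(keep)) return(NULL)
    m <- genes_x_sample[, keep, drop = FALSE]
    sums <- t(rowsum(t(m), asg$roi[keep]))
    cnt <- as.vector(table(asg$roi[keep])[colnames(sums)])
    sweep(sums, 2L, cnt, "/")
  })
  genes <- rownames(donor_means[[which(!vapply(donor_means, is.null,
                                               logical(1)))[1]]])
  acc <- matrix(0, length(genes), length(rois),
                dimnames = list(genes, rois))
  nobs <- matrix(0L, length(genes), length(rois),
                 dimnames = list(genes, rois))
  for (dm in donor_means) {
    if (is.null(dm)) next
    cols <- intersect(colnames(dm), rois)
    acc[, cols] <- acc[, cols] + dm[, cols, drop = FALSE]
    nobs[, cols] <- nobs[, cols] + 1L
  }
  covered <- colSums(nobs) > 0
  if (!all(covered))
    warning("dropping regions with no samples in any donor: ",
            paste(rois[!covered], collapse = ", "))
  if (!any(covered)) stop("no region was sampled by any donor")
  values <- (acc / pmax(nobs, 1L))[, covered, drop = FALSE]
  structure(values, class = c("expression_matrix", "matrix", "array"),
            excluded_rois = rois[!covered],
            provenance = seq_along(dset$donors))
}

#' Quality-control filter on regional expression columns
#'
#' Computes two per-region summaries across genes -- the mean and the range
#' (max - min) -- and excludes regions where either summary exceeds its
#' cross-region mean + `z_threshold` standard deviations (single pass, not
#' iterated). With `statistic = "mean"` or `"range"` only that summary is
#' tested.
#'
#' @param m An `expression_matrix` (or gene x ROI matrix).
#' @param z_threshold Exclusion threshold in cross-region SD units.
#' @param statistic Which summaries can trigger exclusion.
#' @return The filtered `expression_matrix`; excluded regions and their
#'   statistics are recorded in attribute `qc_report`.
#' @export
qc_filter_rois <- function(m, z_threshold = 2,
                           statistic = c("either", "mean", "range")) {
  statistic <- match.arg(statistic)
  if (ncol(m) < 3L) stop("need >= 3 regions for QC")
  mu <- colMeans(m)
  rng <- apply(m, 2L, function(x) diff(range(x)))
  flag <- function(s) s > mean(s) + z_threshold * stats::sd(s)
  bad <- switch(statistic,
                either = flag(mu) | flag(rng),
                mean = flag(mu),
                range = flag(rng))
  bad[is.na(bad)] <- FALSE
  if (all(bad)) stop("QC excluded every region")
  report <- data.frame(roi = colnames(m), mean = mu, range = rng,
                       excluded = bad, row.names = NULL,
                       stringsAsFactors = FALSE)
  out <- m[, !bad, drop = FALSE]
  structure(out, class = c("expression_matrix", "matrix", "array"),
            excluded_rois = c(attr(m, "excluded_rois"),
                              colnames(m)[bad]),
            provenance = attr(m, "provenance"),
            qc_report = report)
}

#' Donor resampling of the regional expression matrix
#'
#' Rebuilds the gene x ROI matrix over donor subsets: `leave_one_out` drops
#' each donor in turn; `choose_k` draws `n_subsets` distinct donor subsets
#' of size `k` (seeded sampling without replacement from the C(n, k)
#' possible subsets).
#'
#' @param dset A `donor_expression_set`.
#' @param atlas An `atlas_table`.
#' @param mode `"leave_one_out"` or `"choose_k"`.
#' @param k Subset size for `choose_k`.
#' @param n_subsets Number of subsets for `choose_k`.
#' @param seed Integer seed (used by `choose_k`).
#' @param radius Matching radius.
#' @return Named list of `expression_matrix` objects; names record the
#'   donors used.
#' @export
donor_resamples <- function(dset, atlas, mode = c("leave_one_out", "choose_k"),
                            k = NULL, n_subsets = NULL, seed = 1L,
                            radius = 20) {
  mode <- match.arg(mode)
  stopifnot(inherits(dset, "donor_expression_set"))
  nd <- length(dset$donors)
  subset_dset <- function(idx) {
    sub <- dset
    sub$donors <- dset$donors[idx]
    sub
  }
  if (mode == "leave_one_out") {
    if (nd < 2L) stop("leave_one_out needs >= 2 donors")
    subsets <- lapply(seq_len(nd), function(i) setdiff(seq_len(nd), i))
    names(subsets) <- sprintf("drop_donor%02d", seq_len(nd))
  } else {
    k <- assert_count(k, "k")
    n_subsets <- assert_count(n_subsets, "n_subsets")
    if (k >= nd) stop("choose_k needs k < n_donors")
    all_subsets <- utils::combn(nd, k, simplify = FALSE)
    if (n_subsets > length(all_subsets))
      stop(sprintf("n_subsets exceeds C(%d, %d) = %d", nd, k,
                   length(all_subsets)))
    pick <- with_seed(seed, sample.int(length(all_subsets), n_subsets))
    subsets <- all_subsets[pick]
    names(subsets) <- vapply(subsets, function(s)
      paste0("donors_", paste(s, collapse = "_")), character(1))
  }
  out <- lapply(subsets, function(idx) {
    em <- regional_expression(subset_dset(idx), atlas, radius = radius)
    attr(em, "provenance") <- idx
    em
  })
  out
}

#' Write / read a regional expression matrix (TSV, genes x ROIs)
#' @param m An `expression_matrix`.
#' @param path File path.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), as.data.frame(unclass(m),
                                                     check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  structure(m, class = c("expression_matrix", "matrix", "array"),
            excluded_rois = character(), provenance = NULL)
}
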