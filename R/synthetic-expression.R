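#' Generate donor-level probe expression with a planted regional gradient
#'
#' Emulates a multi-donor microarray atlas: each donor contributes samples
#' whose coordinates are the cortical ROI centroids plus isotropic Gaussian
#' jitter, and each gene is measured by one or more probes. The probe value
#' for gene g at a sample near ROI r is
#' `baseline_g + amplitude * loading_g * gradient_r + Normal(0, noise_sd)`,
#' with `loading` and `gradient` the planted ground-truth vectors rescaled
#' to unit variance (so `amplitude` and `noise_sd` share a scale), plus a
#' per-probe offset; a second planted component is added the same way when
#' the truth carries one. Baselines are Normal(8, 1) on a log2-like scale.
#'
#' @param atlas An `atlas_table`.
#' @param n_genes Number of genes (must match `truth$gene_loadings`).
#' @param n_donors Number of donors (>= 1; resampling modes need >= 2).
#' @param truth A `ground_truth`.
#' @param probes_per_gene Probes measuring each gene (>= 1).
#' @param seed Integer seed.
#' @param samples_per_roi Samples per cortical ROI per donor.
#' @param jitter_sd Isotropic sd (mm) of sample coordinates around the ROI
#'   centroid.
#' @param amplitude Strength of the planted latent component on the
#'   expression scale.
#' @param n_nuisance Number of additional unplanted latent components
#'   (random loading/gradient pairs at the same amplitude, drawn from the
#'   call's seed). Real transcriptome atlases carry many comparable spatial
#'   expression components besides any one pattern of interest; these
#'   nuisance components are biological (shared across donors and probes)
#'   and give the regional matrix realistic rank.
#' @return A `donor_expression_set`: list with `donors` (per donor: `samples`
#'   data.frame of sample_id/x/y/z/roi (true assignment), `values` probe x
#'   sample matrix), `probe_map` (data.frame probe_id, gene), `genes`,
#'   and the generating `truth`.
#' @export
generate_expression <- function(atlas, n_genes, n_donors, truth,
                                probes_per_gene = 2L, seed = 1L,
                                samples_per_roi = 1L, jitter_sd = 2,
                                amplitude = 1, n_nuisance = 10L) {
  validate_atlas(atlas)
  stopifnot(inherits(truth, "ground_truth"))
  n_genes <- assert_count(n_genes, "n_genes", min = 10L)
  n_donors <- assert_count(n_donors, "n_donors", min = 1L)
  probes_per_gene <- assert_count(probes_per_gene, "probes_per_gene")
  samples_per_roi <- assert_count(samples_per_roi, "samples_per_roi")
  genes <- names(truth$gene_loadings)
  if (length(genes) != n_genes)
    stop("n_genes does not match truth$gene_loadings")
  rois <- cortical_names(atlas)
  cent <- as.matrix(atlas[atlas$node_class == "cortical", c("x", "y", "z")])
  rownames(cent) <- rois

  comps <- list(list(l = scale_unit_sd(truth$gene_loadings),
                     g = scale_unit_sd(truth$roi_gradient)))
  if (!is.null(truth$gene_loadings2))
    comps <- c(comps, list(list(l = scale_unit_sd(truth$gene_loadings2),
                                g = scale_unit_sd(truth$roi_gradient2))))

  probe_map <- data.frame(
    probe_id = sprintf("p%05d", seq_len(n_genes * probes_per_gene)),
    gene = rep(genes, each = probes_per_gene),
    stringsAsFactors = FALSE)

  n_nuisance <- assert_count(n_nuisance, "n_nuisance", min = 0L)
  with_seed(seed, {
    baseline <- stats::setNames(stats::rnorm(n_genes, 8, 1), genes)
    for (k in seq_len(n_nuisance))
      comps <- c(comps, list(list(
        l = stats::setNames(stats::rnorm(n_genes), genes),
        g = stats::setNames(stats::rnorm(length(rois)), rois))))
    # small fixed probe offsets around the gene baseline
    probe_offset <- if (probes_per_gene > 1L)
      stats::rnorm(nrow(probe_map), 0, 0.1) else rep(0, nrow(probe_map))
    donors <- lapply(seq_len(n_donors), function(d) {
      roi_of_sample <- rep(rois, each = samples_per_roi)
      ns <- length(roi_of_sample)
      coords <- cent[roi_of_sample, , drop = FALSE] +
        matrix(stats::rnorm(ns * 3L, 0, jitter_sd), ns, 3L)
      samples <- data.frame(
        sample_id = sprintf("d%02d_s%03d", d, seq_len(ns)),
        x = coords[, 1], y = coords[, 2], z = coords[, 3],
        roi = roi_of_sample, stringsAsFactors = FALSE)
      signal <- matrix(0, n_genes, ns)
      for (comp in comps)
        signal <- signal + amplitude * outer(comp$l, comp$g[roi_of_sample])
      gene_vals <- baseline + signal
      vals <- gene_vals[probe_map$gene, , drop = FALSE] + probe_offset +
        matrix(stats::rnorm(nrow(probe_map) * ns, 0, truth$noise_sd),
               nrow(probe_map), ns)
      dimnames(vals) <- list(probe_map$probe_id, samples$sample_id)
      list(samples = samples, values = vals)
    })
    structure(list(donors = donors, probe_map = probe_map, genes = genes,
                   truth = truth),
              class = "donor_expression_set")
  })
}

#' @export
print.donor_expression_set <- function(x, ...) {
  cat(sprintf(
    "donor_expression_set: %d donors, %d probes / %d genes, %d samples each\n",
    length(x$donors), nrow(x$probe_map), length(x$genes),
    nrow(x$donors[[1]]$samples)))
  invisible(x)
}

#' Write / read a donor expression set as plain TSV files
#'
#' One `<prefix>_donor<k>.tsv` per donor (columns sample_id, x, y, z then one
#' column per probe) plus `<prefix>_probe_map.tsv` (probe_id, gene).
#' @param dset A `donor_expression_set`.
#' @param prefix Path prefix for the written files.
#' @export
write_expression_set <- function(dset, prefix) {
  stopifnot(inherits(dset, "donor_expression_set"))
  for (d in seq_along(dset$donors)) {
    don <- dset$donors[[d]]
    df <- cbind(don$samples[, c("sample_id", "x", "y", "z")],
                as.data.frame(t(don$values), check.names = FALSE))
    write_tsv(df, sprintf("%s_donor%02d.tsv", prefix, d))
  }
  write_tsv(dset$probe_map, paste0(prefix, "_probe_map.tsv"))
  invisible(prefix)
}

#' @rdname write_expression_set
#' @export
read_expression_set <- function(prefix) {
  probe_map <- read_tsv(paste0(prefix, "_probe_map.tsv"))
  files <- sort(Sys.glob(sprintf("%s_donor*.tsv", prefix)))
  if (!length(files)) stop("no donor files found for prefix ", prefix)
  donors <- lapply(files, function(f) {
    df <- read_tsv(f)
    samples <- df[, c("sample_id", "x", "y", "z")]
    vals <- t(as.matrix(df[, setdiff(names(df),
                                     c("sample_id", "x", "y", "z")),
                           drop = FALSE]))
    colnames(vals) <- samples$sample_id
    list(samples = samples, values = vals)
  })
  structure(list(donors = donors, probe_map = probe_map,
                 genes = unique(probe_map$gene), truth = NULL),
            class = "donor_expression_set")
}
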