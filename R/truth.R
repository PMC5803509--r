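#' Planted ground truth for synthetic studies
#'
#' A `ground_truth` object records the latent structure a synthetic study is
#' built around: a unit-norm atrophy gradient over cortical ROIs, a unit-norm
#' gene-loading vector over the gene universe, the ids of gene sets planted
#' to be enriched, and the expression noise level. An optional second
#' latent component (orthogonal gradient and disjoint loading pattern) lets a
#' study plant two dissociated expression/atrophy patterns, e.g. one driving
#' corticostriatal plus interhemispheric loss and one driving
#' intrahemispheric loss.
#'
#' @param roi_gradient Named numeric vector over cortical ROI names; scaled
#'   to unit Euclidean norm.
#' @param gene_loadings Named numeric vector over gene ids; scaled to unit
#'   Euclidean norm.
#' @param planted_sets Character vector of gene-set ids expected to be
#'   recovered as enriched (may be empty).
#' @param noise_sd Standard deviation of the additive expression noise, on
#'   the same log2-like scale as the expression values.
#' @param roi_gradient2,gene_loadings2 Optional second latent component;
#'   `roi_gradient2` is orthogonalized against `roi_gradient` and both are
#'   unit-normalized.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(roi_gradient, gene_loadings,
                         planted_sets = character(), noise_sd = 0.5,
                         roi_gradient2 = NULL, gene_loadings2 = NULL) {
  stopifnot(!is.null(names(roi_gradient)), !is.null(names(gene_loadings)))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  out <- list(
    roi_gradient = unit_norm(roi_gradient),
    gene_loadings = unit_norm(gene_loadings),
    planted_sets = as.character(planted_sets),
    noise_sd = noise_sd)
  if (!is.null(roi_gradient2)) {
    g1 <- out$roi_gradient
    g2 <- roi_gradient2 - sum(roi_gradient2 * g1) * g1
    out$roi_gradient2 <- unit_norm(g2)
    out$gene_loadings2 <- unit_norm(gene_loadings2)
  }
  class(out) <- "ground_truth"
  out
}

#' Draw a random ground truth for an atlas
#'
#' Gradients and loadings are standard-normal draws, unit-normalized; with
#' `two_components = TRUE` a second gradient orthogonal to the first and an
#' independent loading vector are added.
#'
#' @param atlas An `atlas_table`.
#' @param n_genes Number of genes in the universe (ids `g0001`, ...).
#' @param seed Integer seed.
#' @param noise_sd Expression noise standard deviation.
#' @param two_components Plant a second, orthogonal latent component.
#' @return A `ground_truth` object.
#' @export
random_ground_truth <- function(atlas, n_genes, seed, noise_sd = 0.5,
                                two_components = FALSE) {
  validate_atlas(atlas)
  n_genes <- assert_count(n_genes, "n_genes", min = 10L)
  rois <- cortical_names(atlas)
  genes <- sprintf("g%04d", seq_len(n_genes))
  with_seed(seed, {
    grad <- stats::setNames(stats::rnorm(length(rois)), rois)
    load <- stats::setNames(stats::rnorm(n_genes), genes)
    if (two_components) {
      grad2 <- stats::setNames(stats::rnorm(length(rois)), rois)
      load2 <- stats::setNames(stats::rnorm(n_genes), genes)
      ground_truth(grad, load, noise_sd = noise_sd,
                   roi_gradient2 = grad2, gene_loadings2 = load2)
    } else {
      ground_truth(grad, load, noise_sd = noise_sd)
    }
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground_truth: %d ROIs, %d genes, noise_sd = %g, %d planted set(s)%s\n",
    length(x$roi_gradient), length(x$gene_loadings), x$noise_sd,
    length(x$planted_sets),
    if (!is.null(x$roi_gradient2)) ", 2 latent components" else ""))
  invisible(x)
}

#' Write / read ground truth as JSON
#' @param truth A `ground_truth`.
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  payload <- unclass(truth)
  for (f in c("roi_gradient", "gene_loadings", "roi_gradient2",
              "gene_loadings2"))
    if (!is.null(payload[[f]])) payload[[f]] <- as.list(payload[[f]])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(unlist(raw$roi_gradient), unlist(raw$gene_loadings),
               planted_sets = raw$planted_sets %||% character(),
               noise_sd = raw$noise_sd,
               roi_gradient2 = if (!is.null(raw$roi_gradient2))
                 unlist(raw$roi_gradient2),
               gene_loadings2 = if (!is.null(raw$gene_loadings2))
                 unlist(raw$gene_loadings2))
}

# Gradient rescaled so max |entry| = 1: effect sizes then read as the
# maximal fractional edge-weight loss.
#' @keywords internal
scale_max_abs <- function(v) {
  m <- max(abs(v))
  if (m == 0) return(v)
  v / m
}

# Loading/gradient vectors rescaled to unit variance for the expression
# forward model, so `amplitude` is on the same scale as `noise_sd`.
#' @keywords internal
scale_unit_sd <- function(v) {
  s <- stats::sd(v)
  if (s == 0) return(v)
  v / s
}
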