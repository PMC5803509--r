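#' Generate a gene-set collection with planted enriched terms
#'
#' Unplanted terms draw members uniformly from the gene universe. A planted
#' term of size s with top-fraction f draws `round(f * s)` members from the
#' s genes with the largest loading and the remainder from the rest of the
#' universe, so its members concentrate at the top of the loading-ranked
#' list. By default the signed loading is used (the pole that aligns with
#' atrophy after sign alignment, hence recoverable from the descending
#' weight ranking); `plant_by = "abs"` ranks by |loading| instead.
#'
#' @param genes Character vector: the gene universe.
#' @param n_terms Number of terms.
#' @param size_range Length-2 integer vector: inclusive term-size range.
#' @param planted Named numeric vector `term_id -> top fraction` in (0, 1];
#'   names must be a subset of the generated term ids `set001`, ... , or new
#'   ids appended after the random terms.
#' @param seed Integer seed.
#' @param loadings Named numeric vector used to rank genes for planting
#'   (e.g. `truth$gene_loadings`); required when `planted` is non-empty.
#' @param plant_by Rank genes by `"signed"` (default) or `"abs"` loading
#'   when drawing planted members.
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `description` attribute per term.
#' @export
generate_gene_sets <- function(genes, n_terms, size_range = c(10L, 50L),
                               planted = numeric(), seed = 1L,
                               loadings = NULL,
                               plant_by = c("signed", "abs")) {
  plant_by <- match.arg(plant_by)
  n_terms <- assert_count(n_terms, "n_terms")
  size_range <- as.integer(size_range)
  if (length(size_range) != 2L || size_range[1] < 2L ||
      size_range[2] > length(genes) || size_range[1] > size_range[2])
    stop("size_range must lie within [2, length(genes)]")
  if (length(planted)) {
    if (any(planted <= 0 | planted > 1))
      stop("planted fractions must lie in (0, 1]")
    if (is.null(loadings)) stop("planting requires `loadings`")
    stopifnot(setequal(names(loadings), genes))
  }
  with_seed(seed, {
    ids <- sprintf("set%03d", seq_len(n_terms))
    extra <- setdiff(names(planted), ids)
    ids <- c(ids, extra)
    ranked_by_loading <- if (!is.null(loadings)) {
      key <- if (plant_by == "abs") abs(loadings[genes]) else loadings[genes]
      names(sort(key, decreasing = TRUE))
    } else NULL
    sets <- lapply(ids, function(id) {
      size <- if (size_range[1] == size_range[2]) size_range[1]
              else sample(seq(size_range[1], size_range[2]), 1L)
      if (id %in% names(planted)) {
        k_top <- max(1L, round(planted[[id]] * size))
        pool <- ranked_by_loading[seq_len(size)]
        top <- sample(pool, k_top)
        rest <- sample(setdiff(genes, pool), size - k_top)
        members <- c(top, rest)
      } else {
        members <- sample(genes, size)
      }
      sort(members)
    })
    names(sets) <- ids
    desc <- ifelse(ids %in% names(planted),
                   "planted enriched term", "random term")
    gene_set_collection(sets, descriptions = stats::setNames(desc, ids))
  })
}

#' Construct a gene-set collection
#' @param sets Named list of character vectors (term id -> members).
#' @param descriptions Optional named character vector of term descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  sets <- lapply(sets, function(m) sort(unique(as.character(m))))
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(sets, descriptions = descriptions[names(sets)],
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("gene_set_collection: %d terms, sizes %d-%d\n",
              length(x), min(sizes), max(sizes)))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' One tab-separated line per term: term id, description, then members.
#' @param sets A `gene_set_collection`.
#' @param path File path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]] %||% "", sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  desc <- vapply(parts, `[`, character(1), 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  gene_set_collection(sets, descriptions = stats::setNames(desc, ids))
}

#' Generate a log2 fold-change table rank-correlated with planted loadings
#'
#' Uses a Gaussian-copula construction: the loadings are rank-transformed to
#' normal scores and mixed with independent noise at the Pearson correlation
#' `2 * sin(pi * target / 6)` that induces the requested Spearman correlation
#' for bivariate normal pairs. Targets of +/-1 reproduce the exact
#' (anti-)ranking.
#'
#' @param truth A `ground_truth`.
#' @param target_correlation Desired Spearman correlation with
#'   `truth$gene_loadings`, in [-1, 1].
#' @param seed Integer seed.
#' @return A data.frame with columns `gene` and `log2fc`.
#' @export
generate_foldchange <- function(truth, target_correlation, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (abs(target_correlation) > 1)
    stop("target_correlation must lie in [-1, 1]")
  l <- truth$gene_loadings
  n <- length(l)
  with_seed(seed, {
    z1 <- stats::qnorm((rank(l, ties.method = "first") - 0.5) / n)
    if (abs(target_correlation) == 1) {
      z2 <- sign(target_correlation) * z1
    } else {
      r <- 2 * sin(pi * target_correlation / 6)
      z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
    }
    data.frame(gene = names(l), log2fc = z2, stringsAsFactors = FALSE)
  })
}

#' Write / read a log2 fold-change table (TSV: gene, log2fc)
#' @param fc Data frame with columns `gene`, `log2fc`.
#' @param path File path.
#' @export
write_foldchange <- function(fc, path) write_tsv(fc, path)

#' @rdname write_foldchange
#' @export
read_foldchange <- function(path) read_tsv(path)
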