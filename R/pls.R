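#' Partial least squares regression of regional loss on regional expression
#'
#' Fits a SIMPLS-style PLS: columns of the ROI x gene predictor matrix and
#' the ROI x response matrix are z-scored across ROIs, then each component's
#' gene-weight vector is the dominant left singular vector of the (deflated)
#' cross-covariance `t(X) %*% Y`, which maximizes covariance between the
#' X-score `X w` and the responses. Deflation projects the cross-covariance
#' onto the orthogonal complement of the fitted X-loadings, so successive
#' X-scores are mutually orthogonal. Per-component fractions of response
#' variance explained are incremental R-squared values from regressing the
#' standardized responses on the cumulative scores.
#'
#' @param X ROI x gene numeric matrix (rows = regions; must carry dimnames).
#' @param Y ROI x response matrix (same rows as `X`).
#' @param n_components Number of components; truncated with a warning when
#'   it exceeds the rank bound.
#' @return A `pls_model`: list with `gene_weights` (gene x component,
#'   unit-norm columns), `roi_scores` (ROI x component), `x_loadings`,
#'   `y_loadings`, `y_variance_fraction`, `n_components`, `sign_convention`
#'   (flips applied by [align_sign()]), `genes`, `rois`, `constant_genes`.
#' @examples
#' X <- matrix(rnorm(80), 10, 8, dimnames = list(paste0("r", 1:10),
#'                                               paste0("g", 1:8)))
#' Y <- cbind(loss = X[, 3] + rnorm(10, 0, 0.1))
#' fit <- fit_pls(X, Y, 2)
#' fit$y_variance_fraction
#' @export
fit_pls <- function(X, Y, n_components = 2L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same ROI rows")
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%04d", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("y%d", seq_len(ncol(Y)))
  if (is.null(rownames(X))) rownames(X) <- sprintf("roi%03d", seq_len(nrow(X)))
  n_components <- assert_count(n_components, "n_components")
  ysd <- apply(Y, 2L, stats::sd)
  if (any(ysd == 0)) stop("constant response column: ",
                          paste(colnames(Y)[ysd == 0], collapse = ", "))
  Xs <- zscore_cols(X)
  Ys <- zscore_cols(Y)
  const <- attr(Xs, "constant")
  rank_bound <- min(nrow(X) - 1L, sum(!const))
  if (n_components > rank_bound) {
    warning(sprintf("n_components truncated from %d to rank bound %d",
                    n_components, rank_bound))
    n_components <- rank_bound
  }
  p <- ncol(X)
  W <- matrix(0, p, n_components,
              dimnames = list(colnames(X), paste0("comp", seq_len(n_components))))
  Tm <- matrix(0, nrow(X), n_components,
               dimnames = list(rownames(X), colnames(W)))
  P <- matrix(0, p, n_components, dimnames = dimnames(W))
  Q <- matrix(0, ncol(Y), n_components,
              dimnames = list(colnames(Y), colnames(W)))
  V <- matrix(0, p, n_components)
  S <- crossprod(Xs, Ys)
  for (a in seq_len(n_components)) {
    sv <- svd(S, nu = 1L, nv = 0L)
    w <- drop(sv$u)
    t_a <- drop(Xs %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) {
      warning(sprintf("component %d degenerate; truncating model", a))
      n_components <- a - 1L
      W <- W[, seq_len(n_components), drop = FALSE]
      Tm <- Tm[, seq_len(n_components), drop = FALSE]
      P <- P[, seq_len(n_components), drop = FALSE]
      Q <- Q[, seq_len(n_components), drop = FALSE]
      break
    }
    p_a <- drop(crossprod(Xs, t_a)) / tt
    q_a <- drop(crossprod(Ys, t_a)) / tt
    v <- p_a
    if (a > 1L) {
      prev <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    W[, a] <- w
    Tm[, a] <- t_a
    P[, a] <- p_a
    Q[, a] <- q_a
    V[, a] <- v
  }
  model <- structure(list(
    n_components = n_components,
    gene_weights = W, roi_scores = Tm, x_loadings = P, y_loadings = Q,
    y_variance_fraction = numeric(0),
    sign_convention = rep(1, n_components),
    genes = colnames(X), rois = rownames(X),
    responses = colnames(Y), constant_genes = colnames(X)[const],
    Ys = Ys), class = "pls_model")
  model$y_variance_fraction <- variance_explained(model)$fraction
  model
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d components, %d genes, %d ROIs, %d response(s)\n",
              x$n_components, length(x$genes), length(x$rois),
              length(x$responses)))
  if (x$n_components)
    cat("  Y-variance fraction:",
        paste(sprintf("%.3f", x$y_variance_fraction), collapse = ", "), "\n")
  invisible(x)
}

#' Per-component and cumulative response variance explained
#'
#' The fraction for component a is the increment in the regression
#' sum-of-squares of the standardized responses on the first a ROI scores,
#' relative to the total response sum-of-squares.
#'
#' @param model A `pls_model`.
#' @param Y Optional response matrix; defaults to the standardized responses
#'   stored at fit time.
#' @return Data frame `component`, `fraction`, `cumulative`.
#' @export
variance_explained <- function(model, Y = NULL) {
  stopifnot(inherits(model, "pls_model"))
  Ys <- if (is.null(Y)) model$Ys else zscore_cols(as.matrix(Y))
  if (!model$n_components)
    return(data.frame(component = integer(0), fraction = numeric(0),
                      cumulative = numeric(0)))
  sst <- sum(Ys^2)
  cum <- vapply(seq_len(model$n_components), function(a) {
    Tc <- model$roi_scores[, seq_len(a), drop = FALSE]
    fit <- Tc %*% qr.solve(crossprod(Tc), crossprod(Tc, Ys))
    sum(fit^2) / sst
  }, numeric(1))
  data.frame(component = seq_len(model$n_components),
             fraction = diff(c(0, cum)), cumulative = cum)
}

#' Rank genes by their signed PLS weight
#'
#' @param model A `pls_model`.
#' @param component Component index.
#' @param descending `TRUE` for the positive pole first (default); `FALSE`
#'   exposes the ascending (negative-pole) view.
#' @return A `ranked_gene_list` data.frame: `gene`, `weight`, `rank`; ties
#'   broken lexicographically by gene id.
#' @export
gene_ranking <- function(model, component = 1L, descending = TRUE) {
  stopifnot(inherits(model, "pls_model"))
  if (component < 1L || component > model$n_components)
    stop("no such component: ", component)
  w <- model$gene_weights[, component]
  o <- order(if (descending) -w else w, model$genes)
  out <- data.frame(gene = model$genes[o], weight = w[o],
                    rank = seq_along(w), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "component") <- component
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

#' Fix component signs against the first response column
#'
#' PLS component signs are arbitrary; each component is flipped so that the
#' correlation between its ROI scores and the first response column is
#' positive, making "top genes" reproducible. Idempotent; zero correlations
#' leave the component unflipped.
#'
#' @param model A `pls_model`.
#' @return The model with `gene_weights`, `roi_scores`, loadings and
#'   `sign_convention` updated.
#' @export
align_sign <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  y1 <- model$Ys[, 1L]
  for (a in seq_len(model$n_components)) {
    r <- stats::cor(model$roi_scores[, a], y1)
    if (is.na(r) || r == 0) next
    s <- sign(r)
    if (s < 0) {
      model$gene_weights[, a] <- -model$gene_weights[, a]
      model$roi_scores[, a] <- -model$roi_scores[, a]
      model$x_loadings[, a] <- -model$x_loadings[, a]
      model$y_loadings[, a] <- -model$y_loadings[, a]
      model$sign_convention[a] <- -model$sign_convention[a]
    }
  }
  model
}

#' Permutation null for the gene predictor
#'
#' Each replicate permutes the ROI rows of `X` (breaking the X-Y regional
#' correspondence), refits, and records the component-1 response-variance
#' fraction. The empirical p-value uses the add-one correction
#' `(1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param X,Y As in [fit_pls()].
#' @param n_components Components to fit per replicate.
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param seed Integer seed.
#' @param keep_weights Also return the aligned component-1 weight vector of
#'   every replicate (gene x n_perm matrix).
#' @return List with `observed` (component-1 fraction), `null` (numeric
#'   vector), `p_value`, and optionally `null_weights`.
#' @export
permutation_null_genes <- function(X, Y, n_components = 1L, n_perm = 199L,
                                   seed = 1L, keep_weights = FALSE) {
  X <- as.matrix(X)
  fit <- fit_pls(X, Y, n_components)
  obs <- fit$y_variance_fraction[1L]
  with_seed(seed, {
    null <- numeric(n_perm)
    nw <- if (keep_weights)
      matrix(NA_real_, ncol(X), n_perm, dimnames = list(colnames(X), NULL))
    for (i in seq_len(n_perm)) {
      perm <- sample.int(nrow(X))
      f <- align_sign(fit_pls(X[perm, , drop = FALSE], Y, n_components))
      null[i] <- f$y_variance_fraction[1L]
      if (keep_weights) nw[, i] <- f$gene_weights[, 1L]
    }
    out <- list(observed = obs, null = null,
                p_value = (1 + sum(null >= obs)) / (n_perm + 1))
    if (keep_weights) out$null_weights <- nw
    out
  })
}

#' Permutation null for the regional response
#'
#' Permutes the ROI rows of `Y`, refits, and collects aligned component-1
#' ROI scores, giving per-ROI null bands, plus the component-1 variance
#' fraction null.
#'
#' @inheritParams permutation_null_genes
#' @param band Two-sided band coverage (default 0.95).
#' @return List with `observed` (fraction), `observed_scores`, `null`
#'   (fractions), `p_value`, `score_bands` (data.frame roi, lower, upper),
#'   `null_scores` (ROI x n_perm).
#' @export
permutation_null_rois <- function(X, Y, n_components = 1L, n_perm = 199L,
                                  seed = 1L, band = 0.95) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  fit <- align_sign(fit_pls(X, Y, n_components))
  obs <- fit$y_variance_fraction[1L]
  with_seed(seed, {
    null <- numeric(n_perm)
    ns <- matrix(NA_real_, nrow(X), n_perm,
                 dimnames = list(rownames(fit$roi_scores), NULL))
    for (i in seq_len(n_perm)) {
      perm <- sample.int(nrow(Y))
      f <- align_sign(fit_pls(X, Y[perm, , drop = FALSE], n_components))
      null[i] <- f$y_variance_fraction[1L]
      ns[, i] <- f$roi_scores[, 1L]
    }
    alpha <- (1 - band) / 2
    bands <- t(apply(ns, 1L, stats::quantile, probs = c(alpha, 1 - alpha)))
    list(observed = obs, observed_scores = fit$roi_scores[, 1L],
         null = null, p_value = (1 + sum(null >= obs)) / (n_perm + 1),
         score_bands = data.frame(roi = rownames(ns), lower = bands[, 1],
                                  upper = bands[, 2],
                                  stringsAsFactors = FALSE),
         null_scores = ns)
  })
}

#' Gene-weight stability under added predictor noise
#'
#' Adds Normal(0, sigma) noise to the standardized predictor entries,
#' refits, aligns signs, and reports the Spearman correlation between each
#' replicate's component-1 gene weights and the baseline fit's.
#'
#' @param X,Y As in [fit_pls()].
#' @param sigma Noise standard deviation on the standardized scale (>= 0).
#' @param n_rep Number of replicates.
#' @param seed Integer seed.
#' @return List with `correlations` (length `n_rep`), `sigma`, and the
#'   baseline component-1 `weights`.
#' @export
noise_robustness <- function(X, Y, sigma, n_rep = 20L, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  X <- as.matrix(X)
  Xs <- zscore_cols(X)
  base <- align_sign(fit_pls(Xs, Y, 1L))
  w0 <- base$gene_weights[, 1L]
  with_seed(seed, {
    cors <- vapply(seq_len(n_rep), function(i) {
      Xn <- Xs + matrix(stats::rnorm(length(Xs), 0, sigma),
                        nrow(Xs), ncol(Xs))
      f <- align_sign(fit_pls(Xn, Y, 1L))
      stats::cor(f$gene_weights[, 1L], w0, method = "spearman")
    }, numeric(1))
    list(correlations = cors, sigma = sigma, weights = w0)
  })
}
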