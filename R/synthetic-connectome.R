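#' Cohort design for synthetic connectome generation
#'
#' @param n_patients,n_controls Subject counts (>= 2 each).
#' @param timepoints Strictly increasing visit times in months; the default
#'   emulates a three-visit, 24-month longitudinal design.
#' @param effect_size_by_class Named vector / list with entries
#'   `corticostriatal`, `interhemispheric`, `intrahemispheric`, each in
#'   [0, 1): the maximal fractional edge-weight loss of that connection class
#'   in patients at the final visit.
#' @param seed Integer seed; identical specs give identical cohorts.
#' @param effect2_size_by_class Optional effects for the second latent
#'   gradient of a two-component ground truth.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 20L, n_controls = 20L,
                        timepoints = c(0, 12, 24),
                        effect_size_by_class = c(corticostriatal = 0.3,
                                                 interhemispheric = 0.3,
                                                 intrahemispheric = 0.3),
                        seed = 1L, effect2_size_by_class = NULL) {
  n_patients <- assert_count(n_patients, "n_patients", min = 2L)
  n_controls <- assert_count(n_controls, "n_controls", min = 2L)
  if (length(timepoints) < 1L || is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  check_effects <- function(e, what) {
    e <- unlist(e)
    need <- c("corticostriatal", "interhemispheric", "intrahemispheric")
    if (!all(need %in% names(e)))
      stop(what, " must name corticostriatal, interhemispheric and ",
           "intrahemispheric")
    if (any(e < 0 | e >= 1))
      stop(what, " entries must lie in [0, 1)")
    e[need]
  }
  spec <- list(
    n_patients = n_patients, n_controls = n_controls,
    timepoints = as.numeric(timepoints),
    effect_size_by_class = check_effects(effect_size_by_class,
                                         "effect_size_by_class"),
    seed = as.integer(seed))
  if (!is.null(effect2_size_by_class))
    spec$effect2_size_by_class <- check_effects(effect2_size_by_class,
                                                "effect2_size_by_class")
  class(spec) <- "cohort_spec"
  spec
}

#' Generate grouped synthetic connectomes with planted class-specific loss
#'
#' All subjects share one base connectome: an Erdos-Renyi edge mask at the
#' given density with log-normal edge weights, a stand-in for the sparse,
#' heavy-tailed streamline-count structure of tractography-derived networks.
#' Controls are multiplicative log-normal perturbations of the base.
#' Patient edge weights in connection class c are additionally scaled by
#' `prod_k (1 - effect_k[c] * gradient_k(edge) * t / t_max)` (clamped at 0),
#' where `gradient_k(edge)` is the planted cortical gradient (rescaled to
#' max |value| = 1) at the cortical endpoint for corticostriatal edges and
#' the mean over both endpoints for corticocortical edges; atrophy is thus
#' multiplicative in weight and linear in time, so per-subject slopes are
#' well defined.
#'
#' @param atlas An `atlas_table`.
#' @param spec A `cohort_spec`.
#' @param truth A `ground_truth` whose `roi_gradient` is indexed by the
#'   atlas's cortical ROIs.
#' @param density Base edge density of the Erdos-Renyi mask
#'   (cortico-cortical and striato-striatal edges).
#' @param corticostriatal_density Edge density for cortex-striatum pairs;
#'   defaults to 1 because tractography assigns every cortical region
#'   streamlines to the striatum, keeping the per-target response matrix
#'   fully observed.
#' @param weight_meanlog,weight_sdlog Log-normal base edge-weight parameters.
#' @param subject_noise_sd Standard deviation (log scale) of the per-subject,
#'   per-visit multiplicative edge noise.
#' @return A list of `connectome` objects (fields `subject_id`, `group`,
#'   `timepoint`, `weights`), one per subject x visit, with the atlas
#'   attached as attribute `atlas`.
#' @export
generate_cohort_connectomes <- function(atlas, spec, truth, density = 0.35,
                                        corticostriatal_density = 1,
                                        weight_meanlog = log(50),
                                        weight_sdlog = 0.8,
                                        subject_noise_sd = 0.1) {
  validate_atlas(atlas)
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "ground_truth"))
  rois <- cortical_names(atlas)
  if (!setequal(names(truth$roi_gradient), rois))
    stop("truth$roi_gradient must be indexed by the atlas's cortical ROIs")
  n <- nrow(atlas)
  cls <- edge_class_matrix(atlas)
  cls[is.na(cls)] <- "diagonal"
  upper <- upper.tri(matrix(0, n, n))

  grad_edge <- function(gvec) {
    g <- scale_max_abs(gvec[rois])
    node_g <- stats::setNames(rep(0, n), atlas$name)
    node_g[rois] <- g
    m <- matrix(0, n, n, dimnames = list(atlas$name, atlas$name))
    gi <- matrix(node_g, n, n)          # by column: value of row node
    gj <- t(gi)
    # corticostriatal: gradient of the cortical endpoint
    is_cort <- atlas$node_class == "cortical"
    ci <- matrix(is_cort, n, n)
    cj <- t(ci)
    cs <- cls == "corticostriatal"
    m[cs] <- (gi * ci + gj * cj)[cs]
    cc <- cls %in% c("interhemispheric", "intrahemispheric")
    m[cc] <- ((gi + gj) / 2)[cc]
    m
  }

  effects_edge <- function(eff) {
    e <- matrix(0, n, n)
    for (k in names(eff)) e[cls == k] <- eff[[k]]
    e
  }

  with_seed(spec$seed, {
    dens <- matrix(density, n, n)
    dens[cls == "corticostriatal"] <- corticostriatal_density
    mask <- matrix(0L, n, n)
    mask[upper] <- stats::rbinom(sum(upper), 1L, dens[upper])
    mask <- mask + t(mask)
    base <- matrix(0, n, n)
    base[upper] <- stats::rlnorm(sum(upper), weight_meanlog, weight_sdlog)
    base <- (base + t(base)) * mask
    dimnames(base) <- list(atlas$name, atlas$name)

    comps <- list(list(g = grad_edge(truth$roi_gradient),
                       e = effects_edge(spec$effect_size_by_class)))
    if (!is.null(spec$effect2_size_by_class)) {
      if (is.null(truth$roi_gradient2))
        stop("spec has effect2_size_by_class but truth has no roi_gradient2")
      comps <- c(comps, list(list(g = grad_edge(truth$roi_gradient2),
                                  e = effects_edge(spec$effect2_size_by_class))))
    }

    t_max <- max(spec$timepoints)
    if (t_max <= 0) t_max <- 1
    subjects <- data.frame(
      subject_id = c(sprintf("pat%03d", seq_len(spec$n_patients)),
                     sprintf("con%03d", seq_len(spec$n_controls))),
      group = rep(c("patient", "control"),
                  c(spec$n_patients, spec$n_controls)),
      stringsAsFactors = FALSE)

    out <- list()
    for (s in seq_len(nrow(subjects))) {
      for (tp in spec$timepoints) {
        mult <- matrix(1, n, n)
        if (subjects$group[s] == "patient") {
          for (comp in comps)
            mult <- mult * pmax(1 - comp$e * comp$g * (tp / t_max), 0)
        }
        noise <- matrix(0, n, n)
        noise[upper] <- stats::rnorm(sum(upper), 0, subject_noise_sd)
        noise <- exp(noise + t(noise))
        w <- base * mult * noise
        w[mask == 0] <- 0
        diag(w) <- 0
        out[[length(out) + 1L]] <- structure(
          list(subject_id = subjects$subject_id[s],
               group = subjects$group[s],
               timepoint = tp, weights = w),
          class = "connectome")
      }
    }
    attr(out, "atlas") <- atlas
    out
  })
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %s (%s) at %g months, %d nodes, %d edges\n",
              x$subject_id, x$group, x$timepoint, nrow(x$weights),
              sum(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

#' Write / read one connectome adjacency matrix as TSV
#'
#' Square matrix with a header of ROI names; symmetric, zero diagonal.
#' @param conn A `connectome` (or bare matrix for `write_connectome`).
#' @param path File path.
#' @export
write_connectome <- function(conn, path) {
  w <- if (inherits(conn, "connectome")) conn$weights else conn
  utils::write.table(w, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_connectome
#' @param subject_id,group,timepoint Metadata attached to the read matrix.
#' @export
read_connectome <- function(path, subject_id = NA_character_,
                            group = NA_character_, timepoint = NA_real_) {
  w <- as.matrix(read_tsv(path))
  if (nrow(w) != ncol(w)) stop("connectome matrix must be square")
  rownames(w) <- colnames(w)
  structure(list(subject_id = subject_id, group = group,
                 timepoint = timepoint, weights = w),
            class = "connectome")
}
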