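#' Classify an edge by its endpoints' connection class
#'
#' Cortical-striatal edges are corticostriatal; cortical-cortical edges are
#' interhemispheric across hemispheres and intrahemispheric within one;
#' striatal-striatal edges are striatostriatal and excluded from all
#' downstream analyses.
#'
#' @param atlas An `atlas_table`.
#' @param roi_a,roi_b ROI names or roi_ids.
#' @return One of `"corticostriatal"`, `"interhemispheric"`,
#'   `"intrahemispheric"`, `"striatostriatal"`.
#' @examples
#' atlas <- generate_atlas(2, seed = 7)
#' classify_edge(atlas, "ctx_L_001", "caudate_L")
#' @export
classify_edge <- function(atlas, roi_a, roi_b) {
  validate_atlas(atlas)
  find <- function(r) {
    i <- if (is.numeric(r)) match(r, atlas$roi_id) else match(r, atlas$name)
    if (is.na(i)) stop("unknown ROI: ", r)
    i
  }
  i <- find(roi_a)
  j <- find(roi_b)
  cls <- c(atlas$node_class[i], atlas$node_class[j])
  if (all(cls == "striatal")) return("striatostriatal")
  if ("striatal" %in% cls) return("corticostriatal")
  if (atlas$hemisphere[i] == atlas$hemisphere[j]) "intrahemispheric"
  else "interhemispheric"
}

#' Full ROI x ROI matrix of edge classes
#' @param atlas An `atlas_table`.
#' @return Character matrix over atlas nodes; diagonal is `NA`.
#' @export
edge_class_matrix <- function(atlas) {
  validate_atlas(atlas)
  n <- nrow(atlas)
  cortical <- atlas$node_class == "cortical"
  ci <- matrix(cortical, n, n)
  cj <- t(ci)
  same_hemi <- outer(atlas$hemisphere, atlas$hemisphere, "==")
  cls <- matrix("corticostriatal", n, n,
                dimnames = list(atlas$name, atlas$name))
  cls[!ci & !cj] <- "striatostriatal"
  cls[ci & cj & same_hemi] <- "intrahemispheric"
  cls[ci & cj & !same_hemi] <- "interhemispheric"
  diag(cls) <- NA_character_
  cls
}

#' Consensus edge mask from baseline control connectomes
#'
#' An edge is retained iff it is nonzero in at least `threshold` of the
#' baseline-timepoint control subjects; defining topology from healthy
#' anatomy only.
#'
#' @param controls List of `connectome` objects (controls; the earliest
#'   timepoint per subject is used).
#' @param threshold Fraction in (0, 1].
#' @return Logical symmetric matrix over atlas nodes.
#' @export
consensus_mask <- function(controls, threshold = 0.75) {
  if (!length(controls)) stop("need at least one control connectome")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  ids <- vapply(controls, function(c) c$subject_id, character(1))
  tps <- vapply(controls, function(c) c$timepoint, numeric(1))
  keep <- vapply(unique(ids), function(id) {
    which(ids == id)[which.min(tps[ids == id])]
  }, integer(1))
  mats <- lapply(controls[keep], function(c) (c$weights > 0) * 1)
  frac <- Reduce(`+`, mats) / length(mats)
  mask <- frac >= threshold
  diag(mask) <- FALSE
  mask
}

#' Per-ROI connection-class connectivity profile
#'
#' For each cortical ROI: the masked edge weight to each striatal target
#' (one corticostriatal column per striatal node), and the sum of masked
#' edge weights over its interhemispheric and intrahemispheric
#' cortical-cortical connections ("sum" preserves streamline-count
#' semantics; `aggregate = "mean"` averages over retained edges instead).
#'
#' @param conn A `connectome` (or bare weight matrix with dimnames).
#' @param atlas An `atlas_table`.
#' @param mask Logical edge mask (e.g. from [consensus_mask()]); `NULL`
#'   keeps all edges.
#' @param aggregate `"sum"` (default) or `"mean"` over retained
#'   cortical-cortical edges.
#' @return A `roi_class_profile`: numeric matrix, cortical ROIs x columns
#'   `cs_<striatal name>` (4 with the default atlas), `interhemispheric`,
#'   `intrahemispheric`; attributes `subject_id`, `group`, `timepoint`.
#' @export
roi_class_connectivity <- function(conn, atlas, mask = NULL,
                                   aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  validate_atlas(atlas)
  w <- if (inherits(conn, "connectome")) conn$weights else conn
  n <- nrow(atlas)
  if (!all(dim(w) == n)) stop("connectome does not match atlas dimensions")
  if (is.null(mask)) mask <- matrix(TRUE, n, n)
  if (!all(dim(mask) == n)) stop("mask does not match atlas dimensions")
  wm <- w * mask
  cls <- edge_class_matrix(atlas)
  cort <- which(atlas$node_class == "cortical")
  stri <- which(atlas$node_class == "striatal")
  out <- matrix(0, length(cort), length(stri) + 2L,
                dimnames = list(atlas$name[cort],
                                c(paste0("cs_", atlas$name[stri]),
                                  "interhemispheric", "intrahemispheric")))
  out[, seq_along(stri)] <- wm[cort, stri, drop = FALSE]
  for (k in c("interhemispheric", "intrahemispheric")) {
    sel <- cls == k & mask
    sel[is.na(sel)] <- FALSE
    if (aggregate == "sum") {
      out[, k] <- rowSums(wm[cort, , drop = FALSE] *
                            sel[cort, , drop = FALSE])
    } else {
      cnt <- rowSums(sel[cort, , drop = FALSE])
      out[, k] <- ifelse(cnt > 0,
                         rowSums(wm[cort, , drop = FALSE] *
                                   sel[cort, , drop = FALSE]) / pmax(cnt, 1),
                         0)
    }
  }
  structure(out, class = c("roi_class_profile", class(out)),
            subject_id = if (inherits(conn, "connectome")) conn$subject_id,
            group = if (inherits(conn, "connectome")) conn$group,
            timepoint = if (inherits(conn, "connectome")) conn$timepoint)
}

#' Control-referenced atrophy scores
#'
#' Each patient cell is z-scored against the control distribution for the
#' same ROI x column (`z = (x - mean_controls) / sd_controls`) and
#' sign-flipped so loss is positive; the group matrix averages patients.
#' Cells with zero control variance are excluded (set `NA`) and reported.
#'
#' @param patients,controls Lists of `roi_class_profile` matrices with
#'   identical layout (one per subject, single timepoint or slopes).
#' @return List with `per_patient` (ROI x column x patient array), `group`
#'   (ROI x column matrix of patient means), and `excluded` (data.frame of
#'   zero-variance cells).
#' @export
atrophy_scores <- function(patients, controls) {
  if (length(controls) < 2L) stop("need >= 2 control profiles")
  if (!length(patients)) stop("need >= 1 patient profile")
  ref <- patients[[1]]
  all_mats <- c(patients, controls)
  for (m in all_mats)
    if (!identical(dim(m), dim(ref)) ||
        !identical(dimnames(m), dimnames(ref)))
      stop("all profiles must share the same ROI x column layout")
  carr <- simplify2array(lapply(controls, unclass))
  mu <- apply(carr, c(1, 2), mean)
  sdv <- apply(carr, c(1, 2), stats::sd)
  bad <- sdv == 0
  if (all(bad)) stop("all control cells have zero variance")
  sdv[bad] <- NA_real_
  per_patient <- simplify2array(lapply(patients, function(p) {
    -(unclass(p) - mu) / sdv
  }))
  dimnames(per_patient)[[3]] <- vapply(seq_along(patients), function(i) {
    as.character(attr(patients[[i]], "subject_id") %||%
                   sprintf("patient%02d", i))
  }, character(1))
  group <- apply(per_patient, c(1, 2), mean)
  idx <- which(bad, arr.ind = TRUE)
  excluded <- data.frame(
    roi = rownames(ref)[idx[, 1]],
    column = colnames(ref)[idx[, 2]],
    reason = rep("zero control variance", nrow(idx)),
    stringsAsFactors = FALSE)
  list(per_patient = per_patient, group = group, excluded = excluded)
}

#' Per-subject rate of change of connectivity profiles
#'
#' Ordinary least-squares slope across timepoints for every ROI x column,
#' rescaled to units per 12 months. Feed the slope profiles to
#' [atrophy_scores()] to obtain rate-of-atrophy.
#'
#' @param profiles List of `roi_class_profile` matrices for one subject,
#'   in any order; timepoints are read from the `timepoint` attribute (or
#'   supplied via `timepoints`).
#' @param timepoints Optional numeric vector (months) overriding attributes.
#' @return A matrix of slopes with the same layout, `timepoint` attribute
#'   dropped.
#' @export
rate_of_change <- function(profiles, timepoints = NULL) {
  if (length(profiles) < 2L) stop("need >= 2 timepoints to estimate a slope")
  if (is.null(timepoints))
    timepoints <- vapply(profiles, function(p) attr(p, "timepoint"),
                         numeric(1))
  if (anyNA(timepoints)) stop("timepoints missing")
  o <- order(timepoints)
  timepoints <- timepoints[o]
  profiles <- profiles[o]
  ref <- profiles[[1]]
  tc <- timepoints - mean(timepoints)
  denom <- sum(tc^2)
  if (denom == 0) stop("timepoints must not be identical")
  num <- Reduce(`+`, Map(function(p, t) unclass(p) * t, profiles, tc))
  slope <- num / denom * 12    # per year
  structure(slope, class = c("roi_class_profile", class(slope)),
            subject_id = attr(ref, "subject_id"),
            group = attr(ref, "group"), timepoint = NULL)
}

#' Build the response matrix for one analysis class
#'
#' Selects the response columns of a group atrophy matrix for one
#' connection-class analysis: all corticostriatal target columns (ROI x 4
#' with the default atlas) or the single interhemispheric /
#' intrahemispheric column; rows with excluded (`NA`) cells are dropped.
#'
#' @param group_atrophy ROI x column matrix from [atrophy_scores()]`$group`.
#' @param analysis One of `"corticostriatal"`, `"interhemispheric"`,
#'   `"intrahemispheric"`.
#' @return ROI x response matrix.
#' @export
atrophy_response <- function(group_atrophy,
                             analysis = c("corticostriatal",
                                          "interhemispheric",
                                          "intrahemispheric")) {
  analysis <- match.arg(analysis)
  cols <- if (analysis == "corticostriatal")
    grep("^cs_", colnames(group_atrophy), value = TRUE) else analysis
  y <- group_atrophy[, cols, drop = FALSE]
  keep <- stats::complete.cases(y)
  y[keep, , drop = FALSE]
}
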