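#' Simulate a complete study to disk
#'
#' Generates every input the pipeline consumes -- atlas, grouped cohort
#' connectomes (with manifest), donor expression, gene sets, curated gene
#' lists, a fold-change table and the planted ground truth -- and writes
#' them as plain-text files under `dir`, returning a ready-to-run config.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param n_cortical_per_hemisphere,n_genes,n_donors,probes_per_gene
#'   Atlas/expression sizes.
#' @param noise_sd Expression noise SD.
#' @param n_patients,n_controls,timepoints Cohort design.
#' @param effect_size_by_class Planted class effects for the first latent
#'   gradient.
#' @param effect2_size_by_class Optional effects for a second, orthogonal
#'   gradient (`two_components` is implied).
#' @param n_terms,size_range Gene-set collection shape.
#' @param planted_fraction Top-fraction for the planted term(s).
#' @param fc_target Spearman correlation planted between log2 fold changes
#'   and the gene loadings.
#' @param curated_size Size of the planted curated ("disease") gene list
#'   (top positive-loading genes).
#' @param n_nuisance Unplanted latent expression components (see
#'   [generate_expression()]).
#' @return The config list (also written as `config.yaml`), with the truth
#'   at `$truth_path`.
#' @export
simulate_study <- function(dir, seed = 1L, n_cortical_per_hemisphere = 34L,
                           n_genes = 2000L, n_donors = 6L,
                           probes_per_gene = 2L, noise_sd = 0.5,
                           n_patients = 20L, n_controls = 20L,
                           timepoints = c(0, 12, 24),
                           effect_size_by_class = c(corticostriatal = 0.3,
                                                    interhemispheric = 0.3,
                                                    intrahemispheric = 0.3),
                           effect2_size_by_class = NULL,
                           n_terms = 40L, size_range = c(10L, 50L),
                           planted_fraction = 0.9, fc_target = -0.23,
                           curated_size = 25L, n_nuisance = 10L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "connectomes"), showWarnings = FALSE)
  seeds <- derive_seeds(seed, 6L)
  atlas <- generate_atlas(n_cortical_per_hemisphere, seed = seeds[1])
  two <- !is.null(effect2_size_by_class)
  truth <- random_ground_truth(atlas, n_genes, seed = seeds[2],
                               noise_sd = noise_sd, two_components = two)
  spec <- cohort_spec(n_patients, n_controls, timepoints,
                      effect_size_by_class, seed = seeds[3],
                      effect2_size_by_class = effect2_size_by_class)
  conns <- generate_cohort_connectomes(atlas, spec, truth)
  manifest <- data.frame(
    subject_id = vapply(conns, `[[`, character(1), "subject_id"),
    group = vapply(conns, `[[`, character(1), "group"),
    timepoint = vapply(conns, `[[`, numeric(1), "timepoint"),
    path = NA_character_, stringsAsFactors = FALSE)
  manifest$path <- sprintf("connectomes/%s_t%02d.tsv", manifest$subject_id,
                           match(manifest$timepoint, spec$timepoints))
  for (i in seq_along(conns))
    write_connectome(conns[[i]], file.path(dir, manifest$path[i]))
  write_tsv(manifest, file.path(dir, "connectome_manifest.tsv"))
  write_atlas(atlas, file.path(dir, "atlas.tsv"))
  write_ground_truth(truth, file.path(dir, "truth.json"))

  dset <- generate_expression(atlas, n_genes, n_donors, truth,
                              probes_per_gene = probes_per_gene,
                              seed = seeds[4], n_nuisance = n_nuisance)
  write_expression_set(dset, file.path(dir, "expression"))

  planted <- stats::setNames(planted_fraction, "planted_A")
  sets <- generate_gene_sets(truth_genes(truth), n_terms, size_range,
                             planted = planted, seed = seeds[5],
                             loadings = truth$gene_loadings)
  if (two) {
    sets_b <- generate_gene_sets(truth_genes(truth), 1L, size_range,
                                 planted = c(planted_B = planted_fraction),
                                 seed = seeds[5] + 1L,
                                 loadings = truth$gene_loadings2)
    sets <- gene_set_collection(
      c(unclass(sets), unclass(sets_b)["planted_B"]),
      descriptions = c(attr(sets, "descriptions"),
                       attr(sets_b, "descriptions")["planted_B"]))
    truth$planted_sets <- c("planted_A", "planted_B")
  } else {
    truth$planted_sets <- "planted_A"
  }
  write_ground_truth(truth, file.path(dir, "truth.json"))
  write_gmt(sets, file.path(dir, "gene_sets.gmt"))

  fc <- generate_foldchange(truth, fc_target, seed = seeds[6])
  write_foldchange(fc, file.path(dir, "foldchange.tsv"))

  curated <- planted_gene_list(truth, curated_size, pole = "positive")
  write_tsv(data.frame(gene = curated, stringsAsFactors = FALSE),
            file.path(dir, "curated_disease_list.tsv"))

  config <- list(
    inputs = list(
      atlas = "atlas.tsv",
      connectome_manifest = "connectome_manifest.tsv",
      expression_prefix = "expression",
      gene_sets = "gene_sets.gmt",
      foldchange = "foldchange.tsv",
      curated_lists = list(disease = "curated_disease_list.tsv")),
    analysis = list(
      tags = c("corticostriatal", "interhemispheric", "intrahemispheric"),
      modes = c("cross_sectional", "longitudinal"),
      consensus_threshold = 0.75,
      n_components = 2L,
      n_perm = 0L,
      mean_weight_n_perm = 999L,
      seed = seed,
      qc_z_threshold = 2,
      qc_statistic = "either",
      match_radius = 20,
      aggregate = "sum",
      max_term_size = 1000L,
      min_term_size = 3L),
    base_dir = dir,
    truth_path = "truth.json")
  yaml::write_yaml(config[setdiff(names(config), "base_dir")],
                   file.path(dir, "config.yaml"))
  config
}

#' @keywords internal
truth_genes <- function(truth) names(truth$gene_loadings)

#' Top genes of the planted loading vector
#' @param truth A `ground_truth`.
#' @param size List size.
#' @param pole Rank by signed loading (`"positive"`, `"negative"`) or
#'   absolute value (`"abs"`).
#' @param component Latent component (1 or 2).
#' @return Character vector of gene ids.
#' @export
planted_gene_list <- function(truth, size,
                              pole = c("positive", "negative", "abs"),
                              component = 1L) {
  pole <- match.arg(pole)
  l <- if (component == 1L) truth$gene_loadings else truth$gene_loadings2
  key <- switch(pole, positive = -l, negative = l, abs = -abs(l))
  names(sort(key))[seq_len(size)]
}

# Deterministic sub-seeds below 2^31 from one master seed.
#' @keywords internal
derive_seeds <- function(seed, n) {
  as.integer((as.numeric(seed) * 1000003 + 7919 * seq_len(n)) %% 2147483647)
}

#' Load a pipeline configuration from YAML
#'
#' Validates the schema (unknown keys rejected, seeds explicit) and records
#' the directory the relative input paths resolve against.
#'
#' @param path Path to the YAML config.
#' @return Config list.
#' @export
read_config <- function(path) {
  config <- yaml::read_yaml(path)
  config$base_dir <- dirname(normalizePath(path))
  validate_config(config)
}

#' @keywords internal
validate_config <- function(config) {
  top_allowed <- c("inputs", "analysis", "base_dir", "truth_path")
  unknown <- setdiff(names(config), top_allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  in_allowed <- c("atlas", "connectome_manifest", "expression_prefix",
                  "gene_sets", "foldchange", "curated_lists")
  unknown <- setdiff(names(config$inputs), in_allowed)
  if (length(unknown))
    stop("unknown config input keys: ", paste(unknown, collapse = ", "))
  an_allowed <- c("tags", "modes", "consensus_threshold", "n_components",
                  "n_perm", "mean_weight_n_perm", "seed", "qc_z_threshold",
                  "qc_statistic", "match_radius", "aggregate",
                  "max_term_size", "min_term_size", "top_fraction",
                  "cross_sectional_timepoint")
  unknown <- setdiff(names(config$analysis), an_allowed)
  if (length(unknown))
    stop("unknown config analysis keys: ", paste(unknown, collapse = ", "))
  for (k in c("atlas", "connectome_manifest", "expression_prefix",
              "gene_sets"))
    if (is.null(config$inputs[[k]]))
      stop("config input `", k, "` is required")
  if (is.null(config$analysis$seed)) stop("config analysis seed is required")
  config
}

#' @keywords internal
config_path <- function(config, rel) {
  if (is.null(rel)) return(NULL)
  if (!is.null(config$base_dir)) file.path(config$base_dir, rel) else rel
}

#' Run the full analysis pipeline from a config
#'
#' Executes atrophy scoring, expression mapping, PLS and enrichment for each
#' requested connection class and mode. Cross-sectional mode z-scores each
#' patient's baseline class profile against the controls; longitudinal mode
#' first reduces each subject (restricted to subjects observed at every
#' timepoint) to per-year OLS slopes and z-scores those. Deterministic given
#' the config.
#'
#' @param config A config list from [read_config()] / [simulate_study()].
#' @param out_dir Optional directory: report tables are written as TSV.
#' @return An `analysis_report`: list with `analyses` (per tag x mode:
#'   `variance`, `ranked_genes`, `roi_scores`, `enrichment`, optional
#'   `foldchange_correlation`, `curated_enrichment`, `permutation`),
#'   `expression` (the QC-filtered matrix), `qc`, and `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  an <- config$analysis
  paths <- list(
    atlas = config_path(config, config$inputs$atlas),
    manifest = config_path(config, config$inputs$connectome_manifest),
    expression = config_path(config, config$inputs$expression_prefix),
    gene_sets = config_path(config, config$inputs$gene_sets),
    foldchange = config_path(config, config$inputs$foldchange))
  for (k in c("atlas", "manifest", "gene_sets"))
    if (!file.exists(paths[[k]]))
      stop("input file not found (", k, "): ", paths[[k]])

  atlas <- read_atlas(paths$atlas)
  manifest <- read_tsv(paths$manifest)
  conns <- lapply(seq_len(nrow(manifest)), function(i)
    read_connectome(config_path(config, manifest$path[i]),
                    subject_id = manifest$subject_id[i],
                    group = manifest$group[i],
                    timepoint = manifest$timepoint[i]))

  controls <- Filter(function(c) c$group == "control", conns)
  patients <- Filter(function(c) c$group == "patient", conns)
  if (!length(controls) || !length(patients))
    stop("stage connectome_atrophy: need both patient and control subjects")
  mask <- consensus_mask(controls, an$consensus_threshold %||% 0.75)
  prof <- lapply(conns, roi_class_connectivity, atlas = atlas, mask = mask,
                 aggregate = an$aggregate %||% "sum")
  groups <- vapply(conns, `[[`, character(1), "group")
  tps <- vapply(conns, `[[`, numeric(1), "timepoint")
  subj <- vapply(conns, `[[`, character(1), "subject_id")
  all_tps <- sort(unique(tps))
  # cross-sectional visit: the synthetic forward model expresses planted
  # atrophy linearly in time, so the last visit is the analog of a
  # cross-sectional patient-vs-control comparison; configurable.
  cs_tp <- an$cross_sectional_timepoint %||% "last"
  cs_tp <- if (identical(cs_tp, "last")) max(tps)
           else if (identical(cs_tp, "first")) min(tps)
           else as.numeric(cs_tp)
  if (!cs_tp %in% tps) stop("cross_sectional_timepoint not in the data")

  baseline_profiles <- function(g)
    prof[groups == g & tps == cs_tp]
  slope_profiles <- function(g) {
    ids <- unique(subj[groups == g])
    keep <- ids[vapply(ids, function(id)
      setequal(tps[subj == id], all_tps), logical(1))]
    dropped <- setdiff(ids, keep)
    if (length(dropped))
      message("longitudinal mode drops subjects missing visits: ",
              paste(dropped, collapse = ", "))
    lapply(keep, function(id) rate_of_change(prof[subj == id]))
  }

  # expression side
  dset <- read_expression_set(paths$expression)
  em <- regional_expression(dset, atlas, radius = an$match_radius %||% 20)
  em <- qc_filter_rois(em, z_threshold = an$qc_z_threshold %||% 2,
                       statistic = an$qc_statistic %||% "either")
  X_full <- t(unclass(em))    # ROI x gene

  sets <- read_gmt(paths$gene_sets)
  fc <- if (!is.null(paths$foldchange) && file.exists(paths$foldchange))
    read_foldchange(paths$foldchange)
  curated <- lapply(config$inputs$curated_lists, function(p)
    read_tsv(config_path(config, p))$gene)

  modes <- an$modes %||% "cross_sectional"
  tags <- an$tags %||% c("corticostriatal", "interhemispheric",
                         "intrahemispheric")
  atro <- list()
  if ("cross_sectional" %in% modes)
    atro$cross_sectional <- atrophy_scores(baseline_profiles("patient"),
                                           baseline_profiles("control"))
  if ("longitudinal" %in% modes)
    atro$longitudinal <- atrophy_scores(slope_profiles("patient"),
                                        slope_profiles("control"))

  analyses <- list()
  for (mode in modes) {
    for (tag in tags) {
      Y <- atrophy_response(atro[[mode]]$group, tag)
      rois <- intersect(rownames(X_full), rownames(Y))
      if (length(rois) < 3L)
        stop("stage pls: fewer than 3 ROIs shared between expression and ",
             tag, " atrophy")
      X <- X_full[rois, , drop = FALSE]
      Yr <- Y[rois, , drop = FALSE]
      fit <- align_sign(fit_pls(X, Yr, an$n_components %||% 2L))
      ranked <- gene_ranking(fit, 1L)
      enr <- go_enrichment(ranked, sets,
                           max_term_size = an$max_term_size %||% 1000L,
                           min_term_size = an$min_term_size %||% 3L,
                           top_fraction = an$top_fraction)
      w <- stats::setNames(ranked$weight, ranked$gene)
      res <- list(tag = tag, mode = mode,
                  variance = variance_explained(fit),
                  model = fit,
                  ranked_genes = ranked,
                  roi_scores = fit$roi_scores,
                  enrichment = enr)
      if (!is.null(fc))
        res$foldchange_correlation <- weight_foldchange_correlation(w, fc)
      if (length(curated))
        res$curated_enrichment <- lapply(curated, function(g)
          geneset_weight_enrichment(w, g,
                                    n_perm = an$mean_weight_n_perm %||% 999L,
                                    seed = an$seed))
      if ((an$n_perm %||% 0L) > 0L)
        res$permutation <- permutation_null_genes(
          X, Yr, 1L, n_perm = an$n_perm, seed = an$seed)
      analyses[[paste(tag, mode, sep = ".")]] <- res
    }
  }

  report <- structure(list(
    analyses = analyses, expression = em,
    qc = attr(em, "qc_report"),
    atrophy = lapply(atro, `[[`, "group"),
    provenance = pipeline_provenance(config, paths)),
    class = "analysis_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @keywords internal
pipeline_provenance <- function(config, paths) {
  files <- unlist(paths[!vapply(paths, is.null, logical(1))])
  files <- files[file.exists(files)]
  hashes <- tools::md5sum(files)
  cfg <- config[setdiff(names(config), "base_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  list(config_hash = unname(tools::md5sum(tmp)),
       input_hashes = hashes,
       seed = config$analysis$seed,
       package_version = as.character(utils::packageVersion("connectopls")),
       timestamp = NA_character_)  # kept NA so reports are byte-stable
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis_report: %d analyses\n", length(x$analyses)))
  for (a in x$analyses)
    cat(sprintf("  %-18s %-16s comp1 varfrac %.3f, top term %s (q=%.2g)\n",
                a$tag, a$mode, a$variance$fraction[1],
                a$enrichment$term_id[1], a$enrichment$q_value[1]))
  invisible(x)
}

#' Write report tables as TSV (12 significant digits)
#' @param report An `analysis_report`.
#' @param out_dir Output directory.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  old <- options(digits = 12)
  on.exit(options(old))
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 12))
    df
  }
  for (nm in names(report$analyses)) {
    a <- report$analyses[[nm]]
    write_tsv(fmt(a$variance), file.path(out_dir, paste0(nm, "_variance.tsv")))
    write_tsv(fmt(a$ranked_genes),
              file.path(out_dir, paste0(nm, "_gene_weights.tsv")))
    scores <- data.frame(roi = rownames(a$roi_scores),
                         as.data.frame(a$roi_scores), check.names = FALSE)
    write_tsv(fmt(scores), file.path(out_dir, paste0(nm, "_roi_scores.tsv")))
    write_tsv(fmt(a$enrichment),
              file.path(out_dir, paste0(nm, "_enrichment.tsv")))
  }
  if (!is.null(report$qc))
    write_tsv(fmt(report$qc), file.path(out_dir, "expression_qc.tsv"))
  prov <- report$provenance
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Paired ROI-score table for two analyses (spatial dissociation)
#'
#' @param result_a,result_b Two entries of `report$analyses` (or any lists
#'   with a `roi_scores` matrix) fitted on the same ROI set.
#' @param component Component to compare.
#' @return List with `table` (roi, score_a, score_b, rank_a, rank_b) and
#'   `spearman` (correlation between the score vectors).
#' @export
roi_weight_dissociation <- function(result_a, result_b, component = 1L) {
  sa <- result_a$roi_scores[, component]
  sb <- result_b$roi_scores[, component]
  if (!identical(names(sa), names(sb)))
    stop("analyses were fitted on different ROI sets")
  tab <- data.frame(roi = names(sa), score_a = sa, score_b = sb,
                    rank_a = rank(-sa, ties.method = "first"),
                    rank_b = rank(-sb, ties.method = "first"),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab,
       spearman = stats::cor(sa, sb, method = "spearman"))
}
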