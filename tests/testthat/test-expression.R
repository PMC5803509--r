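test_that("collapse_probes averages probes per gene (groupby oracle)", {
  pm <- matrix(c(2, 4), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
  map <- data.frame(probe_id = c("p1", "p2"), gene = c("gA", "gA"))
  expect_equal(unname(collapse_probes(pm, map)["gA", 1]), 3)

  single <- matrix(5, 1, 2, dimnames = list("p1", c("s1", "s2")))
  map1 <- data.frame(probe_id = "p1", gene = "gZ")
  expect_equal(unname(collapse_probes(single, map1)["gZ", ]), c(5, 5))

  # random 50-probe / 10-gene fixture vs independent mean-by-group oracle
  set.seed(5)
  probes <- sprintf("p%02d", 1:50)
  genes10 <- sprintf("g%02d", 1:10)
  map50 <- data.frame(probe_id = probes, gene = sample(genes10, 50, TRUE))
  vals <- matrix(rnorm(50 * 4), 50, 4,
                 dimnames = list(probes, paste0("s", 1:4)))
  got <- collapse_probes(vals, map50)
  for (g in unique(map50$gene)) {
    sel <- map50$probe_id[map50$gene == g]
    oracle <- colMeans(vals[sel, , drop = FALSE])
    expect_equal(got[g, ], oracle)
  }
  expect_error(collapse_probes(vals, map50[-1, ]), "unmapped probes")
})

test_that("match_regions assigns samples to the nearest cortical centroid", {
  atlas <- data.frame(
    roi_id = 1:3, name = c("ctx_L_001", "ctx_L_002", "ctx_R_001"),
    hemisphere = c("L", "L", "R"),
    node_class = "cortical",
    x = c(0, 40, -40), y = 0, z = 0, stringsAsFactors = FALSE)
  sc <- data.frame(sample_id = c("s1", "s2", "s3"),
                   x = c(1, 39, 200), y = 0, z = 0)
  asg <- match_regions(sc, atlas)
  expect_equal(asg$roi, c("ctx_L_001", "ctx_L_002", NA))
  # exact tie between two centroids -> lowest roi_id
  tie <- match_regions(data.frame(sample_id = "t", x = 20, y = 0, z = 0),
                       atlas)
  expect_equal(tie$roi, "ctx_L_001")
  expect_error(match_regions(sc[0, ], atlas), "empty sample set")
})

test_that("jittered synthetic donors are matched 100% to their true ROI", {
  study <- small_study()
  for (don in study$dset$donors) {
    asg <- match_regions(don$samples, study$atlas)
    expect_identical(asg$roi, don$samples$roi)
  }
})

test_that("regional_expression is a two-stage (donor then region) mean", {
  atlas <- generate_atlas(2, seed = 61)
  truth <- random_ground_truth(atlas, 20, seed = 62, noise_sd = 0)
  # one donor, one sample per region: matrix equals sample values
  d1 <- generate_expression(atlas, 20, 1, truth, probes_per_gene = 1,
                            seed = 63, jitter_sd = 0, n_nuisance = 0)
  em1 <- regional_expression(d1, atlas)
  vals <- collapse_probes(d1$donors[[1]]$values, d1$probe_map)
  colnames(vals) <- d1$donors[[1]]$samples$roi
  expect_equal(bare(em1), vals[, colnames(em1)])

  # two donors offset by +2 -> mean is +1
  d2 <- d1
  don2 <- d1$donors[[1]]
  don2$values <- don2$values + 2
  don2$samples$sample_id <- paste0("d2_", don2$samples$sample_id)
  colnames(don2$values) <- don2$samples$sample_id
  d2$donors <- c(d1$donors, list(don2))
  em2 <- regional_expression(d2, atlas)
  expect_equal(bare(em2), bare(em1) + 1)

  # unbalanced samples-per-ROI: two-stage oracle, not pooled mean
  set.seed(64)
  d3 <- generate_expression(atlas, 20, 2, truth, probes_per_gene = 1,
                            seed = 65, samples_per_roi = 3, jitter_sd = 0,
                            n_nuisance = 0)
  # drop two samples of the first ROI from donor 1 -> unbalanced
  keep <- c(-1L, -2L)
  d3$donors[[1]]$samples <- d3$donors[[1]]$samples[keep, ]
  d3$donors[[1]]$values <- d3$donors[[1]]$values[, keep]
  em3 <- regional_expression(d3, atlas)
  oracle <- local({
    per_donor <- lapply(d3$donors, function(don) {
      gv <- collapse_probes(don$values, d3$probe_map)
      sapply(unique(don$samples$roi), function(r)
        rowMeans(gv[, don$samples$roi == r, drop = FALSE]))
    })
    rois <- colnames(em3)
    sapply(rois, function(r) {
      cols <- lapply(per_donor, function(m)
        if (r %in% colnames(m)) m[, r] else NULL)
      Reduce(`+`, Filter(Negate(is.null), cols)) /
        sum(!vapply(cols, is.null, logical(1)))
    })
  })
  expect_equal(bare(em3), oracle[rownames(em3), colnames(em3)])
})

test_that("noise-free end-to-end matrix equals baseline + loading x gradient", {
  atlas <- generate_atlas(4, seed = 71)
  truth <- random_ground_truth(atlas, 30, seed = 72, noise_sd = 0)
  dset <- generate_expression(atlas, 30, 3, truth, probes_per_gene = 3,
                              seed = 73, n_nuisance = 0)
  em <- regional_expression(dset, atlas)
  # reconstruct the planted signal: center per gene and compare to the
  # unit-variance-scaled outer product
  l <- truth$gene_loadings / sd(truth$gene_loadings)
  g <- truth$roi_gradient / sd(truth$roi_gradient)
  planted <- outer(l[rownames(em)], g[colnames(em)])
  centered <- unclass(em) - rowMeans(unclass(em))
  planted_c <- planted - rowMeans(planted)
  expect_equal(centered, planted_c, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("qc_filter_rois excludes constructed outlier columns only", {
  set.seed(81)
  m <- matrix(rnorm(100 * 10, 8, 0.5), 100, 10,
              dimnames = list(sprintf("g%03d", 1:100),
                              sprintf("r%02d", 1:10)))
  ident <- m
  ident[] <- rep(m[, 1], 10)        # identical columns: nothing excluded
  expect_equal(ncol(qc_filter_rois(ident)), 10)

  m_out <- m
  m_out[, "r05"] <- m_out[, "r05"] + 10 * sd(colMeans(m))
  filt <- qc_filter_rois(m_out)
  expect_false("r05" %in% colnames(filt))
  expect_equal(ncol(filt), 9)
  expect_true("r05" %in% attr(filt, "excluded_rois"))

  # infinite threshold is the identity
  expect_equal(ncol(qc_filter_rois(m_out, z_threshold = Inf)), 10)

  # a range-only outlier is caught by the OR rule but not by mean-only
  m_rng <- m
  m_rng[1, "r07"] <- m_rng[1, "r07"] + 30   # one wild value widens range
  m_rng[2, "r07"] <- m_rng[2, "r07"] - 30   # keeps the mean in place
  expect_false("r07" %in% colnames(qc_filter_rois(m_rng)))
  expect_true("r07" %in% colnames(qc_filter_rois(m_rng,
                                                 statistic = "mean")))

  # single pass: the surviving columns pass the thresholds computed on the
  # original matrix (exclusion is not iterated on recomputed statistics)
  report <- attr(filt, "qc_report")
  thr_mean <- mean(report$mean) + 2 * sd(report$mean)
  thr_rng <- mean(report$range) + 2 * sd(report$range)
  surv <- report[!report$excluded, ]
  expect_true(all(surv$mean <= thr_mean & surv$range <= thr_rng))
})

test_that("donor_resamples enumerates leave-one-out and k-subsets", {
  study <- small_study()
  loo <- donor_resamples(study$dset, study$atlas, "leave_one_out")
  expect_length(loo, 3)
  expect_equal(attr(loo[[2]], "provenance"), c(1L, 3L))

  # choose_k: distinct subsets, seeded, full enumeration allowed
  ck <- donor_resamples(study$dset, study$atlas, "choose_k", k = 2,
                        n_subsets = 3, seed = 5)
  expect_length(ck, 3)
  subs <- lapply(ck, attr, "provenance")
  expect_equal(anyDuplicated(subs), 0L)
  all3 <- donor_resamples(study$dset, study$atlas, "choose_k", k = 2,
                          n_subsets = 3L, seed = 9)
  expect_equal(length(unique(lapply(all3, attr, "provenance"))), 3)
  expect_error(donor_resamples(study$dset, study$atlas, "choose_k", k = 2,
                               n_subsets = 4), "exceeds C")
  expect_error(donor_resamples(study$dset, study$atlas, "choose_k", k = 3,
                               n_subsets = 1), "k < n_donors")

  # resampled matrices equal direct reconstruction from the donor subset
  sub <- study$dset
  sub$donors <- sub$donors[subs[[1]]]
  expect_equal(bare(ck[[1]]), bare(regional_expression(sub, study$atlas)))
})

test_that("collapse then regional mapping commutes with gene subsetting", {
  study <- small_study()
  em <- regional_expression(study$dset, study$atlas)
  pick <- c("g0003", "g0050", "g0101")
  sub <- study$dset
  keep <- sub$probe_map$gene %in% pick
  sub$probe_map <- sub$probe_map[keep, ]
  sub$donors <- lapply(sub$donors, function(d) {
    d$values <- d$values[keep, , drop = FALSE]
    d
  })
  em_sub <- regional_expression(sub, study$atlas)
  expect_equal(bare(em_sub), bare(em)[pick, ])
})

test_that("expression matrix TSV round-trips at full precision", {
  study <- small_study()
  em <- regional_expression(study$dset, study$atlas)
  tmp <- tempfile(fileext = ".tsv")
  write_expression_matrix(em, tmp)
  back <- read_expression_matrix(tmp)
  expect_equal(unclass(back), unclass(em), tolerance = 1e-10,
               ignore_attr = TRUE)
})
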