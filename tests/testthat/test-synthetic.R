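test_that("generate_atlas builds a mirrored cortical + striatal table", {
  atlas <- generate_atlas(34, seed = 1)
  expect_equal(nrow(atlas), 72)
  expect_equal(sum(atlas$node_class == "cortical"), 68)
  expect_equal(sum(atlas$node_class == "striatal"), 4)
  expect_setequal(atlas$name[atlas$node_class == "striatal"],
                  c("caudate_L", "caudate_R", "putamen_L", "putamen_R"))

  small <- generate_atlas(2, seed = 7)
  expect_equal(nrow(small), 8)
  expect_true(all(small$x[small$hemisphere == "L" &
                            small$node_class == "cortical"] < 0))
  expect_true(all(small$x[small$hemisphere == "R" &
                            small$node_class == "cortical"] > 0))
  # homologues mirror exactly
  l <- small[small$name == "ctx_L_001", c("x", "y", "z")]
  r <- small[small$name == "ctx_R_001", c("x", "y", "z")]
  expect_equal(unlist(l), unlist(r) * c(-1, 1, 1), ignore_attr = TRUE)

  expect_identical(generate_atlas(5, seed = 3), generate_atlas(5, seed = 3))
  expect_error(generate_atlas(1, seed = 1), "must be an integer >= 2")
})

test_that("cohort connectomes are symmetric, nonnegative, zero-diagonal", {
  study <- small_study()
  for (c in study$conns[c(1, 10, 20)]) {
    expect_true(isSymmetric(c$weights))
    expect_equal(diag(c$weights), rep(0, nrow(c$weights)),
                 ignore_attr = TRUE)
    expect_true(all(c$weights >= 0))
  }
  # seeded determinism
  again <- generate_cohort_connectomes(study$atlas, study$spec, study$truth)
  expect_identical(again[[5]]$weights, study$conns[[5]]$weights)
})

test_that("planted class effect lowers patient corticostriatal weights only", {
  set.seed(42)
  atlas <- generate_atlas(8, seed = 2)
  genes <- 60
  cls <- edge_class_matrix(atlas)
  # nonnegative gradient so every corticostriatal edge loses weight
  grad <- abs(rnorm(16))
  names(grad) <- atlas$name[atlas$node_class == "cortical"]
  deltas <- replicate(25, {
    seed <- sample.int(1e6, 1)
    truth <- ground_truth(grad, setNames(rnorm(genes),
                                         sprintf("g%04d", 1:genes)),
                          noise_sd = 0.3)
    spec <- cohort_spec(4, 4, c(0, 24),
                        effect_size_by_class = c(corticostriatal = 0.3,
                                                 interhemispheric = 0,
                                                 intrahemispheric = 0),
                        seed = seed)
    conns <- generate_cohort_connectomes(atlas, spec, truth)
    final <- Filter(function(c) c$timepoint == 24, conns)
    mean_class <- function(group, klass) {
      ms <- Filter(function(c) c$group == group, final)
      mean(vapply(ms, function(c) {
        sel <- cls == klass & c$weights > 0
        sel[is.na(sel)] <- FALSE
        mean(c$weights[sel])
      }, numeric(1)))
    }
    c(cs = mean_class("patient", "corticostriatal") /
        mean_class("control", "corticostriatal"),
      intra = mean_class("patient", "intrahemispheric") /
        mean_class("control", "intrahemispheric"))
  })
  expect_lt(mean(deltas["cs", ]), 0.95)          # clear loss
  expect_equal(mean(deltas["intra", ]), 1, tolerance = 0.05)  # untouched
})

test_that("null cohort (all effects zero) leaves groups exchangeable", {
  atlas <- generate_atlas(5, seed = 4)
  truth <- random_ground_truth(atlas, 50, seed = 5)
  spec <- cohort_spec(6, 6, c(0, 12),
                      effect_size_by_class = c(corticostriatal = 0,
                                               interhemispheric = 0,
                                               intrahemispheric = 0),
                      seed = 6)
  conns <- generate_cohort_connectomes(atlas, spec, truth)
  final <- Filter(function(c) c$timepoint == 12, conns)
  pick_edges <- function(group) {
    w <- unlist(lapply(Filter(function(c) c$group == group, final),
                       function(c) c$weights[upper.tri(c$weights)]))
    w[w > 0][1:200]
  }
  ks <- suppressWarnings(ks.test(pick_edges("patient"),
                                 pick_edges("control")))
  expect_gt(ks$p.value, 0.01)
})

test_that("expression generator plants baseline + rank-1 latent structure", {
  atlas <- generate_atlas(5, seed = 21)
  truth <- random_ground_truth(atlas, 40, seed = 22, noise_sd = 0)
  dset <- generate_expression(atlas, 40, 1, truth, probes_per_gene = 1,
                              seed = 23, jitter_sd = 0, n_nuisance = 0)
  em <- regional_expression(dset, atlas)
  expect_lte(qr(sweep(unclass(em), 1, 0))$rank, 2)  # baseline + one latent

  # a zero-loading gene is flat across regions at zero noise
  truth0 <- truth
  truth0$gene_loadings["g0005"] <- 0
  dset0 <- generate_expression(atlas, 40, 1, truth0, probes_per_gene = 1,
                               seed = 23, jitter_sd = 0, n_nuisance = 0)
  em0 <- regional_expression(dset0, atlas)
  expect_equal(diff(range(em0["g0005", ])), 0, tolerance = 1e-12)

  # max-loading gene tracks the gradient; fidelity decreases with noise
  cors <- vapply(c(0, 0.5, 2), function(ns) {
    tr <- truth
    tr$noise_sd <- ns
    mean(vapply(1:10, function(s) {
      d <- generate_expression(atlas, 40, 2, tr, probes_per_gene = 1,
                               seed = 100 + s, n_nuisance = 0)
      e <- regional_expression(d, atlas)
      g <- names(which.max(abs(tr$gene_loadings)))
      abs(cor(e[g, ], tr$roi_gradient[colnames(e)]))
    }, numeric(1)))
  }, numeric(1))
  expect_gte(cors[1], 0.99)
  expect_true(all(diff(cors) < 0))
})

test_that("gene-set generator plants top-loading members and round-trips GMT", {
  atlas <- generate_atlas(4, seed = 31)
  truth <- random_ground_truth(atlas, 200, seed = 32)
  genes <- names(truth$gene_loadings)
  sets <- generate_gene_sets(genes, 10, size_range = c(20L, 20L),
                             planted = c(planted = 1.0), seed = 33,
                             loadings = truth$gene_loadings)
  top20 <- names(sort(truth$gene_loadings, decreasing = TRUE))[1:20]
  expect_setequal(sets[["planted"]], top20)
  sets_abs <- generate_gene_sets(genes, 10, size_range = c(20L, 20L),
                                 planted = c(planted = 1.0), seed = 33,
                                 loadings = truth$gene_loadings,
                                 plant_by = "abs")
  top20a <- names(sort(abs(truth$gene_loadings), decreasing = TRUE))[1:20]
  expect_setequal(sets_abs[["planted"]], top20a)

  # unplanted membership is independent of loadings
  pb <- vapply(1:100, function(s) {
    ss <- generate_gene_sets(genes, 1, c(30L, 30L), seed = s)
    memb <- as.numeric(genes %in% ss[[1]])
    cor(memb, abs(truth$gene_loadings))
  }, numeric(1))
  expect_lt(abs(mean(pb)), 0.02)

  tmp <- tempfile(fileext = ".gmt")
  write_gmt(sets, tmp)
  back <- read_gmt(tmp)
  expect_identical(unclass(back)[names(sets)], unclass(sets)[names(sets)])
  expect_error(generate_gene_sets(genes, 2, c(5L, 5L), planted = c(a = 1.5),
                                  seed = 1, loadings = truth$gene_loadings),
               "planted fractions")
})

test_that("fold-change generator hits its target Spearman correlation", {
  atlas <- generate_atlas(4, seed = 41)
  truth <- random_ground_truth(atlas, 2000, seed = 42)
  rho_of <- function(target, seed) {
    fc <- generate_foldchange(truth, target, seed = seed)
    cor(truth$gene_loadings[fc$gene], fc$log2fc, method = "spearman")
  }
  expect_equal(rho_of(-1, 1), -1)
  expect_lt(abs(rho_of(0, 2)), 0.1)
  expect_lt(abs(rho_of(-0.23, 3) + 0.23), 0.05)
  rhos <- vapply(4:9, function(s) rho_of(-0.23, s), numeric(1))
  expect_true(all(abs(rhos + 0.23) < 0.05))
})

test_that("generators are pure functions of their seeds", {
  a1 <- generate_atlas(5, seed = 9)
  t1 <- random_ground_truth(a1, 50, seed = 8)
  expect_identical(t1, random_ground_truth(a1, 50, seed = 8))
  d1 <- generate_expression(a1, 50, 2, t1, seed = 7)
  d2 <- generate_expression(a1, 50, 2, t1, seed = 7)
  expect_identical(d1$donors[[2]]$values, d2$donors[[2]]$values)
  f1 <- generate_foldchange(t1, -0.3, seed = 6)
  expect_identical(f1, generate_foldchange(t1, -0.3, seed = 6))
})

test_that("ground truth serializes losslessly and keeps unit norms", {
  atlas <- generate_atlas(4, seed = 51)
  truth <- random_ground_truth(atlas, 30, seed = 52, two_components = TRUE)
  expect_equal(sum(truth$roi_gradient^2), 1)
  expect_equal(sum(truth$gene_loadings^2), 1)
  expect_equal(sum(truth$roi_gradient * truth$roi_gradient2), 0,
               tolerance = 1e-12)
  tmp <- tempfile(fileext = ".json")
  write_ground_truth(truth, tmp)
  back <- read_ground_truth(tmp)
  expect_equal(back$roi_gradient, truth$roi_gradient)
  expect_equal(back$gene_loadings2, truth$gene_loadings2)
})
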