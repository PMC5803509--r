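# Shared fixtures, generated in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- make()
  .fixtures[[key]]
}

# Small but non-degenerate study used by several files: 12+4 nodes, 120
# genes, 3 donors, 5+5 subjects, 3 visits.
small_study <- function() cached("small_study", function() {
  atlas <- generate_atlas(6, seed = 11)
  truth <- random_ground_truth(atlas, 120, seed = 12, noise_sd = 0.3)
  spec <- cohort_spec(5, 5, c(0, 12, 24), seed = 13)
  conns <- generate_cohort_connectomes(atlas, spec, truth)
  dset <- generate_expression(atlas, 120, 3, truth, seed = 14,
                              n_nuisance = 2)
  list(atlas = atlas, truth = truth, spec = spec, conns = conns,
       dset = dset)
})

conns_of <- function(study, group, timepoint = NULL) {
  Filter(function(c) {
    c$group == group && (is.null(timepoint) || c$timepoint == timepoint)
  }, study$conns)
}

profiles_of <- function(study, group, timepoint, mask = NULL) {
  lapply(conns_of(study, group, timepoint), roi_class_connectivity,
         atlas = study$atlas, mask = mask)
}

# Exhaustive mHG oracle: scan + exact p by enumerating all C(N, K)
# placements. Independent of the package's DP.
mhg_enumeration <- function(membership) {
  N <- length(membership)
  K <- sum(membership)
  stat <- function(v) {
    b <- cumsum(v)
    min(phyper(b - 1, K, N - K, seq_len(N), lower.tail = FALSE))
  }
  obs <- stat(membership)
  placements <- utils::combn(N, K)
  null <- apply(placements, 2L, function(idx) {
    v <- logical(N)
    v[idx] <- TRUE
    stat(v)
  })
  list(mhg = obs, p_value = mean(null <= obs * (1 + 1e-12)))
}

# Strip class and bookkeeping attributes, keep dim/dimnames.
bare <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  m
}

# Step-up BH oracle.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
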