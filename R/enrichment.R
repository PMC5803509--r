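#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= b)` for `X ~ Hypergeometric(N, B, n)`: drawing `n` genes from a
#' universe of `N` containing `B` term members. Evaluated through the
#' log-scale distribution function for numerical stability in the far tail.
#'
#' @param b Observed intersection count.
#' @param n Draw (target-set) size.
#' @param B Term size in the universe.
#' @param N Universe size.
#' @return The tail probability in [0, 1].
#' @examples
#' hypergeom_tail(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeom_tail <- function(b, n, B, N) {
  if (any(c(b, n, B, N) < 0) || b > min(n, B) || n > N || B > N)
    stop("inconsistent counts: need 0 <= b <= min(n, B) <= N")
  if (b <= 0) return(1)
  exp(stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE, log.p = TRUE))
}

#' Enrichment ratio at a cutoff
#'
#' `E = (b / n) / (B / N)`: the observed fraction of term members in the
#' target set over the fraction expected from the universe.
#'
#' @inheritParams hypergeom_tail
#' @return The exact ratio.
#' @export
enrichment_ratio <- function(b, n, B, N) {
  if (n <= 0 || B <= 0) stop("n and B must be positive")
  (b / n) / (B / N)
}

#' Minimum-hypergeometric scan of a ranked membership vector
#'
#' The threshold-free ranked enrichment statistic: for every cutoff position
#' n in the ranked universe, the hypergeometric tail probability of seeing
#' `b(n)` term members in the top n is computed, and the minimum over
#' cutoffs (mHG) is taken. The exact p-value is the probability, over all
#' `choose(N, K)` equally likely placements of the K members, that the
#' minimum reaches the observed one; it is computed by dynamic programming
#' over the (position, member-count) lattice, propagating the survival
#' probability of a uniformly random ranking and absorbing mass at cells
#' whose tail probability is at or below the observed minimum.
#'
#' @param ranked_membership Logical/0-1 vector over the ranked universe
#'   (TRUE = gene belongs to the term), best genes first.
#' @param limit Optional largest cutoff position to scan (default: the
#'   whole list); the exact p accounts for the restriction.
#' @return List with `n_star`, `b_star` (smallest optimal cutoff and its
#'   member count), `mhg` (the minimized tail probability) and `p_value`
#'   (exact).
#' @examples
#' mhg_scan(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))  # p = 1/15
#' @export
mhg_scan <- function(ranked_membership, limit = NULL) {
  v <- as.logical(ranked_membership)
  if (anyNA(v)) stop("membership vector must not contain NA")
  N <- length(v)
  K <- sum(v)
  if (K == 0L) stop("term has no members in the ranked universe")
  b_at <- cumsum(v)
  if (is.null(limit)) limit <- N
  if (limit < 1L || limit > N) stop("limit must be in [1, N]")
  ns <- seq_len(limit)
  log_tails <- stats::phyper(b_at[ns] - 1, K, N - K, ns,
                             lower.tail = FALSE, log.p = TRUE)
  i_star <- which.min(log_tails)      # smallest n on ties
  lmhg <- log_tails[i_star]
  list(n_star = i_star, b_star = b_at[i_star], mhg = exp(lmhg),
       p_value = mhg_exact_p(N, K, lmhg, limit))
}

# Exact P(mHG <= observed) over uniformly random member placements.
# `m[b + 1]` carries the probability that a random ranking reaches position
# n with b members seen and has not yet entered the rejection region
# {(n, b): log-tail <= lmhg, n <= limit}. Tolerance absorbs floating-point
# ties.
mhg_exact_p <- function(N, K, lmhg, limit = N, tol = 1e-9) {
  m <- numeric(K + 1L)
  m[1L] <- 1
  rejected <- 0
  for (n in seq_len(limit)) {
    b_lo <- max(0L, n - (N - K))
    b_hi <- min(n, K)
    new <- numeric(K + 1L)
    bs <- seq.int(b_lo, b_hi)
    # from (n-1, b): next element is a member with prob (K - b) / remaining
    remaining <- N - (n - 1L)
    stay <- m[bs + 1L] * ((remaining - (K - bs)) / remaining)
    step <- numeric(length(bs))
    pos <- bs >= 1L
    step[pos] <- m[bs[pos]] * ((K - (bs[pos] - 1L)) / remaining)
    new[bs + 1L] <- stay + step
    # absorb rejection-region cells at level n
    lt <- stats::phyper(bs - 1, K, N - K, n, lower.tail = FALSE,
                        log.p = TRUE)
    hit <- lt <= lmhg + tol
    if (any(hit)) {
      rejected <- rejected + sum(new[bs + 1L][hit])
      new[bs + 1L][hit] <- 0
    }
    m <- new
  }
  min(1, max(rejected, 0))
}

#' Ranked gene-set enrichment over a collection
#'
#' Intersects every term with the ranked universe, drops terms smaller than
#' `min_term_size` or larger than `max_term_size` after intersection (and
#' exact duplicate member sets, keeping the first), then scores each term
#' with [mhg_scan()]. Benjamini-Hochberg q-values are computed across the
#' tested terms and the enrichment ratio is evaluated at the optimal cutoff.
#'
#' @param ranked A `ranked_gene_list` (from [gene_ranking()]) or character
#'   vector of genes, best first.
#' @param sets A `gene_set_collection`.
#' @param max_term_size Terms associated with more genes are excluded.
#' @param min_term_size Minimum post-intersection term size.
#' @param top_fraction Optional fraction in (0, 1]; when set, the scan is
#'   restricted to cutoffs within the top fraction of the list (fixed
#'   top-set mode); default `NULL` scans the full ranked list.
#' @return Data frame sorted by p: `term_id`, `description`, `p_value`,
#'   `q_value`, `enrichment`, `B`, `n`, `b`, `N`.
#' @export
go_enrichment <- function(ranked, sets, max_term_size = 1000L,
                          min_term_size = 3L, top_fraction = NULL) {
  universe <- if (inherits(ranked, "ranked_gene_list")) ranked$gene
              else as.character(ranked)
  if (anyDuplicated(universe)) stop("ranked universe contains duplicates")
  stopifnot(inherits(sets, "gene_set_collection"))
  N <- length(universe)
  desc <- attr(sets, "descriptions")
  members <- lapply(sets, intersect, universe)
  sizes <- lengths(members)
  keep <- sizes >= min_term_size & sizes <= max_term_size
  sig <- vapply(members, paste, character(1), collapse = "|")
  keep <- keep & !duplicated(sig)
  if (!any(keep)) stop("no gene set left after size/duplicate filters")
  members <- members[keep]
  limit <- if (is.null(top_fraction)) N else {
    if (top_fraction <= 0 || top_fraction > 1)
      stop("top_fraction must be in (0, 1]")
    max(1L, floor(top_fraction * N))
  }
  rows <- lapply(names(members), function(id) {
    memb <- universe %in% members[[id]]
    scan <- mhg_scan(memb, limit = limit)
    K <- length(members[[id]])
    data.frame(term_id = id, description = desc[[id]] %||% "",
               p_value = scan$p_value,
               enrichment = enrichment_ratio(scan$b_star, scan$n_star, K, N),
               B = K, n = scan$n_star, b = scan$b_star, N = N,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id),
             c("term_id", "description", "p_value", "q_value", "enrichment",
               "B", "n", "b", "N")]
  rownames(out) <- NULL
  out
}

#' Mean-weight permutation enrichment of a curated gene list
#'
#' Compares the mean PLS weight of a target gene list against the means of
#' random same-size gene sets drawn from the weight universe:
#' `p = (1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param weights Named numeric vector of gene weights.
#' @param target Character vector of target genes (must intersect the
#'   universe; genes outside the universe are dropped with a warning).
#' @param n_perm Number of random sets (>= 100 recommended).
#' @param seed Integer seed.
#' @return List with `observed`, `null` (numeric vector), `p_value`,
#'   `n_target`.
#' @export
geneset_weight_enrichment <- function(weights, target, n_perm = 999L,
                                      seed = 1L) {
  stopifnot(!is.null(names(weights)))
  target <- unique(as.character(target))
  missing <- setdiff(target, names(weights))
  if (length(missing)) {
    warning(length(missing), " target gene(s) absent from weight universe")
    target <- setdiff(target, missing)
  }
  if (!length(target)) stop("empty target list")
  obs <- mean(weights[target])
  k <- length(target)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i)
      mean(sample(weights, k)), numeric(1))
    list(observed = obs, null = null,
         p_value = (1 + sum(null >= obs)) / (n_perm + 1), n_target = k)
  })
}

#' Competitive comparison of a target list against plausible gene sets
#'
#' Ranks the target list's mean weight against the mean weights of curated
#' competitor sets; competitors whose size differs from the target's are
#' subsampled (or the target size is used as-is when smaller) with a
#' warning.
#'
#' @param weights Named numeric vector of gene weights.
#' @param target Character vector of target genes.
#' @param competitors List of >= 20 character vectors.
#' @param seed Seed for size-matching subsampling.
#' @return List with `observed`, `competitor_means`, `p_value` (fraction of
#'   competitor means >= observed) and `p_floor` (`1 / #competitors`).
#' @export
competitive_geneset_comparison <- function(weights, target, competitors,
                                           seed = 1L) {
  stopifnot(!is.null(names(weights)))
  if (length(competitors) < 20L) stop("need >= 20 competitor sets")
  target <- intersect(unique(target), names(weights))
  if (!length(target)) stop("empty target list")
  k <- length(target)
  obs <- mean(weights[target])
  with_seed(seed, {
    sizes <- lengths(lapply(competitors, intersect, names(weights)))
    if (any(sizes != k))
      warning("size-mismatched competitor sets; subsampling to target size")
    means <- vapply(competitors, function(s) {
      s <- intersect(unique(s), names(weights))
      if (length(s) > k) s <- sample(s, k)
      mean(weights[s])
    }, numeric(1))
    list(observed = obs, competitor_means = means,
         p_value = mean(means >= obs),
         p_floor = 1 / length(competitors))
  })
}

#' Hypergeometric overlap between two gene lists
#'
#' @param list_a,list_b Character vectors (deduplicated with a warning).
#' @param universe Universe size N (both lists must fit in it).
#' @return List with `overlap`, `p_value`
#'   (`hypergeom_tail(b, |A|, |B|, N)`), `n_a`, `n_b`.
#' @export
overlap_test <- function(list_a, list_b, universe) {
  dedup <- function(x, nm) {
    if (anyDuplicated(x)) {
      warning("duplicate genes in ", nm, "; deduplicated")
      x <- unique(x)
    }
    as.character(x)
  }
  a <- dedup(list_a, "list_a")
  b <- dedup(list_b, "list_b")
  N <- assert_count(universe, "universe")
  if (length(a) > N || length(b) > N) stop("lists larger than the universe")
  ov <- length(intersect(a, b))
  list(overlap = ov,
       p_value = hypergeom_tail(ov, length(a), length(b), N),
       n_a = length(a), n_b = length(b))
}

#' Spearman correlation between PLS weights and log2 fold changes
#'
#' Intersects on shared genes (>= 10 required) and reports the Spearman
#' rank correlation with its asymptotic p-value.
#'
#' @param weights Named numeric vector of gene weights.
#' @param log2fc_table Data frame with columns `gene`, `log2fc`.
#' @return List with `rho`, `p_value`, `n_shared`.
#' @export
weight_foldchange_correlation <- function(weights, log2fc_table) {
  stopifnot(!is.null(names(weights)),
            all(c("gene", "log2fc") %in% names(log2fc_table)))
  shared <- intersect(names(weights), log2fc_table$gene)
  if (length(shared) < 10L) stop("fewer than 10 shared genes")
  fc <- log2fc_table$log2fc[match(shared, log2fc_table$gene)]
  ct <- suppressWarnings(stats::cor.test(weights[shared], fc,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_shared = length(shared))
}
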