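# Brute-force O(n^2) oracles for the interval operations, deliberately
# independent of the package's sweep-line/IRanges code paths: pairwise
# overlap adjacency + graph connected components (igraph).

pair_overlap <- function(d) {
  # n x n matrix of pairwise overlap lengths (bp) within one chromosome
  outer(d$end, d$end, pmin) - outer(d$start, d$start, pmax)
}

oracle_merge <- function(df, min_overlap = 1L) {
  if (!nrow(df)) return(df[, c("chrom", "start", "end")])
  parts <- lapply(split(df, df$chrom), function(d) {
    adj <- pair_overlap(d) >= min_overlap
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    memb <- igraph::components(g)$membership
    do.call(rbind, lapply(split(seq_len(nrow(d)), memb), function(idx) {
      data.frame(chrom = d$chrom[1L], start = min(d$start[idx]),
                 end = max(d$end[idx]), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$start, out$end), ]
  rownames(out) <- NULL
  out
}

# overlap of each row of a with >= 1 row of b, by exhaustive comparison
oracle_any_overlap <- function(a, b, min_overlap = 1L) {
  vapply(seq_len(nrow(a)), function(i) {
    same <- b$chrom == a$chrom[i]
    any(pmin(b$end[same], a$end[i]) - pmax(b$start[same], a$start[i]) >=
          min_overlap)
  }, logical(1))
}

oracle_occupancy <- function(peaksets, min_overlap = 1L) {
  pooled <- do.call(rbind, lapply(peaksets, function(d) {
    d[, c("chrom", "start", "end")]
  }))
  merged <- oracle_merge(pooled, min_overlap)
  occ <- vapply(names(peaksets), function(s) {
    pk <- peaksets[[s]]
    if (!nrow(pk)) return(rep(0L, nrow(merged)))
    as.integer(oracle_any_overlap(merged, pk))
  }, integer(nrow(merged)))
  occ <- matrix(occ, nrow = nrow(merged),
                dimnames = list(NULL, names(peaksets)))
  list(regions = merged, occ = occ,
       codes = apply(occ, 1L, paste0, collapse = ""))
}

oracle_pattern_freqs <- function(codes) {
  counts <- vapply(sort(unique(codes)), function(cd) sum(codes == cd), 0L)
  list(count = counts, pct = 100 * counts / length(codes))
}

oracle_sharing <- function(occ) {
  subs <- colnames(occ)
  with_s <- lapply(subs, function(s) which(occ[, s] == 1L))
  names(with_s) <- subs
  multi <- which(rowSums(occ) > 1L)
  shared <- vapply(subs, function(s) {
    if (!length(with_s[[s]])) return(NA_real_)
    length(intersect(with_s[[s]], multi)) / length(with_s[[s]])
  }, 0)
  pairwise <- sapply(subs, function(t) vapply(subs, function(s) {
    if (!length(with_s[[s]])) return(NA_real_)
    length(intersect(with_s[[s]], with_s[[t]])) / length(with_s[[s]])
  }, 0))
  list(shared = shared, pairwise = pairwise)
}

random_peaksets <- function(n_per_subunit, span = 10000L, width_max = 400L) {
  setNames(lapply(seq_len(4L), function(i) {
    n <- n_per_subunit
    start <- sample.int(span, n, replace = TRUE)
    w <- sample.int(width_max, n, replace = TRUE)
    sort_unique <- regions(rep("chr1", n), start, start + w)
    sort_unique
  }), c("p50", "p52", "RelA", "RelB"))
}

# target-table-shaped data frame from a sim_truth genes table
truth_targets <- function(truth_genes) {
  tg <- truth_genes[truth_genes$canonical_regulated |
                      truth_genes$noncanonical_regulated, , drop = FALSE]
  rownames(tg) <- NULL
  tg
}
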