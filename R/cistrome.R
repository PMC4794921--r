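## Combinatorial occupancy analysis of per-subunit ChIP-seq peak sets:
## unification into an occupancy matrix, 4-bit pattern codes and frequencies,
## sharing statistics, TSS-distance and genomic-feature annotation, k-means
## profile clustering, and cross-cistrome comparison.

#' Unify per-subunit peak sets into an occupancy matrix
#'
#' The union of all input peaks is merged by single linkage (pairwise overlap
#' of at least `min_overlap` bp), so each unified region is a maximal run of
#' mutually connected peaks from any subunit. A subunit's indicator is set
#' when at least one of its peaks overlaps the unified region. The summit of
#' a unified region is the summit of the strongest (highest-score)
#' contributing peak, falling back to the region midpoint.
#'
#' @param peaksets Named list of region sets, names drawn from
#'   `p50`, `p52`, `RelA`, `RelB` (case-insensitive).
#' @param min_overlap Minimum pairwise overlap (bp) for merging; default 1.
#' @return An `occupancy_matrix`: list with `regions` (unified region set in
#'   canonical order), `occ` (regions x 4 binary indicator matrix in fixed
#'   subunit order p50, p52, RelA, RelB), `codes` (4-character pattern codes)
#'   and `profiles` (`NULL` until [attach_profiles()]).
#' @examples
#' pk <- regions("chr1", c(100L, 300L), c(200L, 400L))
#' m <- build_occupancy_matrix(list(p50 = pk, p52 = pk[1, ]))
#' m$codes
#' @export
build_occupancy_matrix <- function(peaksets, min_overlap = 1L) {
  stopifnot(is.list(peaksets), length(peaksets) >= 1L)
  names(peaksets) <- normalize_subunits(names(peaksets))
  if (anyDuplicated(names(peaksets))) stop("duplicated subunit name")
  for (s in names(peaksets)) validate_regions(peaksets[[s]], what = s)
  if (all(vapply(peaksets, nrow, 0L) == 0L)) {
    stop("all peak sets are empty")
  }
  pooled <- do.call(rbind, lapply(names(peaksets), function(s) {
    d <- peaksets[[s]]
    data.frame(chrom = d$chrom, start = d$start, end = d$end,
               summit = if ("summit" %in% names(d)) d$summit else NA_integer_,
               score = if ("score" %in% names(d)) d$score else NA_real_,
               subunit = s, stringsAsFactors = FALSE)
  }))
  unified <- merge_regions(pooled[, c("chrom", "start", "end")],
                           min_overlap = min_overlap)
  occ <- matrix(0L, nrow(unified), length(SUBUNITS),
                dimnames = list(NULL, SUBUNITS))
  ugr <- regions_to_granges(unified)
  hits_all <- GenomicRanges::findOverlaps(regions_to_granges(pooled), ugr)
  qh <- S4Vectors::queryHits(hits_all); sh <- S4Vectors::subjectHits(hits_all)
  for (s in names(peaksets)) {
    if (nrow(peaksets[[s]]) == 0L) next
    occ[unique(sh[pooled$subunit[qh] == s]), s] <- 1L
  }
  # summit from the strongest contributing peak (midpoint fallback)
  summit <- rep(NA_integer_, nrow(unified))
  score <- rep(NA_real_, nrow(unified))
  peak_score <- ifelse(is.na(pooled$score), -Inf, pooled$score)
  ord <- order(sh, -peak_score[qh])
  first <- !duplicated(sh[ord])
  best <- qh[ord][first]
  at <- sh[ord][first]
  abs_summit <- summit_positions(pooled)[best]
  summit[at] <- pmin(pmax(abs_summit - unified$start[at], 0L),
                     unified$end[at] - unified$start[at] - 1L)
  score[at] <- ifelse(is.finite(peak_score[best]), pooled$score[best], NA_real_)
  regions_df <- data.frame(chrom = unified$chrom, start = unified$start,
                           end = unified$end, summit = summit, score = score,
                           stringsAsFactors = FALSE)
  stopifnot(all(rowSums(occ) > 0L))
  obj <- list(regions = regions_df, occ = occ,
              codes = apply(occ, 1L, paste0, collapse = ""),
              profiles = NULL)
  class(obj) <- "occupancy_matrix"
  obj
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat(sprintf("occupancy_matrix: %d unified regions on %d chromosome(s)\n",
              nrow(x$regions), length(unique(x$regions$chrom))))
  cat("subunit region counts:",
      paste(sprintf("%s=%d", SUBUNITS, colSums(x$occ)), collapse = ", "), "\n")
  if (!is.null(x$profiles)) {
    cat(sprintf("profiles attached: %d bins per subunit\n",
                ncol(x$profiles[[1L]])))
  }
  invisible(x)
}

#' 4-bit combinatorial pattern code
#'
#' Encodes subunit presence as a 4-character binary string in the fixed order
#' p50, p52, RelA, RelB; e.g. p50+p52 is `"1100"`, p50+RelA `"1010"`,
#' p52+RelB `"0101"`.
#'
#' @param indicators Length-4 0/1 vector in subunit order, or a named 0/1
#'   vector / character vector of subunit names.
#' @return A 4-character code string.
#' @export
pattern_code <- function(indicators) {
  if (is.character(indicators)) {
    x <- as.integer(SUBUNITS %in% normalize_subunits(indicators))
  } else if (!is.null(names(indicators))) {
    x <- integer(4)
    names(x) <- SUBUNITS
    x[normalize_subunits(names(indicators))] <- as.integer(indicators)
  } else {
    stopifnot(length(indicators) == 4L)
    x <- as.integer(indicators)
  }
  if (!all(x %in% 0:1)) stop("indicators must be 0/1")
  if (sum(x) == 0L) stop("all-zero pattern: a unified region must contain ",
                         "at least one subunit")
  paste0(x, collapse = "")
}

#' Pattern frequency table
#'
#' Counts and percentages of the 4-bit subunit combination codes over the
#' unified regions.
#'
#' @param m An `occupancy_matrix`.
#' @return Data frame with columns `pattern`, `count`, `pct`, sorted by
#'   decreasing count; the total region count is attached as attribute
#'   `total`.
#' @export
pattern_frequencies <- function(m) {
  stopifnot(inherits(m, "occupancy_matrix"), nrow(m$regions) > 0L)
  tab <- table(m$codes)
  df <- data.frame(pattern = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df$pct <- 100 * df$count / sum(df$count)
  df <- df[order(-df$count, df$pattern), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "total") <- sum(df$count)
  df
}

#' Subunit sharing statistics
#'
#' `shared[s]` is the fraction of regions containing subunit `s` that contain
#' at least one other subunit; `pairwise[s, t]` is the fraction of `s` regions
#' that also contain `t`. Subunits with no regions get `NA`.
#'
#' @param m An `occupancy_matrix`.
#' @return List with `shared` (named numeric length 4) and `pairwise`
#'   (4 x 4 matrix; the diagonal is 1 where defined).
#' @export
sharing_statistics <- function(m) {
  stopifnot(inherits(m, "occupancy_matrix"), nrow(m$regions) > 0L)
  occ <- m$occ
  n_s <- colSums(occ)
  shared <- setNames(rep(NA_real_, 4L), SUBUNITS)
  pairwise <- matrix(NA_real_, 4L, 4L, dimnames = list(SUBUNITS, SUBUNITS))
  for (s in SUBUNITS) {
    if (n_s[s] == 0L) next
    with_s <- occ[, s] == 1L
    shared[s] <- mean(rowSums(occ[with_s, , drop = FALSE]) > 1L)
    for (t in SUBUNITS) {
      if (n_s[t] == 0L && t != s) next
      pairwise[s, t] <- sum(occ[with_s, t]) / n_s[s]
    }
  }
  list(shared = shared, pairwise = pairwise)
}

# Signed summit-to-TSS distance, negative upstream with respect to the gene's
# strand. Returns the distance to the nearest TSS and that gene's id.
nearest_tss_distance <- function(m, ann) {
  genes <- ann$genes
  if (!nrow(genes)) stop("empty annotation")
  summits <- summit_positions(m$regions)
  n <- nrow(m$regions)
  dist <- rep(NA_real_, n); gene <- rep(NA_character_, n)
  for (chr in unique(m$regions$chrom)) {
    ri <- which(m$regions$chrom == chr)
    gi <- which(genes$chrom == chr)
    if (!length(gi)) next
    tss <- genes$tss[gi]
    for (i in ri) {
      d <- summits[i] - tss
      j <- which.min(abs(d))
      signed <- if (genes$strand[gi[j]] == "+") d[j] else -d[j]
      dist[i] <- signed
      gene[i] <- genes$gene_id[gi[j]]
    }
  }
  data.frame(distance = dist, gene_id = gene, stringsAsFactors = FALSE)
}

#' TSS-distance histogram of binding regions
#'
#' Signed distance from each unified region's summit to the nearest TSS
#' (upstream negative with respect to gene strand), binned over
#' `[-window, window]`; regions farther than `window` (or on chromosomes
#' without genes) fall in an overflow bin.
#'
#' @param m An `occupancy_matrix`.
#' @param ann A [gene_annotation()].
#' @param window Half-width of the histogram in bp.
#' @param nbins Number of bins across `[-window, window]`; use an odd number
#'   so that the TSS sits in the central bin.
#' @return List with `breaks`, `mid`, `counts`, `overflow` and the per-region
#'   `distances`; `sum(counts) + overflow == nrow(m$regions)`.
#' @export
tss_distance_profile <- function(m, ann, window = 10000L, nbins = 41L) {
  stopifnot(window > 0L, nbins >= 1L)
  nt <- nearest_tss_distance(m, ann)
  d <- nt$distance
  breaks <- seq(-window, window, length.out = nbins + 1L)
  inside <- !is.na(d) & abs(d) <= window
  idx <- pmin(findInterval(d[inside], breaks, rightmost.closed = TRUE), nbins)
  counts <- tabulate(idx, nbins)
  list(breaks = breaks, mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
       counts = counts, overflow = sum(!inside), distances = d)
}

#' Genomic feature annotation of regions
#'
#' Labels each region by its summit position with fixed precedence
#' promoter > exon > intron > intergenic. A summit is `promoter` when within
#' `promoter_window` bp of any TSS, `exon`/`intron` when inside an annotated
#' exon / gene body, else `intergenic`. Without exon or gene-body intervals
#' in the annotation those categories cannot be assigned.
#'
#' @param m An `occupancy_matrix` (or a region set).
#' @param ann A [gene_annotation()].
#' @param promoter_window Promoter half-width in bp (default 2 kb).
#' @return Character vector of labels, one per region.
#' @export
genomic_feature_annotation <- function(m, ann, promoter_window = 2000L) {
  reg <- if (inherits(m, "occupancy_matrix")) m$regions else m
  summits <- summit_positions(reg)
  genes <- ann$genes
  n <- nrow(reg)
  out <- rep("intergenic", n)
  pts <- data.frame(chrom = reg$chrom, start = summits, end = summits + 1L)
  if (!is.null(ann$exons) && nrow(ann$exons)) {
    ex <- merge(ann$exons, genes[, c("gene_id", "chrom")], by = "gene_id")
    in_exon <- overlaps_any(pts, ex[, c("chrom", "start", "end")])
  } else in_exon <- rep(FALSE, n)
  if (all(c("start", "end") %in% names(genes))) {
    in_body <- overlaps_any(pts, genes[, c("chrom", "start", "end")])
  } else in_body <- rep(FALSE, n)
  out[in_body] <- "intron"
  out[in_exon] <- "exon"
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(genes$tss - promoter_window, 0L),
                     end = genes$tss + promoter_window + 1L)
  in_prom <- overlaps_any(pts, prom)
  out[in_prom] <- "promoter"
  out
}

#' Attach summit-centered signal profiles to an occupancy matrix
#'
#' Matches each profile record to the unified region containing its summit
#' position. Every region must receive one profile per subunit before
#' [cluster_profiles()] can run.
#'
#' @param m An `occupancy_matrix`.
#' @param profile_table Data frame with columns `chrom`, `pos` (absolute
#'   summit bp), `subunit`, and one numeric column per profile bin
#'   (`bin_001`, ...).
#' @return `m` with `profiles` set: a named list (one per subunit) of
#'   regions x bins matrices.
#' @export
attach_profiles <- function(m, profile_table) {
  stopifnot(inherits(m, "occupancy_matrix"))
  bins <- grep("^bin_", names(profile_table), value = TRUE)
  if (!length(bins)) stop("profile_table has no bin_* columns")
  pts <- data.frame(chrom = profile_table$chrom,
                    start = profile_table$pos, end = profile_table$pos + 1L)
  hits <- GenomicRanges::findOverlaps(regions_to_granges(pts),
                                      regions_to_granges(m$regions))
  ridx <- rep(NA_integer_, nrow(profile_table))
  ridx[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  profs <- list()
  for (s in SUBUNITS) {
    mat <- matrix(NA_real_, nrow(m$regions), length(bins))
    rows <- which(profile_table$subunit == s & !is.na(ridx))
    mat[ridx[rows], ] <- as.matrix(profile_table[rows, bins])
    profs[[s]] <- mat
  }
  m$profiles <- profs
  m
}

#' k-means clustering of occupancy profiles
#'
#' Clusters the concatenated 4-subunit summit-centered profile vectors with
#' k-means (k-means++-quality via multiple random restarts, best
#' within-cluster SSE kept), reproducibly for a fixed seed. Also tabulates
#' the percentage of each cluster falling in each combinatorial pattern.
#'
#' @param m An `occupancy_matrix` with profiles attached
#'   (see [attach_profiles()]).
#' @param k Number of clusters (default 8).
#' @param seed Integer seed; clustering is deterministic given the seed.
#' @param nstart Random restarts (default 10).
#' @return A `profile_clusters` list: `labels` (1..k per region), `centers`,
#'   `tot_withinss`, and `cluster_pattern_pct` (k x patterns percentage
#'   matrix).
#' @export
cluster_profiles <- function(m, k = 8L, seed = 1L, nstart = 10L) {
  stopifnot(inherits(m, "occupancy_matrix"))
  if (is.null(m$profiles)) stop("no profiles attached; see attach_profiles()")
  X <- do.call(cbind, m$profiles)
  if (any(is.na(X))) stop("every region needs a profile for all 4 subunits")
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(X)) stop("k exceeds the number of regions")
  set.seed(as.integer(seed))
  km <- kmeans(X, centers = k, nstart = nstart, iter.max = 100L)
  pat <- table(factor(km$cluster, levels = seq_len(k)), m$codes)
  pct <- 100 * sweep(unclass(pat), 1L, pmax(rowSums(pat), 1L), "/")
  obj <- list(labels = km$cluster, centers = km$centers,
              tot_withinss = km$tot.withinss, cluster_pattern_pct = pct,
              k = k)
  class(obj) <- "profile_clusters"
  obj
}

#' Compare two cistromes
#'
#' For each subunit present in both occupancy matrices, the fraction of A's
#' subunit regions overlapping at least one of B's subunit regions (by at
#' least 1 bp), the mean over those subunits, and side-by-side pattern
#' frequency tables. Also usable for DHS-overlap comparisons by passing a
#' single-subunit matrix.
#'
#' @param mA,mB `occupancy_matrix` objects.
#' @return List with `overlap` (named fraction per subunit, `NA` where a
#'   subunit is absent from either side), `mean_overlap`, and
#'   `pattern_tables` (list of the two frequency tables).
#' @export
compare_cistromes <- function(mA, mB) {
  stopifnot(inherits(mA, "occupancy_matrix"), inherits(mB, "occupancy_matrix"),
            nrow(mA$regions) > 0L, nrow(mB$regions) > 0L)
  overlap <- setNames(rep(NA_real_, 4L), SUBUNITS)
  for (s in SUBUNITS) {
    ia <- mA$occ[, s] == 1L
    ib <- mB$occ[, s] == 1L
    if (!any(ia) || !any(ib)) next
    overlap[s] <- mean(overlaps_any(mA$regions[ia, , drop = FALSE],
                                    mB$regions[ib, , drop = FALSE]))
  }
  list(overlap = 100 * overlap,
       mean_overlap = 100 * mean(overlap, na.rm = TRUE),
       pattern_tables = list(A = pattern_frequencies(mA),
                             B = pattern_frequencies(mB)))
}
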