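## Genomic-region plumbing shared by all modules.
##
## A region set is a data.frame with columns chrom (character), start, end
## (0-based half-open integers), summit (offset from start, NA if unknown)
## and score (numeric, NA if unknown). Region identity for set operations is
## (chrom, start, end); sorting ties break by (chrom lexicographic, start, end).

#' Construct a validated region set
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; 0-based half-open coordinates.
#' @param summit Optional integer offset of the peak summit from `start`
#'   (narrowPeak convention); `NA` if unknown.
#' @param score Optional numeric enrichment score; `NA` if unknown.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `summit`,
#'   `score`.
#' @examples
#' regions(c("chr1", "chr1"), c(100L, 300L), c(200L, 400L))
#' @export
regions <- function(chrom, start, end, summit = NA_integer_, score = NA_real_) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   summit = as.integer(rep_len(summit, length(chrom))),
                   score = as.numeric(rep_len(score, length(chrom))),
                   stringsAsFactors = FALSE)
  validate_regions(df)
  df
}

validate_regions <- function(df, what = "region set") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop(what, " must have columns chrom, start, end")
  }
  if (nrow(df)) {
    if (any(df$start < 0L)) stop(what, ": start must be >= 0")
    if (any(df$end <= df$start)) stop(what, ": end must be > start")
    if ("summit" %in% names(df)) {
      s <- df$summit
      bad <- !is.na(s) & (s < 0L | s >= df$end - df$start)
      if (any(bad)) stop(what, ": summit offset outside [0, end - start)")
    }
  }
  invisible(df)
}

# Canonical sort order: chrom lexicographic, then start, then end.
sort_regions <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

# 0-based half-open -> GRanges (1-based closed).
regions_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# Absolute summit position; midpoint fallback when the summit is unknown.
summit_positions <- function(df) {
  s <- if ("summit" %in% names(df)) df$summit else rep(NA_integer_, nrow(df))
  mid <- df$start + (df$end - df$start) %/% 2L
  ifelse(is.na(s), mid, df$start + s)
}

#' Single-linkage merge of genomic intervals
#'
#' Merges every group of intervals connected by pairwise overlaps of at least
#' `min_overlap` bp into one interval. With the default `min_overlap = 1`,
#' abutting intervals (zero overlap) are kept separate.
#'
#' @param df A region set (see [regions()]).
#' @param min_overlap Minimum pairwise overlap in bp required to merge.
#' @return A region set of merged intervals in canonical sort order, with a
#'   `n_input` column counting contributing input intervals.
#' @export
merge_regions <- function(df, min_overlap = 1L) {
  validate_regions(df)
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  if (!nrow(df)) {
    return(cbind(df[, c("chrom", "start", "end")], n_input = integer(0)))
  }
  df <- sort_regions(df)
  out <- vector("list", length(unique(df$chrom)))
  i <- 0L
  for (chr in unique(df$chrom)) {
    d <- df[df$chrom == chr, , drop = FALSE]
    start <- d$start; end <- d$end
    m_start <- start[1L]; m_end <- end[1L]; m_n <- 1L
    starts <- ends <- integer(0); ns <- integer(0)
    if (nrow(d) > 1L) {
      for (j in 2:nrow(d)) {
        # best pairwise overlap with a member of the growing run: all members
        # start at or before start[j], and one of them ends at m_end
        if (min(m_end, end[j]) - start[j] >= min_overlap) {
          m_end <- max(m_end, end[j]); m_n <- m_n + 1L
        } else {
          starts <- c(starts, m_start); ends <- c(ends, m_end); ns <- c(ns, m_n)
          m_start <- start[j]; m_end <- end[j]; m_n <- 1L
        }
      }
    }
    starts <- c(starts, m_start); ends <- c(ends, m_end); ns <- c(ns, m_n)
    i <- i + 1L
    out[[i]] <- data.frame(chrom = chr, start = starts, end = ends,
                           n_input = ns, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  sort_regions(res)
}

# Indices of query regions overlapping >= 1 subject region by >= minoverlap bp.
overlaps_any <- function(query, subject, minoverlap = 1L) {
  if (!nrow(query)) return(logical(0))
  if (!nrow(subject)) return(rep(FALSE, nrow(query)))
  hits <- GenomicRanges::findOverlaps(regions_to_granges(query),
                                      regions_to_granges(subject),
                                      minoverlap = as.integer(minoverlap))
  out <- rep(FALSE, nrow(query))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}
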