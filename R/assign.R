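## Region-to-gene assignment: proximal links through a TSS window, distal
## links through chromatin-loop anchors, optionally gated on DHS overlap.

#' Assign unified binding regions to genes
#'
#' Produces proximal and distal region-gene links:
#' \itemize{
#'   \item proximal: the gene's TSS lies within `proximal_window` bp of the
#'     region summit (`|distance| <= proximal_window`), evidence
#'     `"tss-window"`;
#'   \item distal: the region overlaps one loop anchor and the gene's TSS
#'     lies within `proximal_window` bp of the other anchor, with
#'     `proximal_window < |distance| <= max_distal`, evidence `"loop"`.
#'     When a DHS site set is supplied, distal links additionally require
#'     the region to overlap a DHS site; proximal links stand on TSS
#'     distance alone.
#' }
#' Distances are signed summit-to-TSS offsets, negative upstream with
#' respect to gene strand. A region may link to several genes; unlinked
#' regions are retained in the `unlinked` attribute.
#'
#' @param m An `occupancy_matrix`.
#' @param ann A [gene_annotation()].
#' @param dhs Optional region set of DNase hypersensitive sites.
#' @param loops Optional [loop_set()].
#' @param proximal_window Proximal TSS window half-width in bp (default 5 kb).
#' @param max_distal Maximum |distance| for distal links in bp (default 250 kb).
#' @return Data frame with columns `region` (row index into `m$regions`),
#'   `code`, `gene_id`, `stratum` (`proximal`/`distal`), `evidence`
#'   (`tss-window`/`loop`), `distance`; attribute `unlinked` lists region
#'   indices without any link.
#' @export
assign_regions <- function(m, ann, dhs = NULL, loops = NULL,
                           proximal_window = 5000L, max_distal = 250000L) {
  stopifnot(inherits(m, "occupancy_matrix"))
  proximal_window <- as.integer(proximal_window)
  max_distal <- as.integer(max_distal)
  if (proximal_window >= max_distal) {
    stop("proximal_window must be smaller than max_distal")
  }
  genes <- ann$genes
  summits <- summit_positions(m$regions)
  links <- list()

  signed_dist <- function(summit, tss, strand) {
    if (strand == "+") summit - tss else tss - summit
  }

  # (1) proximal links: TSS within +-proximal_window of the summit
  pts <- data.frame(chrom = m$regions$chrom, start = summits,
                    end = summits + 1L)
  tsswin <- data.frame(chrom = genes$chrom,
                       start = pmax(genes$tss - proximal_window, 0L),
                       end = genes$tss + proximal_window + 1L)
  hits <- GenomicRanges::findOverlaps(regions_to_granges(pts),
                                      regions_to_granges(tsswin))
  for (h in seq_along(hits)) {
    ri <- S4Vectors::queryHits(hits)[h]
    gi <- S4Vectors::subjectHits(hits)[h]
    d <- signed_dist(summits[ri], genes$tss[gi], genes$strand[gi])
    links[[length(links) + 1L]] <- data.frame(
      region = ri, gene_id = genes$gene_id[gi], stratum = "proximal",
      evidence = "tss-window", distance = d, stringsAsFactors = FALSE)
  }

  # (2) distal links through loop anchors
  if (!is.null(loops) && nrow(loops)) {
    in_dhs <- if (!is.null(dhs) && nrow(dhs)) {
      overlaps_any(m$regions, dhs)
    } else rep(TRUE, nrow(m$regions))
    anchors <- list(
      A = data.frame(chrom = loops$chromA, start = loops$startA,
                     end = loops$endA),
      B = data.frame(chrom = loops$chromB, start = loops$startB,
                     end = loops$endB))
    for (side in c("A", "B")) {
      other <- if (side == "A") "B" else "A"
      ra <- GenomicRanges::findOverlaps(regions_to_granges(m$regions),
                                        regions_to_granges(anchors[[side]]))
      if (!length(ra)) next
      # genes whose TSS is within proximal_window of the other anchor
      oth <- anchors[[other]]
      ga <- GenomicRanges::findOverlaps(
        regions_to_granges(data.frame(chrom = genes$chrom,
                                      start = pmax(genes$tss - proximal_window, 0L),
                                      end = genes$tss + proximal_window + 1L)),
        regions_to_granges(oth))
      gene_by_loop <- split(S4Vectors::queryHits(ga), S4Vectors::subjectHits(ga))
      for (h in seq_along(ra)) {
        ri <- S4Vectors::queryHits(ra)[h]
        if (!in_dhs[ri]) next
        li <- S4Vectors::subjectHits(ra)[h]
        for (gi in gene_by_loop[[as.character(li)]]) {
          d <- signed_dist(summits[ri], genes$tss[gi], genes$strand[gi])
          if (abs(d) <= proximal_window || abs(d) > max_distal) next
          links[[length(links) + 1L]] <- data.frame(
            region = ri, gene_id = genes$gene_id[gi], stratum = "distal",
            evidence = "loop", distance = d, stringsAsFactors = FALSE)
        }
      }
    }
  }

  out <- if (length(links)) do.call(rbind, links) else
    data.frame(region = integer(0), gene_id = character(0),
               stratum = character(0), evidence = character(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  # one link per (region, gene, stratum); proximal already excludes distal
  out <- out[!duplicated(out[, c("region", "gene_id", "stratum")]), ,
             drop = FALSE]
  out <- out[order(out$region, out$gene_id, out$stratum), , drop = FALSE]
  out <- data.frame(region = out$region, code = m$codes[out$region],
                    gene_id = out$gene_id, stratum = out$stratum,
                    evidence = out$evidence, distance = out$distance,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unlinked") <- setdiff(seq_len(nrow(m$regions)), out$region)
  out
}
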