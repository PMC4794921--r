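## Differential expression on the four-group knockdown design and
## direct-target calling: per-cluster two-sample t-tests with
## Benjamini-Hochberg control, the gene-level FDR < alpha plus >= 10 %
## expression-difference rule, and intersection with subunit binding.

#' Benjamini-Hochberg step-up adjustment
#'
#' The multiple-testing adjustment used throughout the package (thin wrapper
#' over [stats::p.adjust()] with `method = "BH"`), exposed so that q-values
#' can be recomputed on any P-value vector.
#'
#' @param p Numeric vector of raw P values.
#' @return Adjusted q values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04 by the step-up formula
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Per-row two-sample t-tests between two sample groups
#'
#' Welch (default) or pooled-variance two-sample t-test per expression row,
#' group A minus group B, with Benjamini-Hochberg adjustment over all tested
#' rows. Rows that are constant within both groups get `P = 1` when the
#' group means are equal (no evidence) and `P = 0` when they differ
#' (noiseless separation).
#'
#' @param expr An [expression_matrix()].
#' @param groupA,groupB Group labels; the difference is mean(A) - mean(B),
#'   so with A = control and B = knockdown a positive difference means the
#'   gene falls upon knockdown (activated by NF-kB).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Data frame with columns `cluster_id`, `diff` (log2), `t`, `p`,
#'   `q`, one row per expression row.
#' @export
test_differential <- function(expr, groupA, groupB, var_equal = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"))
  ca <- which(expr$groups == groupA)
  cb <- which(expr$groups == groupB)
  if (length(ca) < 2L || length(cb) < 2L) {
    stop("each group needs >= 2 samples (", groupA, ": ", length(ca), ", ",
         groupB, ": ", length(cb), ")")
  }
  A <- expr$values[, ca, drop = FALSE]
  B <- expr$values[, cb, drop = FALSE]
  n <- nrow(A)
  tstat <- pval <- numeric(n)
  dmean <- rowMeans(A) - rowMeans(B)
  for (i in seq_len(n)) {
    a <- A[i, ]; b <- B[i, ]
    if (sd(a) == 0 && sd(b) == 0) {
      if (dmean[i] == 0) { tstat[i] <- 0; pval[i] <- 1 }
      else { tstat[i] <- sign(dmean[i]) * Inf; pval[i] <- 0 }
    } else {
      tt <- t.test(a, b, var.equal = var_equal)
      tstat[i] <- unname(tt$statistic)
      pval[i] <- tt$p.value
    }
  }
  data.frame(cluster_id = rownames(expr$values), diff = unname(dmean),
             t = tstat, p = pval, q = bh_adjust(pval),
             stringsAsFactors = FALSE)
}

#' Call regulated genes from transcript-cluster test results
#'
#' A gene is regulated when at least one of its transcript clusters is
#' differential at FDR < `alpha` and shows at least `min_diff` (fractional,
#' linear scale) expression difference, implemented on the log2 scale as
#' `|diff| >= log2(1 + min_diff)`. Direction comes from the sign of the
#' best cluster's control-minus-knockdown difference: positive = activated
#' by NF-kB, negative = repressed.
#'
#' @param results Output of [test_differential()].
#' @param ann A [gene_annotation()] carrying the transcript-cluster to gene
#'   mapping; clusters absent from the mapping are dropped with a warning.
#' @param pathway Label stored in the calls (`"canonical"` for the p50/RelA
#'   knockdown contrast, `"noncanonical"` for p52/RelB).
#' @param alpha FDR threshold (default 0.05).
#' @param min_diff Minimum fractional expression difference (default 0.10).
#' @return Data frame with one row per gene: `gene_id`, `pathway`,
#'   `regulated`, `direction` (`activated`/`repressed`/`none`),
#'   `cluster_id` (best evidence), `diff`, `q`.
#' @export
call_regulated_genes <- function(results, ann,
                                 pathway = c("canonical", "noncanonical"),
                                 alpha = 0.05, min_diff = 0.10) {
  pathway <- match.arg(pathway)
  map <- setNames(ann$clusters$gene_id, ann$clusters$cluster_id)
  gene <- map[results$cluster_id]
  if (anyNA(gene)) {
    warning(sum(is.na(gene)), " transcript cluster(s) not mapped to a gene; ",
            "excluded")
    results <- results[!is.na(gene), , drop = FALSE]
    gene <- gene[!is.na(gene)]
  }
  thresh <- log2(1 + min_diff)
  hit <- results$q < alpha & abs(results$diff) >= thresh
  out <- lapply(split(seq_along(gene), gene), function(idx) {
    r <- results[idx, , drop = FALSE]
    h <- hit[idx]
    if (any(h)) {
      cand <- which(h)
      best <- cand[order(r$q[cand], -abs(r$diff[cand]))][1L]
      data.frame(gene_id = gene[idx][1L], pathway = pathway, regulated = TRUE,
                 direction = if (r$diff[best] > 0) "activated" else "repressed",
                 cluster_id = r$cluster_id[best], diff = r$diff[best],
                 q = r$q[best], stringsAsFactors = FALSE)
    } else {
      best <- order(r$q)[1L]
      data.frame(gene_id = gene[idx][1L], pathway = pathway, regulated = FALSE,
                 direction = "none", cluster_id = r$cluster_id[best],
                 diff = r$diff[best], q = r$q[best], stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Define direct NF-kB target genes
#'
#' A canonical direct target is regulated upon p50/RelA knockdown and has at
#' least one assigned binding region containing p50; a non-canonical direct
#' target is regulated upon p52/RelB knockdown with at least one assigned
#' region containing p52. Genes regulated in neither knockdown are absent
#' from the table.
#'
#' @param calls Combined [call_regulated_genes()] output for both pathways
#'   (rbind of the canonical and noncanonical call tables).
#' @param links [assign_regions()] output.
#' @param m The `occupancy_matrix` the links index into.
#' @return A `target_gene_table` data frame: per regulated gene, per-pathway
#'   regulation, direction and direct-target flags, plus bound-subunit
#'   summary columns `has_p50`, `has_p52`. The attribute `venn` counts
#'   activated/repressed genes per pathway and their intersections.
#' @export
define_direct_targets <- function(calls, links, m) {
  stopifnot(all(c("gene_id", "pathway", "regulated", "direction") %in%
                  names(calls)))
  if (nrow(links) && (max(links$region) > nrow(m$regions) ||
                        min(links$region) < 1L)) {
    stop("link region indices out of range for the occupancy matrix")
  }
  bound <- split(links$region, links$gene_id)
  has_bit <- function(g, bit) {
    idx <- bound[[g]]
    !is.null(idx) && any(substr(m$codes[idx], bit, bit) == "1")
  }
  get_call <- function(p) {
    d <- calls[calls$pathway == p & calls$regulated, , drop = FALSE]
    setNames(d$direction, d$gene_id)
  }
  can <- get_call("canonical"); non <- get_call("noncanonical")
  genes <- sort(unique(c(names(can), names(non))))
  if (!length(genes)) {
    out <- data.frame(gene_id = character(0), canonical_regulated = logical(0),
                      canonical_direction = character(0),
                      canonical_direct = logical(0),
                      noncanonical_regulated = logical(0),
                      noncanonical_direction = character(0),
                      noncanonical_direct = logical(0),
                      has_p50 = logical(0), has_p52 = logical(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      gene_id = genes,
      canonical_regulated = genes %in% names(can),
      canonical_direction = ifelse(genes %in% names(can), can[genes], "none"),
      noncanonical_regulated = genes %in% names(non),
      noncanonical_direction = ifelse(genes %in% names(non), non[genes], "none"),
      has_p50 = vapply(genes, has_bit, logical(1), bit = 1L),
      has_p52 = vapply(genes, has_bit, logical(1), bit = 2L),
      stringsAsFactors = FALSE)
    out$canonical_direct <- out$canonical_regulated & out$has_p50
    out$noncanonical_direct <- out$noncanonical_regulated & out$has_p52
    out <- out[, c("gene_id", "canonical_regulated", "canonical_direction",
                   "canonical_direct", "noncanonical_regulated",
                   "noncanonical_direction", "noncanonical_direct",
                   "has_p50", "has_p52")]
  }
  venn <- sapply(c(activated = "activated", repressed = "repressed"),
                 function(dir) {
    c(canonical = sum(out$canonical_direct & out$canonical_direction == dir),
      noncanonical = sum(out$noncanonical_direct &
                           out$noncanonical_direction == dir),
      both = sum(out$canonical_direct & out$canonical_direction == dir &
                   out$noncanonical_direct &
                   out$noncanonical_direction == dir))
  })
  rownames(out) <- NULL
  class(out) <- c("target_gene_table", "data.frame")
  attr(out, "venn") <- venn
  out
}
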