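## Lymphoma-panel concordance: low-expression filtering, HL-vs-rest
## differential expression (same method as the knockdown analysis), and
## intersection of direct NF-kB targets with concordant expression changes.

#' Remove low-expression genes from a panel
#'
#' Drops rows whose mean log2 expression across all panel samples is
#' strictly below `floor` (Affymetrix-style hybridization-signal filter).
#'
#' @param panel An [expression_matrix()] on the log2 scale.
#' @param floor Log2 floor (default 6); the comparison is strict `<`, so a
#'   gene with mean exactly `floor` is retained.
#' @return The filtered [expression_matrix()]; warns when nothing survives.
#' @export
filter_low_expression <- function(panel, floor = 6) {
  stopifnot(inherits(panel, "expression_matrix"))
  keep <- rowMeans(panel$values) >= floor
  if (!any(keep)) {
    warning("all genes fall below the expression floor of ", floor)
  }
  expression_matrix(panel$values[keep, , drop = FALSE], panel$groups)
}

#' HL-versus-rest differential expression on a lymphoma panel
#'
#' Compares the HL samples against all remaining panel samples with the same
#' method as the knockdown analysis: per-row Welch t-test,
#' Benjamini-Hochberg control, and the gene-level FDR < `alpha` plus
#' >= `min_diff` fractional expression-difference rule. The difference is
#' HL minus rest, so positive means up in HL.
#'
#' @param panel An [expression_matrix()] whose groups include `hl_label`.
#' @param hl_label Group label of the HL samples (default `"HL"`).
#' @param alpha FDR threshold (default 0.05).
#' @param min_diff Minimum fractional expression difference (default 0.10).
#' @param var_equal Pooled-variance instead of Welch t-test.
#' @return Data frame per gene: `gene_id`, `diff`, `t`, `p`, `q`, `called`,
#'   `direction` (`up`/`down`/`none` in HL).
#' @export
hl_vs_rest <- function(panel, hl_label = "HL", alpha = 0.05, min_diff = 0.10,
                       var_equal = FALSE) {
  stopifnot(inherits(panel, "expression_matrix"))
  grp <- ifelse(panel$groups == hl_label, "HL", ".rest")
  if (sum(grp == "HL") < 2L || sum(grp == ".rest") < 2L) {
    stop("need >= 2 HL and >= 2 non-HL samples")
  }
  em <- expression_matrix(panel$values, setNames(grp, names(panel$groups)))
  res <- test_differential(em, "HL", ".rest", var_equal = var_equal)
  called <- res$q < alpha & abs(res$diff) >= log2(1 + min_diff)
  data.frame(gene_id = res$cluster_id, diff = res$diff, t = res$t, p = res$p,
             q = res$q, called = called,
             direction = ifelse(called, ifelse(res$diff > 0, "up", "down"),
                                "none"),
             stringsAsFactors = FALSE)
}

#' Concordant direct targets in the lymphoma panel
#'
#' Intersects direct NF-kB target genes with the HL-vs-rest differential
#' genes and keeps those with concordant changes: activated by NF-kB and up
#' in HL, or repressed and down in HL. Genes whose canonical and
#' non-canonical direct calls disagree in direction have no coherent NF-kB
#' direction and are excluded. Rows are ordered canonical-only, both,
#' non-canonical-only, then by direction.
#'
#' @param targets A `target_gene_table` (see [define_direct_targets()]).
#' @param hl_de Output of [hl_vs_rest()].
#' @param panel Optional filtered [expression_matrix()]; when given, the
#'   log2 submatrix of the concordant genes (heat-map export) is attached
#'   as attribute `heatmap`.
#' @return A `concordance_table` data frame: `gene_id`, `class`
#'   (`canonical`/`noncanonical`/`both`), `nfkb_direction`, `hl_direction`,
#'   `concordant` (all `TRUE`); attribute `n_concordant`.
#' @export
concordant_targets <- function(targets, hl_de, panel = NULL) {
  tg <- as.data.frame(targets)
  stopifnot(nrow(tg) > 0L, nrow(hl_de) > 0L)
  direct <- tg[tg$canonical_direct | tg$noncanonical_direct, , drop = FALSE]
  if (nrow(direct)) {
    nf_dir <- vapply(seq_len(nrow(direct)), function(i) {
      d <- direct[i, ]
      ds <- unique(c(if (d$canonical_direct) d$canonical_direction,
                     if (d$noncanonical_direct) d$noncanonical_direction))
      if (length(ds) == 1L) ds else NA_character_
    }, character(1))
    cls <- ifelse(direct$canonical_direct & direct$noncanonical_direct, "both",
                  ifelse(direct$canonical_direct, "canonical", "noncanonical"))
    de <- hl_de[match(direct$gene_id, hl_de$gene_id), , drop = FALSE]
    hl_dir <- ifelse(is.na(de$called) | !de$called, "none", de$direction)
    conc <- !is.na(nf_dir) &
      ((nf_dir == "activated" & hl_dir == "up") |
         (nf_dir == "repressed" & hl_dir == "down"))
    out <- data.frame(gene_id = direct$gene_id, class = cls,
                      nfkb_direction = nf_dir, hl_direction = hl_dir,
                      concordant = conc, stringsAsFactors = FALSE)
    out <- out[out$concordant, , drop = FALSE]
    ord <- order(match(out$class, c("canonical", "both", "noncanonical")),
                 match(out$nfkb_direction, c("activated", "repressed")),
                 out$gene_id)
    out <- out[ord, , drop = FALSE]
  } else {
    out <- data.frame(gene_id = character(0), class = character(0),
                      nfkb_direction = character(0),
                      hl_direction = character(0), concordant = logical(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("concordance_table", "data.frame")
  attr(out, "n_concordant") <- nrow(out)
  if (!is.null(panel) && nrow(out)) {
    keep <- intersect(out$gene_id, rownames(panel$values))
    attr(out, "heatmap") <- panel$values[keep, , drop = FALSE]
  }
  out
}
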