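# Knockdown differential expression and direct-target calling.

make_expr <- function(n = 20, n_per = 4, effect = 0, sigma = 0.2,
                      seed = 1) {
  set.seed(seed)
  samples <- c(paste0("a", 1:n_per), paste0("b", 1:n_per))
  groups <- setNames(rep(c("A", "B"), each = n_per), samples)
  m <- matrix(rnorm(n * 2 * n_per, 8, sigma), n, 2 * n_per,
              dimnames = list(sprintf("t%03d", 1:n), samples))
  m[1, groups == "B"] <- m[1, groups == "B"] - effect
  expression_matrix(m, groups)
}

test_that("per-row Welch tests flag a planted effect and control the null", {
  em <- make_expr(n = 50, n_per = 6, effect = 2, sigma = 0.1, seed = 2)
  de <- test_differential(em, "A", "B")
  expect_equal(de$cluster_id[1], "t001")
  expect_lt(de$q[1], 0.05)
  expect_equal(de$diff[1], 2, tolerance = 0.25)
  expect_gt(min(de$p[-1]), 0) # nulls are not degenerate
  expect_true(all(de$q >= de$p))
  em_null <- make_expr(n = 200, n_per = 6, effect = 0, seed = 3)
  de_null <- test_differential(em_null, "A", "B")
  expect_lt(mean(de_null$q < 0.05), 0.02)
})

test_that("groups with fewer than two samples are rejected", {
  em <- make_expr()
  em$groups[1] <- "C"
  expect_error(test_differential(em, "C", "B"), ">= 2 samples")
})

test_that("constant rows get P = 1 when means agree, P = 0 when not", {
  m <- rbind(t1 = c(5, 5, 5, 5), t2 = c(5, 5, 7, 7))
  colnames(m) <- c("a1", "a2", "b1", "b2")
  em <- expression_matrix(m, setNames(c("A", "A", "B", "B"), colnames(m)))
  de <- test_differential(em, "A", "B")
  expect_equal(de$p, c(1, 0))
})

test_that("the gene rule needs FDR < alpha AND a 10 % linear difference", {
  ann <- gene_annotation(
    data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1", strand = "+",
               tss = c(0L, 1000L, 2000L)),
    clusters = data.frame(cluster_id = c("t1", "t2", "t3a", "t3b"),
                          gene_id = c("g1", "g2", "g3", "g3")))
  res <- data.frame(cluster_id = c("t1", "t2", "t3a", "t3b"),
                    diff = c(0.2, 0.05, 0.1, -0.3),
                    t = 0, p = c(0.001, 0.001, 0.4, 0.001),
                    q = c(0.04, 0.04, 0.5, 0.01))
  calls <- call_regulated_genes(res, ann, "canonical")
  g <- function(id) calls[calls$gene_id == id, ]
  expect_true(g("g1")$regulated)          # 0.2 > log2(1.1) ~ 0.1375
  expect_equal(g("g1")$direction, "activated")
  expect_false(g("g2")$regulated)         # below the difference threshold
  expect_true(g("g3")$regulated)          # one qualifying cluster suffices
  expect_equal(g("g3")$direction, "repressed")
  expect_equal(g("g3")$cluster_id, "t3b")
})

test_that("negating all expression differences flips directions only", {
  ann <- simulate_genome(50, seed = 30)
  cis <- simulate_cistrome(ann, n_regions = 100, seed = 31)
  expr <- simulate_knockdown_expression(ann, cis$truth, effect_log2 = 1.5,
                                        sigma = 0.2, seed = 32)
  de <- test_differential(expr, "Group1", "Group2")
  de_neg <- de
  de_neg$diff <- -de$diff
  c1 <- call_regulated_genes(de, ann, "canonical")
  c2 <- call_regulated_genes(de_neg, ann, "canonical")
  expect_identical(c1$regulated, c2$regulated)
  swap <- c(activated = "repressed", repressed = "activated", none = "none")
  expect_identical(unname(swap[c1$direction]), c2$direction)
})

test_that("unmapped transcript clusters are dropped with a warning", {
  ann <- gene_annotation(data.frame(gene_id = "g1", chrom = "chr1",
                                    strand = "+", tss = 0L),
                         clusters = data.frame(cluster_id = "t1",
                                               gene_id = "g1"))
  res <- data.frame(cluster_id = c("t1", "tX"), diff = c(0.5, 0.5), t = 0,
                    p = c(0.001, 0.001), q = c(0.01, 0.01))
  expect_warning(calls <- call_regulated_genes(res, ann, "canonical"),
                 "not mapped")
  expect_equal(calls$gene_id, "g1")
})

test_that("direct targets require regulation plus the pathway's subunit", {
  pk50 <- regions("chr1", c(100L, 5000L), c(500L, 5400L))
  pk52 <- regions("chr1", 10000L, 10400L)
  m <- build_occupancy_matrix(list(p50 = pk50, p52 = pk52))
  links <- data.frame(region = c(1L, 2L, 3L), code = m$codes,
                      gene_id = c("gA", "gB", "gB"),
                      stratum = "proximal", evidence = "tss-window",
                      distance = 0)
  calls <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    pathway = c("canonical", "canonical", "noncanonical"),
    regulated = c(TRUE, TRUE, TRUE),
    direction = c("activated", "activated", "repressed"),
    stringsAsFactors = FALSE)
  tg <- define_direct_targets(calls, links, m)
  row <- function(g) tg[tg$gene_id == g, ]
  expect_true(row("gA")$canonical_direct)   # bound 1000, regulated canonical
  expect_true(row("gB")$canonical_direct)   # has a p50 region among links
  expect_false(row("gC")$noncanonical_direct) # regulated but unbound
  # bound-but-unregulated genes are absent from the table
  expect_false(any(tg$gene_id == "gD"))
  venn <- attr(tg, "venn")
  expect_equal(venn["canonical", "activated"], 2L)
  expect_equal(venn["noncanonical", "repressed"], 0L)
})

test_that("a gene whose only linked region lacks the subunit is not direct", {
  pk52 <- regions("chr1", 100L, 500L)
  m <- build_occupancy_matrix(list(p52 = pk52))
  links <- data.frame(region = 1L, code = "0100", gene_id = "gA",
                      stratum = "proximal", evidence = "tss-window",
                      distance = 0)
  calls <- data.frame(gene_id = "gA", pathway = "canonical", regulated = TRUE,
                      direction = "activated", stringsAsFactors = FALSE)
  tg <- define_direct_targets(calls, links, m)
  expect_true(tg$canonical_regulated)
  expect_false(tg$canonical_direct)
})
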