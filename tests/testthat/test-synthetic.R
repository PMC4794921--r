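# Synthetic-data generator: seeding contracts, conservation laws, planted
# effect sizes and multinomial pattern sampling.

test_that("gene placement is reproducible, collision-free and validated", {
  a1 <- simulate_genome(10, 1e6, seed = 1)
  a2 <- simulate_genome(10, 1e6, seed = 1)
  expect_identical(a1, a2)
  expect_false(identical(a1, simulate_genome(10, 1e6, seed = 2)))
  expect_equal(nrow(a1$genes), 10L)
  expect_true(all(diff(sort(a1$genes$tss)) >= 20000))
  expect_true(all(table(a1$genes$strand) == 5))
  expect_error(simulate_genome(0), "n_genes")
  expect_error(simulate_genome(100, 1e5), "too small")
})

test_that("every emitted peak belongs to a planted pattern with its subunit", {
  ann <- simulate_genome(30, seed = 3)
  cis <- simulate_cistrome(ann, n_regions = 50, seed = 4)
  planted <- cis$truth$regions
  expect_equal(nrow(planted), 50L)
  for (b in 1:4) {
    s <- c("p50", "p52", "RelA", "RelB")[b]
    n_expected <- sum(substr(planted$pattern, b, b) == "1")
    expect_equal(nrow(cis$peaks[[s]]), n_expected)
  }
  # conservation: pattern counts over planted regions sum to n_regions
  expect_equal(sum(table(planted$pattern)), 50L)
})

test_that("degenerate pattern frequencies place peaks exactly as coded", {
  ann <- simulate_genome(20, seed = 5)
  cis <- simulate_cistrome(ann, pattern_freqs = c("1111" = 1), n_regions = 5,
                           seed = 6)
  expect_true(all(vapply(cis$peaks, nrow, 0L) == 5L))
  # co-located: all four subunit peaks of a region share the summit
  summits <- sapply(cis$peaks, function(p) sort(p$start + p$summit))
  expect_true(all(summits == summits[, 1]))
  cis2 <- simulate_cistrome(ann, pattern_freqs = c("1100" = 1), n_regions = 5,
                            seed = 6)
  expect_equal(nrow(cis2$peaks$RelA), 0L)
  expect_equal(nrow(cis2$peaks$RelB), 0L)
  expect_error(simulate_cistrome(ann, proximal_frac = 1.2), "proximal_frac")
  expect_error(simulate_cistrome(ann, pattern_freqs = c("1100" = 0.5)),
               "sum to 1")
})

test_that("realized pattern frequencies follow the multinomial draw", {
  ann <- simulate_genome(600, seed = 7)
  freqs <- setNames(rep(1 / 15, 15), nfkbmap:::all_pattern_codes())
  cis <- simulate_cistrome(ann, pattern_freqs = freqs, n_regions = 2000,
                           seed = 8)
  counts <- table(factor(cis$truth$regions$pattern, levels = names(freqs)))
  p <- 1 / 15
  sd3 <- 3 * sqrt(2000 * p * (1 - p))
  expect_true(all(abs(counts - 2000 * p) <= sd3))
})

test_that("cistrome and expression simulators are byte-deterministic", {
  ann <- simulate_genome(20, seed = 9)
  c1 <- simulate_cistrome(ann, n_regions = 30, seed = 10)
  c2 <- simulate_cistrome(ann, n_regions = 30, seed = 10)
  expect_identical(c1, c2)
  e1 <- simulate_knockdown_expression(ann, c1$truth, seed = 11)
  e2 <- simulate_knockdown_expression(ann, c1$truth, seed = 11)
  expect_identical(e1, e2)
})

test_that("planted knockdown effects land where the truth says", {
  ann <- simulate_genome(40, seed = 13)
  cis <- simulate_cistrome(ann, n_regions = 80, seed = 14)
  expr <- simulate_knockdown_expression(ann, cis$truth, n_reps = 3,
                                        effect_log2 = 2, sigma = 0.1,
                                        seed = 15)
  tg <- cis$truth$genes
  act <- tg$gene_id[tg$canonical_direction == "activated"]
  skip_if(length(act) == 0)
  de <- test_differential(expr, "Group1", "Group2")
  map <- setNames(ann$clusters$gene_id, ann$clusters$cluster_id)
  d_act <- de$diff[map[de$cluster_id] %in% act]
  expect_true(all(abs(d_act - 2) < 0.2)) # Group1 - Group2 ~ +effect
  # unregulated genes stay near zero difference
  none <- tg$gene_id[tg$canonical_direction == "none"]
  d_none <- de$diff[map[de$cluster_id] %in% none]
  expect_true(all(abs(d_none) < 0.5))
})

test_that("a null knockdown produces no calls beyond chance", {
  ann <- simulate_genome(100, seed = 16)
  null_truth <- list(genes = data.frame(gene_id = character(0),
                                        canonical_direction = character(0),
                                        noncanonical_direction = character(0),
                                        stringsAsFactors = FALSE))
  expr <- simulate_knockdown_expression(ann, null_truth, effect_log2 = 0,
                                        sigma = 0.25, seed = 17)
  de <- test_differential(expr, "Group1", "Group2")
  calls <- call_regulated_genes(de, ann, "canonical")
  expect_lte(mean(calls$regulated), 0.05)
})

test_that("lymphoma panel plants the requested concordant fraction", {
  ann <- simulate_genome(60, seed = 18)
  cis <- simulate_cistrome(ann, n_regions = 120, seed = 19)
  p1 <- simulate_lymphoma_panel(cis$truth$genes, concordant_frac = 1,
                                seed = 20)
  usable <- !is.na(p1$truth$direction)
  expect_true(all(p1$truth$concordant[usable]))
  p0 <- simulate_lymphoma_panel(cis$truth$genes, concordant_frac = 0,
                                seed = 20)
  expect_equal(sum(p0$truth$concordant), 0L)
  expect_identical(p1,
                   simulate_lymphoma_panel(cis$truth$genes,
                                           concordant_frac = 1, seed = 20))
  expect_error(simulate_lymphoma_panel(cis$truth$genes, n_hl = 1),
               ">= 2 samples")
})
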