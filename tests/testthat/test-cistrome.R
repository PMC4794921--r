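# Occupancy-matrix construction, pattern combinatorics and profile
# clustering, checked against brute-force oracles on random instances.

test_that("co-located peaks in all four sets give one 1111 region", {
  pk <- regions("chr1", 100L, 200L)
  m <- build_occupancy_matrix(list(p50 = pk, p52 = pk, RelA = pk, RelB = pk))
  expect_equal(nrow(m$regions), 1L)
  expect_equal(m$codes, "1111")
})

test_that("disjoint single-subunit peaks stay separate with their code", {
  pk <- regions(c("chr1", "chr1"), c(100L, 300L), c(200L, 400L))
  m <- build_occupancy_matrix(list(p50 = pk))
  expect_equal(nrow(m$regions), 2L)
  expect_equal(m$codes, c("1000", "1000"))
})

test_that("merging respects the minimum-overlap criterion", {
  # abutting intervals (zero overlap) must not merge at min_overlap = 1
  d <- regions(c("chr1", "chr1"), c(0L, 100L), c(100L, 200L))
  expect_equal(nrow(merge_regions(d, 1L)), 2L)
  # 10 bp overlap merges at min_overlap 10 but not 11
  d2 <- regions(c("chr1", "chr1"), c(0L, 90L), c(100L, 200L))
  expect_equal(nrow(merge_regions(d2, 10L)), 1L)
  expect_equal(nrow(merge_regions(d2, 11L)), 2L)
})

test_that("unknown subunit names are rejected", {
  expect_error(build_occupancy_matrix(list(cRel = regions("chr1", 1L, 10L))),
               "unknown subunit")
})

test_that("unification and indicators match the exhaustive oracle", {
  set.seed(101)
  for (rep in 1:5) {
    ps <- random_peaksets(20L)
    m <- build_occupancy_matrix(ps)
    o <- oracle_occupancy(ps)
    expect_equal(m$regions[, c("chrom", "start", "end")], o$regions)
    expect_equal(unname(m$occ), unname(o$occ))
  }
})

test_that("re-unifying the unified regions is idempotent", {
  set.seed(7)
  ps <- random_peaksets(40L)
  m <- build_occupancy_matrix(ps)
  m2 <- build_occupancy_matrix(list(p50 = m$regions))
  expect_equal(m2$regions[, c("chrom", "start", "end")],
               m$regions[, c("chrom", "start", "end")])
})

test_that("pattern codes follow the fixed p50 p52 RelA RelB order", {
  expect_equal(pattern_code(c("p50", "p52")), "1100")
  expect_equal(pattern_code(c("p50", "RelA")), "1010")
  expect_equal(pattern_code(c("p52", "RelB")), "0101")
  expect_equal(pattern_code(c(1L, 1L, 0L, 1L)), "1101")
  expect_error(pattern_code(character(0)), "all-zero")
})

test_that("pattern frequencies are exact and normalized", {
  pk50 <- regions(c("chr1", "chr1", "chr1"), c(0L, 1000L, 2000L),
                  c(100L, 1100L, 2100L))
  pk52 <- pk50
  pkA <- pk50[3, ]; pkB <- pk50[3, ]
  m <- build_occupancy_matrix(list(p50 = pk50, p52 = pk52,
                                   RelA = pkA, RelB = pkB))
  pf <- pattern_frequencies(m)
  expect_equal(pf$count[pf$pattern == "1100"], 2L)
  expect_equal(pf$pct[pf$pattern == "1100"], 200 / 3)
  expect_equal(sum(pf$pct), 100, tolerance = 1e-6)
  expect_equal(sum(pf$count), attr(pf, "total"))
})

test_that("pattern counts and sharing agree with set-algebra oracles", {
  set.seed(202)
  for (rep in 1:5) {
    m <- build_occupancy_matrix(random_peaksets(25L))
    pf <- pattern_frequencies(m)
    o <- oracle_pattern_freqs(m$codes)
    expect_equal(setNames(pf$count, pf$pattern)[names(o$count)], o$count)
    sh <- sharing_statistics(m)
    osh <- oracle_sharing(m$occ)
    expect_equal(sh$shared, osh$shared)
    expect_equal(sh$pairwise, osh$pairwise)
  }
})

test_that("pattern conservation: per-subunit sums match indicator counts", {
  set.seed(9)
  m <- build_occupancy_matrix(random_peaksets(30L))
  pf <- pattern_frequencies(m)
  for (b in 1:4) {
    with_s <- substr(pf$pattern, b, b) == "1"
    expect_equal(sum(pf$count[with_s]), unname(colSums(m$occ)[b]))
  }
})

test_that("sharing statistics handle single-pattern edge cases", {
  pk <- regions("chr1", 100L, 200L)
  m <- build_occupancy_matrix(list(p50 = pk, p52 = pk))
  sh <- sharing_statistics(m)
  expect_equal(unname(sh$shared["p50"]), 1.0)
  expect_equal(sh$pairwise["p50", "p52"], 1.0)
  expect_true(is.na(sh$shared["RelA"]))
  m2 <- build_occupancy_matrix(list(p50 = regions("chr1", c(0L, 500L),
                                                  c(100L, 600L))))
  expect_equal(unname(sharing_statistics(m2)$shared["p50"]), 0.0)
})

test_that("TSS-distance histogram is signed, strand-aware and conserved", {
  genes <- data.frame(gene_id = c("A", "B"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(10000L, 50000L))
  ann <- gene_annotation(genes)
  # summit exactly at the + TSS; 500 bp downstream of it; far away
  pk <- regions(rep("chr1", 3), c(9800L, 10300L, 30000L),
                c(10200L, 10700L, 30400L), summit = 200L)
  m <- build_occupancy_matrix(list(p50 = pk))
  pr <- tss_distance_profile(m, ann, window = 5000L, nbins = 5L)
  expect_equal(sum(pr$counts) + pr$overflow, nrow(m$regions))
  expect_equal(pr$counts[3L], 2L) # central bin holds d=0 and d=+500
  expect_equal(pr$overflow, 1L)
  expect_equal(pr$distances[1:2], c(0, 500))
  # upstream of a - strand gene: summit right of the TSS => negative
  pk2 <- regions("chr1", 50800L, 51200L, summit = 200L)
  m2 <- build_occupancy_matrix(list(p50 = pk2))
  expect_equal(tss_distance_profile(m2, ann, 5000L, 5L)$distances, -1000)
  expect_error(tss_distance_profile(m, gene_annotation(genes[0, ]), 5000L, 5L),
               "empty annotation")
})

test_that("genomic feature labels follow promoter > exon > intron precedence", {
  genes <- data.frame(gene_id = "A", chrom = "chr1", strand = "+",
                      tss = 10000L, start = 10000L, end = 30000L)
  exons <- data.frame(gene_id = "A", start = c(10000L, 20000L),
                      end = c(10500L, 21000L))
  ann <- gene_annotation(genes, exons = exons)
  # canonical region order after unification: 9300, 15000, 20100, 80000
  pk <- regions(rep("chr1", 4),
                c(9300L, 15000L, 20100L, 80000L),
                c(9700L, 15400L, 20500L, 80400L), summit = 200L)
  m <- build_occupancy_matrix(list(p50 = pk))
  expect_equal(genomic_feature_annotation(m, ann, promoter_window = 2000L),
               c("promoter", "intron", "exon", "intergenic"))
})

test_that("profile k-means recovers planted clusters and is seed-stable", {
  ann <- simulate_genome(40, seed = 11)
  cis <- simulate_cistrome(ann, n_regions = 80,
                           pattern_freqs = c("1100" = 0.5, "0011" = 0.5),
                           seed = 12)
  m <- build_occupancy_matrix(cis$peaks)
  m <- attach_profiles(m, cis$profiles)
  cl <- cluster_profiles(m, k = 2L, seed = 5)
  # two well-separated profile groups: partition must match the codes
  expect_equal(length(unique(tapply(cl$labels, m$codes, function(x)
    length(unique(x))))), 1L)
  expect_true(all(tapply(cl$labels, m$codes, function(x)
    length(unique(x))) == 1L))
  cl2 <- cluster_profiles(m, k = 2L, seed = 5)
  expect_identical(cl$labels, cl2$labels)
  expect_error(cluster_profiles(m, k = nrow(m$regions) + 1L, seed = 1),
               "exceeds")
  # cluster x pattern percentages: rows sum to 100 for non-empty clusters
  expect_true(all(abs(rowSums(cl$cluster_pattern_pct) - 100) < 1e-6))
})

test_that("cistrome comparison matches identity, disjointness and oracle", {
  set.seed(33)
  psA <- random_peaksets(20L)
  mA <- build_occupancy_matrix(psA)
  cmp_id <- compare_cistromes(mA, mA)
  expect_true(all(cmp_id$overlap == 100, na.rm = TRUE))
  shift <- lapply(psA, function(d) regions(d$chrom, d$start + 50000L,
                                           d$end + 50000L))
  cmp0 <- compare_cistromes(mA, build_occupancy_matrix(shift))
  expect_true(all(cmp0$overlap == 0, na.rm = TRUE))
  psB <- random_peaksets(20L)
  mB <- build_occupancy_matrix(psB)
  cmp <- compare_cistromes(mA, mB)
  for (s in c("p50", "p52", "RelA", "RelB")) {
    ia <- mA$occ[, s] == 1L; ib <- mB$occ[, s] == 1L
    expect_equal(unname(cmp$overlap[s]),
                 100 * mean(oracle_any_overlap(mA$regions[ia, ],
                                               mB$regions[ib, ])))
  }
})
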