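# The binding-pattern logistic model: design construction, estimation,
# inference conventions and bootstrap stability.

simple_links <- function() {
  # three genes: gA one proximal 1101; gB proximal + distal 1100; gC 0101
  data.frame(region = 1:4,
             code = c("1101", "1100", "1100", "0101"),
             gene_id = c("gA", "gB", "gB", "gC"),
             stratum = c("proximal", "proximal", "distal", "proximal"),
             evidence = c("tss-window", "tss-window", "loop", "tss-window"),
             distance = c(0, 0, 50000, 0), stringsAsFactors = FALSE)
}

test_that("design features are one indicator per (pattern, stratum)", {
  ann <- simulate_genome(80, seed = 40)
  cis <- simulate_cistrome(ann, n_regions = 160, seed = 41)
  m <- build_occupancy_matrix(cis$peaks)
  links <- assign_regions(m, ann, loops = cis$loops)
  tg <- truth_targets(cis$truth$genes)
  d <- build_design_matrix(links, m, tg, "noncanonical-vs-none")
  expect_true(all(d$X %in% 0:1))
  # recount oracle: each feature's marginal equals a direct recount from links
  feat <- paste0(links$code, ":", links$stratum)
  for (f in colnames(d$X)) {
    carriers <- unique(links$gene_id[feat == f])
    expect_equal(unname(colSums(d$X)[f]),
                 length(intersect(carriers, rownames(d$X))))
  }
  # outcome: positives are the noncanonical-regulated genes
  expect_setequal(rownames(d$X)[d$y == 1],
                  intersect(tg$gene_id[tg$noncanonical_regulated],
                            unique(links$gene_id)))
  # negatives carry no regulation call at all
  expect_length(intersect(rownames(d$X)[d$y == 0], tg$gene_id), 0)
})

test_that("a gene with proximal and distal regions sets both features", {
  links <- simple_links()
  X_feats <- paste0(links$code, ":", links$stratum)
  expect_setequal(X_feats[links$gene_id == "gB"],
                  c("1100:proximal", "1100:distal"))
  expect_equal(sum(links$gene_id == "gA"), 1L)
})

test_that("contrasts with fewer than 10 genes per class are refused", {
  pk <- regions("chr1", seq(0L, 3900L, by = 1000L),
                seq(400L, 4300L, by = 1000L))
  m <- build_occupancy_matrix(list(p50 = pk))
  links <- data.frame(region = 1:4, code = "1000",
                      gene_id = paste0("g", 1:4), stratum = "proximal",
                      evidence = "tss-window", distance = 0)
  tg <- data.frame(gene_id = "g1", canonical_regulated = TRUE,
                   canonical_direction = "activated",
                   noncanonical_regulated = FALSE,
                   noncanonical_direction = "none")
  expect_error(build_design_matrix(links, m, tg, "canonical-vs-none"),
               "fewer than 10")
})

test_that("a strong planted coefficient is recovered inside its own CI", {
  beta <- c("1101:proximal" = 2, "1100:proximal" = 0, "1010:proximal" = 0,
            "0101:distal" = 0)
  sim <- simulate_pattern_design(2000, beta, seed = 42)
  fit <- fit_pattern_logit(sim$design)
  r <- fit$report[fit$report$feature == "1101:proximal", ]
  expect_true(r$ci_lo <= 2 && 2 <= r$ci_hi)
  expect_true(r$significant)
  expect_lt(abs(r$estimate - 2), 0.5)
  # CI ordering invariant
  obs <- fit$report[fit$report$observed, ]
  expect_true(all(obs$ci_lo <= obs$estimate & obs$estimate <= obs$ci_hi))
})

test_that("unobserved combinations are reported as missing, not estimated", {
  set.seed(43)
  X <- cbind("1100:proximal" = rbinom(60, 1, 0.5),
             "1111:proximal" = 0L)
  y <- rbinom(60, 1, plogis(-0.5 + X[, 1]))
  # the all-zero column is dropped at design level and resurfaces as missing
  d <- pattern_design(X[, 1, drop = FALSE], y,
                      unobserved = "1111:proximal")
  fit <- fit_pattern_logit(d)
  miss <- fit$report[fit$report$feature == "1111:proximal", ]
  expect_false(miss$observed)
  expect_true(is.na(miss$estimate) && is.na(miss$ci_lo))
})

test_that("perfect separation yields a missing estimate, not divergence", {
  set.seed(44)
  x2 <- rbinom(80, 1, 0.4)
  X <- cbind("1111:proximal" = rep(c(0L, 1L), each = 40),
             "1100:distal" = x2)
  y <- X[, 1] # separating feature
  d <- pattern_design(X, y)
  fit <- fit_pattern_logit(d)
  sep <- fit$report[fit$report$feature == "1111:proximal", ]
  expect_true(is.na(sep$estimate))
  expect_true(sep$observed)
  # a ridge-stabilized fit produces a finite estimate for the same design
  fit_r <- fit_pattern_logit(d, ridge = 1)
  sep_r <- fit_r$report[fit_r$report$feature == "1111:proximal", ]
  expect_true(is.finite(sep_r$estimate))
})

test_that("model methods behave like a fitted classed model", {
  beta <- c("1101:proximal" = 1.5, "1100:distal" = 0)
  sim <- simulate_pattern_design(500, beta, seed = 45)
  fit <- fit_pattern_logit(sim$design)
  expect_s3_class(fit, "pattern_logit")
  expect_named(coef(fit), sim$design$features$feature, ignore.order = TRUE)
  ci <- confint(fit)
  expect_equal(dim(ci), c(2L, 2L))
  pr <- predict(fit)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(length(pr), 500L)
  expect_output(print(fit), "pattern_logit")
  expect_output(print(summary(fit)), "log odds ratios")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit))
})

test_that("bootstrap stability is deterministic and rises with effect size", {
  stabs <- vapply(c(0, 1, 2), function(b) {
    sim <- simulate_pattern_design(
      600, c("1101:proximal" = b, "1100:distal" = 0), seed = 46)
    st <- bootstrap_stability(sim$design, B = 60, seed = 47)
    st$stability[st$feature == "1101:proximal"]
  }, 0)
  expect_true(all(diff(stabs) >= 0)) # monotone in |beta|
  sim <- simulate_pattern_design(600, c("1101:proximal" = 2,
                                        "1100:distal" = 0), seed = 48)
  s1 <- bootstrap_stability(sim$design, B = 40, seed = 7)
  s2 <- bootstrap_stability(sim$design, B = 40, seed = 7)
  expect_identical(s1, s2)
  expect_error(bootstrap_stability(sim$design, B = 0), "B must be >= 1")
})

test_that("the prototypic-dimer readout flags 1010/0101 correctly", {
  beta_null <- c("1010:proximal" = 0, "0101:proximal" = 0,
                 "1101:proximal" = 2)
  fit <- fit_pattern_logit(simulate_pattern_design(1500, beta_null,
                                                   seed = 49)$design)
  chk <- prototype_dimer_check(fit)
  expect_true(all(chk$status == "not significant"))
  beta_inv <- c("1010:proximal" = 0, "0101:proximal" = 2,
                "1101:proximal" = 0)
  fit2 <- fit_pattern_logit(simulate_pattern_design(1500, beta_inv,
                                                    seed = 50)$design)
  chk2 <- prototype_dimer_check(fit2)
  expect_equal(chk2$status[chk2$pattern == "0101"], "significant")
  # absent prototypic features are marked not observed
  fit3 <- fit_pattern_logit(simulate_pattern_design(
    400, c("1100:proximal" = 1), seed = 51)$design)
  expect_true(all(prototype_dimer_check(fit3)$status == "not observed"))
})

test_that("end-to-end synthetic fit recovers sign and significance", {
  ann <- simulate_genome(1200, seed = 52)
  cis <- simulate_cistrome(ann, n_regions = 2400, seed = 53)
  m <- build_occupancy_matrix(cis$peaks)
  links <- assign_regions(m, ann, loops = cis$loops)
  tg <- truth_targets(cis$truth$genes)
  d <- build_design_matrix(links, m, tg, "noncanonical-vs-none")
  fit <- fit_pattern_logit(d)
  rep <- fit$report
  bnc <- cis$truth$betas$noncanonical
  for (f in c("1101:proximal", "1101:distal")) { # planted log-odds 2
    r <- rep[rep$feature == f, ]
    expect_true(r$significant)
    expect_gt(r$estimate, 0)
  }
  # prototypic dimers planted at zero stay non-significant
  proto <- rep[rep$pattern %in% c("1010", "0101") & rep$observed, ]
  expect_true(all(!proto$significant))
})
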