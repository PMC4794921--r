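## Synthetic data with planted ground truth, emulating (at toy scale) the
## statistical structure of a four-subunit ChIP-seq cistrome, a four-group
## knockdown expression design, and a multi-entity lymphoma panel.
##
## Placement rules make the planted truth unambiguous: TSSs are spaced
## >= 20 kb apart, proximal regions fall within +-2 kb of their target TSS,
## distal regions 10-100 kb away but never within 6 kb of any TSS (with a
## loop linking them to the target promoter), and planted regions never
## overlap each other. A gene's regulation status is drawn from a logistic
## model on its true (pattern, stratum) features, so the generative
## coefficients are recoverable downstream.

#' Default pattern frequencies for the synthetic cistrome
#'
#' Qualitative shape of the combinatorial pattern spectrum: p50 and p52
#' dominate alone or in combination (the two singletons together make up
#' about 41 % of regions), RelB occurs mostly together with p50/p52, and
#' RelA is the least frequent subunit.
#'
#' @return Named numeric vector over the 15 non-empty 4-bit codes, summing
#'   to 1.
#' @export
default_pattern_freqs <- function() {
  f <- c("1000" = 0.200, "0100" = 0.210, "1100" = 0.180, "1110" = 0.040,
         "1101" = 0.120, "1111" = 0.080, "1010" = 0.040, "0101" = 0.050,
         "0110" = 0.030, "1001" = 0.020, "0010" = 0.010, "0001" = 0.010,
         "0011" = 0.005, "0111" = 0.003, "1011" = 0.002)
  f[all_pattern_codes()]
}

#' Default generative logistic coefficients
#'
#' Log-odds coefficients by (pattern, stratum) feature for the canonical and
#' non-canonical regulation models, encoding the qualitative structure the
#' pipeline is meant to detect: p50+p52 with RelB (1101) and the full
#' complement (1111) drive regulation, the non-canonical association is
#' distance-independent while the canonical one is proximal-only, and the
#' exclusive prototypic dimers (1010, 0101) carry no effect.
#'
#' @param intercept Baseline log-odds of regulation for a bound gene with no
#'   modeled feature (default -2).
#' @return List with named coefficient vectors `canonical`, `noncanonical`
#'   and the `intercept`.
#' @export
default_pattern_betas <- function(intercept = -2) {
  list(canonical = c("1111:proximal" = 2.0, "1101:proximal" = 1.5,
                     "1100:proximal" = 1.0),
       noncanonical = c("1101:proximal" = 2.0, "1101:distal" = 2.0,
                        "1100:proximal" = 1.5, "1100:distal" = 1.5,
                        "1111:proximal" = 1.0),
       intercept = intercept)
}

#' Simulate a toy gene annotation
#'
#' Places `n_genes` genes on a single chromosome with alternating strands,
#' TSSs at least 20 kb apart (no collisions), 1-3 transcript clusters per
#' gene, and a simple exon/intron body structure.
#'
#' @param n_genes Number of genes (>= 1).
#' @param chrom_length Chromosome length in bp; must allow 20 kb spacing.
#' @param seed Integer seed; output is identical for identical seeds.
#' @param chrom Chromosome name.
#' @return A [gene_annotation()].
#' @export
simulate_genome <- function(n_genes, chrom_length = n_genes * 30000,
                            seed = 1L, chrom = "chrS") {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  spacing <- chrom_length / n_genes
  if (spacing < 20000) {
    stop("genome too small to place ", n_genes, " genes with 20 kb spacing; ",
         "need chrom_length >= ", format(n_genes * 20000, scientific = FALSE))
  }
  set.seed(as.integer(seed))
  s <- max(0, (spacing - 20000) / 2)
  tss <- round((seq_len(n_genes) - 0.5) * spacing +
                 runif(n_genes, -s, s))
  strand <- rep(c("+", "-"), length.out = n_genes)
  body_len <- sample(5000:15000, n_genes, replace = TRUE)
  gstart <- ifelse(strand == "+", tss, pmax(tss - body_len + 1, 0))
  gend <- ifelse(strand == "+", pmin(tss + body_len, chrom_length), tss + 1)
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
                      chrom = chrom, strand = strand, tss = as.integer(tss),
                      start = as.integer(gstart), end = as.integer(gend),
                      stringsAsFactors = FALSE)
  n_cl <- sample(1:3, n_genes, replace = TRUE)
  clusters <- data.frame(
    cluster_id = sprintf("TC%05d", seq_len(sum(n_cl))),
    gene_id = rep(genes$gene_id, n_cl), stringsAsFactors = FALSE)
  # 2-4 exons per gene: alternate exon/intron segments across the body
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    ne <- sample(2:4, 1L)
    cuts <- sort(sample(seq(gstart[i] + 200, gend[i] - 200, by = 50),
                        2L * ne - 2L))
    bounds <- c(gstart[i], cuts, gend[i])
    data.frame(gene_id = genes$gene_id[i],
               start = as.integer(bounds[seq(1L, 2L * ne - 1L, by = 2L)]),
               end = as.integer(bounds[seq(2L, 2L * ne, by = 2L)]),
               stringsAsFactors = FALSE)
  }))
  gene_annotation(genes, clusters = clusters, exons = exons)
}

# Draws (pattern, stratum, position) for planted regions; rejection sampling
# keeps distal placements >= tss_margin from every TSS and all regions
# non-overlapping with a 200 bp margin (> 2x the peak-boundary jitter, so
# unified regions never merge across planted regions).
place_regions <- function(ann, n_regions, pattern_freqs, proximal_frac,
                          width, tss_margin = 6000) {
  genes <- ann$genes
  chrom_end <- max(genes$tss) + 110000
  tss <- genes$tss
  placed_start <- numeric(0); placed_end <- numeric(0)
  out <- vector("list", n_regions)
  gene_idx <- sample(rep_len(seq_len(nrow(genes)), n_regions))
  patterns <- sample(names(pattern_freqs), n_regions, replace = TRUE,
                     prob = pattern_freqs)
  for (i in seq_len(n_regions)) {
    gi <- gene_idx[i]
    proximal <- runif(1) < proximal_frac
    center <- NA_real_
    for (try in 1:200) {
      if (proximal) {
        cand <- tss[gi] + round(runif(1, -2000, 2000))
      } else {
        d <- round(runif(1, 10000, 100000)) * sample(c(-1, 1), 1L)
        cand <- tss[gi] + d
        if (min(abs(cand - tss)) < tss_margin) next
      }
      s <- cand - width / 2; e <- cand + width / 2
      if (s < 0 || e > chrom_end) next
      if (length(placed_start) &&
            any(pmin(placed_end + 200, e) > pmax(placed_start - 200, s))) next
      center <- cand
      break
    }
    if (is.na(center)) {
      stop("could not place region ", i, "; genome too crowded")
    }
    placed_start <- c(placed_start, s); placed_end <- c(placed_end, e)
    out[[i]] <- data.frame(
      chrom = genes$chrom[gi], start = as.integer(s), end = as.integer(e),
      summit = as.integer(width / 2), pattern = patterns[i],
      stratum = if (proximal) "proximal" else "distal",
      gene_id = genes$gene_id[gi], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a four-subunit cistrome with planted truth
#'
#' Plants `n_regions` binding regions with combinatorial pattern frequencies
#' `pattern_freqs`, proximal (+-2 kb of the target TSS) or distal (10-100 kb,
#' with an emitted chromatin loop to the target promoter) placement, emits
#' per-subunit peak sets (a region appears in exactly the subunit sets its
#' pattern indicates), summit-centered enrichment profiles (high signal iff
#' the subunit is present), a DHS site covering every region, and draws each
#' bound gene's regulation status per pathway from the logistic model
#' `P(regulated) = plogis(intercept + beta . x)` on the gene's true
#' (pattern, stratum) features. Regulated genes are assigned an activated or
#' repressed direction.
#'
#' @param ann A [gene_annotation()] (see [simulate_genome()]).
#' @param pattern_freqs Probabilities over the 15 non-empty pattern codes,
#'   summing to 1 (default [default_pattern_freqs()]).
#' @param proximal_frac Fraction of regions placed proximally (default 0.6).
#' @param n_regions Number of planted regions.
#' @param betas Generative coefficients, see [default_pattern_betas()].
#' @param p_activated Probability that a regulated gene is activated rather
#'   than repressed (default 0.5).
#' @param seed Integer seed.
#' @param width Planted region width in bp (default 400).
#' @param jitter Per-subunit peak boundary jitter in bp (default 25).
#' @param profile_bins Bins of the summit +-500 bp profile (default 50).
#' @return List with `peaks` (named list of 4 region sets), `profiles`
#'   (long-format profile table for [attach_profiles()]), `loops`
#'   ([loop_set()] for the distal regions), `dhs` (region set), and `truth`
#'   (a `sim_truth` list: planted `regions`, per-gene regulation table
#'   `genes`, feature matrix `features`, `betas`, `seed`).
#' @export
simulate_cistrome <- function(ann, pattern_freqs = default_pattern_freqs(),
                              proximal_frac = 0.6, n_regions = 200L,
                              betas = default_pattern_betas(),
                              p_activated = 0.5, seed = 1L, width = 400L,
                              jitter = 25L, profile_bins = 50L) {
  stopifnot(inherits(ann, "gene_annotation"))
  if (abs(sum(pattern_freqs) - 1) > 1e-9) {
    stop("pattern_freqs must sum to 1")
  }
  if (!all(names(pattern_freqs) %in% all_pattern_codes())) {
    stop("pattern_freqs names must be non-empty 4-bit codes")
  }
  if (proximal_frac < 0 || proximal_frac > 1) {
    stop("proximal_frac must be in [0, 1]")
  }
  set.seed(as.integer(seed))
  planted <- place_regions(ann, n_regions, pattern_freqs, proximal_frac,
                           width)

  # per-subunit peak files: jittered copies of each region whose pattern
  # contains the subunit; all copies share the absolute summit position
  peaks <- setNames(vector("list", 4L), SUBUNITS)
  center <- planted$start + planted$summit
  for (b in 1:4) {
    s <- SUBUNITS[b]
    sel <- substr(planted$pattern, b, b) == "1"
    if (!any(sel)) {
      peaks[[s]] <- regions(character(0), integer(0), integer(0))
      next
    }
    js <- sample(-jitter:jitter, sum(sel), replace = TRUE)
    je <- sample(-jitter:jitter, sum(sel), replace = TRUE)
    st <- planted$start[sel] + js
    en <- planted$end[sel] + je
    peaks[[s]] <- regions(planted$chrom[sel], st, en,
                          summit = center[sel] - st,
                          score = round(runif(sum(sel), 5, 50), 2))
  }

  # summit-centered profiles: Gaussian bump when the subunit is present
  bin_mid <- seq(-500 + 1000 / profile_bins / 2, 500, by = 1000 / profile_bins)
  prof <- do.call(rbind, lapply(1:4, function(b) {
    s <- SUBUNITS[b]
    present <- substr(planted$pattern, b, b) == "1"
    amp <- ifelse(present, runif(n_regions, 10, 30), 0)
    sig <- outer(amp, exp(-bin_mid^2 / (2 * 150^2))) +
      matrix(rnorm(n_regions * profile_bins, 0, 0.5),
             n_regions, profile_bins)
    d <- data.frame(chrom = planted$chrom, pos = center, subunit = s,
                    stringsAsFactors = FALSE)
    colnames(sig) <- sprintf("bin_%03d", seq_len(profile_bins))
    cbind(d, round(sig, 4))
  }))

  distal <- planted$stratum == "distal"
  gtss <- setNames(ann$genes$tss, ann$genes$gene_id)
  loops <- loop_set(data.frame(
    chromA = planted$chrom[distal], startA = planted$start[distal],
    endA = planted$end[distal],
    chromB = planted$chrom[distal],
    startB = as.integer(gtss[planted$gene_id[distal]] - 1000L),
    endB = as.integer(gtss[planted$gene_id[distal]] + 1000L),
    stringsAsFactors = FALSE))
  dhs <- regions(planted$chrom, pmax(planted$start - 100L, 0L),
                 planted$end + 100L)

  # per-gene true (pattern, stratum) features and logistic regulation draw
  feat <- paste0(planted$pattern, ":", planted$stratum)
  bound_genes <- sort(unique(planted$gene_id))
  feats <- sort(unique(feat))
  Xf <- matrix(0L, length(bound_genes), length(feats),
               dimnames = list(bound_genes, feats))
  Xf[cbind(match(planted$gene_id, bound_genes), match(feat, feats))] <- 1L
  draw_reg <- function(beta_vec) {
    bv <- setNames(rep(0, length(feats)), feats)
    common <- intersect(names(beta_vec), feats)
    bv[common] <- beta_vec[common]
    eta <- betas$intercept + drop(Xf %*% bv)
    rbinom(length(eta), 1L, plogis(eta)) == 1L
  }
  reg_can <- draw_reg(betas$canonical)
  reg_non <- draw_reg(betas$noncanonical)
  dir_draw <- function(reg) {
    ifelse(reg, ifelse(runif(length(reg)) < p_activated,
                       "activated", "repressed"), "none")
  }
  genes_truth <- data.frame(
    gene_id = bound_genes,
    canonical_regulated = reg_can,
    canonical_direction = dir_draw(reg_can),
    noncanonical_regulated = reg_non,
    noncanonical_direction = dir_draw(reg_non),
    stringsAsFactors = FALSE)
  has <- function(bit) vapply(bound_genes, function(g) {
    any(substr(planted$pattern[planted$gene_id == g], bit, bit) == "1")
  }, logical(1))
  genes_truth$has_p50 <- has(1L)
  genes_truth$has_p52 <- has(2L)
  genes_truth$canonical_direct <-
    genes_truth$canonical_regulated & genes_truth$has_p50
  genes_truth$noncanonical_direct <-
    genes_truth$noncanonical_regulated & genes_truth$has_p52

  truth <- list(regions = planted, genes = genes_truth, features = Xf,
                betas = betas, seed = as.integer(seed))
  class(truth) <- "sim_truth"
  list(peaks = peaks, profiles = prof, loops = loops, dhs = dhs,
       truth = truth)
}

#' Simulate knockdown expression for the four-group design
#'
#' Emulates two independent knockdown experiments, each with two siRNA
#' variants and `n_reps` biological replicates per sample: Group1/Group2 are
#' control/knockdown for the canonical (p50/RelA) experiment, Group3/Group4
#' for the non-canonical (p52/RelB) experiment. Transcript clusters of a
#' gene activated by a pathway are shifted down by `effect_log2` in that
#' pathway's knockdown group (repressed genes up); everything else is i.i.d.
#' Normal(baseline, sigma) in log2 space, with per-cluster baselines drawn
#' Normal(8, 1).
#'
#' @param ann A [gene_annotation()].
#' @param truth A `sim_truth` (see [simulate_cistrome()]); genes absent from
#'   it are unregulated.
#' @param n_reps Biological replicates per sample (>= 2; default 3, giving
#'   6 samples per group).
#' @param effect_log2 Planted knockdown effect in log2 units.
#' @param sigma Log2 noise standard deviation (> 0).
#' @param seed Integer seed.
#' @return An [expression_matrix()] with groups `Group1`..`Group4`.
#' @export
simulate_knockdown_expression <- function(ann, truth, n_reps = 3L,
                                          effect_log2 = 1, sigma = 0.25,
                                          seed = 1L) {
  stopifnot(inherits(ann, "gene_annotation"))
  if (n_reps < 2L) stop("n_reps must be >= 2")
  if (sigma <= 0) stop("sigma must be > 0")
  set.seed(as.integer(seed))
  cl <- ann$clusters
  samples <- character(0); groups <- character(0)
  for (g in 1:4) {
    for (v in 1:2) {
      nm <- sprintf("G%d_si%d_r%d", g, v, seq_len(n_reps))
      samples <- c(samples, nm)
      groups <- c(groups, rep(sprintf("Group%d", g), n_reps))
    }
  }
  baseline <- rnorm(nrow(cl), 8, 1)
  vals <- matrix(rnorm(nrow(cl) * length(samples), 0, sigma),
                 nrow(cl), length(samples),
                 dimnames = list(cl$cluster_id, samples)) + baseline
  tg <- truth$genes
  shift_for <- function(direction) {
    ifelse(direction == "activated", -effect_log2,
           ifelse(direction == "repressed", +effect_log2, 0))
  }
  can_shift <- setNames(shift_for(tg$canonical_direction), tg$gene_id)
  non_shift <- setNames(shift_for(tg$noncanonical_direction), tg$gene_id)
  gid <- cl$gene_id
  in_truth <- gid %in% tg$gene_id
  g2 <- groups == "Group2"; g4 <- groups == "Group4"
  vals[in_truth, g2] <- vals[in_truth, g2] + can_shift[gid[in_truth]]
  vals[in_truth, g4] <- vals[in_truth, g4] + non_shift[gid[in_truth]]
  expression_matrix(vals, setNames(groups, samples))
}

#' Simulate a multi-entity lymphoma expression panel with planted concordance
#'
#' Builds a log2 panel of Hodgkin-lymphoma (HL) samples versus other
#' lymphoma entities and normal B cells. A deterministic fraction
#' `concordant_frac` of the supplied direct-target genes is planted
#' concordant (activated targets shifted up in HL, repressed targets down by
#' `effect_log2`); the remaining targets are planted with the opposite
#' (anti-concordant) shift so the planted concordant set is exactly
#' recoverable. Background genes are unshifted and a fraction `low_frac` of
#' them is planted below the low-expression `floor`. Target baselines are
#' drawn Normal(9, 0.5) so no target is lost to the floor filter.
#'
#' @param targets A `target_gene_table` (or the `genes` table of a
#'   `sim_truth`): per-gene direct flags and directions.
#' @param n_hl Number of HL samples (>= 2).
#' @param n_other Number of non-HL samples (>= 2), split round-robin over
#'   DLBCL, BL, FL, NLPHL and normal germinal-center B cells.
#' @param concordant_frac Fraction of direct targets planted concordant.
#' @param effect_log2 Planted HL-vs-rest shift in log2 units (default 3).
#' @param sigma Log2 noise standard deviation (default 1).
#' @param floor Low-expression floor on the log2 scale (default 6).
#' @param low_frac Fraction of background genes planted below the floor.
#' @param n_background Number of non-target background genes.
#' @param seed Integer seed.
#' @return List with `panel` (an [expression_matrix()] with groups `HL` and
#'   entity labels) and `truth` (data frame: `gene_id`, `direction`,
#'   `concordant`, `low_expressed`).
#' @export
simulate_lymphoma_panel <- function(targets, n_hl = 10L, n_other = 20L,
                                    concordant_frac = 0.5, effect_log2 = 3,
                                    sigma = 1, floor = 6, low_frac = 0.1,
                                    n_background = 100L, seed = 1L) {
  if (n_hl < 2L || n_other < 2L) stop("need >= 2 samples per side")
  if (concordant_frac < 0 || concordant_frac > 1) {
    stop("concordant_frac must be in [0, 1]")
  }
  tg <- as.data.frame(targets)
  direct <- tg[tg$canonical_direct | tg$noncanonical_direct, , drop = FALSE]
  # per-gene NF-kB direction; genes whose two direct pathways disagree get
  # NA and are planted unshifted (they can never be concordant)
  direction <- vapply(seq_len(nrow(direct)), function(i) {
    d <- direct[i, ]
    ds <- unique(c(if (d$canonical_direct) d$canonical_direction,
                   if (d$noncanonical_direct) d$noncanonical_direction))
    if (length(ds) == 1L) ds else NA_character_
  }, character(1))
  set.seed(as.integer(seed))
  usable <- which(!is.na(direction))
  n_conc <- base::floor(concordant_frac * length(usable))
  conc_idx <- if (n_conc) sample(usable, n_conc) else integer(0)
  concordant <- seq_len(nrow(direct)) %in% conc_idx

  samples <- c(sprintf("HL_%02d", seq_len(n_hl)),
               sprintf("%s_%02d",
                       rep_len(c("DLBCL", "BL", "FL", "NLPHL", "GCB"),
                               n_other), seq_len(n_other)))
  groups <- setNames(sub("_[0-9]+$", "", samples), samples)
  hl <- groups == "HL"

  bg_ids <- sprintf("BG%04d", seq_len(n_background))
  ids <- c(direct$gene_id, bg_ids)
  n_low <- base::floor(low_frac * n_background)
  low <- c(rep(FALSE, nrow(direct)),
           seq_len(n_background) %in% sample.int(n_background, n_low))
  baseline <- c(rnorm(nrow(direct), 9, 0.5),
                ifelse(low[-seq_len(nrow(direct))],
                       rnorm(n_background, 4.5, 0.5),
                       rnorm(n_background, 8, 1)))
  vals <- matrix(rnorm(length(ids) * length(samples), 0, sigma),
                 length(ids), length(samples),
                 dimnames = list(ids, samples)) + baseline
  # planted HL shift: concordant = with the NF-kB direction, the rest against
  sgn <- ifelse(is.na(direction), 0, ifelse(direction == "activated", 1, -1))
  shift <- sgn * ifelse(concordant, effect_log2, -effect_log2)
  shift[is.na(direction)] <- 0
  vals[seq_len(nrow(direct)), hl] <- vals[seq_len(nrow(direct)), hl] + shift
  truth <- data.frame(gene_id = ids,
                      direction = c(direction, rep(NA_character_,
                                                   n_background)),
                      concordant = c(concordant, rep(FALSE, n_background)),
                      low_expressed = low, stringsAsFactors = FALSE)
  list(panel = expression_matrix(vals, groups), truth = truth)
}

#' Simulate a pattern design matrix with a planted logistic model
#'
#' Design-level generator for the parameter-recovery loop: binary (pattern,
#' stratum) features drawn independently per gene with the given carrier
#' probabilities, and a single 0/1 outcome drawn from
#' `P(y = 1) = plogis(intercept + X beta)`.
#'
#' @param n_genes Number of rows.
#' @param beta Named coefficient vector; names like `"1101:proximal"`.
#' @param intercept Model intercept (default -1).
#' @param feature_prob Carrier probability per feature column; recycled over
#'   `names(beta)` (default 0.15).
#' @param seed Integer seed.
#' @return List with `design` (a [pattern_design()]) and `beta` (the planted
#'   coefficients in column order).
#' @export
simulate_pattern_design <- function(n_genes, beta, intercept = -1,
                                    feature_prob = 0.15, seed = 1L) {
  stopifnot(!is.null(names(beta)), n_genes >= 1L)
  set.seed(as.integer(seed))
  p <- length(beta)
  prob <- rep_len(feature_prob, p)
  X <- matrix(0L, n_genes, p, dimnames = list(
    sprintf("G%05d", seq_len(n_genes)), names(beta)))
  for (j in seq_len(p)) X[, j] <- rbinom(n_genes, 1L, prob[j])
  eta <- intercept + drop(X %*% beta)
  y <- rbinom(n_genes, 1L, plogis(eta))
  list(design = pattern_design(X, y, contrast = "simulated"), beta = beta)
}

#' Write a complete synthetic dataset to disk
#'
#' Runs [simulate_genome()], [simulate_cistrome()],
#' [simulate_knockdown_expression()] and [simulate_lymphoma_panel()] with a
#' single master seed (fanned out per stage) and writes every artifact as a
#' plain-text file: per-subunit narrowPeak files, BEDPE loops, DHS BED,
#' annotation/expression/groups/panel TSVs, the profile table, a JSON truth
#' file and a ready-to-run pipeline configuration.
#'
#' @param dir Output directory (created if needed).
#' @param n_genes,n_regions Scale of the dataset.
#' @param n_reps Replicates per knockdown sample.
#' @param effect_log2,sigma Knockdown effect size and noise.
#' @param panel_effect_log2,panel_sigma Panel effect size and noise.
#' @param concordant_frac Fraction of direct targets planted concordant.
#' @param proximal_frac Fraction of regions placed proximally.
#' @param seed Master seed.
#' @param ... Further arguments to [simulate_cistrome()].
#' @return Named list of file paths (including `config`), invisibly; the
#'   `truth` component holds the in-memory truth objects.
#' @export
write_synthetic_dataset <- function(dir, n_genes = 220L, n_regions = 370L,
                                    n_reps = 3L, effect_log2 = 2,
                                    sigma = 0.02, panel_effect_log2 = 3,
                                    panel_sigma = 0.05,
                                    concordant_frac = 0.5,
                                    proximal_frac = 0.6, seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  ann <- simulate_genome(n_genes, seed = stage_seed(seed, "genome"))
  cis <- simulate_cistrome(ann, proximal_frac = proximal_frac,
                           n_regions = n_regions,
                           seed = stage_seed(seed, "cistrome"), ...)
  expr <- simulate_knockdown_expression(
    ann, cis$truth, n_reps = n_reps, effect_log2 = effect_log2,
    sigma = sigma, seed = stage_seed(seed, "knockdown"))
  panel <- simulate_lymphoma_panel(
    cis$truth$genes, concordant_frac = concordant_frac,
    effect_log2 = panel_effect_log2, sigma = panel_sigma,
    seed = stage_seed(seed, "panel"))

  files <- list()
  for (s in SUBUNITS) {
    files[[paste0("peaks_", s)]] <-
      write_bed(cis$peaks[[s]], pth(sprintf("peaks_%s.narrowPeak", s)),
                format = "narrowPeak")
  }
  files$loops <- write_loops(cis$loops, pth("loops.bedpe"))
  files$dhs <- write_bed(cis$dhs, pth("dhs.bed"), format = "bed3")
  files$annotation <- write_annotation(ann, pth("annotation.tsv"))
  write.table(cis$profiles, pth("profiles.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files$profiles <- pth("profiles.tsv")
  files$expression <- write_expression(expr, pth("knockdown_expression.tsv"))
  write.table(data.frame(sample = names(expr$groups), group = expr$groups),
              pth("knockdown_groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files$groups <- pth("knockdown_groups.tsv")
  files$panel <- write_expression(panel$panel, pth("panel.tsv"))
  write.table(data.frame(sample = names(panel$panel$groups),
                         class = panel$panel$groups),
              pth("panel_classes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files$panel_classes <- pth("panel_classes.tsv")
  jsonlite::write_json(
    list(regions = cis$truth$regions, genes = cis$truth$genes,
         betas = cis$truth$betas, panel = panel$truth,
         seed = as.integer(seed)),
    pth("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files$truth_json <- pth("truth.json")

  cfg <- pipeline_config(
    peaks = setNames(unlist(files[paste0("peaks_", SUBUNITS)],
                            use.names = FALSE), SUBUNITS),
    annotation = files$annotation, loops = files$loops, dhs = files$dhs,
    profiles = files$profiles, expression = files$expression,
    groups = files$groups, panel = files$panel,
    panel_classes = files$panel_classes, seed = as.integer(seed))
  yaml::write_yaml(unclass(cfg), pth("config.yaml"))
  files$config <- pth("config.yaml")
  files$truth <- list(cistrome = cis$truth, panel = panel$truth)
  invisible(files)
}
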