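## Config-driven orchestration of the full pipeline:
## cistrome -> assign -> de -> targets -> regress -> signature,
## with per-stage seeds, JSON run-logs and write-once output directories.

# Stable per-stage seed fan-out from one master seed; stays below 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Build and validate a pipeline configuration
#'
#' Collects the input file paths and every analysis threshold in one object:
#' FDR level `alpha` (0.05), minimum fractional expression difference
#' `min_diff` (0.10), panel low-expression `floor` (6 on the log2 scale),
#' profile-clustering `k` (8) and window half-width (500 bp),
#' region-to-gene `proximal_window` (5 kb) and `max_distal` (250 kb),
#' bootstrap size `B` and per-coefficient significance/stability cutoffs
#' (P < 0.01, stability >= 0.90), plus the master `seed`.
#'
#' @param peaks Named character vector of per-subunit peak files
#'   (p50, p52, RelA, RelB).
#' @param annotation Gene annotation file (TSV or GFF3).
#' @param expression,groups Knockdown expression TSV and its sample-to-group
#'   TSV (columns `sample`, `group`; groups `Group1`..`Group4`).
#' @param loops,dhs,profiles Optional BEDPE loops, DHS BED, and profile
#'   table TSV.
#' @param panel,panel_classes Optional lymphoma panel TSV and its
#'   sample-to-class TSV (columns `sample`, `class`).
#' @param alpha,min_diff,floor,k,window,proximal_window,max_distal,B,
#'   alpha_sig,stable_at Analysis thresholds (see above).
#' @param min_overlap Peak-merge overlap criterion in bp.
#' @param contrasts Regression contrasts to fit.
#' @param seed Master seed, fanned out per stage.
#' @param stages Stages to run, in dependency order.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(peaks, annotation, expression, groups,
                            loops = NULL, dhs = NULL, profiles = NULL,
                            panel = NULL, panel_classes = NULL,
                            alpha = 0.05, min_diff = 0.10, floor = 6,
                            k = 8L, window = 500L, min_overlap = 1L,
                            proximal_window = 5000L, max_distal = 250000L,
                            B = 1000L, alpha_sig = 0.01, stable_at = 0.90,
                            contrasts = CONTRASTS, seed = 1L,
                            stages = c("cistrome", "assign", "de", "targets",
                                       "regress", "signature")) {
  cfg <- list(peaks = as.list(peaks), annotation = annotation,
              expression = expression, groups = groups, loops = loops,
              dhs = dhs, profiles = profiles, panel = panel,
              panel_classes = panel_classes, alpha = alpha,
              min_diff = min_diff, floor = floor, k = as.integer(k),
              window = as.integer(window),
              min_overlap = as.integer(min_overlap),
              proximal_window = as.integer(proximal_window),
              max_distal = as.integer(max_distal), B = as.integer(B),
              alpha_sig = alpha_sig, stable_at = stable_at,
              contrasts = contrasts, seed = as.integer(seed),
              stages = stages)
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  chk(length(cfg$peaks) >= 1L, "at least one peak file required")
  normalize_subunits(names(cfg$peaks))
  chk(cfg$alpha > 0 && cfg$alpha <= 1, "alpha must be in (0, 1]")
  chk(cfg$min_diff >= 0, "min_diff must be >= 0")
  chk(cfg$k >= 2L, "k must be >= 2")
  chk(cfg$window > 0L, "window must be > 0")
  chk(cfg$min_overlap >= 1L, "min_overlap must be >= 1")
  chk(cfg$proximal_window > 0L && cfg$proximal_window < cfg$max_distal,
      "need 0 < proximal_window < max_distal")
  chk(cfg$B >= 1L, "B must be >= 1")
  chk(cfg$alpha_sig > 0 && cfg$alpha_sig < 1, "alpha_sig must be in (0, 1)")
  chk(cfg$stable_at > 0 && cfg$stable_at <= 1, "stable_at must be in (0, 1]")
  chk(all(cfg$stages %in% c("cistrome", "assign", "de", "targets", "regress",
                            "signature")), "unknown stage name")
  invisible(cfg)
}

#' Load a pipeline configuration from YAML/JSON
#' @param path Configuration file.
#' @return A validated `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- read_config(path)
  raw$peaks <- unlist(raw$peaks)
  do.call(pipeline_config, raw[!vapply(raw, is.null, NA)])
}

read_two_col <- function(path, value_col) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.character(df[[value_col]]), df$sample)
}

write_stage_log <- function(dir, stage, cfg, params, inputs, outputs) {
  inputs <- as.character(unlist(inputs))
  outputs <- as.character(unlist(outputs))
  hashes <- vapply(inputs, function(f) unname(tools::md5sum(f)), character(1))
  log <- list(stage = stage,
              package = as.character(utils::packageVersion("nfkbmap")),
              seed = stage_seed(cfg$seed, stage), parameters = params,
              input_md5 = as.list(hashes),
              outputs = as.list(basename(outputs)))
  jsonlite::write_json(log, file.path(dir, paste0(stage, "_runlog.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full pipeline
#'
#' Executes the configured stages in dependency order, writing each stage's
#' tables plus a JSON run-log (package version, stage seed, parameters,
#' input MD5 hashes) into `out_dir`. The configuration is serialized
#' verbatim into the output directory, the directory is write-once (reruns
#' need a fresh directory), and a rerun with an identical configuration is
#' byte-identical.
#'
#' @param config A [pipeline_config()] (or a path to a YAML/JSON config).
#' @param out_dir Output directory; must not already contain a run.
#' @return Named list of stage artifact paths, invisibly; the in-memory
#'   stage results are attached as attribute `results`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- load_pipeline_config(config)
  validate_config(config)
  cfg <- config
  if (dir.exists(out_dir) && length(list.files(out_dir))) {
    stop("output directory ", out_dir, " is not empty; ",
         "runs are write-once, use a fresh directory")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  pth <- function(f) file.path(out_dir, f)
  wr <- function(df, f) {
    write.table(df, pth(f), sep = "\t", quote = FALSE, row.names = FALSE)
    pth(f)
  }
  msg <- function(...) message("[nfkbmap] ", ...)
  need <- function(x, stage, dep) {
    if (is.null(x)) stop("stage '", stage, "' needs the output of stage '",
                         dep, "'; run it first")
    x
  }
  out <- list()
  res <- list()
  m <- NULL; links <- NULL; targets <- NULL; ann <- NULL

  if ("cistrome" %in% cfg$stages) {
    msg("cistrome: unifying ", length(cfg$peaks), " peak sets")
    peaksets <- lapply(cfg$peaks, read_bed)
    m <- build_occupancy_matrix(peaksets, min_overlap = cfg$min_overlap)
    out$unified <- write_bed(m$regions, pth("unified_regions.narrowPeak"),
                             format = "narrowPeak", name = m$codes)
    out$pattern_freqs <- wr(pattern_frequencies(m), "pattern_frequencies.tsv")
    sh <- sharing_statistics(m)
    out$sharing <- wr(data.frame(subunit = SUBUNITS, shared = sh$shared,
                                 sh$pairwise), "sharing.tsv")
    outputs <- c(out$unified, out$pattern_freqs, out$sharing)
    if (!is.null(cfg$profiles)) {
      prof <- read.delim(cfg$profiles, stringsAsFactors = FALSE)
      m <- attach_profiles(m, prof)
      cl <- cluster_profiles(m, k = cfg$k,
                             seed = stage_seed(cfg$seed, "cistrome"))
      out$clusters <- wr(data.frame(region = seq_along(cl$labels),
                                    code = m$codes, cluster = cl$labels),
                         "profile_clusters.tsv")
      res$clusters <- cl
      outputs <- c(outputs, out$clusters)
    }
    res$occupancy <- m
    write_stage_log(out_dir, "cistrome", cfg,
                    list(min_overlap = cfg$min_overlap, k = cfg$k,
                         window = cfg$window),
                    unlist(cfg$peaks), outputs)
  }

  if ("assign" %in% cfg$stages) {
    m <- need(m, "assign", "cistrome")
    ann <- read_annotation(cfg$annotation)
    loops <- if (!is.null(cfg$loops)) read_loops(cfg$loops) else NULL
    dhs <- if (!is.null(cfg$dhs)) read_bed(cfg$dhs) else NULL
    msg("assign: linking regions to genes")
    links <- assign_regions(m, ann, dhs = dhs, loops = loops,
                            proximal_window = cfg$proximal_window,
                            max_distal = cfg$max_distal)
    out$links <- wr(links, "region_gene_links.tsv")
    res$links <- links
    write_stage_log(out_dir, "assign", cfg,
                    list(proximal_window = cfg$proximal_window,
                         max_distal = cfg$max_distal),
                    c(cfg$annotation, cfg$loops, cfg$dhs), out$links)
  }

  calls <- NULL
  if ("de" %in% cfg$stages) {
    if (is.null(ann)) ann <- read_annotation(cfg$annotation)
    grp <- read_two_col(cfg$groups, "group")
    expr <- read_expression(cfg$expression, grp)
    msg("de: testing Group1 vs Group2 (canonical) and Group3 vs Group4 ",
        "(non-canonical)")
    de_can <- test_differential(expr, "Group1", "Group2")
    de_non <- test_differential(expr, "Group3", "Group4")
    out$de_canonical <- wr(de_can, "de_canonical_clusters.tsv")
    out$de_noncanonical <- wr(de_non, "de_noncanonical_clusters.tsv")
    calls <- rbind(
      call_regulated_genes(de_can, ann, "canonical", cfg$alpha, cfg$min_diff),
      call_regulated_genes(de_non, ann, "noncanonical", cfg$alpha,
                           cfg$min_diff))
    out$gene_calls <- wr(calls, "gene_regulation_calls.tsv")
    res$calls <- calls
    write_stage_log(out_dir, "de", cfg,
                    list(alpha = cfg$alpha, min_diff = cfg$min_diff),
                    c(cfg$expression, cfg$groups),
                    c(out$de_canonical, out$de_noncanonical, out$gene_calls))
  }

  if ("targets" %in% cfg$stages) {
    calls <- need(calls, "targets", "de")
    links <- need(links, "targets", "assign")
    targets <- define_direct_targets(calls, links, m)
    msg("targets: ", nrow(targets), " regulated genes, ",
        sum(targets$canonical_direct), " canonical / ",
        sum(targets$noncanonical_direct), " non-canonical direct targets")
    out$targets <- wr(as.data.frame(targets), "target_genes.tsv")
    res$targets <- targets
    write_stage_log(out_dir, "targets", cfg, list(), character(0),
                    out$targets)
  }

  if ("regress" %in% cfg$stages) {
    targets <- need(targets, "regress", "targets")
    reports <- list()
    for (ctr in cfg$contrasts) {
      fitted <- tryCatch({
        d <- build_design_matrix(links, m, targets, ctr)
        fit <- fit_pattern_logit(d, alpha_sig = cfg$alpha_sig)
        st <- bootstrap_stability(d, B = cfg$B,
                                  seed = stage_seed(cfg$seed, paste0(
                                    "regress:", ctr)),
                                  alpha_sig = cfg$alpha_sig,
                                  stable_at = cfg$stable_at)
        rpt <- merge(fit$report,
                     st[, c("feature", "stability", "stable")],
                     by = "feature", all.x = TRUE, sort = FALSE)
        rpt <- rpt[order(rpt$stratum, rpt$pattern), ]
        res[[paste0("fit_", ctr)]] <- fit
        rpt
      }, error = function(e) {
        msg("regress: skipping contrast '", ctr, "': ", conditionMessage(e))
        NULL
      })
      if (is.null(fitted)) next
      f <- sprintf("regression_%s.tsv", gsub("[^a-z]+", "_", ctr))
      reports[[ctr]] <- wr(fitted, f)
      msg("regress: ", ctr, " written")
    }
    out$regression <- unlist(reports)
    write_stage_log(out_dir, "regress", cfg,
                    list(B = cfg$B, alpha_sig = cfg$alpha_sig,
                         stable_at = cfg$stable_at,
                         contrasts = names(reports)),
                    character(0), out$regression)
  }

  if ("signature" %in% cfg$stages && !is.null(cfg$panel)) {
    targets <- need(targets, "signature", "targets")
    classes <- read_two_col(cfg$panel_classes, "class")
    panel <- read_expression(cfg$panel, classes)
    panel_f <- filter_low_expression(panel, floor = cfg$floor)
    de <- hl_vs_rest(panel_f, alpha = cfg$alpha, min_diff = cfg$min_diff)
    conc <- concordant_targets(targets, de, panel = panel_f)
    msg("signature: ", nrow(conc), " concordant direct targets")
    out$hl_de <- wr(de, "hl_vs_rest.tsv")
    out$concordance <- wr(as.data.frame(conc), "concordance.tsv")
    hm <- attr(conc, "heatmap")
    if (!is.null(hm)) {
      out$heatmap <- wr(data.frame(gene_id = rownames(hm), hm,
                                   check.names = FALSE),
                        "concordance_heatmap_log2.tsv")
    }
    res$concordance <- conc
    write_stage_log(out_dir, "signature", cfg,
                    list(floor = cfg$floor, alpha = cfg$alpha,
                         min_diff = cfg$min_diff),
                    c(cfg$panel, cfg$panel_classes),
                    c(out$hl_de, out$concordance))
  }

  attr(out, "results") <- res
  invisible(out)
}
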