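## The core model: logistic regression predicting gene regulation mode from
## distance-stratified combinatorial subunit binding patterns, with Wald
## inference and bootstrap stability scoring.
##
## A feature is one (4-bit pattern, stratum) pair, named like "1101:proximal".
## Coefficients are interpreted as log odds ratios; a feature never observed
## among the contrast's rows is reported with a missing estimate, mirroring
## the convention of reporting unobserved subunit combinations as missing
## rather than extrapolating.

CONTRASTS <- c("noncanonical-vs-none", "canonical-vs-none",
               "canonical-vs-noncanonical", "activated-vs-repressed")

#' Build a pattern design matrix for a regulation contrast
#'
#' Rows are genes with at least one assigned binding region; columns are
#' binary (pattern, stratum) indicator features: `feature(g, pattern,
#' stratum) = 1` iff gene `g` has at least one linked region with exactly
#' that pattern code in that stratum. Outcomes:
#' \describe{
#'   \item{noncanonical-vs-none}{1 = regulated by the non-canonical pathway,
#'     0 = bound but regulated by neither pathway (canonical-only genes are
#'     excluded).}
#'   \item{canonical-vs-none}{symmetric.}
#'   \item{canonical-vs-noncanonical}{rows restricted to regulated genes;
#'     1 = canonical (genes regulated by both pathways count as canonical),
#'     0 = non-canonical only.}
#'   \item{activated-vs-repressed}{rows restricted to regulated genes with a
#'     coherent direction; 1 = activated.}
#' }
#' Feature columns that are all-zero among the contrast's rows are dropped
#' and recorded as not observed.
#'
#' @param links [assign_regions()] output.
#' @param m The `occupancy_matrix` the links index into.
#' @param targets A `target_gene_table` from [define_direct_targets()]
#'   (regulated genes only; bound genes absent from it are the unregulated
#'   negatives).
#' @param contrast One of `"noncanonical-vs-none"`, `"canonical-vs-none"`,
#'   `"canonical-vs-noncanonical"`, `"activated-vs-repressed"`.
#' @return A `pattern_design` object: `X` (genes x features 0/1 matrix),
#'   `y` (0/1 outcome), `features` (data frame of pattern/stratum per kept
#'   column), `unobserved` (dropped feature names), `genes`, `contrast`.
#' @export
build_design_matrix <- function(links, m, targets, contrast = CONTRASTS) {
  contrast <- match.arg(contrast)
  stopifnot(nrow(links) > 0L)
  feat_name <- paste0(links$code, ":", links$stratum)
  gene_ids <- sort(unique(links$gene_id))
  feats <- sort(unique(feat_name))
  X <- matrix(0L, length(gene_ids), length(feats),
              dimnames = list(gene_ids, feats))
  X[cbind(match(links$gene_id, gene_ids), match(feat_name, feats))] <- 1L

  tg <- as.data.frame(targets)
  can <- setNames(tg$canonical_regulated, tg$gene_id)
  non <- setNames(tg$noncanonical_regulated, tg$gene_id)
  dir_can <- setNames(tg$canonical_direction, tg$gene_id)
  dir_non <- setNames(tg$noncanonical_direction, tg$gene_id)
  is_reg <- gene_ids %in% tg$gene_id
  can_v <- can[gene_ids]; non_v <- non[gene_ids]
  reg_can <- !is.na(can_v) & can_v
  reg_non <- !is.na(non_v) & non_v

  keep <- y <- NULL
  if (contrast == "noncanonical-vs-none") {
    keep <- reg_non | !is_reg
    y <- as.integer(reg_non[keep])
  } else if (contrast == "canonical-vs-none") {
    keep <- reg_can | !is_reg
    y <- as.integer(reg_can[keep])
  } else if (contrast == "canonical-vs-noncanonical") {
    keep <- is_reg
    y <- as.integer(reg_can[keep])
  } else { # activated-vs-repressed
    gdir <- vapply(gene_ids, function(g) {
      dc <- if (g %in% names(can) && can[[g]]) dir_can[[g]] else NA_character_
      dn <- if (g %in% names(non) && non[[g]]) dir_non[[g]] else NA_character_
      ds <- unique(stats::na.omit(c(dc, dn)))
      if (length(ds) == 1L) ds else NA_character_ # conflicting or none
    }, character(1))
    keep <- !is.na(gdir)
    y <- as.integer(gdir[keep] == "activated")
  }
  X <- X[keep, , drop = FALSE]
  if (min(sum(y == 1L), sum(y == 0L)) < 10L) {
    stop("contrast '", contrast, "' has fewer than 10 genes in one class; ",
         "provide a larger input")
  }
  observed <- colSums(X) > 0L
  unobserved <- colnames(X)[!observed]
  X <- X[, observed, drop = FALSE]
  parts <- strsplit(colnames(X), ":", fixed = TRUE)
  obj <- list(X = X, y = y,
              features = data.frame(
                feature = colnames(X),
                pattern = vapply(parts, `[[`, character(1), 1L),
                stratum = vapply(parts, `[[`, character(1), 2L),
                stringsAsFactors = FALSE),
              unobserved = unobserved,
              genes = rownames(X), contrast = contrast)
  class(obj) <- "pattern_design"
  obj
}

#' Construct a pattern design matrix directly
#'
#' Low-level constructor used when the design is produced outside
#' [build_design_matrix()] (e.g. by [simulate_pattern_design()]).
#'
#' @param X 0/1 matrix, columns named `"<pattern>:<stratum>"`.
#' @param y 0/1 outcome vector.
#' @param contrast Label for the contrast the outcome encodes.
#' @param unobserved Character vector of feature names observed nowhere.
#' @return A `pattern_design` object.
#' @export
pattern_design <- function(X, y, contrast = "custom",
                           unobserved = character(0)) {
  stopifnot(is.matrix(X), nrow(X) == length(y), all(X %in% 0:1),
            all(y %in% 0:1), !is.null(colnames(X)))
  parts <- strsplit(colnames(X), ":", fixed = TRUE)
  obj <- list(X = X, y = as.integer(y),
              features = data.frame(
                feature = colnames(X),
                pattern = vapply(parts, `[[`, character(1), 1L),
                stratum = vapply(parts, function(p)
                  if (length(p) > 1L) p[[2L]] else NA_character_, character(1)),
                stringsAsFactors = FALSE),
              unobserved = unobserved,
              genes = rownames(X), contrast = contrast)
  class(obj) <- "pattern_design"
  obj
}

#' @export
print.pattern_design <- function(x, ...) {
  cat(sprintf("pattern_design (%s): %d genes x %d features; %d/%d in class 1\n",
              x$contrast, nrow(x$X), ncol(x$X), sum(x$y), length(x$y)))
  if (length(x$unobserved)) {
    cat("not observed:", paste(x$unobserved, collapse = ", "), "\n")
  }
  invisible(x)
}

# Wald z inference from a fitted glm; features with exploded standard errors
# (perfect separation) are reported as missing estimates.
wald_report <- function(fit, features, se_limit = 20) {
  cf <- summary(fit)$coefficients
  out <- data.frame(feature = features,
                    estimate = NA_real_, se = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  rn <- rownames(cf)
  idx <- match(features, rn)
  ok <- !is.na(idx)
  out$estimate[ok] <- cf[idx[ok], 1L]
  out$se[ok] <- cf[idx[ok], 2L]
  out$p[ok] <- cf[idx[ok], 4L]
  z <- qnorm(0.975)
  out$ci_lo <- out$estimate - z * out$se
  out$ci_hi <- out$estimate + z * out$se
  sep <- !is.na(out$se) & (out$se > se_limit | abs(out$estimate) > se_limit)
  out[sep, c("estimate", "se", "ci_lo", "ci_hi", "p")] <- NA_real_
  out$separated <- sep
  out
}

#' Fit the combinatorial binding-pattern logistic regression
#'
#' Maximum-likelihood logistic regression of the contrast outcome on the
#' binary (pattern, stratum) features, with intercept. Coefficients are log
#' odds ratios; 95 % confidence intervals and P values are Wald-based.
#' Features causing perfect separation, and features not observed among the
#' contrast's rows, are reported with missing estimates. An optional
#' ridge-stabilized fit (quadratic penalty on the slopes) is available for
#' separated designs.
#'
#' @param design A `pattern_design`.
#' @param alpha_sig Significance threshold on the Wald P value (default 0.01).
#' @param ridge Ridge penalty lambda (0 = plain maximum likelihood).
#' @return A `pattern_logit` object with methods [print()], [summary()],
#'   [coef()], [confint()], [predict()] and [plot()]. The `$report` data
#'   frame has one row per feature (including unobserved ones): `feature`,
#'   `pattern`, `stratum`, `estimate`, `ci_lo`, `ci_hi`, `p`, `significant`,
#'   `observed`.
#' @export
fit_pattern_logit <- function(design, alpha_sig = 0.01, ridge = 0) {
  stopifnot(inherits(design, "pattern_design"))
  y <- design$y
  if (length(unique(y)) < 2L) stop("outcome has a single class; cannot fit")
  df <- data.frame(.y = y, design$X, check.names = FALSE)
  if (ridge > 0) {
    fit <- ridge_logit(design$X, y, lambda = ridge)
  } else {
    fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  }
  rep0 <- wald_report(fit, paste0("`", colnames(design$X), "`"))
  rep0$feature <- colnames(design$X)
  report <- merge(design$features, rep0, by = "feature", sort = FALSE)
  if (length(design$unobserved)) {
    parts <- strsplit(design$unobserved, ":", fixed = TRUE)
    report <- rbind(report, data.frame(
      feature = design$unobserved,
      pattern = vapply(parts, `[[`, character(1), 1L),
      stratum = vapply(parts, function(p)
        if (length(p) > 1L) p[[2L]] else NA_character_, character(1)),
      estimate = NA_real_, se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
      p = NA_real_, separated = FALSE, stringsAsFactors = FALSE))
  }
  report$observed <- !(report$feature %in% design$unobserved)
  report$significant <- !is.na(report$p) & report$p < alpha_sig
  report <- report[order(report$stratum, report$pattern), , drop = FALSE]
  rownames(report) <- NULL
  obj <- list(report = report, fit = fit, design = design,
              contrast = design$contrast, alpha_sig = alpha_sig,
              ridge = ridge)
  class(obj) <- "pattern_logit"
  obj
}

# Ridge-penalized logistic regression by Newton iterations; the intercept is
# unpenalized. Returns an object quacking enough like a glm for wald_report.
ridge_logit <- function(X, y, lambda = 1, max_iter = 100L, tol = 1e-9) {
  Z <- cbind(`(Intercept)` = 1, X)
  beta <- rep(0, ncol(Z))
  pen <- diag(c(0, rep(lambda, ncol(X))))
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    H <- crossprod(Z, Z * W) + pen
    g <- crossprod(Z, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(H)))
  zstat <- beta / se
  cf <- cbind(Estimate = beta, `Std. Error` = se, `z value` = zstat,
              `Pr(>|z|)` = 2 * pnorm(-abs(zstat)))
  rownames(cf) <- c("(Intercept)",
                    paste0("`", colnames(X), "`"))
  structure(list(coefficients = setNames(beta, rownames(cf)),
                 summary_coefficients = cf, lambda = lambda),
            class = "ridge_logit")
}

#' @export
summary.ridge_logit <- function(object, ...) {
  structure(list(coefficients = object$summary_coefficients),
            class = "summary.ridge_logit")
}

#' @export
print.pattern_logit <- function(x, ...) {
  r <- x$report
  cat(sprintf("pattern_logit: %s (%d genes, %d observed features%s)\n",
              x$contrast, nrow(x$design$X), sum(r$observed),
              if (x$ridge > 0) sprintf(", ridge=%g", x$ridge) else ""))
  sig <- r$feature[r$significant]
  cat("significant (P <", format(x$alpha_sig), "):",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @export
summary.pattern_logit <- function(object, ...) {
  structure(list(report = object$report, contrast = object$contrast,
                 n = nrow(object$design$X), alpha_sig = object$alpha_sig),
            class = "summary.pattern_logit")
}

#' @export
print.summary.pattern_logit <- function(x, ...) {
  cat(sprintf("Combinatorial binding-pattern logistic regression: %s\n",
              x$contrast))
  cat(sprintf("%d genes; coefficients are log odds ratios; Wald 95%% CIs\n",
              x$n))
  df <- x$report
  df$estimate <- round(df$estimate, 3)
  df$ci <- ifelse(is.na(df$ci_lo), "-",
                  sprintf("[%.2f, %.2f]", df$ci_lo, df$ci_hi))
  df$p <- signif(df$p, 3)
  print(df[, c("pattern", "stratum", "estimate", "ci", "p", "significant",
               "observed")], row.names = FALSE)
  invisible(x)
}

#' @export
coef.pattern_logit <- function(object, ...) {
  setNames(object$report$estimate, object$report$feature)
}

#' @export
confint.pattern_logit <- function(object, parm, level = 0.95, ...) {
  r <- object$report
  z <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(lower = r$estimate - z * r$se, upper = r$estimate + z * r$se)
  rownames(ci) <- r$feature
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.pattern_logit <- function(object, newdata = NULL,
                                  type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$design$X
    else if (inherits(newdata, "pattern_design")) newdata$X
    else as.matrix(newdata)
  feats <- colnames(object$design$X)
  Xn <- matrix(0, nrow(X), length(feats), dimnames = list(rownames(X), feats))
  common <- intersect(colnames(X), feats)
  Xn[, common] <- X[, common]
  cf <- coef(object$fit)
  cf[is.na(cf)] <- 0
  eta <- drop(cbind(1, Xn) %*% cf)
  if (type == "link") eta else plogis(eta)
}

#' Forest plot of a fitted binding-pattern model
#'
#' Log-odds estimates with 95 % confidence intervals per (pattern, stratum)
#' feature; filled points are significant at the model's threshold. When a
#' bootstrap stability table is supplied, stability percentages are drawn in
#' the right margin with the 90 % reference marked.
#'
#' @param x A `pattern_logit`.
#' @param stability Optional output of [bootstrap_stability()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pattern_logit <- function(x, stability = NULL, ...) {
  r <- x$report[x$report$observed, , drop = FALSE]
  r <- r[order(r$stratum, r$pattern), , drop = FALSE]
  n <- nrow(r)
  ypos <- rev(seq_len(n))
  xlim <- range(c(r$ci_lo, r$ci_hi, 0), na.rm = TRUE)
  op <- graphics::par(mar = c(4, 9, 2, if (is.null(stability)) 2 else 6))
  on.exit(graphics::par(op))
  graphics::plot(r$estimate, ypos, xlim = xlim, pch = ifelse(r$significant, 16, 1),
                 yaxt = "n", xlab = "log odds ratio", ylab = "",
                 main = x$contrast, panel.first = graphics::abline(v = 0, lty = 3), ...)
  graphics::segments(r$ci_lo, ypos, r$ci_hi, ypos)
  graphics::axis(2, at = ypos, labels = paste(r$pattern, r$stratum), las = 1,
                 cex.axis = 0.8)
  if (!is.null(stability)) {
    st <- stability$stability[match(r$feature, stability$feature)]
    graphics::mtext(sprintf("%.0f%%", 100 * st), side = 4, at = ypos, las = 1,
                    cex = 0.7, line = 0.5)
    graphics::mtext("bootstrap % P<0.01 (90% = stable)", side = 4, line = 4,
                    cex = 0.7)
  }
  invisible(x)
}

#' Bootstrap stability of the pattern-model coefficients
#'
#' Resamples genes with replacement `B` times, refits the logistic model,
#' and reports for each feature the fraction of resamples in which its Wald
#' P value is below `alpha_sig`. Features unobserved (all-zero) in a given
#' resample count as not significant there. A feature is flagged stable at
#' stability >= `stable_at`.
#'
#' @param design A `pattern_design`.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; the stability vector is deterministic given it.
#' @param alpha_sig Per-resample significance threshold (default 0.01).
#' @param stable_at Stability flag threshold (default 0.90).
#' @return Data frame `feature`, `pattern`, `stratum`, `stability`, `stable`.
#' @export
bootstrap_stability <- function(design, B = 1000L, seed = 1L,
                                alpha_sig = 0.01, stable_at = 0.90) {
  stopifnot(inherits(design, "pattern_design"))
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  X <- design$X; y <- design$y
  n <- nrow(X); p <- ncol(X)
  sig_count <- setNames(numeric(p), colnames(X))
  set.seed(as.integer(seed))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    Xb <- X[idx, , drop = FALSE]
    yb <- y[idx]
    obs <- colSums(Xb) > 0L
    if (!any(obs) || length(unique(yb)) < 2L) next
    fit <- suppressWarnings(
      glm.fit(cbind(1, Xb[, obs, drop = FALSE]), yb, family = binomial()))
    # Wald z from the IRLS weights at convergence
    W <- fit$weights
    Z <- cbind(1, Xb[, obs, drop = FALSE])
    H <- crossprod(Z, Z * W)
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(cov)) next
    se <- sqrt(pmax(diag(cov), 0))[-1L]
    est <- fit$coefficients[-1L]
    ok <- is.finite(se) & se > 0 & se < 20 & abs(est) < 20
    pv <- rep(NA_real_, sum(obs))
    pv[ok] <- 2 * pnorm(-abs(est[ok] / se[ok]))
    hit <- !is.na(pv) & pv < alpha_sig
    sig_count[colnames(X)[obs][hit]] <-
      sig_count[colnames(X)[obs][hit]] + 1
  }
  out <- data.frame(feature = colnames(X),
                    pattern = design$features$pattern,
                    stratum = design$features$stratum,
                    stability = unname(sig_count) / B,
                    stringsAsFactors = FALSE)
  out$stable <- out$stability >= stable_at
  out
}

#' Prototypic-dimer readout
#'
#' Extracts the `1010` (p50-RelA) and `0101` (p52-RelB) features — the
#' prototypic canonical and non-canonical dimers bound alone — from a fitted
#' model report, as the headline negative-control check that exclusive
#' prototypic-dimer recruitment is (or is not) associated with regulation.
#'
#' @param x A `pattern_logit` or its `$report` data frame.
#' @return Data frame of the prototypic-dimer features with columns
#'   `feature`, `pattern`, `stratum`, `estimate`, `p`, `significant`,
#'   `status` (`"significant"`, `"not significant"` or `"not observed"`).
#' @export
prototype_dimer_check <- function(x) {
  report <- if (inherits(x, "pattern_logit")) x$report else x
  proto <- c("1010", "0101")
  r <- report[report$pattern %in% proto, , drop = FALSE]
  if (!nrow(r)) {
    r <- data.frame(feature = proto, pattern = proto, stratum = NA_character_,
                    estimate = NA_real_, p = NA_real_, significant = FALSE,
                    observed = FALSE, stringsAsFactors = FALSE)
  }
  r$status <- ifelse(!r$observed, "not observed",
                     ifelse(r$significant, "significant", "not significant"))
  rownames(r) <- NULL
  r[, c("feature", "pattern", "stratum", "estimate", "p", "significant",
        "status")]
}
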