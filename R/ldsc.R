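#' Compute LD scores from a genotype panel
#'
#' The LD score of variant j is the sum of squared dosage correlations with
#' every variant k on the same chromosome whose position lies within
#' `window_bp` of j, including k = j (so unadjusted scores are at least 1).
#' An optional small-sample bias adjustment replaces each r-squared by
#' `r2 - (1 - r2) / (n - 2)`.
#'
#' @param genotypes A `genotype_matrix` (used as the LD reference panel).
#' @param window_bp Window half-width in base pairs (inclusive).
#' @param adjusted Apply the bias adjustment (requires `n >= 3`).
#' @return Data.frame with `id`, `chrom`, `pos`, `l` and a `monomorphic`
#'   flag; monomorphic variants contribute zero correlation everywhere and
#'   keep only their self-term.
#' @export
compute_ld_scores <- function(genotypes, window_bp = 1e6, adjusted = FALSE) {
  validate_genotype_matrix(genotypes)
  n <- nrow(genotypes$dosages)
  if (n < 2L) stopf("need at least 2 individuals to compute LD")
  if (adjusted && n < 3L) stopf("bias adjustment requires at least 3 individuals")
  if (window_bp <= 0) stopf("'window_bp' must be positive")
  v <- genotypes$variants
  l <- numeric(nrow(v))
  mono_all <- logical(nrow(v))
  for (c in unique(v$chrom)) {
    idx <- which(v$chrom == c)
    S <- standardize_dosages(genotypes$dosages[, idx, drop = FALSE])
    mono <- attr(S, "monomorphic")
    R <- crossprod(S) / (n - 1)
    r2 <- R^2
    if (adjusted) r2 <- r2 - (1 - r2) / (n - 2)
    # monomorphic variants: cross-correlations defined as 0 (flagged); the
    # self-term of every variant is kept so l_j >= 1 in the unadjusted case
    d <- diag(r2)
    r2[mono, ] <- 0
    r2[, mono] <- 0
    d[mono] <- 1
    diag(r2) <- d
    pos <- v$pos[idx]
    within <- abs(outer(pos, pos, "-")) <= window_bp
    l[idx] <- rowSums(r2 * within)
    mono_all[idx] <- mono
  }
  data.frame(id = v$id, chrom = v$chrom, pos = v$pos, l = l,
             monomorphic = mono_all, stringsAsFactors = FALSE)
}

# contiguous jackknife block ids for M variants
jackknife_blocks <- function(M, n_blocks) {
  n_blocks <- max(1L, min(n_blocks, M))
  sort(rep_len(seq_len(n_blocks), M))
}

jackknife_se <- function(estimates) {
  est <- estimates[is.finite(estimates)]
  B <- length(est)
  if (B < 2L) return(NA_real_)
  sqrt((B - 1) / B * sum((est - mean(est))^2))
}

ldsc_weights <- function(l, weights = c("ld", "none")) {
  weights <- match.arg(weights)
  if (weights == "ld") 1 / pmax(l, 1) else rep(1, length(l))
}

#' Estimate SNP heritability by LD score regression
#'
#' Weighted regression of the per-variant chi-squared statistic on
#' `N * l / M` with a free intercept: the slope estimates the SNP
#' heritability and the intercept absorbs confounding inflation. Standard
#' errors come from a leave-one-block-out jackknife over contiguous variant
#' blocks. Default weights are `1 / max(l, 1)`, countering the
#' heteroskedasticity of high-LD variants.
#'
#' @param sumstats Summary-statistics data.frame (needs `id`, `z`, `n`).
#' @param ld LD score data.frame from [compute_ld_scores()] (or any table
#'   with `id` and `l`).
#' @param n_blocks Number of jackknife blocks.
#' @param weights `"ld"` (default) or `"none"`.
#' @return An object of class `ldsc_h2`: `h2`, `intercept`, `se_h2`,
#'   `se_intercept`, `M`, `n_blocks`.
#' @export
estimate_h2 <- function(sumstats, ld, n_blocks = 50, weights = "ld") {
  d <- merge_sumstats_ld(sumstats, ld)
  fit_h2(d$z^2, d$n * d$l / nrow(d), d$l, n_blocks, weights)
}

merge_sumstats_ld <- function(sumstats, ld) {
  idx <- match(sumstats$id, ld$id)
  keep <- !is.na(idx) & is.finite(sumstats$z)
  d <- sumstats[keep, , drop = FALSE]
  d$l <- ld$l[idx[keep]]
  if (nrow(d) < 50L) stopf("need at least 50 variants overlapping the LD scores")
  d
}

fit_h2 <- function(chi2, x, l, n_blocks, weights) {
  if (stats::var(x) == 0) stopf("rank-deficient LD score regression: all predictors identical")
  w <- ldsc_weights(l, weights)
  cf <- wls_fit(x, chi2, w)
  blocks <- jackknife_blocks(length(x), n_blocks)
  jack <- vapply(unique(blocks), function(b) {
    keep <- blocks != b
    wls_fit(x[keep], chi2[keep], w[keep])
  }, numeric(2))
  out <- list(h2 = cf[2], intercept = cf[1],
              se_h2 = jackknife_se(jack[2, ]),
              se_intercept = jackknife_se(jack[1, ]),
              M = length(x), n_blocks = length(unique(blocks)))
  class(out) <- "ldsc_h2"
  out
}

#' @export
print.ldsc_h2 <- function(x, ...) {
  cat(sprintf("LD score regression: h2 = %.4f (se %.4f), intercept = %.4f (se %.4f), M = %d\n",
              x$h2, x$se_h2, x$intercept, x$se_intercept, x$M))
  invisible(x)
}

#' Cross-trait LD score regression: genetic correlation
#'
#' Estimates the genetic covariance between two traits by regressing the
#' per-variant z-score product on `sqrt(N1 N2) * l / M` with a free
#' intercept, estimates each trait's heritability by [estimate_h2()] on the
#' shared variants, and reports the genetic correlation
#' `rg = gencov / sqrt(h2_1 * h2_2)`. The standard error of rg is a
#' leave-one-block-out jackknife in which heritabilities, covariance and
#' their ratio are all re-estimated per deleted block; the p-value is a
#' two-sided normal test of rg = 0.
#'
#' Both input tables must already share effect-allele orientation (see
#' [harmonize()]); only variants present in both tables and in the LD score
#' table enter the regression.
#'
#' @param sumstats1,sumstats2 Summary-statistics data.frames.
#' @param ld LD score table.
#' @param n_blocks Jackknife blocks (default 50, suited to the few thousand
#'   variants of a desk-scale panel).
#' @param weights `"ld"` or `"none"`.
#' @return An object of class `ldsc_rg`: `rg`, `se_rg`, `p`, `gencov`,
#'   `h2_trait1`, `h2_trait2`, `intercept1`, `intercept2`,
#'   `cross_intercept`, `M`, `n_blocks`, and `reason` (`NA` unless rg is
#'   undefined because a heritability estimate was non-positive).
#' @export
estimate_rg <- function(sumstats1, sumstats2, ld, n_blocks = 50,
                        weights = "ld") {
  idx <- match(sumstats1$id, sumstats2$id)
  keep <- !is.na(idx)
  s1 <- sumstats1[keep, , drop = FALSE]
  s2 <- sumstats2[idx[keep], , drop = FALSE]
  lidx <- match(s1$id, ld$id)
  keep2 <- !is.na(lidx) & is.finite(s1$z) & is.finite(s2$z)
  s1 <- s1[keep2, , drop = FALSE]
  s2 <- s2[keep2, , drop = FALSE]
  l <- ld$l[lidx[keep2]]
  M <- nrow(s1)
  if (M < 50L) stopf("need at least 50 harmonized variants shared with the LD scores")

  w <- ldsc_weights(l, weights)
  x1 <- s1$n * l / M
  x2 <- s2$n * l / M
  xc <- sqrt(s1$n * s2$n) * l / M
  zz <- s1$z * s2$z

  est_all <- function(keep) {
    c1 <- wls_fit(x1[keep], s1$z[keep]^2, w[keep])
    c2 <- wls_fit(x2[keep], s2$z[keep]^2, w[keep])
    cc <- wls_fit(xc[keep], zz[keep], w[keep])
    rg <- if (c1[2] > 0 && c2[2] > 0) cc[2] / sqrt(c1[2] * c2[2]) else NA_real_
    c(h2_1 = c1[2], h2_2 = c2[2], gencov = cc[2], rg = rg,
      i1 = c1[1], i2 = c2[1], ic = cc[1])
  }
  full <- est_all(rep(TRUE, M))
  blocks <- jackknife_blocks(M, n_blocks)
  jack <- vapply(unique(blocks), function(b) est_all(blocks != b)["rg"],
                 numeric(1))
  se_rg <- jackknife_se(jack)

  reason <- NA_character_
  if (is.na(full["rg"])) {
    reason <- sprintf("undefined rg: non-positive heritability estimate (h2_1 = %.4g, h2_2 = %.4g)",
                      full["h2_1"], full["h2_2"])
  }
  p <- if (is.na(full["rg"]) || is.na(se_rg)) NA_real_ else
    2 * stats::pnorm(-abs(full["rg"] / se_rg))
  out <- list(rg = unname(full["rg"]), se_rg = se_rg, p = p,
              gencov = unname(full["gencov"]),
              h2_trait1 = unname(full["h2_1"]), h2_trait2 = unname(full["h2_2"]),
              intercept1 = unname(full["i1"]), intercept2 = unname(full["i2"]),
              cross_intercept = unname(full["ic"]),
              M = M, n_blocks = length(unique(blocks)), reason = reason)
  class(out) <- "ldsc_rg"
  out
}

#' @export
print.ldsc_rg <- function(x, ...) {
  if (!is.na(x$reason)) {
    cat(sprintf("Cross-trait LD score regression: %s\n", x$reason))
  } else {
    cat(sprintf("Cross-trait LD score regression (M = %d, %d jackknife blocks)\n",
                x$M, x$n_blocks))
    cat(sprintf("  rg = %.3f (se %.3f), p = %.3g\n", x$rg, x$se_rg, x$p))
    cat(sprintf("  h2: %.4f / %.4f; gencov = %.4f; intercepts %.3f / %.3f / cross %.3f\n",
                x$h2_trait1, x$h2_trait2, x$gencov,
                x$intercept1, x$intercept2, x$cross_intercept))
  }
  invisible(x)
}
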