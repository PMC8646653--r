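#' Simulate paired GWAS summary statistics under the bivariate LD score model
#'
#' Draws, independently per variant j with LD score l_j, a pair of
#' association z-scores from a bivariate normal with
#' \deqn{Var(z_{ij}) = 1 + N_i h^2_i l_j / M, \quad
#'       Cov(z_{1j}, z_{2j}) = \sqrt{N_1 N_2}\, r_g \sqrt{h^2_1 h^2_2}\, l_j / M,}
#' i.e. the generating model of cross-trait LD score regression with the
#' sample-overlap term fixed at zero (non-overlapping cohorts). Effect sizes
#' and standard errors are back-filled assuming unit phenotypic variance, so
#' `se = 1/sqrt(N)` and `beta = z * se`.
#'
#' @param m_variants Number of variants M.
#' @param ld_scores Vector of positive LD scores (length M, or length 1 to
#'   recycle).
#' @param n1,n2 GWAS sample sizes for the two traits.
#' @param h2_1,h2_2 Heritabilities in `[0, 1)`.
#' @param rg Genetic correlation, `|rg| <= 1`.
#' @param seed Integer seed.
#' @return A list of two summary-statistic data.frames (`trait1`, `trait2`),
#'   each with columns `id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `p`, `z`, `n`.
#' @examples
#' ss <- simulate_model_sumstats(1000, ld_scores = 10, n1 = 2e4, n2 = 2e4,
#'                               h2_1 = 0.3, h2_2 = 0.3, rg = 0.5, seed = 1)
#' mean(ss$trait1$z^2)
#' @export
simulate_model_sumstats <- function(m_variants, ld_scores, n1, n2,
                                    h2_1, h2_2, rg, seed = 1L) {
  if (!is_count(m_variants)) stopf("'m_variants' must be a positive integer")
  if (h2_1 < 0 || h2_1 >= 1 || h2_2 < 0 || h2_2 >= 1) {
    stopf("heritabilities must be in [0, 1)")
  }
  if (abs(rg) > 1) stopf("'rg' must satisfy |rg| <= 1")
  l <- rep_len(ld_scores, m_variants)
  if (any(l <= 0)) stopf("all LD scores must be positive")
  set.seed(derive_seed(seed, 4L))

  M <- m_variants
  v1 <- 1 + n1 * h2_1 * l / M
  v2 <- 1 + n2 * h2_2 * l / M
  cv <- sqrt(n1 * n2) * rg * sqrt(h2_1 * h2_2) * l / M
  bad <- which(cv^2 > v1 * v2 + 1e-12)
  if (length(bad) > 0L) {
    stopf("implied z covariance matrix not positive semi-definite at variant %d",
          bad[1])
  }
  a <- stats::rnorm(M)
  b <- stats::rnorm(M)
  z1 <- sqrt(v1) * a
  z2 <- (cv / sqrt(v1)) * a + sqrt(pmax(v2 - cv^2 / v1, 0)) * b

  ids <- sprintf("snp_%05d", seq_len(M))
  pos <- as.integer(seq_len(M)) * 10000L
  mk <- function(z, n) {
    se <- rep(1 / sqrt(n), M)
    data.frame(id = ids, chrom = 1L, pos = pos,
               effect_allele = "A", other_allele = "G",
               beta = z * se, se = se, p = 2 * stats::pnorm(-abs(z)),
               z = z, n = n, stringsAsFactors = FALSE)
  }
  list(trait1 = mk(z1, n1), trait2 = mk(z2, n2))
}
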