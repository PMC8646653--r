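#' Select variants below a p-value threshold
#'
#' Strict inequality (`p < threshold`), matching the convention of
#' thresholded polygenic scores; variants with missing p are excluded. An
#' empty selection is returned with a warning (scores computed from it are
#' zero for everyone).
#'
#' @param sumstats Summary-statistics data.frame.
#' @param threshold P-value cut-off in `(0, 1]`.
#' @return The selected rows of `sumstats`.
#' @export
select_variants <- function(sumstats, threshold) {
  if (threshold <= 0 || threshold > 1) stopf("'threshold' must be in (0, 1]")
  out <- sumstats[!is.na(sumstats$p) & sumstats$p < threshold, , drop = FALSE]
  if (nrow(out) == 0L) warnf("no variant passes p < %g", threshold)
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the most significant unclaimed variant as an index and
#' removes every unclaimed variant on the same chromosome within
#' `clump_window_bp` whose squared dosage correlation with the index reaches
#' `clump_r2`. Ties in p are broken by (chromosome, position), making the
#' procedure fully deterministic.
#'
#' @param subset Summary-statistics rows (e.g. from [select_variants()]).
#' @param genotypes `genotype_matrix` covering the subset (the LD reference).
#' @param clump_r2 Squared-correlation threshold in `(0, 1]`.
#' @param clump_window_bp Window half-width in base pairs.
#' @return The retained rows of `subset`, in the original row order.
#' @export
ld_clump <- function(subset, genotypes, clump_r2 = 0.1,
                     clump_window_bp = 250000) {
  if (clump_r2 <= 0 || clump_r2 > 1) stopf("'clump_r2' must be in (0, 1]")
  if (nrow(subset) <= 1L) return(subset)
  idx <- match(subset$id, genotypes$variants$id)
  if (anyNA(idx)) stopf("genotypes do not cover %d subset variant(s)", sum(is.na(idx)))
  S <- standardize_dosages(genotypes$dosages[, idx, drop = FALSE])
  n <- nrow(S)
  chrom <- genotypes$variants$chrom[idx]
  pos <- genotypes$variants$pos[idx]
  ord <- order(subset$p, chrom, pos)
  claimed <- rep(FALSE, nrow(subset))
  keep <- rep(FALSE, nrow(subset))
  for (i in ord) {
    if (claimed[i]) next
    keep[i] <- TRUE
    claimed[i] <- TRUE
    near <- which(!claimed & chrom == chrom[i] &
                    abs(pos - pos[i]) <= clump_window_bp)
    if (length(near) > 0L) {
      r <- as.vector(crossprod(S[, i], S[, near, drop = FALSE])) / (n - 1)
      claimed[near[r^2 >= clump_r2]] <- TRUE
    }
  }
  out <- subset[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute polygenic risk scores in sum-calculation mode
#'
#' Per individual, the score is the plain weighted sum
#' `sum_j beta_j * dosage_ij` over the supplied variants — no shrinkage and
#' no regression on phenotype. Weights and genotypes must already share
#' effect-allele orientation. Missing dosages contribute zero and are
#' counted; weight variants absent from the genotype matrix are dropped with
#' a logged count. X-chromosomal male dosages are either kept on the 0/2
#' hemizygous coding (`"zero_two"`, the common scoring default) or halved to
#' 0/1 (`"zero_one"`).
#'
#' @param genotypes A `genotype_matrix`.
#' @param weights Data.frame with `id` and `beta` (typically thresholded,
#'   clumped summary statistics).
#' @param male_x_dosage `"zero_two"` or `"zero_one"`.
#' @param x_chrom Value of the chromosome column denoting the X chromosome.
#' @return An object of class `prs_result`: data.frame with `individual_id`
#'   and `score`; attributes `n_variants_used`, `variant_ids`,
#'   `n_dropped_missing_variant`, `n_missing_dosages`.
#' @export
compute_prs <- function(genotypes, weights,
                        male_x_dosage = c("zero_two", "zero_one"),
                        x_chrom = "X") {
  male_x_dosage <- match.arg(male_x_dosage)
  validate_genotype_matrix(genotypes)
  idx <- match(weights$id, genotypes$variants$id)
  dropped <- sum(is.na(idx))
  keep <- !is.na(idx)
  idx <- idx[keep]
  beta <- weights$beta[keep]
  n <- nrow(genotypes$dosages)
  if (length(idx) == 0L) {
    score <- rep(0, n)
    n_missing <- 0L
  } else {
    D <- genotypes$dosages[, idx, drop = FALSE]
    storage.mode(D) <- "double"
    if (male_x_dosage == "zero_one") {
      is_x <- genotypes$variants$chrom[idx] == x_chrom
      is_male <- genotypes$individuals$sex == "male"
      if (any(is_x) && any(is_male)) {
        D[is_male, is_x] <- D[is_male, is_x] / 2
      }
    }
    n_missing <- sum(is.na(D))
    if (n_missing > 0L) D[is.na(D)] <- 0
    score <- as.vector(D %*% beta)
  }
  out <- data.frame(individual_id = genotypes$individuals$id, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "n_variants_used") <- length(idx)
  attr(out, "variant_ids") <- genotypes$variants$id[idx]
  attr(out, "n_dropped_missing_variant") <- dropped
  attr(out, "n_missing_dosages") <- n_missing
  class(out) <- c("prs_result", "data.frame")
  out
}

#' Sex-stratified, age-corrected association of a polygenic score
#'
#' Logistic regression of hospitalization on (intercept, standardized score,
#' age at event) within one sex stratum. The score is z-scored within the
#' stratum so the reported effect is log-odds per score standard deviation.
#'
#' @param prs A `prs_result` (or data.frame with `individual_id`, `score`).
#' @param phenotypes Phenotype data.frame.
#' @param sex `"male"` or `"female"`.
#' @param label Optional label (e.g. the p-value threshold) carried through.
#' @return Data.frame row with `sex`, `label`, `beta`, `se`, `p`, `z`,
#'   `n_cases`, `n_controls`, `n_variants`.
#' @export
associate_prs <- function(prs, phenotypes, sex = c("male", "female"),
                          label = NA) {
  sex <- match.arg(sex)
  d <- phenotypes[match(prs$individual_id, phenotypes$individual_id), ,
                  drop = FALSE]
  d$score <- prs$score
  d <- d[!is.na(d$sex) & d$sex == sex, , drop = FALSE]
  n_cases <- sum(d$hospitalized)
  n_controls <- sum(!d$hospitalized)
  if (n_cases == 0L || n_controls == 0L) {
    stopf("need at least one case and one control among %ss", sex)
  }
  row <- data.frame(sex = sex, label = label, beta = NA_real_, se = NA_real_,
                    p = NA_real_, z = NA_real_, n_cases = n_cases,
                    n_controls = n_controls,
                    n_variants = attr(prs, "n_variants_used") %||% NA_integer_,
                    stringsAsFactors = FALSE)
  if (stats::sd(d$score) == 0) {
    warnf("constant polygenic score in the %s stratum; association undefined", sex)
    return(row)
  }
  score_std <- as.vector(scale(d$score))
  X <- cbind(1, score_std, d$age_at_event)
  y <- as.numeric(d$hospitalized)
  fit <- fast_logistic(X, y)
  if (is.null(fit)) {
    gf <- tryCatch(suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())),
                   error = function(e) NULL)
    if (is.null(gf) || !gf$converged || anyNA(gf$coefficients)) {
      stopf("polygenic score association did not converge (possible separation)")
    }
    mu <- gf$fitted.values
    V <- solve(crossprod(X, X * (mu * (1 - mu))))
    fit <- list(coef = gf$coefficients, se = sqrt(diag(V)))
  }
  row$beta <- fit$coef[2]
  row$se <- fit$se[2]
  row$z <- row$beta / row$se
  row$p <- 2 * stats::pnorm(-abs(row$z))
  row
}
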