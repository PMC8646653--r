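#' Per-variant association scan (GWAS) on a simulated cohort
#'
#' Regresses a phenotype on each variant's dosage plus covariates, one
#' variant at a time. The linear model is solved for all variants at once by
#' projecting phenotype and dosages off the covariate space (exact ordinary
#' least squares); the logistic model fits an IRLS regression per variant.
#' Monomorphic variants are emitted with missing effect estimates and
#' flagged, as are logistic fits that fail to converge; the scan never stops
#' for a single bad variant.
#'
#' @param genotypes A `genotype_matrix`.
#' @param phenotype Numeric (linear) or 0/1 / logical (logistic) vector
#'   aligned to `genotypes$individuals`; `NA` entries are dropped.
#' @param covariates Optional numeric vector/matrix of covariates (e.g. age),
#'   aligned the same way. An intercept is always included.
#' @param model `"linear"` or `"logistic"`.
#' @param subset Optional logical/integer index restricting individuals
#'   (e.g. males only).
#' @return A summary-statistics data.frame (`id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `p`, `z`, `n`, `note`)
#'   with the coded allele as effect allele. Attribute `n_flagged` counts
#'   monomorphic/non-converged variants.
#' @export
run_gwas <- function(genotypes, phenotype, covariates = NULL,
                     model = c("linear", "logistic"), subset = NULL) {
  model <- match.arg(model)
  validate_genotype_matrix(genotypes)
  G <- genotypes$dosages
  y <- phenotype
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (!is.null(subset)) {
    G <- G[subset, , drop = FALSE]
    y <- y[subset]
    if (!is.null(X)) X <- X[subset, , drop = FALSE]
  }
  keep <- !is.na(y)
  if (!is.null(X)) keep <- keep & stats::complete.cases(X)
  G <- G[keep, , drop = FALSE]
  y <- as.numeric(y[keep])
  if (!is.null(X)) X <- X[keep, , drop = FALSE]
  n <- length(y)
  if (stats::var(y) == 0) stopf("phenotype is constant")
  m <- ncol(G)
  Xf <- cbind(`(Intercept)` = rep(1, n), X)

  beta <- se <- rep(NA_real_, m)
  note <- rep("", m)
  mono <- apply(G, 2L, function(g) length(unique(g)) < 2L)
  note[mono] <- "monomorphic"

  if (model == "linear") {
    Q <- qr.Q(qr(Xf))
    yr <- y - Q %*% crossprod(Q, y)
    Gr <- G - Q %*% crossprod(Q, G)
    gg <- colSums(Gr^2)
    gy <- as.vector(crossprod(Gr, yr))
    ok <- !mono & gg > 1e-12
    b <- gy[ok] / gg[ok]
    rss <- sum(yr^2) - b^2 * gg[ok]
    df <- n - ncol(Xf) - 1L
    if (df <= 0L) stopf("not enough individuals for the covariate model")
    beta[ok] <- b
    se[ok] <- sqrt(pmax(rss, 0) / df / gg[ok])
  } else {
    for (j in seq_len(m)) {
      if (mono[j]) next
      fit <- tryCatch(
        suppressWarnings(stats::glm.fit(cbind(Xf[, 1, drop = FALSE],
                                              dosage = G[, j],
                                              Xf[, -1, drop = FALSE]),
                                        y, family = stats::binomial())),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) {
        note[j] <- "non_converged"
        next
      }
      mu <- fit$fitted.values
      W <- mu * (1 - mu)
      Xj <- cbind(1, G[, j], Xf[, -1, drop = FALSE])
      V <- tryCatch(solve(crossprod(Xj, Xj * W)), error = function(e) NULL)
      if (is.null(V) || any(diag(V) <= 0)) {
        note[j] <- "non_converged"
        next
      }
      beta[j] <- fit$coefficients[2]
      se[j] <- sqrt(V[2, 2])
    }
  }
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(
    id = genotypes$variants$id, chrom = genotypes$variants$chrom,
    pos = genotypes$variants$pos,
    effect_allele = genotypes$variants$coded_allele,
    other_allele = genotypes$variants$other_allele,
    beta = beta, se = se, p = p, z = z, n = n, note = note,
    stringsAsFactors = FALSE
  )
  attr(out, "n_flagged") <- sum(note != "")
  out
}

AMBIGUOUS_PAIRS <- c("A/T", "T/A", "C/G", "G/C")

#' Harmonize summary statistics to a reference allele orientation
#'
#' Aligns a target summary-statistics table to the effect-allele orientation
#' of a reference (another summary-statistics table or a genotype matrix).
#' Variants are matched by id, falling back to chromosome + position for
#' unmatched ids. Where the target's effect allele equals the reference's
#' other allele (and vice versa) the effect is negated and the alleles
#' swapped. Strand-ambiguous palindromic variants (A/T, C/G) are removed
#' outright, as are variants absent from the reference or with irreconcilable
#' allele pairs. Counts of every action are attached as the
#' `harmonization_log` attribute.
#'
#' @param target Summary-statistics data.frame to align.
#' @param reference Summary-statistics data.frame or `genotype_matrix`.
#' @return The harmonized subset of `target`, in its original row order.
#' @export
harmonize <- function(target, reference) {
  ref <- if (inherits(reference, "genotype_matrix")) {
    data.frame(id = reference$variants$id, chrom = reference$variants$chrom,
               pos = reference$variants$pos,
               effect_allele = reference$variants$coded_allele,
               other_allele = reference$variants$other_allele,
               stringsAsFactors = FALSE)
  } else {
    reference[, c("id", "chrom", "pos", "effect_allele", "other_allele")]
  }
  pair <- paste(target$effect_allele, target$other_allele, sep = "/")
  ambiguous <- pair %in% AMBIGUOUS_PAIRS

  idx <- match(target$id, ref$id)
  no_id <- is.na(idx)
  if (any(no_id)) {
    key_t <- paste(target$chrom[no_id], target$pos[no_id])
    idx[no_id] <- match(key_t, paste(ref$chrom, ref$pos))
  }
  unmatched <- is.na(idx)

  ta1 <- target$effect_allele; ta2 <- target$other_allele
  ra1 <- ref$effect_allele[idx]; ra2 <- ref$other_allele[idx]
  aligned <- !unmatched & ta1 == ra1 & ta2 == ra2
  swapped <- !unmatched & ta1 == ra2 & ta2 == ra1
  mismatched <- !unmatched & !aligned & !swapped

  keep <- (aligned | swapped) & !ambiguous
  out <- target[keep, , drop = FALSE]
  flip <- swapped[keep]
  if (any(flip)) {
    out$beta[flip] <- -out$beta[flip]
    if ("z" %in% names(out)) out$z[flip] <- -out$z[flip]
    a1 <- out$effect_allele[flip]
    out$effect_allele[flip] <- out$other_allele[flip]
    out$other_allele[flip] <- a1
  }
  rownames(out) <- NULL
  attr(out, "harmonization_log") <- c(
    n_input = nrow(target), n_aligned = sum(aligned & !ambiguous),
    n_flipped = sum(swapped & !ambiguous), n_ambiguous_removed = sum(ambiguous),
    n_unmatched_removed = sum(unmatched & !ambiguous),
    n_mismatched_removed = sum(mismatched & !ambiguous),
    n_output = nrow(out)
  )
  out
}
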