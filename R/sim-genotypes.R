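#' Simulate an LD-blocked diploid genotype matrix
#'
#' Genotypes follow a threshold-Gaussian haplotype model. For each variant a
#' population allele frequency is drawn uniformly from `maf_range`. Within an
#' LD block of `ld_block_size` consecutive variants, per-haplotype latent
#' Gaussian variables share pairwise correlation `within_block_corr`
#' (equicorrelation via a common block factor); a haplotype carries the coded
#' allele when its latent variable exceeds the `1 - f` normal quantile.
#' Dosages are the sum of two independent haplotypes, so each variant is in
#' Hardy-Weinberg equilibrium marginally while dosage correlation within a
#' block is tunable. Blocks are mutually independent and never span
#' chromosome boundaries; when the variant count is not a multiple of the
#' block size the final block is simply shorter.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `genotype_matrix`: a list with
#'   * `dosages` — integer matrix (individuals x variants) with entries 0/1/2,
#'   * `variants` — data.frame with `id`, `chrom`, `pos`, `coded_allele`,
#'     `other_allele`, `block`, `freq` (the generating frequency),
#'   * `individuals` — data.frame with `id` and `sex`.
#' @examples
#' g <- simulate_genotypes(sim_config(n_individuals = 100, n_variants = 50, seed = 1))
#' dim(g$dosages)
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_individuals
  m <- config$n_variants
  layout <- genome_layout(config)

  # block ids: consecutive runs within each chromosome
  block <- integer(m)
  nxt <- 1L
  i <- 1L
  for (c in seq_len(config$n_chromosomes)) {
    mc <- layout$vars_per_chrom[c]
    if (mc == 0L) next
    b <- rep(seq_len(ceiling(mc / config$ld_block_size)),
             each = config$ld_block_size)[seq_len(mc)]
    block[i:(i + mc - 1L)] <- b + nxt - 1L
    nxt <- nxt + max(b)
    i <- i + mc
  }
  n_blocks <- max(block)

  f <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  thr <- stats::qnorm(1 - f)
  rho <- config$within_block_corr
  dos <- sample_block_dosages(n, block - 1L, thr, rho)

  bases <- c("A", "C", "G", "T")
  coded <- sample(bases, m, replace = TRUE)
  other <- vapply(coded, function(b) sample(setdiff(bases, b), 1L), character(1))

  ids <- sprintf("snp_%05d", seq_len(m))
  iids <- sprintf("ind_%05d", seq_len(n))
  sex <- ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "male", "female")
  dimnames(dos) <- list(iids, ids)

  out <- list(
    dosages = dos,
    variants = data.frame(
      id = ids, chrom = layout$variant_chrom, pos = layout$variant_pos,
      coded_allele = unname(coded), other_allele = unname(other),
      block = block, freq = f, stringsAsFactors = FALSE
    ),
    individuals = data.frame(id = iids, sex = sex, stringsAsFactors = FALSE)
  )
  class(out) <- "genotype_matrix"
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d variants on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$variants$chrom))))
  cat(sprintf("  %d male / %d female; dosage mean %.3f\n",
              sum(x$individuals$sex == "male", na.rm = TRUE),
              sum(x$individuals$sex == "female", na.rm = TRUE),
              mean(x$dosages)))
  invisible(x)
}

validate_genotype_matrix <- function(g) {
  if (!inherits(g, "genotype_matrix")) stopf("expected a 'genotype_matrix' object")
  if (ncol(g$dosages) != nrow(g$variants)) stopf("dosage/variant dimension mismatch")
  if (nrow(g$dosages) != nrow(g$individuals)) stopf("dosage/individual dimension mismatch")
  invisible(g)
}
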