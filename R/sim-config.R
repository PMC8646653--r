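#' Simulation configuration for a synthetic GWAS cohort
#'
#' Bundles every parameter of the synthetic-cohort generator: genotype
#' geometry (LD blocks, allele frequencies, chromosomes), gene annotation
#' tiling, gene-set libraries, the liability model for the ordinal balding
#' pattern, the logistic model for COVID-19 hospitalization, and the optional
#' shared genetic component confined to one planted pathway.
#'
#' The defaults describe a desk-scale cohort emulating the structure of the
#' study population: roughly equal sexes, assessment ages 50-70 with the
#' hospitalization/test event 2-13 years later (event ages spanning 52-83),
#' a four-level balding pattern with marginal frequencies 31/23/27/19%, and
#' an overall hospitalization rate near 9%.
#'
#' @param n_individuals Number of individuals.
#' @param n_variants Number of biallelic variants.
#' @param n_chromosomes Number of chromosomes the variants are spread over.
#' @param ld_block_size Variants per LD block (last block may be shorter).
#' @param within_block_corr Latent pairwise correlation within an LD block,
#'   in `[0, 1)`.
#' @param maf_range Length-2 vector; per-variant allele frequencies are drawn
#'   uniformly from this interval, which must lie in `(0, 0.5]`.
#' @param n_genes Number of genes tiled across the chromosomes.
#' @param gene_length_bp Gene length in base pairs.
#' @param intergenic_gap_bp Gap between consecutive genes in base pairs.
#' @param n_pathways_per_library Pathways per gene-set library (three
#'   libraries are generated).
#' @param genes_per_pathway Genes sampled into each pathway.
#' @param planted_pathway_id Name of the pathway carrying the shared genetic
#'   component, or `NULL` for no planted pathway. When set, a pathway with
#'   this name is placed in the first library.
#' @param aga_h2 Heritability of the balding-pattern liability, in `[0, 1)`.
#' @param aga_n_causal Number of genome-wide causal variants for the balding
#'   liability (planted-pathway variants are added to this set when a pathway
#'   is planted).
#' @param aga_age_slope Liability increase per year of age at assessment
#'   (pattern-scale units per year).
#' @param pattern_freqs Target marginal frequencies of patterns 1-4; must sum
#'   to 1. Thresholds on the liability are derived from these.
#' @param covid_age_log_or Log-odds of hospitalization per year of age at
#'   event.
#' @param covid_base_rate Marginal hospitalization probability the logistic
#'   intercept is tuned to.
#' @param shared_effect_size Log-odds of hospitalization per standard
#'   deviation of the planted-pathway genetic score (zero outside planted
#'   genes).
#' @param age_range Length-2 vector of assessment ages (years), sampled
#'   uniformly.
#' @param event_age_offset Length-2 vector; the event age is the assessment
#'   age plus a uniform draw from this interval.
#' @param mapping_window_bp Strict distance cut-off for SNP-to-gene positional
#'   mapping (default 10 kb, exclusive).
#' @param seed Integer seed; together with the other fields it fully
#'   determines all generator output.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_individuals = 500, n_variants = 200, seed = 7)
#' cfg$maf_range
#' @export
sim_config <- function(n_individuals = 6000,
                       n_variants = 2000,
                       n_chromosomes = 4,
                       ld_block_size = 10,
                       within_block_corr = 0.8,
                       maf_range = c(0.05, 0.5),
                       n_genes = 500,
                       gene_length_bp = 10000,
                       intergenic_gap_bp = 30000,
                       n_pathways_per_library = 50,
                       genes_per_pathway = 20,
                       planted_pathway_id = NULL,
                       aga_h2 = 0.6,
                       aga_n_causal = 120,
                       aga_age_slope = 0.03,
                       pattern_freqs = c(0.31, 0.23, 0.27, 0.19),
                       covid_age_log_or = 0.1,
                       covid_base_rate = 0.09,
                       shared_effect_size = 0,
                       age_range = c(50, 70),
                       event_age_offset = c(2, 13),
                       mapping_window_bp = 10000,
                       seed = 1L) {
  cfg <- list(
    n_individuals = n_individuals, n_variants = n_variants,
    n_chromosomes = n_chromosomes, ld_block_size = ld_block_size,
    within_block_corr = within_block_corr, maf_range = maf_range,
    n_genes = n_genes, gene_length_bp = gene_length_bp,
    intergenic_gap_bp = intergenic_gap_bp,
    n_pathways_per_library = n_pathways_per_library,
    genes_per_pathway = genes_per_pathway,
    planted_pathway_id = planted_pathway_id,
    aga_h2 = aga_h2, aga_n_causal = aga_n_causal,
    aga_age_slope = aga_age_slope, pattern_freqs = pattern_freqs,
    covid_age_log_or = covid_age_log_or, covid_base_rate = covid_base_rate,
    shared_effect_size = shared_effect_size, age_range = age_range,
    event_age_offset = event_age_offset,
    mapping_window_bp = mapping_window_bp, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  for (f in c("n_individuals", "n_variants", "n_chromosomes", "ld_block_size",
              "n_genes", "gene_length_bp", "n_pathways_per_library",
              "genes_per_pathway")) {
    if (!is_count(cfg[[f]])) stopf("invalid config: '%s' must be a positive integer", f)
  }
  if (!is.numeric(cfg$intergenic_gap_bp) || cfg$intergenic_gap_bp < 0) {
    stopf("invalid config: 'intergenic_gap_bp' must be non-negative")
  }
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2]) {
    stopf("invalid config: 'maf_range' must lie within (0, 0.5]")
  }
  if (cfg$within_block_corr < 0 || cfg$within_block_corr >= 1) {
    stopf("invalid config: 'within_block_corr' must be in [0, 1)")
  }
  if (cfg$aga_h2 < 0 || cfg$aga_h2 >= 1) {
    stopf("invalid config: 'aga_h2' must be in [0, 1)")
  }
  if (length(cfg$pattern_freqs) != 4L || any(cfg$pattern_freqs <= 0) ||
      abs(sum(cfg$pattern_freqs) - 1) > 1e-8) {
    stopf("invalid config: 'pattern_freqs' must be 4 positive values summing to 1")
  }
  if (cfg$covid_base_rate <= 0 || cfg$covid_base_rate >= 1) {
    stopf("invalid config: 'covid_base_rate' must be in (0, 1)")
  }
  if (cfg$genes_per_pathway > cfg$n_genes) {
    stopf("invalid config: 'genes_per_pathway' (%d) exceeds 'n_genes' (%d)",
          cfg$genes_per_pathway, cfg$n_genes)
  }
  if (length(cfg$age_range) != 2L || cfg$age_range[1] > cfg$age_range[2]) {
    stopf("invalid config: 'age_range' must be an increasing pair of ages")
  }
  if (length(cfg$event_age_offset) != 2L || cfg$event_age_offset[1] < 0 ||
      cfg$event_age_offset[1] > cfg$event_age_offset[2]) {
    stopf("invalid config: 'event_age_offset' must be a non-negative increasing pair")
  }
  if (cfg$shared_effect_size != 0 && is.null(cfg$planted_pathway_id)) {
    stopf("invalid config: nonzero 'shared_effect_size' requires 'planted_pathway_id'")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d individuals, %d variants on %d chromosome(s)\n",
              x$n_individuals, x$n_variants, x$n_chromosomes))
  cat(sprintf("  LD blocks of %d variants, latent correlation %.2f, MAF in [%.3f, %.3f]\n",
              x$ld_block_size, x$within_block_corr, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  %d genes (%d bp + %d bp gap), 3 libraries x %d pathways x %d genes\n",
              x$n_genes, x$gene_length_bp, x$intergenic_gap_bp,
              x$n_pathways_per_library, x$genes_per_pathway))
  cat(sprintf("  AGA: h2 = %.2f (%d causal), age slope %.3f/yr; COVID: base rate %.2f, age log-OR %.2f\n",
              x$aga_h2, x$aga_n_causal, x$aga_age_slope, x$covid_base_rate,
              x$covid_age_log_or))
  if (!is.null(x$planted_pathway_id)) {
    cat(sprintf("  planted pathway '%s', shared effect %.2f per SD\n",
                x$planted_pathway_id, x$shared_effect_size))
  }
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# Shared genome geometry: chromosome assignment and base-pair positions for
# variants and genes, derived purely from the config so that genotype and
# annotation generation agree.
genome_layout <- function(cfg) {
  split_even <- function(total, k) {
    base <- rep(total %/% k, k)
    extra <- total %% k
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    base
  }
  genes_per_chrom <- split_even(cfg$n_genes, cfg$n_chromosomes)
  vars_per_chrom <- split_even(cfg$n_variants, cfg$n_chromosomes)
  period <- cfg$gene_length_bp + cfg$intergenic_gap_bp
  chrom_len <- pmax(genes_per_chrom, 1L) * period
  chrom <- integer(0); pos <- integer(0)
  for (c in seq_len(cfg$n_chromosomes)) {
    m <- vars_per_chrom[c]
    if (m == 0L) next
    p <- floor((seq_len(m) - 0.5) / m * chrom_len[c]) + 1L
    # enforce strictly increasing positions even for very dense layouts
    p <- p + cumsum(c(0L, as.integer(diff(p) <= 0)))
    chrom <- c(chrom, rep.int(c, m))
    pos <- c(pos, as.integer(p))
  }
  list(genes_per_chrom = genes_per_chrom, vars_per_chrom = vars_per_chrom,
       chrom_len = chrom_len, variant_chrom = chrom, variant_pos = pos,
       period = period)
}
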