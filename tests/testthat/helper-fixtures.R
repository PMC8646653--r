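# Small configurations and hand-built objects shared across test files.

tiny_config <- function(...) {
  sim_config(n_individuals = 400, n_variants = 100, n_chromosomes = 2,
             ld_block_size = 5, n_genes = 40, n_pathways_per_library = 8,
             genes_per_pathway = 6, aga_n_causal = 30, seed = 42, ...)
}

# A genotype_matrix built directly from a dosage matrix (bypassing the
# simulator) for oracle tests with controlled LD.
manual_genotypes <- function(dosages, chrom = NULL, pos = NULL,
                             sex = NULL, coded = "A", other = "G") {
  m <- ncol(dosages)
  n <- nrow(dosages)
  ids <- sprintf("v%03d", seq_len(m))
  dimnames(dosages) <- list(sprintf("i%03d", seq_len(n)), ids)
  storage.mode(dosages) <- "integer"
  g <- list(
    dosages = dosages,
    variants = data.frame(id = ids,
                          chrom = chrom %||% rep(1L, m),
                          pos = pos %||% (seq_len(m) * 1000L),
                          coded_allele = rep_len(coded, m),
                          other_allele = rep_len(other, m),
                          stringsAsFactors = FALSE),
    individuals = data.frame(id = sprintf("i%03d", seq_len(n)),
                             sex = sex %||% rep("male", n),
                             stringsAsFactors = FALSE)
  )
  class(g) <- "genotype_matrix"
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Phenotype table with explicit fields, used by the epi-module tests.
manual_phenotypes <- function(sex, age_a, age_e = age_a, pattern = NA,
                              hosp = FALSE) {
  n <- length(sex)
  data.frame(individual_id = sprintf("i%03d", seq_len(n)), sex = sex,
             age_at_assessment = age_a, age_at_event = age_e,
             aga_pattern = as.integer(rep_len(pattern, n)),
             sars_cov2_positive = TRUE,
             hospitalized = rep_len(hosp, n), stringsAsFactors = FALSE)
}
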