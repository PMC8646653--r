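#' Simulate cohort phenotypes with known genetic ground truth
#'
#' Generates ages, a four-level ordinal balding pattern for males, and a
#' binary COVID-19 hospitalization outcome, on top of a simulated genotype
#' matrix.
#'
#' The male balding pattern follows a liability-threshold model: liability =
#' standardized genome-wide genetic score (scaled to variance `aga_h2`) +
#' `aga_age_slope` x centered age at assessment + Gaussian noise of variance
#' `1 - aga_h2`. Three fixed thresholds, placed at the normal quantiles of
#' the cumulative `pattern_freqs` on the theoretical liability scale, cut the
#' liability into patterns 1-4 so the marginal pattern distribution
#' approximates the configured target (default 31/23/27/19%). Females carry
#' no pattern (missing), mirroring cohorts where balding is only
#' self-reported by men.
#'
#' Hospitalization is Bernoulli with logit = intercept +
#' `covid_age_log_or` x centered age at event + `shared_effect_size` x
#' standardized planted-pathway genetic score. The intercept is tuned
#' numerically so the marginal hospitalization rate matches
#' `covid_base_rate`. The planted-pathway score uses the balding effect sizes
#' at exactly those variants positionally mapped (strictly closer than
#' `mapping_window_bp`) to planted-pathway genes, and is zero elsewhere —
#' the shared genetic component is confined to one pathway by construction.
#' All individuals are flagged SARS-CoV-2 positive: the simulated cohort
#' represents test-positive individuals, among whom hospitalized ones are
#' cases.
#'
#' @param genotypes A `genotype_matrix` from [simulate_genotypes()].
#' @param annotation Gene annotation data.frame from [simulate_annotation()].
#' @param libraries List of `gene_set_library` objects.
#' @param config The same [sim_config()] used for the genotypes.
#' @return A list with
#'   * `phenotypes` — data.frame with `individual_id`, `sex`,
#'     `age_at_assessment`, `age_at_event`, `aga_pattern` (integer 1-4, `NA`
#'     for females), `sars_cov2_positive`, `hospitalized`;
#'   * `true_effects` — list with per-variant `aga_effects` (liability scale,
#'     per standardized dosage), `shared_effects` (nonzero only at
#'     planted-pathway-mapped variants), `planted_pathway_id`,
#'     `planted_variant_ids`, and realized variance components.
#' @export
simulate_phenotypes <- function(genotypes, annotation, libraries, config) {
  validate_sim_config(config)
  validate_genotype_matrix(genotypes)
  set.seed(derive_seed(config$seed, 3L))
  n <- nrow(genotypes$dosages)
  m <- ncol(genotypes$dosages)

  age_a <- stats::runif(n, config$age_range[1], config$age_range[2])
  age_e <- age_a + stats::runif(n, config$event_age_offset[1],
                                config$event_age_offset[2])

  # planted-pathway variants (strict < mapping_window_bp positional rule)
  planted_idx <- integer(0)
  planted_genes <- NULL
  if (!is.null(config$planted_pathway_id)) {
    planted_genes <- find_pathway(libraries, config$planted_pathway_id)
    if (is.null(planted_genes)) {
      stopf("planted pathway '%s' not found in any library", config$planted_pathway_id)
    }
    sgmap <- map_snps_to_genes(genotypes$variants,
                               annotation[annotation$gene_id %in% planted_genes, ,
                                          drop = FALSE],
                               window_bp = config$mapping_window_bp)
    planted_ids <- unique(sgmap$map$variant_id)
    if (length(planted_ids) == 0L) {
      stopf("degenerate simulation: no variant maps to the planted pathway '%s'",
            config$planted_pathway_id)
    }
    planted_idx <- match(planted_ids, genotypes$variants$id)
  }

  # causal architecture: random genome-wide set, plus all planted variants
  n_causal <- min(config$aga_n_causal, m)
  causal_idx <- sort(union(sample.int(m, n_causal), planted_idx))
  aga_effects <- numeric(m)
  aga_effects[causal_idx] <- stats::rnorm(length(causal_idx))

  S <- standardize_dosages(genotypes$dosages[, causal_idx, drop = FALSE])
  raw_g <- as.vector(S %*% aga_effects[causal_idx])
  sd_g <- stats::sd(raw_g)
  if (sd_g == 0) sd_g <- 1
  g <- raw_g / sd_g * sqrt(config$aga_h2)
  # rescale stored effects so that sum_j beta_j * std_dosage_ij equals g
  aga_effects <- aga_effects / sd_g * sqrt(config$aga_h2)

  liability <- g + config$aga_age_slope * (age_a - mean(age_a)) +
    stats::rnorm(n, 0, sqrt(1 - config$aga_h2))
  var_age <- diff(config$age_range)^2 / 12
  sd_liab <- sqrt(1 + config$aga_age_slope^2 * var_age)
  thresholds <- stats::qnorm(cumsum(config$pattern_freqs[1:3])) * sd_liab
  pattern <- findInterval(liability, thresholds) + 1L
  sex <- genotypes$individuals$sex
  pattern[sex != "male"] <- NA_integer_

  # shared (pathway-confined) genetic component of hospitalization risk
  shared_effects <- numeric(m)
  shared_score <- numeric(n)
  if (length(planted_idx) > 0L && config$shared_effect_size != 0) {
    Sp <- standardize_dosages(genotypes$dosages[, planted_idx, drop = FALSE])
    w <- aga_effects[planted_idx]
    raw_s <- as.vector(Sp %*% w)
    sd_s <- stats::sd(raw_s)
    if (sd_s == 0) {
      stopf("degenerate simulation: planted-pathway score has zero variance")
    }
    shared_score <- raw_s / sd_s
    shared_effects[planted_idx] <- config$shared_effect_size * w / sd_s
  }

  eta <- config$covid_age_log_or * (age_e - mean(age_e)) +
    config$shared_effect_size * shared_score
  intercept <- stats::uniroot(
    function(c0) mean(stats::plogis(c0 + eta)) - config$covid_base_rate,
    interval = c(-30, 30), tol = 1e-10
  )$root
  hospitalized <- stats::rbinom(n, 1L, stats::plogis(intercept + eta)) == 1L

  phen <- data.frame(
    individual_id = genotypes$individuals$id,
    sex = sex,
    age_at_assessment = age_a,
    age_at_event = age_e,
    aga_pattern = pattern,
    sars_cov2_positive = TRUE,
    hospitalized = hospitalized,
    stringsAsFactors = FALSE
  )
  true_effects <- list(
    aga_effects = stats::setNames(aga_effects, genotypes$variants$id),
    shared_effects = stats::setNames(shared_effects, genotypes$variants$id),
    planted_pathway_id = config$planted_pathway_id,
    planted_genes = planted_genes,
    planted_variant_ids = genotypes$variants$id[planted_idx],
    causal_variant_ids = genotypes$variants$id[causal_idx],
    realized_h2 = stats::var(g) / sd_liab^2,
    logistic_intercept = intercept
  )
  list(phenotypes = phen, true_effects = true_effects)
}
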