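test_that("genotype generator is deterministic and respects dosage invariants", {
  cfg <- tiny_config()
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  expect_true(all(g1$dosages %in% 0:2))
  expect_identical(sort(unique(g1$variants$chrom)), 1:2)
  for (c in unique(g1$variants$chrom)) {
    expect_true(all(diff(g1$variants$pos[g1$variants$chrom == c]) > 0))
  }
  expect_true(all(g1$variants$coded_allele != g1$variants$other_allele))
  # invalid configs rejected
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(within_block_corr = 1), "within_block_corr")
})

test_that("dosages satisfy Hardy-Weinberg moments at large n", {
  cfg <- sim_config(n_individuals = 6000, n_variants = 60, ld_block_size = 5,
                    within_block_corr = 0.5, maf_range = c(0.5, 0.5), seed = 9)
  g <- simulate_genotypes(cfg)
  mu <- colMeans(g$dosages)
  v <- apply(g$dosages, 2, var)
  expect_true(all(abs(mu - 1.0) < 0.06))
  expect_true(all(abs(v - 0.5) < 0.06))
  # general frequencies: mean ~ 2f, var ~ 2f(1-f)
  cfg2 <- sim_config(n_individuals = 6000, n_variants = 80, seed = 10)
  g2 <- simulate_genotypes(cfg2)
  f <- g2$variants$freq
  expect_lt(max(abs(colMeans(g2$dosages) - 2 * f)), 0.06)
  expect_lt(max(abs(apply(g2$dosages, 2, var) - 2 * f * (1 - f))), 0.08)
})

test_that("within-block correlation is tunable and zero when configured off", {
  cfg0 <- sim_config(n_individuals = 5000, n_variants = 40, ld_block_size = 10,
                     within_block_corr = 0, seed = 3)
  g0 <- simulate_genotypes(cfg0)
  C0 <- cor(g0$dosages)
  off <- abs(C0[upper.tri(C0)])
  expect_lt(max(off), 0.05)

  cfg9 <- sim_config(n_individuals = 5000, n_variants = 40, n_chromosomes = 1,
                     ld_block_size = 10, within_block_corr = 0.9, seed = 3)
  g9 <- simulate_genotypes(cfg9)
  C9 <- cor(g9$dosages)^2
  same_block <- outer(g9$variants$block, g9$variants$block, "==")
  diag(same_block) <- FALSE
  within <- mean(C9[same_block])
  between <- mean(C9[!same_block & upper.tri(C9)])
  expect_gt(within / between, 10)
})

test_that("last LD block is truncated when block size does not divide m", {
  cfg <- sim_config(n_individuals = 50, n_variants = 23, n_chromosomes = 1,
                    ld_block_size = 10, seed = 1)
  g <- simulate_genotypes(cfg)
  expect_identical(as.vector(table(g$variants$block)), c(10L, 10L, 3L))
})

test_that("gene annotation tiles genes with the configured length and gap", {
  cfg <- sim_config(n_genes = 10, n_chromosomes = 1, gene_length_bp = 1000,
                    intergenic_gap_bp = 20000, n_pathways_per_library = 5,
                    genes_per_pathway = 3, seed = 2)
  ann <- simulate_annotation(cfg)$annotation
  expect_equal(ann$start[1], 1)
  expect_equal(ann$end[1], 1000)
  # [1,1000] gene + 20000 bp gap occupying [1001,21000] puts the next start
  # at 21001
  expect_equal(ann$start[2], 21001)
  expect_true(all(ann$end - ann$start + 1L == 1000))
  # non-overlap within chromosome
  expect_true(all(ann$start[-1] > ann$end[-nrow(ann)]))
})

test_that("three libraries with the configured pathway counts are generated", {
  cfg <- tiny_config()
  libs <- simulate_annotation(cfg)$libraries
  expect_length(libs, 3)
  for (lib in libs) {
    expect_length(lib$pathways, cfg$n_pathways_per_library)
    expect_true(all(lengths(lib$pathways) == cfg$genes_per_pathway))
  }
  expect_error(sim_config(n_genes = 5, genes_per_pathway = 10), "genes_per_pathway")
})

test_that("wide intergenic gaps make the 10 kb mapping unambiguous", {
  cfg <- sim_config(n_individuals = 50, n_variants = 200, n_chromosomes = 1,
                    n_genes = 40, gene_length_bp = 1000,
                    intergenic_gap_bp = 25000, genes_per_pathway = 5,
                    n_pathways_per_library = 5, seed = 6)
  g <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg)$annotation
  sgmap <- map_snps_to_genes(g$variants, ann, window_bp = 10000)
  hits_per_variant <- table(sgmap$map$variant_id)
  expect_true(all(hits_per_variant <= 1))
})

test_that("balding pattern rises with age and matches target marginals", {
  cfg <- sim_config(n_individuals = 8000, n_variants = 100, aga_n_causal = 40,
                    aga_age_slope = 0.05, seed = 21)
  g <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg)
  ph <- simulate_phenotypes(g, ann$annotation, ann$libraries, cfg)$phenotypes
  males <- ph[ph$sex == "male", ]
  expect_true(all(is.na(ph$aga_pattern[ph$sex == "female"])))
  expect_true(all(ph$age_at_event >= ph$age_at_assessment))
  q <- cut(males$age_at_assessment,
           quantile(males$age_at_assessment, 0:4 / 4), include.lowest = TRUE)
  mean_pat <- tapply(males$aga_pattern, q, mean)
  expect_true(all(diff(mean_pat) >= 0))
  freq <- table(factor(males$aga_pattern, 1:4)) / nrow(males)
  expect_lt(max(abs(as.vector(freq) - cfg$pattern_freqs)), 0.04)
  expect_true(all(ph$sars_cov2_positive[ph$hospitalized]))
})

test_that("hospitalization model recovers the generating age effect", {
  cfg <- sim_config(n_individuals = 20000, n_variants = 50, aga_n_causal = 20,
                    covid_age_log_or = 0.1, covid_base_rate = 0.1, seed = 31)
  g <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg)
  ph <- simulate_phenotypes(g, ann$annotation, ann$libraries, cfg)$phenotypes
  expect_lt(abs(mean(ph$hospitalized) - 0.1), 0.02)
  fit <- glm(hospitalized ~ age_at_event, data = ph, family = binomial())
  est <- summary(fit)$coefficients["age_at_event", ]
  expect_lt(abs(est["Estimate"] - 0.1), 2 * est["Std. Error"])
})

test_that("shared effects are confined to variants near planted-pathway genes", {
  cfg <- sim_config(n_individuals = 500, n_variants = 400, n_genes = 100,
                    n_pathways_per_library = 10, genes_per_pathway = 8,
                    planted_pathway_id = "planted", shared_effect_size = 0.4,
                    aga_n_causal = 50, seed = 12)
  g <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg)
  expect_true("planted" %in% names(ann$libraries[[1]]$pathways))
  sim <- simulate_phenotypes(g, ann$annotation, ann$libraries, cfg)
  te <- sim$true_effects
  planted_genes <- ann$annotation[ann$annotation$gene_id %in% te$planted_genes, ]
  # brute-force distance of every variant to every planted gene
  for (j in seq_len(nrow(g$variants))) {
    v <- g$variants[j, ]
    dmin <- Inf
    for (k in seq_len(nrow(planted_genes))) {
      if (planted_genes$chrom[k] != v$chrom) next
      dmin <- min(dmin, max(0, planted_genes$start[k] - v$pos,
                            v$pos - planted_genes$end[k]))
    }
    if (dmin >= 10000) expect_identical(unname(te$shared_effects[j]), 0)
  }
  expect_gt(sum(te$shared_effects != 0), 0)
})

test_that("planted pathway without mappable variants raises a degenerate-simulation error", {
  cfg <- sim_config(n_individuals = 50, n_variants = 10, n_chromosomes = 1,
                    n_genes = 50, genes_per_pathway = 2,
                    n_pathways_per_library = 3,
                    planted_pathway_id = "nope", shared_effect_size = 0.3,
                    seed = 5)
  g <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg)
  # move all variants far beyond any gene
  g$variants$pos <- g$variants$pos + 10000000L
  expect_error(simulate_phenotypes(g, ann$annotation, ann$libraries, cfg),
               "degenerate")
})

test_that("model-consistent z-scores have the prescribed first two moments", {
  # null model: standard normal z, mean chi-square near 1
  ss0 <- simulate_model_sumstats(5000, ld_scores = 5, n1 = 2e4, n2 = 2e4,
                                 h2_1 = 0, h2_2 = 0, rg = 0, seed = 1)
  expect_lt(abs(mean(ss0$trait1$z^2) - 1), 0.05)
  expect_lt(abs(mean(ss0$trait2$z^2) - 1), 0.05)

  # chi-square expectation 1 + n h2 l / M under constant LD score
  ms <- replicate(20, {
    s <- simulate_model_sumstats(2000, ld_scores = 5, n1 = 2e4, n2 = 2e4,
                                 h2_1 = 0.3, h2_2 = 0.3, rg = 0,
                                 seed = sample.int(1e6, 1))
    mean(s$trait1$z^2)
  })
  expected <- 1 + 2e4 * 0.3 * 5 / 2000
  expect_lt(abs(mean(ms) - expected) / expected, 0.05)

  # rg = 1 with equal h2 and n: z pairs approach perfect correlation as l grows
  s1 <- simulate_model_sumstats(4000, ld_scores = 50, n1 = 2e4, n2 = 2e4,
                                h2_1 = 0.3, h2_2 = 0.3, rg = 1, seed = 3)
  expect_gt(cor(s1$trait1$z, s1$trait2$z), 0.95)
  # sumstats invariants
  expect_true(all(s1$trait1$se > 0))
  expect_lt(max(abs(s1$trait1$z - s1$trait1$beta / s1$trait1$se)), 1e-6)
})
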