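test_that("positional mapping honors containment and the strict boundary", {
  ann <- data.frame(gene_id = "G1", chrom = 1L, start = 1000L, end = 2000L)
  v_inside <- data.frame(id = "a", chrom = 1L, pos = 1500L)
  m1 <- map_snps_to_genes(v_inside, ann)
  expect_identical(m1$map$gene_id, "G1")
  expect_equal(m1$map$distance, 0)
  # distance exactly 10 kb is NOT mapped (strict <)
  v_edge <- data.frame(id = c("b", "c"), chrom = 1L, pos = c(12000L, 11999L))
  m2 <- map_snps_to_genes(v_edge, ann)
  expect_identical(m2$map$variant_id, "c")
  expect_identical(m2$unmapped_ids, "b")
  # wrong chromosome stays unmapped and counted
  v_off <- data.frame(id = "d", chrom = 2L, pos = 1500L)
  expect_equal(map_snps_to_genes(v_off, ann)$n_unmapped, 1)
})

test_that("mapping equals a brute-force double loop on a 30-variant/5-gene toy", {
  set.seed(10)
  ann <- data.frame(gene_id = paste0("G", 1:5),
                    chrom = c(1L, 1L, 1L, 2L, 2L),
                    start = c(5000L, 40000L, 41000L, 10000L, 60000L),
                    end = c(9000L, 45000L, 52000L, 15000L, 61000L))
  variants <- data.frame(id = sprintf("v%02d", 1:30),
                         chrom = sample(1:2, 30, TRUE),
                         pos = sample.int(70000L, 30))
  got <- map_snps_to_genes(variants, ann, window_bp = 10000)
  oracle <- list()
  for (i in 1:30) {
    for (g in 1:5) {
      if (variants$chrom[i] != ann$chrom[g]) next
      d <- max(0, ann$start[g] - variants$pos[i], variants$pos[i] - ann$end[g])
      if (d < 10000) {
        oracle[[length(oracle) + 1]] <- data.frame(
          variant_id = variants$id[i], gene_id = ann$gene_id[g], distance = d)
      }
    }
  }
  oracle <- do.call(rbind, oracle)
  key <- function(d) sort(paste(d$variant_id, d$gene_id, d$distance))
  expect_identical(key(got$map), key(oracle))
})

test_that("pathway variant sets are unions over member genes, built once per variant", {
  ann <- data.frame(gene_id = c("G1", "G2", "G3"), chrom = 1L,
                    start = c(1000L, 50000L, 100000L),
                    end = c(2000L, 51000L, 101000L))
  variants <- data.frame(id = c("a", "b", "c", "d"), chrom = 1L,
                         pos = c(1500L, 50500L, 100500L, 999999L))
  sgmap <- map_snps_to_genes(variants, ann)
  lib <- structure(list(library_name = "toy",
                        pathways = list(p1 = c("G1", "G2"), p2 = c("G2", "G3"),
                                        p3 = "G3", p_empty = "G1")),
                   class = "gene_set_library")
  sets <- build_pathway_variant_sets(sgmap, lib, c("b", "c", "d"))
  expect_identical(sort(sets$p1), "b")           # a not in candidate list
  expect_identical(sort(sets$p2), c("b", "c"))   # shared gene in both sets
  expect_identical(sets$p3, "c")
  expect_identical(attr(sets, "excluded"), "p_empty")
  # a pathway duplicated across genes counts each variant once
  lib2 <- structure(list(library_name = "toy2",
                         pathways = list(q = c("G2", "G2", "G3"))),
                    class = "gene_set_library")
  expect_identical(sort(build_pathway_variant_sets(sgmap, lib2,
                                                   c("b", "c"))$q),
                   c("b", "c"))
})

test_that("pathway sets match brute-force construction on a random toy layout", {
  cfg <- sim_config(n_individuals = 60, n_variants = 30, n_chromosomes = 1,
                    n_genes = 5, gene_length_bp = 8000,
                    intergenic_gap_bp = 12000, n_pathways_per_library = 3,
                    genes_per_pathway = 2, seed = 15)
  g <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg)
  sgmap <- map_snps_to_genes(g$variants, ann$annotation)
  lib <- ann$libraries[[1]]
  candidates <- g$variants$id[seq(1, 30, by = 2)]
  sets <- build_pathway_variant_sets(sgmap, lib, candidates)
  for (pw in names(sets)) {
    genes <- ann$annotation[ann$annotation$gene_id %in% lib$pathways[[pw]], ]
    oracle <- character(0)
    for (i in seq_len(nrow(g$variants))) {
      if (!(g$variants$id[i] %in% candidates)) next
      for (k in seq_len(nrow(genes))) {
        d <- max(0, genes$start[k] - g$variants$pos[i],
                 g$variants$pos[i] - genes$end[k])
        if (d < 10000) oracle <- c(oracle, g$variants$id[i])
      }
    }
    expect_identical(sort(sets[[pw]]), sort(unique(oracle)))
  }
})

test_that("BH adjustment matches the hand step-up computation and its properties", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # independent oracle: explicit step-up on a worked vector
  p <- c(0.005, 0.009, 0.02, 0.04, 0.9)
  m <- length(p)
  q_sorted <- rev(cummin(rev(sort(p) * m / seq_len(m))))
  oracle <- pmin(1, q_sorted)[rank(p)]
  expect_equal(bh_fdr(p), oracle)
  # properties on random vectors
  set.seed(11)
  for (i in 1:1000) {
    pv <- runif(sample(1:20, 1))
    q <- bh_fdr(pv)
    expect_true(all(q >= pv))
    expect_true(all(q <= 1))
    expect_identical(order(q[order(pv)]), seq_along(q))  # monotone in p order
  }
  expect_error(bh_fdr(c(0.5, 0)), "p-values")
  expect_error(bh_fdr(c(0.5, 1.2)), "p-values")
})

pprs_fixture <- function(seed = 16, planted = NULL, shared = 0, n = 1500) {
  cfg <- sim_config(n_individuals = n, n_variants = 300, n_chromosomes = 2,
                    n_genes = 60, n_pathways_per_library = 6,
                    genes_per_pathway = 10, aga_n_causal = 40,
                    planted_pathway_id = planted, shared_effect_size = shared,
                    seed = seed)
  g <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg)
  sim <- simulate_phenotypes(g, ann$annotation, ann$libraries, cfg)
  ss <- run_gwas(g, sim$phenotypes$aga_pattern,
                 covariates = sim$phenotypes$age_at_assessment,
                 model = "linear", subset = sim$phenotypes$sex == "male")
  list(cfg = cfg, g = g, ann = ann, phen = sim$phenotypes, ss = ss)
}

test_that("the scan emits complete iterations with within-iteration FDR", {
  fx <- pprs_fixture()
  tab <- run_pprs_scan(fx$g, fx$ss, fx$phen, fx$ann$annotation,
                       fx$ann$libraries, thresholds = c(5e-5, 1e-2))
  expect_s3_class(tab, "pathway_prs_table")
  ok <- tab[tab$status == "ok", ]
  expect_true(all(ok$p_fdr >= ok$p - 1e-12))
  # within every iteration, p_fdr is exactly BH of that iteration's p set
  key <- paste(ok$sex, ok$threshold, ok$library)
  for (k in unique(key)) {
    rows <- ok[key == k, ]
    expect_equal(rows$p_fdr, bh_fdr(rows$p))
  }
  # deterministic row-for-row
  tab2 <- run_pprs_scan(fx$g, fx$ss, fx$phen, fx$ann$annotation,
                        fx$ann$libraries, thresholds = c(5e-5, 1e-2))
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
  # pathway sets are subsets of the thresholded genome-wide set
  sel <- select_variants(fx$ss, 1e-2)
  expect_true(all(tab$n_variants <= nrow(sel)))
})

test_that("FDR families never borrow p-values from other iteration cells", {
  fx <- pprs_fixture(seed = 17)
  tab <- run_pprs_scan(fx$g, fx$ss, fx$phen, fx$ann$annotation,
                       fx$ann$libraries, thresholds = c(5e-5, 1e-2))
  male_cell <- tab[tab$sex == "male" & tab$threshold == 1e-2 &
                     tab$library == tab$library[1] & tab$status == "ok", ]
  # recompute the male cell's FDR in isolation: identical values
  expect_equal(male_cell$p_fdr, bh_fdr(male_cell$p))
  # library-pooled scope changes the family, hence (generically) the values
  tab_lib <- run_pprs_scan(fx$g, fx$ss, fx$phen, fx$ann$annotation,
                           fx$ann$libraries, thresholds = c(5e-5, 1e-2),
                           fdr_scope = "library")
  key <- paste(tab_lib$library)
  ok <- tab_lib[tab_lib$status == "ok", ]
  for (k in unique(ok$library)) {
    rows <- ok[ok$library == k, ]
    expect_equal(rows$p_fdr, bh_fdr(rows$p))
  }
})

test_that("a pathway covering every mapped variant reduces to the genome-wide PRS", {
  # geometry in which every variant lies within 10 kb of a gene
  cfg <- sim_config(n_individuals = 1200, n_variants = 200, n_chromosomes = 1,
                    n_genes = 50, gene_length_bp = 10000,
                    intergenic_gap_bp = 5000, n_pathways_per_library = 4,
                    genes_per_pathway = 5, aga_n_causal = 30, seed = 18)
  g <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg)
  sim <- simulate_phenotypes(g, ann$annotation, ann$libraries, cfg)
  ss <- run_gwas(g, sim$phenotypes$aga_pattern,
                 covariates = sim$phenotypes$age_at_assessment,
                 model = "linear", subset = sim$phenotypes$sex == "male")
  # add an all-genes pathway to the first library
  ann$libraries[[1]]$pathways$all_genes <- ann$annotation$gene_id
  thr <- 0.5
  tab <- run_pprs_scan(g, ss, sim$phenotypes, ann$annotation, ann$libraries,
                       thresholds = thr, clump = FALSE)
  sel <- select_variants(ss, thr)
  sgmap <- map_snps_to_genes(g$variants, ann$annotation)
  expect_identical(sgmap$n_unmapped, 0L)  # geometry guarantees full coverage
  gw <- associate_prs(compute_prs(g, sel[, c("id", "beta")]),
                      sim$phenotypes, "male")
  row <- tab[tab$pathway == "all_genes" & tab$sex == "male", ]
  expect_equal(row$beta, gw$beta, tolerance = 1e-8)
  expect_equal(row$p, gw$p, tolerance = 1e-8)
})

test_that("a planted pathway is recovered with the smallest adjusted p", {
  fx <- pprs_fixture(seed = 19, planted = "planted_pw", shared = 0.5, n = 4000)
  tab <- run_pprs_scan(fx$g, fx$ss, fx$phen, fx$ann$annotation,
                       fx$ann$libraries, thresholds = 5e-5)
  cell <- tab[tab$sex == "male" & tab$library == fx$ann$libraries[[1]]$library_name &
                tab$status == "ok", ]
  expect_identical(cell$pathway[which.min(cell$p_fdr)], "planted_pw")
})
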