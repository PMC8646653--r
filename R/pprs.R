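#' Positional SNP-to-gene mapping
#'
#' A variant maps to a gene when the distance between its position and the
#' gene interval `[start, end]` (1-based, inclusive) is strictly less than
#' `window_bp`; variants inside a gene have distance 0. Distance from
#' position p to the interval is `max(0, start - p, p - end)`. A variant may
#' map to several genes; variants on chromosomes absent from the annotation
#' are unmapped and counted.
#'
#' @param variants Data.frame with `id`, `chrom`, `pos` (a
#'   `genotype_matrix$variants` table or summary statistics).
#' @param annotation Gene annotation data.frame (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @param window_bp Strict distance cut-off (default 10 kb).
#' @return An object of class `snp_gene_map`: list with `map` (long
#'   data.frame `variant_id`, `gene_id`, `distance`), `window_bp`,
#'   `n_unmapped`, `unmapped_ids`.
#' @export
map_snps_to_genes <- function(variants, annotation, window_bp = 10000) {
  if (window_bp <= 0) stopf("'window_bp' must be positive")
  if (any(annotation$start < 1) || any(annotation$start > annotation$end)) {
    stopf("annotation must use 1-based inclusive coordinates with start <= end")
  }
  pieces <- list()
  for (c in unique(annotation$chrom)) {
    genes <- annotation[annotation$chrom == c, , drop = FALSE]
    vs <- variants[variants$chrom == c, , drop = FALSE]
    if (nrow(vs) == 0L) next
    for (g in seq_len(nrow(genes))) {
      dist <- pmax(0, genes$start[g] - vs$pos, vs$pos - genes$end[g])
      hit <- dist < window_bp
      if (any(hit)) {
        pieces[[length(pieces) + 1L]] <- data.frame(
          variant_id = vs$id[hit], gene_id = genes$gene_id[g],
          distance = dist[hit], stringsAsFactors = FALSE)
      }
    }
  }
  map <- if (length(pieces) > 0L) do.call(rbind, pieces) else
    data.frame(variant_id = character(0), gene_id = character(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  mapped <- unique(map$variant_id)
  unmapped <- setdiff(variants$id, mapped)
  out <- list(map = map, window_bp = window_bp,
              n_unmapped = length(unmapped), unmapped_ids = unmapped)
  class(out) <- "snp_gene_map"
  out
}

#' @export
print.snp_gene_map <- function(x, ...) {
  cat(sprintf("SNP-to-gene map (< %d bp): %d assignments, %d variants mapped, %d unmapped\n",
              x$window_bp, nrow(x$map), length(unique(x$map$variant_id)),
              x$n_unmapped))
  invisible(x)
}

#' Build per-pathway variant sets
#'
#' For each pathway in a library, collects the union over its member genes
#' of mapped variants restricted to a supplied candidate set (typically the
#' thresholded, clumped variants). A variant enters a pathway's set once,
#' however many member genes it maps to. Pathways with fewer than
#' `min_variants` variants are excluded and logged.
#'
#' @param map A `snp_gene_map`.
#' @param library A `gene_set_library`.
#' @param variant_ids Candidate variant ids (thresholded/clumped set).
#' @param min_variants Minimum variants per retained pathway.
#' @return Named list of variant-id vectors; attribute `excluded` names the
#'   pathways dropped for having too few variants.
#' @export
build_pathway_variant_sets <- function(map, library, variant_ids,
                                       min_variants = 1) {
  m <- map$map[map$map$variant_id %in% variant_ids, , drop = FALSE]
  by_gene <- split(m$variant_id, m$gene_id)
  sets <- lapply(library$pathways, function(genes) {
    unique(unlist(by_gene[intersect(genes, names(by_gene))], use.names = FALSE))
  })
  sizes <- lengths(sets)
  excluded <- names(sets)[sizes < min_variants]
  sets <- sets[sizes >= min_variants]
  if (length(sets) == 0L) {
    warnf("library '%s': no pathway retains >= %d candidate variant(s)",
          library$library_name, min_variants)
  }
  attr(sets, "excluded") <- excluded
  sets
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (via [stats::p.adjust()] with `method = "BH"`),
#' after validating that every input p lies in `(0, 1]`.
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stopf("all p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pathway-based polygenic risk score scan
#'
#' The core procedure: for every combination of sex, p-value threshold and
#' gene-set library (one "iteration"), compute each pathway's restricted
#' polygenic score — the genome-wide thresholded (and, by default, clumped)
#' variant set intersected with the variants mapping to the pathway's genes
#' — score all individuals in sum-calculation mode, run the age-corrected
#' logistic association within the sex stratum, and apply Benjamini-Hochberg
#' FDR across exactly the pathways tested in that iteration. Pathway
#' regressions that fail are flagged and excluded from that iteration's FDR
#' family; iterations with no eligible pathway are skipped with a warning.
#'
#' @param genotypes A `genotype_matrix`.
#' @param sumstats Harmonized summary statistics providing the weights.
#' @param phenotypes Phenotype data.frame.
#' @param annotation Gene annotation data.frame.
#' @param libraries List of `gene_set_library` objects.
#' @param thresholds P-value cut-offs (defaults `5e-8` and `5e-5`).
#' @param sexes Sex strata to scan.
#' @param clump Apply genome-wide LD clumping before pathway restriction.
#' @param clump_r2,clump_window_bp Clumping parameters.
#' @param window_bp SNP-to-gene mapping window (strict, default 10 kb).
#' @param min_variants Minimum variants per pathway.
#' @param fdr_scope `"cell"` adjusts within each (sex, threshold, library)
#'   iteration; `"library"` pools all cells of a library.
#' @return A `pathway_prs_table`: data.frame with one row per (library,
#'   pathway, sex, threshold) carrying `n_variants`, `n_genes_hit`, `beta`,
#'   `se`, `p`, `p_fdr`, `status`.
#' @export
run_pprs_scan <- function(genotypes, sumstats, phenotypes, annotation,
                          libraries, thresholds = c(5e-8, 5e-5),
                          sexes = c("male", "female"), clump = TRUE,
                          clump_r2 = 0.1, clump_window_bp = 250000,
                          window_bp = 10000, min_variants = 1,
                          fdr_scope = c("cell", "library")) {
  fdr_scope <- match.arg(fdr_scope)
  sgmap <- map_snps_to_genes(genotypes$variants, annotation, window_bp)
  gene_of <- split(sgmap$map$gene_id, sgmap$map$variant_id)

  rows <- list()
  for (thr in thresholds) {
    sel <- suppressWarnings(select_variants(sumstats, thr))
    if (clump && nrow(sel) > 1L) {
      sel <- ld_clump(sel, genotypes, clump_r2, clump_window_bp)
    }
    for (lib in libraries) {
      sets <- suppressWarnings(
        build_pathway_variant_sets(sgmap, lib, sel$id, min_variants))
      if (length(sets) == 0L) {
        warnf("iteration (threshold %g, library '%s') has no eligible pathway; skipped",
              thr, lib$library_name)
        next
      }
      for (pw in names(sets)) {
        ids <- sets[[pw]]
        w <- sel[sel$id %in% ids, c("id", "beta"), drop = FALSE]
        prs <- compute_prs(genotypes, w)
        n_genes_hit <- length(unique(unlist(gene_of[ids], use.names = FALSE)))
        for (sx in sexes) {
          res <- tryCatch(
            suppressWarnings(associate_prs(prs, phenotypes, sx, label = thr)),
            error = function(e) NULL)
          status <- if (is.null(res) || is.na(res$p)) "failed" else "ok"
          rows[[length(rows) + 1L]] <- data.frame(
            library = lib$library_name, pathway = pw, sex = sx,
            threshold = thr, n_variants = length(ids),
            n_genes_hit = n_genes_hit,
            beta = if (status == "ok") res$beta else NA_real_,
            se = if (status == "ok") res$se else NA_real_,
            p = if (status == "ok") res$p else NA_real_,
            p_fdr = NA_real_, status = status, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) stopf("no pathway was testable in any iteration")
  tab <- do.call(rbind, rows)
  key <- if (fdr_scope == "cell") {
    paste(tab$sex, tab$threshold, tab$library)
  } else {
    tab$library
  }
  for (k in unique(key)) {
    sel_rows <- which(key == k & tab$status == "ok")
    if (length(sel_rows) > 0L) {
      tab$p_fdr[sel_rows] <- bh_fdr(tab$p[sel_rows])
    }
  }
  rownames(tab) <- NULL
  attr(tab, "fdr_scope") <- fdr_scope
  attr(tab, "mapping") <- sgmap
  class(tab) <- c("pathway_prs_table", "data.frame")
  tab
}

#' @export
print.pathway_prs_table <- function(x, max_rows = 10, ...) {
  cat(sprintf("Pathway PRS scan: %d rows (%d libraries, %d pathways, FDR scope '%s')\n",
              nrow(x), length(unique(x$library)), length(unique(x$pathway)),
              attr(x, "fdr_scope")))
  ok <- x[x$status == "ok", , drop = FALSE]
  ord <- order(ok$p_fdr)
  top <- utils::head(ok[ord, c("library", "pathway", "sex", "threshold",
                               "n_variants", "beta", "p", "p_fdr")], max_rows)
  print.data.frame(top, row.names = FALSE, digits = 3)
  if (nrow(ok) > max_rows) cat(sprintf("  ... %d more rows\n", nrow(ok) - max_rows))
  invisible(x)
}
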