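#' Simulate a gene annotation and gene-set libraries
#'
#' Genes are tiled along each chromosome with fixed length
#' `gene_length_bp` and fixed intergenic gap `intergenic_gap_bp`, using
#' 1-based, fully inclusive coordinates (the VCF convention used throughout
#' the package). Three gene-set libraries are generated, each containing
#' `n_pathways_per_library` pathways of `genes_per_pathway` randomly sampled
#' genes — mimicking the redundancy and overlap of curated pathway
#' collections. When `planted_pathway_id` is set in the config, a pathway
#' with that name is placed in the first library; its member genes are the
#' ones the phenotype simulator confines the shared genetic component to.
#'
#' @param config A [sim_config()] object.
#' @return A list with
#'   * `annotation` — data.frame with `gene_id`, `chrom`, `start`, `end`
#'     (1-based inclusive; genes never overlap),
#'   * `libraries` — list of three `gene_set_library` objects, each a list
#'     with `library_name` and `pathways` (named list of gene-id vectors).
#' @examples
#' ann <- simulate_annotation(sim_config(n_genes = 20, n_pathways_per_library = 5,
#'                                       genes_per_pathway = 4))
#' head(ann$annotation)
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 2L))
  layout <- genome_layout(config)
  period <- layout$period

  gene_id <- sprintf("GENE%04d", seq_len(config$n_genes))
  chrom <- rep(seq_len(config$n_chromosomes), layout$genes_per_chrom)
  idx_within <- unlist(lapply(layout$genes_per_chrom, seq_len), use.names = FALSE)
  start <- (idx_within - 1L) * period + 1L
  end <- start + config$gene_length_bp - 1L
  annotation <- data.frame(gene_id = gene_id, chrom = chrom,
                           start = as.integer(start), end = as.integer(end),
                           stringsAsFactors = FALSE)

  lib_names <- c("kegg_like_2019", "wikipathways_like_2019", "panther_like_2016")
  libraries <- lapply(lib_names, function(lib) {
    pw <- lapply(seq_len(config$n_pathways_per_library), function(i) {
      sample(gene_id, config$genes_per_pathway)
    })
    names(pw) <- sprintf("%s_pathway_%03d", lib, seq_along(pw))
    structure(list(library_name = lib, pathways = pw),
              class = "gene_set_library")
  })
  if (!is.null(config$planted_pathway_id)) {
    names(libraries[[1]]$pathways)[1] <- config$planted_pathway_id
  }
  list(annotation = annotation, libraries = libraries)
}

#' @export
print.gene_set_library <- function(x, ...) {
  sizes <- lengths(x$pathways)
  cat(sprintf("Gene-set library '%s': %d pathways (%d-%d genes each)\n",
              x$library_name, length(x$pathways), min(sizes), max(sizes)))
  invisible(x)
}

# Locate a pathway by name across a list of libraries; NULL when absent.
find_pathway <- function(libraries, pathway_id) {
  for (lib in libraries) {
    if (pathway_id %in% names(lib$pathways)) return(lib$pathways[[pathway_id]])
  }
  NULL
}
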