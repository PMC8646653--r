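#' Write a genotype matrix as VCF
#'
#' Diploid, unphased GT records (`0/0`, `0/1`, `1/1`), one sample column per
#' individual. The coded allele is written as ALT (dosage = ALT copies) and
#' the other allele as REF; positions are 1-based as simulated.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output file path (plain text; use a `.vcf` extension).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  validate_genotype_matrix(genotypes)
  v <- genotypes$variants
  gt_codes <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pathprs",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$individuals$id), collapse = "\t")
  ), con)
  gt <- matrix(gt_codes[t(genotypes$dosages) + 1L], nrow = nrow(v))
  body <- paste(v$chrom, v$pos, v$id, v$other_allele, v$coded_allele,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes from VCF or a dosage TSV
#'
#' VCF input (`.vcf` / `.vcf.gz`) is parsed with the vcfR package; dosages
#' count copies of the ALT allele, which becomes the coded allele.
#' Multi-allelic records and non-diploid GT values raise an error naming the
#' offending record. Missing genotypes (`./.`) become `NA` dosages. A
#' dosage TSV (as written by [write_dosage_tsv()]) is read back directly.
#' Sex is not encoded in either format and is returned as `NA`; attach it
#' from a phenotype table if needed.
#'
#' @param path Input file.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) read_genotypes_vcf(path)
  else read_dosage_tsv(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    i <- which(multi)[1]
    stopf("multi-allelic record at %s:%s (record %d) is not supported",
          fix[i, "CHROM"], fix[i, "POS"], i)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  lookup <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = NA_integer_)
  dos_t <- lookup[gt_clean]
  bad <- !is.na(gt_clean) & !(gt_clean %in% names(lookup))
  if (any(bad)) {
    i <- which(bad, arr.ind = FALSE)[1]
    rec <- (i - 1L) %% nrow(gt) + 1L
    stopf("unsupported genotype '%s' (mixed ploidy?) at record %d (%s:%s)",
          gt[i], rec, fix[rec, "CHROM"], fix[rec, "POS"])
  }
  dos <- t(matrix(dos_t, nrow = nrow(gt), dimnames = dimnames(gt)))
  ids <- fix[, "ID"]
  if (any(is.na(ids) | ids == ".")) ids <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  colnames(dos) <- ids
  out <- list(
    dosages = dos,
    variants = data.frame(
      id = ids, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
      coded_allele = alt, other_allele = fix[, "REF"],
      stringsAsFactors = FALSE),
    individuals = data.frame(id = rownames(dos), sex = NA_character_,
                             stringsAsFactors = FALSE)
  )
  class(out) <- "genotype_matrix"
  out
}

#' Write / read a plain dosage TSV
#'
#' One row per variant: `id`, `chrom`, `pos`, `coded_allele`,
#' `other_allele`, then one integer dosage column per individual.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path File path.
#' @return `path` (writer) or a `genotype_matrix` (reader).
#' @export
write_dosage_tsv <- function(genotypes, path) {
  validate_genotype_matrix(genotypes)
  d <- cbind(genotypes$variants[, c("id", "chrom", "pos", "coded_allele",
                                    "other_allele")],
             as.data.frame(t(genotypes$dosages)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("id", "chrom", "pos", "coded_allele", "other_allele")
  dos <- t(as.matrix(d[, setdiff(names(d), meta_cols), drop = FALSE]))
  storage.mode(dos) <- "integer"
  colnames(dos) <- d$id
  out <- list(
    dosages = dos,
    variants = d[, meta_cols],
    individuals = data.frame(id = rownames(dos), sex = NA_character_,
                             stringsAsFactors = FALSE)
  )
  class(out) <- "genotype_matrix"
  out
}

#' Write / read a phenotype TSV
#'
#' Tab-separated with the canonical phenotype columns; missing balding
#' patterns are written as `NA`.
#'
#' @param phenotypes Phenotype data.frame.
#' @param path File path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  d$aga_pattern <- as.integer(d$aga_pattern)
  d
}

#' Write / read GWAS summary statistics
#'
#' Fixed header `SNP CHR BP A1 A2 BETA SE P N` (A1 is the effect allele).
#' The reader tolerates extra columns and gzip-compressed files and
#' recomputes `z = BETA/SE`.
#'
#' @param sumstats Summary-statistics data.frame.
#' @param path File path (`.gz` supported by the reader).
#' @export
write_sumstats <- function(sumstats, path) {
  d <- data.frame(SNP = sumstats$id, CHR = sumstats$chrom, BP = sumstats$pos,
                  A1 = sumstats$effect_allele, A2 = sumstats$other_allele,
                  BETA = sumstats$beta, SE = sumstats$se, P = sumstats$p,
                  N = sumstats$n)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "N")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0L) {
    stopf("summary-statistics file lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  data.frame(id = as.character(d$SNP), chrom = d$CHR, pos = d$BP,
             effect_allele = d$A1, other_allele = d$A2,
             beta = d$BETA, se = d$SE, p = d$P, z = d$BETA / d$SE, n = d$N,
             stringsAsFactors = FALSE)
}

#' Write / read a gene-set library in GMT format
#'
#' Tab-separated, one pathway per line: name, description, then member gene
#' ids.
#'
#' @param library A `gene_set_library`.
#' @param path File path.
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(names(library$pathways), function(pw) {
    paste(c(pw, library$library_name, library$pathways[[pw]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @param library_name Name to give the library on reading (defaults to the
#'   file name without extension).
#' @export
read_gmt <- function(path, library_name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  pathways <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stopf("malformed GMT line (need name, description, >=1 gene): %s", f[1])
    pathways[[f[1]]] <- f[-(1:2)]
  }
  structure(list(library_name = library_name %||%
                   sub("\\.gmt$", "", basename(path)),
                 pathways = pathways),
            class = "gene_set_library")
}

#' Write / read gene annotation as a BED-like TSV
#'
#' Internally the package uses 1-based fully inclusive coordinates (the VCF
#' convention); the BED export converts to 0-based half-open at the
#' boundary, and the header comment states so. The reader converts back.
#'
#' @param annotation Gene annotation data.frame (1-based inclusive).
#' @param path File path.
#' @export
write_annotation_bed <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based half-open (BED); internal convention is 1-based inclusive",
             con)
  writeLines(paste(annotation$chrom, annotation$start - 1L, annotation$end,
                   annotation$gene_id, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start0", "end", "gene_id"))
  data.frame(gene_id = d$gene_id, chrom = d$chrom,
             start = as.integer(d$start0 + 1L), end = as.integer(d$end),
             stringsAsFactors = FALSE)
}

#' Write / read an LD score table
#'
#' Tab-separated with header `SNP CHR BP L2`.
#'
#' @param ld LD score data.frame from [compute_ld_scores()].
#' @param path File path.
#' @export
write_ld_scores <- function(ld, path) {
  d <- data.frame(SNP = ld$id, CHR = ld$chrom, BP = ld$pos, L2 = ld$l)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ld_scores
#' @export
read_ld_scores <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  data.frame(id = as.character(d$SNP), chrom = d$CHR, pos = d$BP, l = d$L2,
             stringsAsFactors = FALSE)
}
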