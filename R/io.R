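# Readers and writers for the pipeline's file dialects.

#' Write / read gene models as BED
#'
#' Six-column BED: chrom, start (0-based), end, name, score (0), strand.
#' The target-gene designation is carried as score 1 on that row.
#'
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   optionally `is_target`).
#' @param path file path.
#' @return `path` (write) or a gene table (read).
#' @export
write_genes_bed <- function(genes, path) {
  is_t <- if ("is_target" %in% names(genes)) genes$is_target else rep(FALSE, nrow(genes))
  strand <- if ("strand" %in% names(genes)) genes$strand else rep("+", nrow(genes))
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                    score = as.integer(is_t), strand = strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_genes_bed
#' @export
read_genes_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("gene BED needs >= 4 columns", call. = FALSE)
  data.frame(
    gene_id = bed[[4L]], chrom = bed[[1L]],
    start = as.integer(bed[[2L]]), end = as.integer(bed[[3L]]),
    strand = if (ncol(bed) >= 6L) bed[[6L]] else "+",
    is_target = if (ncol(bed) >= 5L) bed[[5L]] == 1L else FALSE,
    stringsAsFactors = FALSE)
}

#' Read a variant table (tab-delimited or VCF)
#'
#' Tab-delimited tables need columns `rsid, chrom, pos, ref, alt, maf`
#' (1-based positions). Files starting with `##fileformat=VCF` are parsed
#' with the vcfR package; MAF is taken from an `AF`/`MAF` INFO field when
#' present (capped at 0.5), otherwise `NA`.
#'
#' @param path file path.
#' @return data frame `rsid`, `chrom`, `pos`, `ref`, `alt`, `maf`.
#' @export
read_variants <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the vcfR package", call. = FALSE)
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
    if (all(is.na(af))) {
      af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MAF")))
    }
    maf <- pmin(af, 1 - af)
    return(data.frame(rsid = fix$ID, chrom = fix$CHROM,
                      pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                      maf = maf, stringsAsFactors = FALSE))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("rsid", "chrom", "pos", "ref", "alt", "maf")
  if (!all(needed %in% names(tab))) {
    stop("variant table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  tab[, needed]
}

#' Read a samples-by-features matrix from tab-delimited text
#'
#' First column = sample ids, remaining columns numeric features
#' (variant dosages or gene expression).
#'
#' @param path file path.
#' @return numeric matrix with sample rownames.
#' @export
read_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- tab[[1L]]
  m
}

#' Read the cohort haplotype and individual tables
#'
#' @param haplotype_path tab-delimited table: `haplotype_id`, `count`,
#'   one 0/1 column per site (a `cluster_true` column, if present, is
#'   carried through).
#' @param individual_path tab-delimited table: `individual_id`, `hap1`,
#'   `hap2`, `carrier_flags`, phenotype columns.
#' @return list with `haplotypes` and `individuals`.
#' @export
read_cohort <- function(haplotype_path, individual_path) {
  list(haplotypes = utils::read.delim(haplotype_path, stringsAsFactors = FALSE,
                                      check.names = FALSE),
       individuals = utils::read.delim(individual_path, stringsAsFactors = FALSE,
                                       check.names = FALSE))
}

#' Read a gene-level pLI table
#'
#' Accepts the two-column `gene<TAB>pli` dialect or a gnomAD-style
#' constraint export (`gene` + `pLI` columns).
#'
#' @param path file path.
#' @return data frame `gene`, `pli`.
#' @export
read_pli <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  pli_col <- intersect(c("pli", "pLI"), names(tab))[1L]
  if (is.na(pli_col) || !"gene" %in% names(tab)) {
    stop("pLI table must have columns 'gene' and 'pli'/'pLI'", call. = FALSE)
  }
  data.frame(gene = tab$gene, pli = as.numeric(tab[[pli_col]]),
             stringsAsFactors = FALSE)
}
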