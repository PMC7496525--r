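# Loss-of-function-intolerance (pLI) summaries by connection distance.
#
# Genes reached by significant eQTLs are grouped by connection class
# (cis, trans same-chromosome, trans inter-chromosomal) and compared with
# the unconnected background for their burden of LoF-intolerant genes
# (pLI >= 0.9) and median pLI. The summaries are descriptive — no
# enrichment test is attached.

#' Summarize pLI by connection distance class
#'
#' Deduplicates the significant-eQTL gene list per connection class,
#' defines the background as genes with no significant connection in any
#' class, and reports per class the number of genes, the proportion with
#' pLI at or above the intolerance threshold, and the median pLI. Genes
#' missing from the pLI table are counted and excluded from the statistics.
#' An empty class yields `n_genes = 0` with `NA` statistics.
#'
#' @param records eQTL record data frame with columns `gene_id`,
#'   `connection_class`, `significant` (e.g. from
#'   [confirm_spatial_eqtls()]); only significant records contribute.
#' @param pli data frame with columns `gene` (or `gene_id`) and `pli`,
#'   values in `[0, 1]`.
#' @param background_genes character vector of all genes under study.
#' @param threshold intolerance threshold (default 0.9).
#' @param strict if `TRUE`, count `pli > threshold` instead of the default
#'   `pli >= threshold`.
#' @return data frame with one row per class (`background`, `cis`,
#'   `trans_intra`, `trans_inter`): `class`, `n_genes`, `n_missing_pli`,
#'   `proportion_intolerant`, `median_pli`.
#' @export
#' @examples
#' recs <- data.frame(gene_id = c("g1", "g2"),
#'                    connection_class = c("cis", "trans_inter"),
#'                    significant = TRUE)
#' pli <- data.frame(gene = c("g1", "g2", "g3"), pli = c(0.1, 0.95, 0.83))
#' summarize_pli_by_class(recs, pli, c("g1", "g2", "g3"))
summarize_pli_by_class <- function(records, pli, background_genes,
                                   threshold = 0.9, strict = FALSE) {
  gene_col <- if ("gene" %in% names(pli)) "gene" else "gene_id"
  stopifnot(gene_col %in% names(pli), "pli" %in% names(pli))
  if (any(!is.na(pli$pli) & (pli$pli < 0 | pli$pli > 1))) {
    stop("pli values must lie in [0, 1]", call. = FALSE)
  }
  pli_map <- stats::setNames(pli$pli, pli[[gene_col]])
  sig <- records[!is.na(records$significant) & records$significant, , drop = FALSE]
  lists <- list(
    background = setdiff(unique(background_genes), unique(sig$gene_id)),
    cis = unique(sig$gene_id[sig$connection_class == "cis"]),
    trans_intra = unique(sig$gene_id[sig$connection_class == "trans_intra"]),
    trans_inter = unique(sig$gene_id[sig$connection_class == "trans_inter"])
  )
  rows <- lapply(names(lists), function(cl) {
    genes <- lists[[cl]]
    vals <- pli_map[genes]
    missing <- sum(is.na(vals))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) {
      return(data.frame(class = cl, n_genes = 0L, n_missing_pli = missing,
                        proportion_intolerant = NA_real_,
                        median_pli = NA_real_, stringsAsFactors = FALSE))
    }
    intol <- if (strict) vals > threshold else vals >= threshold
    data.frame(class = cl, n_genes = length(vals), n_missing_pli = missing,
               proportion_intolerant = mean(intol),
               median_pli = stats::median(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
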