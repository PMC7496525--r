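# End-to-end orchestration: locus analysis, genome-wide scan, cohort
# analysis. Each run_* function reads the configured inputs, composes the
# stage functions, writes provenance-stamped tables to the output
# directory, and returns the in-memory results.

#' Build a pipeline configuration
#'
#' Paths may point at a directory produced by [simulate_bundle()] (the
#' default file names are then filled in) or be given individually.
#'
#' @param input_dir directory holding the standard bundle files; individual
#'   path arguments override it.
#' @param out_dir output directory.
#' @param genome_path,genes_path,variants_path,contacts_path paths.
#' @param genotypes_path,expression_paths,haplotypes_path paths;
#'   `expression_paths` is a named vector (names = tissues).
#' @param individuals_path,pli_path paths.
#' @param enzyme_name restriction enzyme (default `"MboI"`).
#' @param locus locus of interest: list/vector with `chrom`, `start`,
#'   `end` (0-based half-open); `NULL` means the target gene flagged in
#'   the gene BED.
#' @param flank_bp flank around the locus for variant selection
#'   (default 20000).
#' @param maf_common common-variant MAF threshold (default 0.01).
#' @param allow_list rsids retained regardless of MAF (rare variants of
#'   known regulatory interest).
#' @param alpha FDR threshold for eQTL confirmation (default 0.05).
#' @param scan_maf_min,scan_p_threshold genome-wide scan thresholds
#'   (defaults 0.05 and 1e-6).
#' @param target_gene scan target; `NULL` means the flagged target gene.
#' @param exclusion carrier exclusion list
#'   (default [default_exclusion_list()]).
#' @param tag_sites tag-site names for cluster labelling; `NULL` uses all
#'   sites.
#' @param seed integer seed for any stochastic step.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = tempfile("speqtl_out"),
                            genome_path = NULL, genes_path = NULL,
                            variants_path = NULL, contacts_path = NULL,
                            genotypes_path = NULL, expression_paths = NULL,
                            haplotypes_path = NULL, individuals_path = NULL,
                            pli_path = NULL,
                            enzyme_name = "MboI", locus = NULL,
                            flank_bp = 20000L, maf_common = 0.01,
                            allow_list = character(), alpha = 0.05,
                            scan_maf_min = 0.05, scan_p_threshold = 1e-6,
                            target_gene = NULL,
                            exclusion = default_exclusion_list(),
                            tag_sites = NULL, seed = 1L) {
  stopifnot(maf_common > 0, maf_common < 1, alpha > 0, alpha < 1)
  d <- input_dir
  pick <- function(given, default) given %||% (if (!is.null(d)) file.path(d, default) else NULL)
  exp_paths <- expression_paths
  if (is.null(exp_paths) && !is.null(d)) {
    files <- list.files(d, pattern = "^expression_.*\\.tsv$", full.names = TRUE)
    exp_paths <- stats::setNames(files, sub("^expression_(.*)\\.tsv$", "\\1",
                                            basename(files)))
  }
  structure(list(
    out_dir = out_dir,
    genome_path = pick(genome_path, "genome.fa"),
    genes_path = pick(genes_path, "genes.bed"),
    variants_path = pick(variants_path, "variants.tsv"),
    contacts_path = pick(contacts_path, "contacts.tsv"),
    genotypes_path = pick(genotypes_path, "genotypes.tsv"),
    expression_paths = exp_paths,
    haplotypes_path = pick(haplotypes_path, "haplotypes.tsv"),
    individuals_path = pick(individuals_path, "individuals.tsv"),
    pli_path = pick(pli_path, "pli.tsv"),
    enzyme_name = enzyme_name, locus = locus, flank_bp = as.integer(flank_bp),
    maf_common = maf_common, allow_list = allow_list, alpha = alpha,
    scan_maf_min = scan_maf_min, scan_p_threshold = scan_p_threshold,
    target_gene = target_gene, exclusion = exclusion, tag_sites = tag_sites,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

require_path <- function(path, what) {
  if (is.null(path) || !all(file.exists(path))) {
    stop("missing ", what, " input: ",
         paste(path %||% "<unset>", collapse = ", "), call. = FALSE)
  }
  path
}

load_expression_set <- function(config) {
  paths <- require_path(config$expression_paths, "expression")
  stats::setNames(lapply(paths, read_matrix), names(paths))
}

#' Run the locus spatial-eQTL analysis
#'
#' Selects variants inside the locus (target gene by default) plus
#' `flank_bp` with MAF >= `maf_common` (plus any allow-listed rare
#' variants), digests the genome, maps variants to fragments, derives
#' chromatin-contact-supported SNP-gene pairs, confirms them as
#' tissue-specific eQTLs under BH-FDR `alpha`, and writes the pair and
#' eQTL tables plus per-class/pair-level connection counts.
#'
#' @param config a [pipeline_config()].
#' @return list with `variants_selected`, `pairs`, `records`,
#'   `connection_counts` (record-level and pair-level per class),
#'   `fragments`.
#' @export
run_locus_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  genome <- Biostrings::readDNAStringSet(require_path(config$genome_path, "genome"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  genes <- read_genes_bed(require_path(config$genes_path, "genes"))
  variants <- read_variants(require_path(config$variants_path, "variants"))
  genotypes <- read_matrix(require_path(config$genotypes_path, "genotypes"))
  expression <- load_expression_set(config)

  locus <- config$locus
  if (is.null(locus)) {
    tg <- genes[genes$is_target, , drop = FALSE]
    if (nrow(tg) == 0L) stop("no locus given and no target gene flagged", call. = FALSE)
    locus <- list(chrom = tg$chrom[1L], start = tg$start[1L], end = tg$end[1L])
  }
  in_locus <- variants$chrom == locus$chrom &
    variants$pos - 1 >= locus$start - config$flank_bp &
    variants$pos - 1 < locus$end + config$flank_bp
  selected <- in_locus & (variants$maf >= config$maf_common |
                            variants$rsid %in% config$allow_list)
  vsel <- variants[selected, , drop = FALSE]

  fragments <- digest(genome, config$enzyme_name)
  contacts <- load_contacts(require_path(config$contacts_path, "contacts"),
                            fragments)
  pairs <- spatial_pairs(vsel, genes, contacts, fragments)
  records <- confirm_spatial_eqtls(pairs, genotypes, expression,
                                   variants, genes, alpha = config$alpha)

  sig <- records[records$significant, , drop = FALSE]
  record_counts <- table(factor(sig$connection_class,
                                levels = c("cis", "trans_intra", "trans_inter")))
  pair_counts <- table(factor(
    unique(sig[, c("rsid", "gene_id", "connection_class")])$connection_class,
    levels = c("cis", "trans_intra", "trans_inter")))
  counts <- data.frame(
    class = c("cis", "trans_intra", "trans_inter"),
    n_records = as.integer(record_counts),
    n_pairs = as.integer(pair_counts), stringsAsFactors = FALSE)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_output_table(pairs, file.path(config$out_dir, "spatial_pairs.tsv"), config)
  write_output_table(records, file.path(config$out_dir, "eqtl_records.tsv"), config)
  write_output_table(counts, file.path(config$out_dir, "connection_counts.tsv"), config)

  list(variants_selected = vsel, pairs = pairs, records = records,
       connection_counts = counts, fragments = fragments)
}

#' Run the genome-wide distal-regulator scan
#'
#' Scans all variants (MAF >= `scan_maf_min`) against the target gene's
#' expression in every tissue at raw p < `scan_p_threshold`, groups hits
#' into 1 Mb loci, and feeds hit variants back through the eQTL engine
#' against all genes to list co-regulated genes.
#'
#' @param config a [pipeline_config()].
#' @return the [genome_wide_scan()] result list.
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  genes <- read_genes_bed(require_path(config$genes_path, "genes"))
  variants <- read_variants(require_path(config$variants_path, "variants"))
  genotypes <- read_matrix(require_path(config$genotypes_path, "genotypes"))
  expression <- load_expression_set(config)
  target <- config$target_gene %||% genes$gene_id[genes$is_target][1L]
  if (is.null(target) || is.na(target)) stop("no target gene", call. = FALSE)
  res <- genome_wide_scan(
    variants, genotypes, expression, genes,
    scan_config(target, maf_min = config$scan_maf_min,
                p_threshold = config$scan_p_threshold))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_output_table(res$hits, file.path(config$out_dir, "scan_hits.tsv"), config)
  write_output_table(res$loci, file.path(config$out_dir, "scan_loci.tsv"), config)
  if (!is.null(res$coregulation)) {
    write_output_table(res$coregulation,
                       file.path(config$out_dir, "scan_coregulation.tsv"), config)
  }
  res
}

#' Run the cohort haplotype analysis
#'
#' Clusters the cohort's distinct haplotypes into clusters A and B,
#' excludes coding-mutation carriers, assigns dosage groups, and regresses
#' each phenotype column on cluster-A allele dosage under the additive
#' model. Writes the membership, group-summary and regression tables.
#'
#' @param config a [pipeline_config()].
#' @param phenotypes phenotype column names (default `onset_age`,
#'   `diagnosis_age`).
#' @return list with `clustering`, `individuals` (post-exclusion),
#'   `assignments`, `group_summary`, `regressions` (one list per
#'   phenotype), `n_excluded`, `n_haplotypes`.
#' @export
run_cohort_analysis <- function(config,
                                phenotypes = c("onset_age", "diagnosis_age")) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- read_cohort(require_path(config$haplotypes_path, "haplotypes"),
                        require_path(config$individuals_path, "individuals"))
  haps <- cohort$haplotypes
  site_cols <- setdiff(names(haps), c("haplotype_id", "count", "cluster_true"))
  clustering <- cluster_haplotypes(
    haps[, c("haplotype_id", "count", site_cols)],
    tag_sites = config$tag_sites %||% site_cols)
  kept <- exclude_carriers(cohort$individuals, config$exclusion)
  assignments <- assign_groups(kept, clustering)
  phenotypes <- intersect(phenotypes, names(kept))
  regressions <- lapply(phenotypes, function(ph)
    additive_regression(assignments, kept, ph))
  names(regressions) <- phenotypes

  group_summary <- data.frame(
    group = 1:3,
    dosage = 2:0,
    n = as.integer(attr(assignments, "group_sizes")),
    stringsAsFactors = FALSE)
  for (ph in phenotypes) {
    group_summary[[paste0("mean_", ph)]] <-
      as.numeric(regressions[[ph]]$group_means)
  }
  reg_table <- do.call(rbind, lapply(regressions, function(r) {
    data.frame(phenotype = r$phenotype, pearson_r = r$pearson_r,
               p_value = r$p_value, slope_per_allele = r$slope, se = r$se,
               n = r$n, diff_g1_g3 = r$diff_g1_g3, stringsAsFactors = FALSE)
  }))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  membership <- data.frame(haplotype_id = names(clustering$labels),
                           cluster = unname(clustering$labels),
                           stringsAsFactors = FALSE)
  write_output_table(membership, file.path(config$out_dir, "haplotype_clusters.tsv"), config)
  write_output_table(group_summary, file.path(config$out_dir, "group_summary.tsv"), config)
  if (!is.null(reg_table)) {
    write_output_table(reg_table, file.path(config$out_dir, "regression_report.tsv"), config)
  }

  list(clustering = clustering, individuals = kept, assignments = assignments,
       group_summary = group_summary, regressions = regressions,
       n_excluded = attr(kept, "n_removed"),
       n_haplotypes = nrow(haps))
}

#' Run the pLI constraint summary
#'
#' @param config a [pipeline_config()].
#' @param records eQTL records (e.g. from [run_locus_analysis()]); if
#'   `NULL` the locus analysis is run first.
#' @return [summarize_pli_by_class()] output.
#' @export
run_pli_summary <- function(config, records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(records)) records <- run_locus_analysis(config)$records
  pli <- read_pli(require_path(config$pli_path, "pLI"))
  genes <- read_genes_bed(require_path(config$genes_path, "genes"))
  out <- summarize_pli_by_class(records, pli, genes$gene_id)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_output_table(out, file.path(config$out_dir, "pli_summary.tsv"), config)
  out
}
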