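# Deterministic synthetic-data generator.
#
# Emulates the statistical structure of the pipeline's real-world inputs —
# a reference genome with restriction motifs at realistic density, a
# common-variant table, fragment-level chromatin contacts with planted
# SNP-gene links plus decoys, Hardy-Weinberg genotypes with per-tissue
# expression carrying planted additive allelic effects, a two-cluster
# haplotype cohort with a planted per-allele onset delay, and a bimodal
# pLI landscape — so every downstream stage is testable offline.
#
# Reproducibility: each generator draws from its own stream seeded at
# cfg$seed plus a fixed documented offset (genome +101, variants +102,
# contacts +103, expression +104, cohort +105, pLI +106), and restores the
# caller's RNG state on exit; identical configs give identical outputs.

#' Build a synthetic-data configuration
#'
#' Defaults describe the package's standard toy study: 3 chromosomes of
#' 200 kb digested with MboI, 20 non-overlapping genes with one designated
#' target gene, 150 common variants (a third concentrated in the target
#' locus), 10 planted contact-supported eQTLs of 1 expression-sd per
#' alternate allele across 5 tissues of 200 samples, and a cohort of 229
#' individuals with a planted +2.85-year onset delay per cluster-A
#' haplotype allele (sd 8.5 y) and a 9.2% coding-mutation carrier
#' fraction at cluster-A allele frequency 0.286.
#'
#' @param seed integer seed; fixes every byte of the generated data.
#' @param n_chromosomes,chromosome_length_bp genome shape.
#' @param enzyme_name restriction enzyme for the digest (registry name).
#' @param n_genes,n_variants annotation sizes.
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param n_planted_contacts number of planted SNP-gene spatial eQTLs.
#' @param n_decoy_contacts random non-planted contact rows.
#' @param n_tissues,n_samples_per_tissue expression panel shape.
#' @param planted_eqtl_effect effect size in expression-sd units per
#'   alternate allele.
#' @param noise_sd expression noise standard deviation.
#' @param cohort_size individuals in the haplotype cohort.
#' @param n_tag_snps tag sites separating the two haplotype clusters.
#' @param n_extra_sites additional polymorphic sites giving within-cluster
#'   haplotype diversity.
#' @param cluster_a_freq population frequency of cluster-A haplotypes.
#' @param planted_onset_delay years of onset delay per cluster-A allele.
#' @param onset_noise_sd onset-age noise sd in years.
#' @param onset_base_age mean onset age of the zero-dosage group, years.
#' @param carrier_fraction proportion of individuals flagged with a coding
#'   mutation.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 3L,
                             chromosome_length_bp = 200000L,
                             enzyme_name = "MboI",
                             n_genes = 20L,
                             n_variants = 150L,
                             maf_range = c(0.05, 0.5),
                             n_planted_contacts = 10L,
                             n_decoy_contacts = 200L,
                             n_tissues = 5L,
                             n_samples_per_tissue = 200L,
                             planted_eqtl_effect = 1.0,
                             noise_sd = 1.0,
                             cohort_size = 229L,
                             n_tag_snps = 3L,
                             n_extra_sites = 12L,
                             cluster_a_freq = 0.286,
                             planted_onset_delay = 2.85,
                             onset_noise_sd = 8.5,
                             onset_base_age = 60,
                             carrier_fraction = 0.092) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chromosome_length_bp = as.integer(chromosome_length_bp),
              enzyme_name = enzyme_name, n_genes = as.integer(n_genes),
              n_variants = as.integer(n_variants), maf_range = maf_range,
              n_planted_contacts = as.integer(n_planted_contacts),
              n_decoy_contacts = as.integer(n_decoy_contacts),
              n_tissues = as.integer(n_tissues),
              n_samples_per_tissue = as.integer(n_samples_per_tissue),
              planted_eqtl_effect = planted_eqtl_effect, noise_sd = noise_sd,
              cohort_size = as.integer(cohort_size),
              n_tag_snps = as.integer(n_tag_snps),
              n_extra_sites = as.integer(n_extra_sites),
              cluster_a_freq = cluster_a_freq,
              planted_onset_delay = planted_onset_delay,
              onset_noise_sd = onset_noise_sd,
              onset_base_age = onset_base_age,
              carrier_fraction = carrier_fraction)
  counts <- c("n_chromosomes", "chromosome_length_bp", "n_tissues",
              "n_samples_per_tissue", "cohort_size", "n_tag_snps")
  for (nm in counts) {
    if (cfg[[nm]] <= 0L) stop(nm, " must be positive", call. = FALSE)
  }
  for (nm in c("n_genes", "n_variants", "n_planted_contacts",
               "n_decoy_contacts", "n_extra_sites")) {
    if (cfg[[nm]] < 0L) stop(nm, " must be non-negative", call. = FALSE)
  }
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  if (cfg$cluster_a_freq <= 0 || cfg$cluster_a_freq >= 1) {
    stop("cluster_a_freq must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$carrier_fraction < 0 || cfg$carrier_fraction > 1) {
    stop("carrier_fraction must lie in [0, 1]", call. = FALSE)
  }
  enzyme_from_name(cfg$enzyme_name)  # validates
  structure(cfg, class = "synthetic_config")
}

#' Default Hi-C library source labels
#'
#' Cell-line labels attached to generated contact rows, mirroring the
#' lines of widely used published in-situ Hi-C libraries.
#'
#' @return character vector.
#' @export
hic_source_labels <- function() {
  c("GM12878", "HMEC", "HUVEC", "IMR90", "K562", "KBM7", "NHEK",
    "hESC", "cortex_DLPFC", "hippocampus")
}

tissue_labels <- function(n) {
  base <- c("substantia_nigra", "cortex", "cerebellum", "blood", "liver")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("tissue%02d", seq_len(n - length(base)) + length(base)))
}

#' Generate a synthetic genome and gene models
#'
#' Random uniform nucleotide sequences (restriction motifs therefore occur
#' at their combinatorial density, e.g. GATC every ~256 bp) and
#' non-overlapping stranded gene intervals, with the gene nearest the
#' middle of the first chromosome designated the target gene (the analysis
#' anchor, analogous to a disease gene under regulatory study).
#'
#' @param cfg a [synthetic_config()].
#' @return list with `genome` (`DNAStringSet`) and `genes` (data frame:
#'   `gene_id`, `chrom`, `start` 0-based, `end`, `strand`, `is_target`).
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed + 101L, {
    chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
    seqs <- vapply(chroms, function(ch) {
      paste(sample(c("A", "C", "G", "T"), cfg$chromosome_length_bp,
                   replace = TRUE), collapse = "")
    }, "")
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chroms
    if (cfg$n_genes == 0L) {
      genes <- data.frame(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), is_target = logical(),
                          stringsAsFactors = FALSE)
      return(list(genome = genome, genes = genes))
    }
    # round-robin genes across chromosomes; one gene per equal-width bin
    # guarantees non-overlap
    chrom_of <- rep_len(chroms, cfg$n_genes)
    gene_len_max <- 6000L
    rows <- vector("list", cfg$n_genes)
    for (ch in chroms) {
      idx <- which(chrom_of == ch)
      if (!length(idx)) next
      bin <- cfg$chromosome_length_bp %/% length(idx)
      if (bin < gene_len_max + 200L) {
        stop("chromosome too short to host ", length(idx),
             " non-overlapping genes", call. = FALSE)
      }
      for (j in seq_along(idx)) {
        len <- sample(2000:gene_len_max, 1L)
        lo <- (j - 1L) * bin + 100L
        start <- lo + sample.int(bin - len - 200L, 1L) - 1L
        rows[[idx[j]]] <- data.frame(
          gene_id = sprintf("G%02d", idx[j]), chrom = ch,
          start = start, end = start + len,
          strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
      }
    }
    genes <- do.call(rbind, rows)
    on_chr1 <- which(genes$chrom == chroms[1L])
    mid <- cfg$chromosome_length_bp / 2
    target <- on_chr1[which.min(abs((genes$start[on_chr1] + genes$end[on_chr1]) / 2 - mid))]
    genes$is_target <- seq_len(nrow(genes)) == target
    list(genome = genome, genes = genes)
  })
}

#' Generate a synthetic common-variant table
#'
#' About a third of the variants are concentrated in the target locus
#' (target gene +/- `locus_flank_bp`), emulating dense locus coverage; the
#' rest are uniform genome-wide. Reference alleles are taken from the
#' genome sequence, alternates drawn from the other three bases, and MAFs
#' uniform over `cfg$maf_range`.
#'
#' @param cfg a [synthetic_config()].
#' @param genome `DNAStringSet` from [generate_genome()].
#' @param genes gene table from [generate_genome()].
#' @param locus_flank_bp flank around the target gene for locus variants.
#' @return data frame `rsid`, `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `maf`, sorted by position.
#' @export
generate_variants <- function(cfg, genome, genes, locus_flank_bp = 10000L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed + 102L, {
    chroms <- names(genome)
    n <- cfg$n_variants
    if (n == 0L) {
      return(data.frame(rsid = character(), chrom = character(),
                        pos = integer(), ref = character(), alt = character(),
                        maf = numeric(), stringsAsFactors = FALSE))
    }
    target <- genes[genes$is_target, , drop = FALSE]
    n_locus <- if (nrow(target)) ceiling(n / 3) else 0L
    pos <- integer(0); chrom <- character(0)
    if (n_locus > 0L) {
      lo <- max(1L, target$start - locus_flank_bp + 1L)
      hi <- min(cfg$chromosome_length_bp, target$end + locus_flank_bp)
      pos <- sample(lo:hi, n_locus)
      chrom <- rep(target$chrom, n_locus)
    }
    n_rest <- n - n_locus
    if (n_rest > 0L) {
      chrom <- c(chrom, sample(chroms, n_rest, replace = TRUE))
      pos <- c(pos, sample.int(cfg$chromosome_length_bp, n_rest, replace = TRUE))
    }
    keep <- !duplicated(paste(chrom, pos))
    chrom <- chrom[keep]; pos <- pos[keep]
    ord <- order(match(chrom, chroms), pos)
    chrom <- chrom[ord]; pos <- pos[ord]
    ref <- vapply(seq_along(pos), function(i) {
      as.character(Biostrings::subseq(genome[[chrom[i]]], pos[i], pos[i]))
    }, "")
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    data.frame(
      rsid = sprintf("rs%06d", seq_along(pos)),
      chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
      maf = stats::runif(length(pos), cfg$maf_range[1], cfg$maf_range[2]),
      stringsAsFactors = FALSE)
  })
}

#' Generate a fragment-level contact table with planted SNP-gene links
#'
#' For every planted pair, one contact row links the variant's restriction
#' fragment to a fragment overlapping the gene (the first overlapping
#' fragment distinct from the variant's own, for determinism); decoy rows
#' pair random fragments. Each row carries a source label drawn from
#' `sources`. A planted pair whose gene lies entirely on the variant's own
#' fragment is trivially "spatial" and is reported with a warning instead
#' of a contact row.
#'
#' @param cfg a [synthetic_config()].
#' @param fragments fragment index from [digest()].
#' @param variants,genes tables the planted pairs refer to.
#' @param planted_pairs data frame with columns `rsid`, `gene_id`.
#' @param sources label pool (default [hic_source_labels()]).
#' @return data frame `chrom_a, start_a, end_a, chrom_b, start_b, end_b,
#'   source` (interval dialect, 0-based half-open).
#' @export
generate_contacts <- function(cfg, fragments, variants, genes, planted_pairs,
                              sources = hic_source_labels()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  bad_v <- setdiff(planted_pairs$rsid, variants$rsid)
  bad_g <- setdiff(planted_pairs$gene_id, genes$gene_id)
  if (length(bad_v) || length(bad_g)) {
    stop("planted pairs reference unknown variants/genes: ",
         paste(c(bad_v, bad_g), collapse = ", "), call. = FALSE)
  }
  with_seed(cfg$seed + 103L, {
    frag_gr <- fragments_as_granges(fragments)
    gene_gr <- genes_as_granges(genes)
    ov <- GenomicRanges::findOverlaps(gene_gr, frag_gr)
    rows <- list()
    for (i in seq_len(nrow(planted_pairs))) {
      v <- variants[variants$rsid == planted_pairs$rsid[i], ]
      loc <- locate(fragments, v$chrom, v$pos)
      snp_key <- fragment_key(loc$chrom, loc$fragment_id)
      gidx <- match(planted_pairs$gene_id[i], genes$gene_id)
      cand <- frag_gr$key[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == gidx]]
      cand <- setdiff(cand, snp_key)
      if (!length(cand)) {
        warning("planted pair ", planted_pairs$rsid[i], "-",
                planted_pairs$gene_id[i],
                ": variant and gene share one fragment (trivially spatial); ",
                "no contact emitted", call. = FALSE)
        next
      }
      gk <- cand[1L]
      fa <- fragments[fragment_key(fragments$chrom, fragments$fragment_id) == snp_key, ]
      fb <- fragments[fragment_key(fragments$chrom, fragments$fragment_id) == gk, ]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom_a = fa$chrom, start_a = fa$start, end_a = fa$end,
        chrom_b = fb$chrom, start_b = fb$start, end_b = fb$end,
        source = sample(sources, 1L), stringsAsFactors = FALSE)
    }
    if (cfg$n_decoy_contacts > 0L && nrow(planted_pairs) + cfg$n_decoy_contacts > 0L) {
      ia <- sample.int(nrow(fragments), cfg$n_decoy_contacts, replace = TRUE)
      ib <- sample.int(nrow(fragments), cfg$n_decoy_contacts, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom_a = fragments$chrom[ia], start_a = fragments$start[ia],
        end_a = fragments$end[ia],
        chrom_b = fragments$chrom[ib], start_b = fragments$start[ib],
        end_b = fragments$end[ib],
        source = sample(sources, cfg$n_decoy_contacts, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    if (!length(rows)) {
      return(data.frame(chrom_a = character(), start_a = integer(),
                        end_a = integer(), chrom_b = character(),
                        start_b = integer(), end_b = integer(),
                        source = character(), stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate Hardy-Weinberg genotypes and per-tissue expression
#'
#' Dosages are drawn per variant as Binomial(2, MAF); expression of gene g
#' in tissue t is `baseline + sum(beta * dosage) + N(0, noise_sd)`, where
#' planted betas are given in expression-sd units (scaled by `noise_sd`)
#' and apply in the named tissue, or all tissues when `tissue == "all"`.
#' Unplanted pairs have beta 0.
#'
#' @param cfg a [synthetic_config()].
#' @param variants,genes annotation tables.
#' @param planted_effects data frame `rsid`, `gene_id`, `tissue`, `beta`
#'   (may have zero rows).
#' @return list with `genotypes` (samples x variants dosage matrix) and
#'   `expression` (named list of samples x genes matrices, one per tissue).
#' @export
generate_expression <- function(cfg, variants, genes, planted_effects) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_samples_per_tissue < 3L) {
    stop("n_samples_per_tissue must be >= 3 (regression undefined below that)",
         call. = FALSE)
  }
  stopifnot(all(is.finite(planted_effects$beta)))
  with_seed(cfg$seed + 104L, {
    n <- cfg$n_samples_per_tissue
    samples <- sprintf("S%04d", seq_len(n))
    genotypes <- vapply(variants$maf, function(p) stats::rbinom(n, 2L, p),
                        integer(n))
    dimnames(genotypes) <- list(samples, variants$rsid)
    tissues <- tissue_labels(cfg$n_tissues)
    baseline <- stats::rnorm(nrow(genes), mean = 5, sd = 1)
    expression <- lapply(tissues, function(t) {
      e <- matrix(stats::rnorm(n * nrow(genes), mean = 0, sd = cfg$noise_sd),
                  nrow = n, dimnames = list(samples, genes$gene_id))
      e <- sweep(e, 2L, baseline, "+")
      eff <- planted_effects[planted_effects$tissue %in% c(t, "all"), , drop = FALSE]
      for (i in seq_len(nrow(eff))) {
        e[, eff$gene_id[i]] <- e[, eff$gene_id[i]] +
          eff$beta[i] * cfg$noise_sd * genotypes[, eff$rsid[i]]
      }
      e
    })
    names(expression) <- tissues
    list(genotypes = genotypes, expression = expression)
  })
}

#' Generate a two-cluster haplotype cohort with phenotypes
#'
#' Haplotypes fall into two clusters: cluster A carries the alternate
#' allele at every tag site, cluster B the reference; additional
#' low-frequency sites create within-cluster diversity. Each individual
#' draws two haplotypes at cluster-A frequency `cfg$cluster_a_freq`
#' (Hardy-Weinberg dosage groups), and onset age is
#' `onset_base_age + planted_onset_delay * (cluster-A allele count) +
#' N(0, onset_noise_sd)`; diagnosis age adds a Uniform(1, 3)-year lag, so
#' the two phenotypes are highly collinear. A `carrier_fraction` of
#' individuals is flagged with a coding-mutation id drawn from
#' `carrier_ids`.
#'
#' @param cfg a [synthetic_config()].
#' @param carrier_ids pool of coding-mutation identifiers
#'   (default [default_exclusion_list()]).
#' @return list with `haplotypes` (data frame: `haplotype_id`, `count`,
#'   `cluster_true`, one 0/1 column per site), `individuals` (data frame:
#'   `individual_id`, `hap1`, `hap2`, `carrier_flags`, `onset_age`,
#'   `diagnosis_age`, `dosage_true`), and `tag_sites`.
#' @export
generate_cohort <- function(cfg, carrier_ids = default_exclusion_list()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$cohort_size < 10L) stop("cohort_size must be >= 10", call. = FALSE)
  if (cfg$n_tag_snps < 1L) stop("n_tag_snps must be >= 1", call. = FALSE)
  with_seed(cfg$seed + 105L, {
    tag_sites <- if (cfg$n_tag_snps == 3L) {
      c("rs9628662", "rs762488", "rs2009578")
    } else {
      sprintf("tag%02d", seq_len(cfg$n_tag_snps))
    }
    extra_sites <- if (cfg$n_extra_sites > 0L) {
      sprintf("site%02d", seq_len(cfg$n_extra_sites))
    } else {
      character(0)
    }
    n_chrom <- 2L * cfg$cohort_size
    cluster <- stats::rbinom(n_chrom, 1L, cfg$cluster_a_freq)  # 1 = A
    tags <- matrix(rep(cluster, each = cfg$n_tag_snps), nrow = n_chrom,
                   byrow = TRUE)
    extras <- if (length(extra_sites)) {
      matrix(stats::rbinom(n_chrom * length(extra_sites), 1L, 0.06),
             nrow = n_chrom)
    } else {
      matrix(integer(0), nrow = n_chrom, ncol = 0L)
    }
    alleles <- cbind(tags, extras)
    colnames(alleles) <- c(tag_sites, extra_sites)
    hap_str <- apply(alleles, 1L, paste, collapse = "")
    tab <- sort(table(hap_str), decreasing = TRUE)
    # most prevalent haplotype first; ties broken by allele string
    ord <- order(-as.integer(tab), names(tab))
    hap_levels <- names(tab)[ord]
    hap_ids <- sprintf("H%02d", seq_along(hap_levels))
    names(hap_ids) <- hap_levels
    first <- match(hap_levels, hap_str)
    haplotypes <- data.frame(
      haplotype_id = hap_ids[hap_levels],
      count = as.integer(tab[hap_levels]),
      cluster_true = ifelse(cluster[first] == 1L, "A", "B"),
      stringsAsFactors = FALSE)
    haplotypes <- cbind(haplotypes,
                        as.data.frame(alleles[first, , drop = FALSE]))
    rownames(haplotypes) <- NULL
    hap_of_chrom <- hap_ids[hap_str]
    h1 <- hap_of_chrom[seq_len(cfg$cohort_size)]
    h2 <- hap_of_chrom[cfg$cohort_size + seq_len(cfg$cohort_size)]
    dosage <- cluster[seq_len(cfg$cohort_size)] +
      cluster[cfg$cohort_size + seq_len(cfg$cohort_size)]
    onset <- cfg$onset_base_age + cfg$planted_onset_delay * dosage +
      stats::rnorm(cfg$cohort_size, 0, cfg$onset_noise_sd)
    diagnosis <- onset + stats::runif(cfg$cohort_size, 1, 3)
    is_carrier <- stats::rbinom(cfg$cohort_size, 1L, cfg$carrier_fraction) == 1L
    flags <- character(cfg$cohort_size)
    flags[is_carrier] <- sample(carrier_ids, sum(is_carrier), replace = TRUE)
    individuals <- data.frame(
      individual_id = sprintf("P%04d", seq_len(cfg$cohort_size)),
      hap1 = unname(h1), hap2 = unname(h2),
      carrier_flags = flags,
      onset_age = onset, diagnosis_age = diagnosis,
      dosage_true = as.integer(dosage),
      stringsAsFactors = FALSE)
    list(haplotypes = haplotypes, individuals = individuals,
         tag_sites = tag_sites)
  })
}

#' Generate a bimodal gene-level pLI table
#'
#' Each gene's pLI is drawn from a two-component mixture (Beta(0.5, 4)
#' tolerant mass near 0, Beta(8, 1) intolerant mass near 1). The
#' probability of the intolerant component can be graded by connection
#' class via `class_of`, reproducing the empirical pattern that genes
#' reached over longer distances carry more loss-of-function-intolerant
#' mass.
#'
#' @param cfg a [synthetic_config()].
#' @param genes gene table.
#' @param class_of optional named character vector `gene_id -> class`
#'   (`cis`, `trans_intra`, `trans_inter`); unnamed genes are background.
#' @param weights named numeric vector of intolerant-component
#'   probabilities per class.
#' @return data frame `gene`, `pli`.
#' @export
generate_pli <- function(cfg, genes, class_of = NULL,
                         weights = c(background = 0.05, cis = 0.20,
                                     trans_intra = 0.50, trans_inter = 0.85)) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed + 106L, {
    cls <- rep("background", nrow(genes))
    if (!is.null(class_of)) {
      hit <- match(genes$gene_id, names(class_of))
      cls[!is.na(hit)] <- class_of[hit[!is.na(hit)]]
    }
    w <- weights[cls]
    hi <- stats::rbinom(nrow(genes), 1L, w) == 1L
    pli <- ifelse(hi, stats::rbeta(nrow(genes), 8, 1),
                  stats::rbeta(nrow(genes), 0.5, 4))
    data.frame(gene = genes$gene_id, pli = pli, stringsAsFactors = FALSE)
  })
}

#' Generate the full synthetic input bundle
#'
#' Orchestrates all generators under one configuration: genome and genes,
#' digest, variant table, planted SNP-gene pairs (locus variants paired
#' alternately with genes on the target chromosome and on other
#' chromosomes, giving a mix of cis and trans-interchromosomal links),
#' contacts, genotypes and expression with the planted effects in all
#' tissues, the haplotype cohort, and a class-graded pLI table. With `dir`
#' set, all inputs are also serialized in the pipeline's file dialects.
#'
#' @param cfg a [synthetic_config()].
#' @param dir optional output directory for the serialized bundle.
#' @return list with every generated object plus `planted_pairs` (with a
#'   `class` column), `planted_effects`, `fragments` and `target_gene`.
#' @export
simulate_bundle <- function(cfg = synthetic_config(), dir = NULL) {
  gen <- generate_genome(cfg)
  fragments <- digest(gen$genome, cfg$enzyme_name)
  variants <- generate_variants(cfg, gen$genome, gen$genes)
  target <- gen$genes$gene_id[gen$genes$is_target]

  planted_pairs <- data.frame(rsid = character(), gene_id = character(),
                              stringsAsFactors = FALSE)
  if (cfg$n_planted_contacts > 0L && nrow(variants) > 0L && nrow(gen$genes) > 0L) {
    tg <- gen$genes[gen$genes$is_target, , drop = FALSE]
    tchrom <- tg$chrom
    # plant within the densely covered target locus so locus-scale analyses
    # see every planted link
    locus_vars <- variants$rsid[variants$chrom == tchrom &
                                  variants$pos - 1 >= tg$start - 10000L &
                                  variants$pos - 1 < tg$end + 10000L]
    if (!length(locus_vars)) locus_vars <- variants$rsid[variants$chrom == tchrom]
    with_seed(cfg$seed + 107L, {
      vs <- sample(locus_vars, min(cfg$n_planted_contacts, length(locus_vars)))
      cis_genes <- gen$genes$gene_id[gen$genes$chrom == tchrom]
      trans_genes <- gen$genes$gene_id[gen$genes$chrom != tchrom]
      gene_pool <- character(length(vs))
      for (i in seq_along(vs)) {
        # trans links are much rarer than cis in fragment-level contact
        # maps; plant 1 trans pair in 4
        pool <- if (i %% 4L != 0L || !length(trans_genes)) cis_genes else trans_genes
        gene_pool[i] <- sample(pool, 1L)
      }
      planted_pairs <- data.frame(rsid = vs, gene_id = gene_pool,
                                  stringsAsFactors = FALSE)
    })
    vi <- match(planted_pairs$rsid, variants$rsid)
    gi <- match(planted_pairs$gene_id, gen$genes$gene_id)
    planted_pairs$class <- classify_connection(
      variants$chrom[vi], variants$pos[vi],
      gen$genes$chrom[gi], gen$genes$start[gi], gen$genes$end[gi])
  }

  contacts <- generate_contacts(cfg, fragments, variants, gen$genes,
                                planted_pairs[, c("rsid", "gene_id"), drop = FALSE])
  planted_effects <- if (nrow(planted_pairs)) {
    data.frame(rsid = planted_pairs$rsid, gene_id = planted_pairs$gene_id,
               tissue = "all", beta = cfg$planted_eqtl_effect,
               stringsAsFactors = FALSE)
  } else {
    data.frame(rsid = character(), gene_id = character(), tissue = character(),
               beta = numeric(), stringsAsFactors = FALSE)
  }
  expr <- generate_expression(cfg, variants, gen$genes, planted_effects)
  cohort <- generate_cohort(cfg)
  class_of <- if (nrow(planted_pairs)) {
    stats::setNames(planted_pairs$class, planted_pairs$gene_id)
  } else {
    NULL
  }
  pli <- generate_pli(cfg, gen$genes, class_of = class_of)

  bundle <- list(cfg = cfg, genome = gen$genome, genes = gen$genes,
                 fragments = fragments, variants = variants,
                 planted_pairs = planted_pairs,
                 planted_effects = planted_effects,
                 contacts = contacts, genotypes = expr$genotypes,
                 expression = expr$expression, cohort = cohort, pli = pli,
                 target_gene = if (length(target)) target else NA_character_)
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' Serialize a synthetic bundle to the pipeline's file formats
#'
#' Writes FASTA (genome), BED (genes), tab-delimited variant, contact,
#' genotype, per-tissue expression, haplotype, individual and pLI tables,
#' and the configuration as YAML.
#'
#' @param bundle output of [simulate_bundle()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(bundle$genome, p("genome.fa"))
  write_genes_bed(bundle$genes, p("genes.bed"))
  tsv <- function(x, f) utils::write.table(x, p(f), sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  tsv(bundle$variants, "variants.tsv")
  utils::write.table(bundle$contacts, p("contacts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  gt <- data.frame(sample = rownames(bundle$genotypes), bundle$genotypes,
                   check.names = FALSE)
  tsv(gt, "genotypes.tsv")
  for (t in names(bundle$expression)) {
    e <- data.frame(sample = rownames(bundle$expression[[t]]),
                    bundle$expression[[t]], check.names = FALSE)
    tsv(e, sprintf("expression_%s.tsv", t))
  }
  tsv(bundle$cohort$haplotypes, "haplotypes.tsv")
  tsv(bundle$cohort$individuals, "individuals.tsv")
  tsv(bundle$pli, "pli.tsv")
  yaml::write_yaml(c(unclass(bundle$cfg),
                     list(target_gene = bundle$target_gene,
                          tag_sites = bundle$cohort$tag_sites)),
                   p("config.yaml"))
  invisible(dir)
}
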