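# The synthetic-data generator: determinism, planted structure, and the
# statistical properties downstream stages rely on.

test_that("config validation rejects out-of-range parameters", {
  expect_error(synthetic_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(synthetic_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(synthetic_config(n_tissues = 0), "positive")
  expect_error(synthetic_config(enzyme_name = "NotARealEnzyme"), "MboI")
  expect_error(synthetic_config(cluster_a_freq = 1.2), "cluster_a_freq")
})

test_that("identical configs give byte-identical serialized bundles", {
  cfg <- tiny_config(seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_bundle(cfg, dir = d1)
  simulate_bundle(cfg, dir = d2)
  files <- list.files(d1)
  expect_true(length(files) > 5)
  for (f in files) {
    expect_equal(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                 readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                 info = f)
  }
  # and the generators do not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_genome(cfg)); after <- runif(3)
  expect_equal(before, after)
})

test_that("generated genome hosts motifs at scan-verified positions and genes as requested", {
  cfg <- tiny_config(seed = 6)
  gen <- generate_genome(cfg)
  expect_equal(length(gen$genome), cfg$n_chromosomes)
  expect_equal(unname(Biostrings::width(gen$genome)),
               rep(cfg$chromosome_length_bp, cfg$n_chromosomes))
  # motif count equals an independent naive string scan
  for (i in seq_along(gen$genome)) {
    s <- as.character(gen$genome[[i]])
    naive <- gregexpr("GATC", s, fixed = TRUE)[[1]]
    n_naive <- if (naive[1] == -1) 0L else length(naive)
    expect_equal(length(Biostrings::matchPattern("GATC", gen$genome[[i]])),
                 n_naive)
    # uniform bases: GATC about every 256 bp
    expect_gt(n_naive, cfg$chromosome_length_bp / 256 * 0.6)
  }
  # genes: non-overlapping within chromosome, one target
  expect_equal(nrow(gen$genes), cfg$n_genes)
  expect_equal(sum(gen$genes$is_target), 1L)
  for (ch in unique(gen$genes$chrom)) {
    g <- gen$genes[gen$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # n_genes = 0: valid genome, empty gene set
  gen0 <- generate_genome(tiny_config(seed = 6, n_genes = 0L))
  expect_equal(nrow(gen0$genes), 0L)
  expect_equal(length(gen0$genome), cfg$n_chromosomes)
  # sizing error when the chromosome cannot host the genes
  expect_error(generate_genome(synthetic_config(
    seed = 1, n_chromosomes = 1, chromosome_length_bp = 10000L, n_genes = 10)),
    "too short")
})

test_that("variant table is consistent with the genome", {
  cfg <- tiny_config(seed = 8)
  gen <- generate_genome(cfg)
  v <- generate_variants(cfg, gen$genome, gen$genes)
  expect_false(any(duplicated(paste(v$chrom, v$pos))))
  expect_true(all(v$maf > 0 & v$maf <= 0.5))
  # ref alleles match the sequence at the stated 1-based positions
  for (i in sample(nrow(v), 10)) {
    expect_equal(v$ref[i], as.character(
      Biostrings::subseq(gen$genome[[v$chrom[i]]], v$pos[i], v$pos[i])))
    expect_false(v$alt[i] == v$ref[i])
  }
})

test_that("contacts cover every planted pair and carry configured source labels", {
  cfg <- tiny_config(seed = 9)
  b <- simulate_bundle(cfg)
  expect_gt(nrow(b$planted_pairs), 0L)
  resolved <- resolve_contacts(b$contacts, b$fragments)
  pairs <- spatial_pairs(b$variants, b$genes, resolved, b$fragments)
  expect_true(all(paste(b$planted_pairs$rsid, b$planted_pairs$gene_id) %in%
                    paste(pairs$rsid, pairs$gene_id)))
  expect_true(all(resolved$source %in% hic_source_labels()))
  custom <- generate_contacts(cfg, b$fragments, b$variants, b$genes,
                              b$planted_pairs[, c("rsid", "gene_id")],
                              sources = c("libX", "libY"))
  expect_true(all(custom$source %in% c("libX", "libY")))
  # zero planted pairs and zero decoys -> empty table
  cfg0 <- tiny_config(seed = 9, n_decoy_contacts = 0L)
  empty <- generate_contacts(cfg0, b$fragments, b$variants, b$genes,
                             b$planted_pairs[0, c("rsid", "gene_id")])
  expect_equal(nrow(empty), 0L)
  expect_error(generate_contacts(cfg, b$fragments, b$variants, b$genes,
                                 data.frame(rsid = "rs_nope", gene_id = "G01")),
               "unknown")
})

test_that("dosages follow Hardy-Weinberg at the configured MAF", {
  cfg <- synthetic_config(seed = 10, n_chromosomes = 1, n_genes = 2,
                          n_variants = 1, n_samples_per_tissue = 10000L,
                          n_tissues = 1)
  gen <- generate_genome(cfg)
  v <- generate_variants(cfg, gen$genome, gen$genes)[1, , drop = FALSE]
  v$maf <- 0.3
  ex <- generate_expression(cfg, v, gen$genes,
                            data.frame(rsid = character(), gene_id = character(),
                                       tissue = character(), beta = numeric()))
  freq <- as.numeric(table(factor(ex$genotypes[, 1], levels = 0:2))) / 10000
  expect_equal(freq, c(0.49, 0.42, 0.09), tolerance = 0.035)
})

test_that("planted beta is recovered by the closed-form OLS oracle; beta 0 gives null structure", {
  cfg <- synthetic_config(seed = 11, n_chromosomes = 1, n_genes = 5,
                          n_variants = 10, n_samples_per_tissue = 500L,
                          n_tissues = 1, noise_sd = 1.0)
  gen <- generate_genome(cfg)
  v <- generate_variants(cfg, gen$genome, gen$genes)
  eff <- data.frame(rsid = v$rsid[2], gene_id = gen$genes$gene_id[3],
                    tissue = "all", beta = 0.8)
  ex <- generate_expression(cfg, v, gen$genes, eff)
  x <- ex$genotypes[, v$rsid[2]]
  y <- ex$expression[[1]][, gen$genes$gene_id[3]]
  fit <- summary(lm(y ~ x))
  # planted beta (x noise_sd = 0.8 raw units) within 3 standard errors
  expect_lt(abs(coef(fit)[2, 1] - 0.8), 3 * coef(fit)[2, 2])

  # no planted effects: genotype-expression correlations center on zero
  ex0 <- generate_expression(cfg, v, gen$genes,
                             eff[0, , drop = FALSE])
  cors <- abs(cor(ex0$genotypes, ex0$expression[[1]]))
  expect_lt(mean(cors), 0.06)
  expect_error(generate_expression(
    synthetic_config(seed = 1, n_samples_per_tissue = 2), v, gen$genes,
    eff[0, , drop = FALSE]), ">= 3")
})

test_that("cohort generator plants the configured group structure", {
  cfg <- synthetic_config(seed = 12, cohort_size = 5000L)
  cohort <- generate_cohort(cfg)
  ind <- cohort$individuals
  # dosage groups approximate Hardy-Weinberg at cluster_a_freq
  p <- cfg$cluster_a_freq
  freq <- as.numeric(table(factor(ind$dosage_true, levels = 2:0))) / nrow(ind)
  expect_equal(freq, c(p^2, 2 * p * (1 - p), (1 - p)^2), tolerance = 0.03)
  # diagnosis lags onset by 1-3 years
  lag <- ind$diagnosis_age - ind$onset_age
  expect_true(all(lag >= 1 & lag <= 3))
  expect_gt(cor(ind$onset_age, ind$diagnosis_age), 0.95)
  # haplotype counts sum to 2N and tag alleles separate the clusters
  expect_equal(sum(cohort$haplotypes$count), 2L * nrow(ind))
  tags <- as.matrix(cohort$haplotypes[, cohort$tag_sites])
  expect_true(all(tags[cohort$haplotypes$cluster_true == "A", ] == 1))
  expect_true(all(tags[cohort$haplotypes$cluster_true == "B", ] == 0))
  expect_error(generate_cohort(synthetic_config(cohort_size = 5)), ">= 10")
})

test_that("null onset delay leaves no dosage effect; carrier count matches its expectation", {
  cfg0 <- synthetic_config(seed = 14, cohort_size = 4000L,
                           planted_onset_delay = 0)
  ind <- generate_cohort(cfg0)$individuals
  fit <- summary(lm(onset_age ~ dosage_true, data = ind))
  expect_gt(coef(fit)[2, 4], 0.01)  # no detectable effect at large n

  # default carrier fraction 0.092 on a 229-strong cohort: ~21 expected
  flagged <- vapply(1:30, function(s) {
    sum(generate_cohort(synthetic_config(seed = s))$individuals$carrier_flags != "")
  }, 0)
  expect_equal(mean(flagged), 229 * 0.092, tolerance = 0.1)
})

test_that("graded pLI generator is bimodal and respects class weighting", {
  cfg <- synthetic_config(seed = 15)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:400))
  class_of <- setNames(rep(c("trans_inter", NA), c(100, 300)), genes$gene_id)[1:100]
  pli <- generate_pli(cfg, genes, class_of = class_of)
  expect_true(all(pli$pli >= 0 & pli$pli <= 1))
  expect_gt(median(pli$pli[1:100]), median(pli$pli[101:400]))
  # bimodal: clear mass in both tails for the graded class mix
  expect_gt(mean(pli$pli < 0.3), 0.4)
  expect_gt(mean(pli$pli > 0.7), 0.15)
})
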