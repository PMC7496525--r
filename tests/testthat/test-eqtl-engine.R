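# Association testing, cis/trans classification, FDR and the scan.

test_that("test_association matches the lm oracle on a worked example", {
  dosage <- c(0, 1, 2, 0, 1, 2)
  expr <- c(1.0, 2.0, 2.9, 1.1, 2.1, 3.0)

  # raw scale: closed form vs stats::lm
  got <- test_association(dosage, expr, normalize = FALSE)
  fit <- summary(lm(expr ~ dosage))
  expect_equal(got$nes, unname(coef(fit)[2, 1]))
  expect_equal(got$se, unname(coef(fit)[2, 2]))
  expect_equal(got$p_value, unname(coef(fit)[2, 4]))
  expect_equal(got$n, 6L)
  expect_equal(got$status, "ok")

  # default path: OLS of rank-inverse-normal expression on dosage
  got_n <- test_association(dosage, expr)
  fit_n <- summary(lm(inverse_normal_transform(expr) ~ dosage))
  expect_equal(got_n$nes, unname(coef(fit_n)[2, 1]))
  expect_equal(got_n$p_value, unname(coef(fit_n)[2, 4]))
})

test_that("untestable inputs are signalled, not thrown", {
  expect_equal(test_association(c(0, 1, 2), c(5, 5, 5))$status, "untestable")
  expect_equal(test_association(c(1, 1, 1, 1), rnorm(4))$status, "untestable")
  expect_equal(test_association(c(0, 1), c(1, 2))$status, "untestable")  # n < 3
  # missing entries dropped pairwise
  got <- test_association(c(0, 1, 2, NA, 1), c(1, 2, 3, 4, NA),
                          normalize = FALSE)
  expect_equal(got$n, 3L)
})

test_that("jointly permuting samples leaves nes and p unchanged", {
  set.seed(31)
  dosage <- rbinom(50, 2, 0.4)
  expr <- rnorm(50) + 0.3 * dosage
  perm <- sample(50)
  a <- test_association(dosage, expr)
  b <- test_association(dosage[perm], expr[perm])
  expect_equal(a$nes, b$nes)
  expect_equal(a$p_value, b$p_value)
})

test_that("classify_connection partitions by distance and chromosome", {
  # gap 500 kb on the same chromosome -> cis
  expect_equal(classify_connection("chr1", 100, "chr1", 500099, 501000), "cis")
  expect_equal(classify_connection("chr1", 100, "chr2", 100, 200), "trans_inter")
  # gap exactly 1 Mb -> trans (strict < rule), 1 bp less -> cis
  expect_equal(classify_connection("chr1", 1, "chr1", 1e6, 1e6 + 100),
               "trans_intra")
  expect_equal(classify_connection("chr1", 2, "chr1", 1e6, 1e6 + 100), "cis")
  # variant inside the gene: distance 0
  expect_equal(classify_connection("chr1", 50, "chr1", 10, 100), "cis")
  # boundary enumeration around the strict-< rule
  for (gap in c(999999, 1000000, 1000001)) {
    cls <- classify_connection("chr5", 1, "chr5", gap + 0, gap + 50)
    expect_equal(cls, if (gap < 1e6) "cis" else "trans_intra")
  }
  # exactly one class each, symmetric in orientation
  set.seed(32)
  for (i in 1:50) {
    vchrom <- sample(c("chr1", "chr2"), 1)
    gchrom <- sample(c("chr1", "chr2"), 1)
    vpos <- sample.int(5e6, 1)
    gs <- sample.int(5e6, 1)
    cls <- classify_connection(vchrom, vpos, gchrom, gs, gs + 1000)
    expect_true(cls %in% c("cis", "trans_intra", "trans_inter"))
  }
})

test_that("confirm_spatial_eqtls applies BH to adjusted p over the whole family", {
  cfg <- tiny_config(seed = 33)
  b <- simulate_bundle(cfg)
  pairs <- unique(rbind(b$planted_pairs[, c("rsid", "gene_id")],
                        data.frame(rsid = b$variants$rsid[1:10],
                                   gene_id = rep(b$genes$gene_id[1:2], 5))))
  recs <- confirm_spatial_eqtls(pairs, b$genotypes, b$expression,
                                b$variants, b$genes, alpha = 0.05)
  ok <- recs$status == "ok"
  expect_equal(recs$p_adjusted[ok],
               p.adjust(recs$p_value[ok], method = "BH"))
  expect_true(all(recs$p_adjusted[ok] >= recs$p_value[ok]))
  expect_true(all(recs$p_adjusted[ok] <= 1))
  # BH monotone in raw-p rank
  ord <- order(recs$p_value[ok])
  expect_true(all(diff(recs$p_adjusted[ok][ord]) >= -1e-12))
  # significance flag keyed on adjusted p, not raw p
  expect_equal(recs$significant, !is.na(recs$p_adjusted) & recs$p_adjusted < 0.05)
  # every (pair x tissue) emitted
  expect_equal(nrow(recs), nrow(pairs) * length(b$expression))
})

test_that("pairs referencing absent genes or variants are skipped with a message", {
  cfg <- tiny_config(seed = 34)
  b <- simulate_bundle(cfg)
  pairs <- data.frame(rsid = c(b$variants$rsid[1], "rs_nope"),
                      gene_id = c(b$genes$gene_id[1], b$genes$gene_id[1]))
  expect_message(
    recs <- confirm_spatial_eqtls(pairs, b$genotypes, b$expression,
                                  b$variants, b$genes),
    "skipped")
  expect_equal(attr(recs, "n_skipped"), 1L)
  expect_equal(unique(recs$rsid), b$variants$rsid[1])
})

test_that("planting a positive beta yields a positive nes", {
  cfg <- synthetic_config(seed = 35, n_chromosomes = 1, n_genes = 4,
                          n_variants = 5, n_samples_per_tissue = 200,
                          n_tissues = 1)
  gen <- generate_genome(cfg)
  variants <- generate_variants(cfg, gen$genome, gen$genes)
  eff <- data.frame(rsid = variants$rsid[1], gene_id = gen$genes$gene_id[1],
                    tissue = "all", beta = 1.0)
  ex <- generate_expression(cfg, variants, gen$genes, eff)
  got <- test_association(ex$genotypes[, variants$rsid[1]],
                          ex$expression[[1]][, gen$genes$gene_id[1]])
  expect_gt(got$nes, 0)
  expect_lt(got$p_value, 1e-6)
  # and a planted negative beta flips the sign
  eff$beta <- -1.0
  ex2 <- generate_expression(cfg, variants, gen$genes, eff)
  expect_lt(test_association(ex2$genotypes[, variants$rsid[1]],
                             ex2$expression[[1]][, gen$genes$gene_id[1]])$nes, 0)
})

test_that("vectorized scan OLS agrees with the scalar path", {
  set.seed(36)
  X <- sapply(runif(20, 0.1, 0.5), function(p) rbinom(100, 2, p))
  y <- rnorm(100) + 0.4 * X[, 3]
  vec <- speqtl:::ols_columns(X, y)
  for (j in c(1, 3, 20)) {
    sc <- speqtl:::ols_scalar(X[, j], y)
    expect_equal(vec$nes[j], sc$nes)
    expect_equal(vec$p_value[j], sc$p_value)
  }
})

test_that("genome_wide_scan filters by MAF, applies the strict p threshold, clusters loci", {
  cfg <- synthetic_config(seed = 37, n_chromosomes = 3, n_genes = 9,
                          n_variants = 60, n_samples_per_tissue = 200,
                          n_tissues = 2, n_planted_contacts = 0)
  gen <- generate_genome(cfg)
  variants <- generate_variants(cfg, gen$genome, gen$genes)
  target <- gen$genes$gene_id[gen$genes$is_target]
  # a rare variant (MAF 0.04) with an enormous planted effect must be
  # excluded before testing
  variants$maf[variants$chrom == "chr2"][1] <- 0.04
  rare <- variants$rsid[variants$chrom == "chr2"][1]
  strong <- variants$rsid[variants$chrom == "chr3"][1]
  eff <- data.frame(rsid = c(rare, strong), gene_id = target,
                    tissue = "all", beta = 2.0)
  ex <- generate_expression(cfg, variants, gen$genes, eff)
  res <- genome_wide_scan(variants, ex$genotypes, ex$expression, gen$genes,
                          scan_config(target))
  expect_false(rare %in% res$hits$rsid)
  expect_true(strong %in% res$hits$rsid)
  expect_true(all(res$hits$p_value < 1e-6))
  expect_true(all(res$hits$connection_class != "cis" |
                    res$hits$chrom == gen$genes$chrom[gen$genes$is_target]))
  # hit variants fed back against all genes: coregulation table present
  expect_false(is.null(res$coregulation))
  expect_true(target %in% res$coregulation$gene_id)
  # empty variant set -> empty result
  res0 <- genome_wide_scan(variants[0, ], ex$genotypes, ex$expression,
                           gen$genes, scan_config(target))
  expect_equal(nrow(res0$hits), 0L)
  expect_equal(nrow(res0$loci), 0L)
})

test_that("locus clustering is single-linkage within the gap", {
  chrom <- c("chr1", "chr1", "chr1", "chr2")
  pos <- c(100, 900000, 2500000, 100)
  lid <- speqtl:::cluster_loci(chrom, pos, gap = 1e6)
  expect_equal(lid[1], lid[2])      # 900 kb apart: same locus
  expect_false(lid[2] == lid[3])    # 1.6 Mb apart: new locus
  expect_false(lid[4] %in% lid[1:3])  # other chromosome
})
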