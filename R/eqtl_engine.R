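# eQTL confirmation, cis/trans classification and genome-wide scanning.
#
# Each candidate SNP-gene pair is tested per tissue by ordinary least
# squares of rank-normalized expression on allele dosage (0/1/2); the slope
# is the normalized effect size (NES), the sign giving the direction of
# regulation by the alternate allele. Benjamini-Hochberg correction is
# applied across all tests in one invocation.

ols_scalar <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(unique(x)) < 2L || stats::var(y) == 0) {
    return(list(nes = NA_real_, se = NA_real_, p_value = NA_real_,
                n = n, status = "untestable"))
  }
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  beta <- sum(xc * yc) / sxx
  resid <- yc - beta * xc
  df <- n - 2L
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 / sxx)
  if (se == 0) {
    p <- if (beta == 0) 1 else 0
  } else {
    p <- 2 * stats::pt(-abs(beta / se), df)
  }
  list(nes = beta, se = se, p_value = p, n = n, status = "ok")
}

#' Test one SNP-gene association
#'
#' Ordinary least squares of (optionally rank-inverse-normal-transformed)
#' expression on allele dosage. Returns the slope (normalized effect size,
#' NES), its standard error, the two-sided t-test p-value and the number of
#' samples used. Missing entries are dropped pairwise. A monomorphic dosage
#' vector or zero expression variance is reported as `status =
#' "untestable"` rather than an error.
#'
#' @param dosage numeric vector of alternate-allele counts (0/1/2).
#' @param expression numeric expression vector, same length.
#' @param normalize apply [inverse_normal_transform()] to `expression`
#'   before regression (default `TRUE`).
#' @return list with `nes`, `se`, `p_value`, `n`, `status`.
#' @export
#' @examples
#' test_association(c(0, 1, 2, 0, 1, 2), c(1.0, 2.0, 2.9, 1.1, 2.1, 3.0))
test_association <- function(dosage, expression, normalize = TRUE) {
  stopifnot(length(dosage) == length(expression))
  ok <- !is.na(dosage) & !is.na(expression)
  x <- dosage[ok]
  y <- expression[ok]
  if (length(unique(y)) < 2L) {
    return(list(nes = NA_real_, se = NA_real_, p_value = NA_real_,
                n = length(x), status = "untestable"))
  }
  if (normalize) y <- inverse_normal_transform(y)
  ols_scalar(x, y)
}

# vectorized OLS of one response on each column of X (no NAs expected;
# monomorphic columns yield NA). Used by the genome-wide scan.
ols_columns <- function(X, y) {
  n <- length(y)
  yc <- y - mean(y)
  xm <- colMeans(X)
  sxx <- colSums(X^2) - n * xm^2
  sxy <- as.vector(crossprod(X, yc))
  beta <- sxy / sxx
  syy <- sum(yc^2)
  df <- n - 2L
  rss <- syy - beta * sxy
  rss[rss < 0] <- 0
  se <- sqrt((rss / df) / sxx)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se == 0 & beta == 0] <- 1
  p[se == 0 & beta != 0] <- 0
  bad <- !is.finite(sxx) | sxx <= 0
  beta[bad] <- NA_real_; se[bad] <- NA_real_; p[bad] <- NA_real_
  data.frame(nes = beta, se = se, p_value = p, n = n)
}

#' Classify a SNP-gene connection as cis or trans
#'
#' Distance is the minimum bp gap between the variant position and the gene
#' interval (0 if the variant lies inside the gene). A pair is `cis` when
#' on the same chromosome with distance < 1 Mb, `trans_intra` when on the
#' same chromosome at >= 1 Mb (the 1 Mb boundary itself is trans), and
#' `trans_inter` when on different chromosomes.
#'
#' @param variant_chrom,variant_pos variant chromosome and 1-based position.
#' @param gene_chrom,gene_start,gene_end gene chromosome and 0-based
#'   half-open interval.
#' @param cis_window cis distance threshold in bp (default 1e6).
#' @return character vector in `{cis, trans_intra, trans_inter}`.
#' @export
classify_connection <- function(variant_chrom, variant_pos,
                                gene_chrom, gene_start, gene_end,
                                cis_window = 1e6) {
  n <- max(length(variant_chrom), length(gene_chrom))
  variant_chrom <- rep_len(variant_chrom, n)
  variant_pos <- rep_len(variant_pos, n)
  gene_chrom <- rep_len(gene_chrom, n)
  gene_start <- rep_len(gene_start, n)
  gene_end <- rep_len(gene_end, n)
  p0 <- variant_pos - 1  # 0-based
  dist <- pmax(gene_start - p0, p0 - (gene_end - 1), 0)
  out <- ifelse(variant_chrom != gene_chrom, "trans_inter",
                ifelse(dist < cis_window, "cis", "trans_intra"))
  out
}

#' Confirm spatial SNP-gene pairs as tissue-specific eQTLs
#'
#' Tests every (pair x tissue) combination with [test_association()],
#' applies Benjamini-Hochberg correction across all testable results in
#' this invocation, and classifies each record as cis / trans_intra /
#' trans_inter from the variant and gene coordinates. All records are
#' returned, significant or not, with a `significant` flag
#' (`p_adjusted < alpha`). Pairs referencing a variant or gene absent from
#' the matrices are counted and skipped.
#'
#' @param pairs data frame with columns `rsid`, `gene_id` (e.g. from
#'   [spatial_pairs()]).
#' @param genotypes samples x variants dosage matrix, column names = rsids.
#' @param expression named list of samples x genes expression matrices,
#'   one per tissue.
#' @param variants variant table (`rsid`, `chrom`, `pos`) for
#'   classification.
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param alpha FDR threshold applied to the adjusted p-value
#'   (default 0.05).
#' @param normalize rank-normalize expression before regression.
#' @return data frame of eQTL records: `rsid`, `gene_id`, `tissue`, `nes`,
#'   `se`, `p_value`, `p_adjusted`, `n`, `connection_class`, `significant`;
#'   attribute `n_skipped` counts unresolvable pairs.
#' @export
confirm_spatial_eqtls <- function(pairs, genotypes, expression,
                                  variants, genes, alpha = 0.05,
                                  normalize = TRUE) {
  stopifnot(is.list(expression), length(expression) > 0L)
  tissues <- names(expression)
  resolvable <- pairs$rsid %in% colnames(genotypes) &
    vapply(pairs$gene_id, function(g)
      all(vapply(expression, function(m) g %in% colnames(m), TRUE)), TRUE)
  n_skipped <- sum(!resolvable)
  if (n_skipped > 0L) {
    message(n_skipped, " pair(s) skipped: variant or gene absent from matrices")
  }
  pairs <- pairs[resolvable, , drop = FALSE]
  recs <- vector("list", nrow(pairs) * length(tissues))
  k <- 0L
  vi <- match(pairs$rsid, variants$rsid)
  gi <- match(pairs$gene_id, genes$gene_id)
  cls <- classify_connection(variants$chrom[vi], variants$pos[vi],
                             genes$chrom[gi], genes$start[gi], genes$end[gi])
  for (i in seq_len(nrow(pairs))) {
    dos <- genotypes[, pairs$rsid[i]]
    for (t in tissues) {
      fit <- test_association(dos, expression[[t]][, pairs$gene_id[i]],
                              normalize = normalize)
      k <- k + 1L
      recs[[k]] <- data.frame(
        rsid = pairs$rsid[i], gene_id = pairs$gene_id[i], tissue = t,
        nes = fit$nes, se = fit$se, p_value = fit$p_value, n = fit$n,
        connection_class = cls[i], status = fit$status,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (k > 0L) do.call(rbind, recs[seq_len(k)]) else {
    data.frame(rsid = character(), gene_id = character(), tissue = character(),
               nes = numeric(), se = numeric(), p_value = numeric(),
               n = integer(), connection_class = character(),
               status = character(), stringsAsFactors = FALSE)
  }
  out$p_adjusted <- NA_real_
  testable <- out$status == "ok"
  out$p_adjusted[testable] <- stats::p.adjust(out$p_value[testable], method = "BH")
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Configuration for the genome-wide distal-regulator scan
#'
#' @param target_gene gene id whose expression is scanned against.
#' @param maf_min minimum minor allele frequency for a variant to be
#'   tested (default 0.05, i.e. common variants).
#' @param p_threshold raw p-value retention threshold (default 1e-6,
#'   exome-wide significance; no FDR at this stage).
#' @param tissues tissue names to scan, `NULL` = all available.
#' @param locus_gap_bp single-linkage gap for grouping hits into loci
#'   (default 1 Mb).
#' @return a `scan_config` list.
#' @export
scan_config <- function(target_gene, maf_min = 0.05, p_threshold = 1e-6,
                        tissues = NULL, locus_gap_bp = 1e6) {
  stopifnot(maf_min > 0, maf_min < 1, p_threshold > 0, p_threshold < 1)
  structure(list(target_gene = target_gene, maf_min = maf_min,
                 p_threshold = p_threshold, tissues = tissues,
                 locus_gap_bp = locus_gap_bp),
            class = "scan_config")
}

cluster_loci <- function(chrom, pos, gap = 1e6) {
  ord <- order(chrom, pos)
  ch <- chrom[ord]; ps <- pos[ord]
  new_locus <- c(TRUE, ch[-1] != ch[-length(ch)] | diff(ps) > gap)
  locus <- cumsum(new_locus)
  out <- integer(length(chrom))
  out[ord] <- locus
  out
}

#' Genome-wide scan for distal regulators of a target gene
#'
#' Tests every variant with MAF >= `maf_min` against the target gene's
#' rank-normalized expression in each requested tissue, retaining hits at
#' raw p < `p_threshold` (a fixed exome-wide threshold; no FDR here). Hits
#' are grouped into loci per tissue by single-linkage clustering within
#' `locus_gap_bp`, and hit variants are then fed back through
#' [confirm_spatial_eqtls()] against all genes to discover co-regulated
#' genes.
#'
#' @param variants variant table (`rsid`, `chrom`, `pos`, `maf`).
#' @param genotypes samples x variants dosage matrix.
#' @param expression named list of per-tissue expression matrices.
#' @param genes gene table; must contain `cfg$target_gene`.
#' @param cfg a [scan_config()].
#' @param normalize rank-normalize expression before regression.
#' @return list with `hits` (eQTL records for retained variants, classified
#'   against the target gene), `loci` (per-tissue locus summary), and
#'   `coregulation` (records of hit variants against all genes, BH-adjusted).
#' @export
genome_wide_scan <- function(variants, genotypes, expression, genes, cfg,
                             normalize = TRUE) {
  stopifnot(inherits(cfg, "scan_config"))
  gi <- match(cfg$target_gene, genes$gene_id)
  if (is.na(gi)) stop("target gene '", cfg$target_gene, "' not in gene table",
                      call. = FALSE)
  tissues <- cfg$tissues %||% names(expression)
  missing_t <- setdiff(tissues, names(expression))
  if (length(missing_t)) stop("tissue(s) not in expression set: ",
                              paste(missing_t, collapse = ", "), call. = FALSE)
  keep <- variants$maf >= cfg$maf_min & variants$rsid %in% colnames(genotypes)
  vars <- variants[keep, , drop = FALSE]
  empty_hits <- data.frame(rsid = character(), chrom = character(),
                           pos = numeric(), tissue = character(),
                           nes = numeric(), se = numeric(), p_value = numeric(),
                           n = integer(), connection_class = character(),
                           stringsAsFactors = FALSE)
  if (nrow(vars) == 0L) {
    return(list(hits = empty_hits,
                loci = data.frame(tissue = character(), locus = integer(),
                                  chrom = character(), start = numeric(),
                                  end = numeric(), n_snps = integer(),
                                  min_p = numeric()),
                coregulation = NULL))
  }
  X <- genotypes[, vars$rsid, drop = FALSE]
  hit_list <- list()
  for (t in tissues) {
    y <- expression[[t]][, cfg$target_gene]
    if (normalize) y <- inverse_normal_transform(y)
    if (anyNA(X) || anyNA(y)) {
      fits <- do.call(rbind, lapply(seq_len(ncol(X)), function(j) {
        f <- ols_scalar(X[, j], y)
        data.frame(nes = f$nes, se = f$se, p_value = f$p_value, n = f$n)
      }))
    } else {
      fits <- ols_columns(X, y)
    }
    sel <- !is.na(fits$p_value) & fits$p_value < cfg$p_threshold
    if (any(sel)) {
      hit_list[[t]] <- data.frame(
        rsid = vars$rsid[sel], chrom = vars$chrom[sel], pos = vars$pos[sel],
        tissue = t, nes = fits$nes[sel], se = fits$se[sel],
        p_value = fits$p_value[sel], n = fits$n[sel],
        connection_class = classify_connection(
          vars$chrom[sel], vars$pos[sel],
          genes$chrom[gi], genes$start[gi], genes$end[gi]),
        stringsAsFactors = FALSE
      )
    }
  }
  hits <- if (length(hit_list)) do.call(rbind, hit_list) else empty_hits
  rownames(hits) <- NULL
  loci <- if (nrow(hits)) {
    pieces <- lapply(split(hits, hits$tissue), function(d) {
      lid <- cluster_loci(d$chrom, d$pos, gap = cfg$locus_gap_bp)
      agg <- lapply(split(seq_len(nrow(d)), lid), function(idx) {
        data.frame(tissue = d$tissue[idx[1]], chrom = d$chrom[idx[1]],
                   start = min(d$pos[idx]), end = max(d$pos[idx]),
                   n_snps = length(unique(d$rsid[idx])),
                   min_p = min(d$p_value[idx]), stringsAsFactors = FALSE)
      })
      do.call(rbind, agg)
    })
    out <- do.call(rbind, pieces)
    out <- out[order(out$tissue, out$chrom, out$start), , drop = FALSE]
    out$locus <- seq_len(nrow(out))
    rownames(out) <- NULL
    out[, c("locus", "tissue", "chrom", "start", "end", "n_snps", "min_p")]
  } else {
    data.frame(locus = integer(), tissue = character(), chrom = character(),
               start = numeric(), end = numeric(), n_snps = integer(),
               min_p = numeric())
  }
  coreg <- NULL
  if (nrow(hits)) {
    hit_rsids <- unique(hits$rsid)
    all_pairs <- expand.grid(rsid = hit_rsids, gene_id = genes$gene_id,
                             stringsAsFactors = FALSE)
    coreg <- confirm_spatial_eqtls(all_pairs, genotypes, expression,
                                   variants, genes, normalize = normalize)
  }
  list(hits = hits, loci = loci, coregulation = coreg)
}
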