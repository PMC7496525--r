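# Independent brute-force oracles used to check the fast implementations.

# naive digestion: scan for motif occurrences with gregexpr on the raw
# string and rebuild fragments from first principles
naive_digest <- function(seq_str, motif, cut_offset, chrom = "chr") {
  hits <- gregexpr(motif, toupper(seq_str), fixed = TRUE)[[1]]
  starts0 <- if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
  len <- nchar(seq_str)
  cuts <- sort(unique(starts0 + cut_offset))
  cuts <- cuts[cuts > 0 & cuts < len]
  bounds <- c(0L, cuts, len)
  data.frame(chrom = chrom, start = bounds[-length(bounds)], end = bounds[-1L],
             fragment_id = seq_len(length(bounds) - 1L),
             stringsAsFactors = FALSE)
}

# linear-scan fragment lookup (oracle for locate's binary search)
naive_locate <- function(fragments, chrom, pos) {
  p0 <- pos - 1
  hit <- which(fragments$chrom == chrom & fragments$start <= p0 &
                 p0 < fragments$end)
  fragments[hit, , drop = FALSE]
}

# nested-loop spatial-pair oracle: enumerates every variant x gene
# combination, checks every contact in both orientations (vectorized over
# the contact rows), and decides gene-fragment overlap by a linear scan
# over every fragment — no index structures shared with the implementation
brute_spatial_pairs <- function(variants, genes, contacts, fragments) {
  fkey <- paste0(fragments$chrom, ":", fragments$fragment_id)
  out <- character(0)
  for (vi in seq_len(nrow(variants))) {
    vf <- naive_locate(fragments, variants$chrom[vi], variants$pos[vi])
    vkey <- paste0(vf$chrom, ":", vf$fragment_id)
    for (gi in seq_len(nrow(genes))) {
      ov <- fragments$chrom == genes$chrom[gi] &
        fragments$start < genes$end[gi] & genes$start[gi] < fragments$end
      gkeys <- fkey[ov]
      found <- any(
        (contacts$key_a == vkey & contacts$key_b != vkey &
           contacts$key_b %in% gkeys) |
        (contacts$key_b == vkey & contacts$key_a != vkey &
           contacts$key_a %in% gkeys))
      if (found) out <- c(out, paste(variants$rsid[vi], genes$gene_id[gi]))
    }
  }
  sort(out)
}

# exhaustive Ward oracle for small n: enumerate all 2-partitions and pick
# the one minimizing total within-cluster sum of squares (Ward objective)
ward_two_cluster_oracle <- function(m) {
  n <- nrow(m)
  best <- NULL
  best_wss <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n - 1)]
    grp <- c(1L, bits + 1L)  # point 1 fixed in cluster 1
    if (!any(grp == 2L)) next
    wss <- 0
    for (g in 1:2) {
      pts <- m[grp == g, , drop = FALSE]
      ctr <- colMeans(pts)
      wss <- wss + sum(sweep(pts, 2, ctr)^2)
    }
    if (wss < best_wss) { best_wss <- wss; best <- grp }
  }
  best
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# tiny config for fast module tests
tiny_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_chromosomes = 2L,
                   chromosome_length_bp = 60000L, n_genes = 6L,
                   n_variants = 40L, n_planted_contacts = 4L,
                   n_decoy_contacts = 40L, n_tissues = 2L,
                   n_samples_per_tissue = 60L, cohort_size = 120L)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

random_fragment_index <- function(seqlen = 50000L, chroms = c("chrA", "chrB")) {
  seqs <- vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), seqlen, replace = TRUE), collapse = ""), "")
  digest(seqs, "MboI")
}
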