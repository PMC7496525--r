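# Fragment-fragment contact tables and SNP-gene spatial pairing.
#
# A Hi-C contact is an unordered pair of restriction fragments observed in
# physical proximity, labelled with the cell line or tissue of the library.
# A variant-gene pair is "spatial" when some contact links the variant's
# fragment to a distal fragment overlapping the gene.

#' Resolve interval-pair contact rows to fragments
#'
#' Contact rows give two genomic intervals plus a source label. Each
#' interval is resolved to a fragment: an exact boundary match is preferred;
#' otherwise the fragment containing the interval midpoint is used (robust
#' to off-by-one dialects in published contact dumps). Rows with an unknown
#' chromosome or out-of-range coordinates are skipped and counted.
#'
#' @param contacts data frame with columns `chrom_a, start_a, end_a,
#'   chrom_b, start_b, end_b, source` (starts 0-based, ends exclusive).
#' @param fragments fragment index from [digest()].
#' @return data frame with columns `key_a`, `key_b` (fragment keys
#'   `chrom:ordinal`), `chrom_a`, `chrom_b`, `source`; attribute
#'   `n_unresolved` counts skipped rows.
#' @export
resolve_contacts <- function(contacts, fragments) {
  required <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b", "source")
  if (!all(required %in% names(contacts))) {
    stop("contact table must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(contacts) == 0L) {
    out <- data.frame(key_a = character(), key_b = character(),
                      chrom_a = character(), chrom_b = character(),
                      source = character(), stringsAsFactors = FALSE)
    attr(out, "n_unresolved") <- 0L
    return(out)
  }
  exact <- stats::setNames(
    fragment_key(fragments$chrom, fragments$fragment_id),
    paste(fragments$chrom, fragments$start, fragments$end)
  )
  seqlens <- attr(fragments, "seqlengths")
  resolve_side <- function(chrom, start, end) {
    key <- rep(NA_character_, length(chrom))
    hit <- exact[paste(chrom, start, end)]
    key[!is.na(hit)] <- hit[!is.na(hit)]
    todo <- which(is.na(key))
    if (length(todo)) {
      mid <- floor((start[todo] + end[todo]) / 2)  # 0-based midpoint
      ok <- chrom[todo] %in% names(seqlens) &
        !is.na(mid) & mid >= 0 & mid < seqlens[chrom[todo]] &
        start[todo] < end[todo]
      ok[is.na(ok)] <- FALSE
      if (any(ok)) {
        loc <- locate(fragments, chrom[todo][ok], mid[ok] + 1)
        key[todo[ok]] <- fragment_key(loc$chrom, loc$fragment_id)
      }
    }
    key
  }
  key_a <- resolve_side(contacts$chrom_a, contacts$start_a, contacts$end_a)
  key_b <- resolve_side(contacts$chrom_b, contacts$start_b, contacts$end_b)
  keep <- !is.na(key_a) & !is.na(key_b)
  n_bad <- sum(!keep)
  if (n_bad > 0L && n_bad > nrow(contacts) / 2) {
    stop(n_bad, " of ", nrow(contacts),
         " contact rows unresolvable (>50%); wrong fragment index or coordinate dialect?",
         call. = FALSE)
  }
  if (n_bad > 0L) {
    message(n_bad, " contact row(s) skipped (unresolvable to fragments)")
  }
  out <- data.frame(
    key_a = key_a[keep], key_b = key_b[keep],
    chrom_a = contacts$chrom_a[keep], chrom_b = contacts$chrom_b[keep],
    source = as.character(contacts$source[keep]),
    stringsAsFactors = FALSE
  )
  attr(out, "n_unresolved") <- n_bad
  out
}

#' Load a contact table from disk and resolve it against a fragment index
#'
#' Reads a tab-delimited 7-column file (`chrom_a start_a end_a chrom_b
#' start_b end_b source`, with or without a header row). Malformed rows
#' (non-numeric coordinates) are skipped with a logged count.
#'
#' @param path file path.
#' @param fragments fragment index from [digest()].
#' @return resolved contact set; see [resolve_contacts()].
#' @export
load_contacts <- function(path, fragments) {
  if (!file.exists(path)) stop("contact file not found: ", path, call. = FALSE)
  empty <- data.frame(chrom_a = character(), start_a = integer(),
                      end_a = integer(), chrom_b = character(),
                      start_b = integer(), end_b = integer(),
                      source = character(), stringsAsFactors = FALSE)
  if (length(readLines(path, n = 1L)) == 0L) {
    return(resolve_contacts(empty, fragments))
  }
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (nrow(raw) == 0L || ncol(raw) < 7L) {
    if (nrow(raw) > 0L) stop("contact file must have 7 columns", call. = FALSE)
    return(resolve_contacts(
      data.frame(chrom_a = character(), start_a = integer(), end_a = integer(),
                 chrom_b = character(), start_b = integer(), end_b = integer(),
                 source = character()), fragments))
  }
  names(raw)[1:7] <- c("chrom_a", "start_a", "end_a",
                       "chrom_b", "start_b", "end_b", "source")
  # drop a header row if present
  if (suppressWarnings(is.na(as.numeric(raw$start_a[1])))) raw <- raw[-1L, , drop = FALSE]
  for (col in c("start_a", "end_a", "start_b", "end_b")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  malformed <- is.na(raw$start_a) | is.na(raw$end_a) | is.na(raw$start_b) | is.na(raw$end_b)
  if (any(malformed)) {
    message(sum(malformed), " malformed contact row(s) skipped")
    raw <- raw[!malformed, , drop = FALSE]
  }
  resolve_contacts(raw[, 1:7], fragments)
}

genes_as_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    gene_id = genes$gene_id
  )
}

#' Derive SNP-gene spatial pairs from chromatin contacts
#'
#' Emits a pair `(variant, gene)` whenever some contact links the variant's
#' restriction fragment to a *distal* fragment (a fragment other than the
#' variant's own) that overlaps the gene's annotated interval. Overlap is
#' any overlap of at least 1 bp, strand-agnostic, with no binning or
#' padding; `containment = "full"` instead requires the gene to lie
#' entirely within the distal fragment. Contacts are unordered, so both
#' orientations of every row are considered. Source labels of all
#' supporting contacts are aggregated per pair.
#'
#' @param variants data frame with columns `rsid`, `chrom`, `pos` (1-based).
#' @param genes data frame with columns `gene_id`, `chrom`, `start`
#'   (0-based), `end`, optionally `strand` (carried, ignored for overlap).
#' @param contacts resolved contact set from [resolve_contacts()] /
#'   [load_contacts()].
#' @param fragments fragment index from [digest()].
#' @param containment `"any"` (default) or `"full"`.
#' @return data frame with columns `rsid`, `gene_id`, `snp_fragment`,
#'   `gene_fragments` (comma-separated keys), `n_sources`, `sources`
#'   (comma-separated, sorted, unique).
#' @export
spatial_pairs <- function(variants, genes, contacts, fragments,
                          containment = c("any", "full")) {
  containment <- match.arg(containment)
  empty <- data.frame(rsid = character(), gene_id = character(),
                      snp_fragment = character(), gene_fragments = character(),
                      n_sources = integer(), sources = character(),
                      stringsAsFactors = FALSE)
  if (nrow(variants) == 0L || nrow(genes) == 0L || nrow(contacts) == 0L) {
    return(empty)
  }
  loc <- locate(fragments, variants$chrom, variants$pos)
  snp_key <- fragment_key(loc$chrom, loc$fragment_id)

  frag_gr <- fragments_as_granges(fragments)
  gene_gr <- genes_as_granges(genes)
  ov <- GenomicRanges::findOverlaps(
    gene_gr, frag_gr,
    type = if (containment == "full") "within" else "any"
  )
  # fragment key -> gene ids overlapping it
  frag2gene <- split(
    genes$gene_id[S4Vectors::queryHits(ov)],
    frag_gr$key[S4Vectors::subjectHits(ov)]
  )

  # both orientations: (snp side, distal side)
  snp_side <- c(contacts$key_a, contacts$key_b)
  distal_side <- c(contacts$key_b, contacts$key_a)
  src <- rep(contacts$source, 2L)

  hit <- snp_side %in% snp_key & distal_side %in% names(frag2gene)
  if (!any(hit)) return(empty)
  snp_side <- snp_side[hit]; distal_side <- distal_side[hit]; src <- src[hit]

  rows <- vector("list", length(snp_side))
  for (i in seq_along(snp_side)) {
    vs <- which(snp_key == snp_side[i])
    gs <- frag2gene[[distal_side[i]]]
    grid <- expand.grid(v = vs, g = gs, stringsAsFactors = FALSE)
    rows[[i]] <- data.frame(
      rsid = variants$rsid[grid$v],
      gene_id = grid$g,
      snp_fragment = snp_side[i],
      gene_fragment = distal_side[i],
      source = src[i],
      stringsAsFactors = FALSE
    )
  }
  long <- do.call(rbind, rows)
  # a distal fragment must differ from the SNP's own fragment
  long <- long[long$gene_fragment != long$snp_fragment, , drop = FALSE]
  if (nrow(long) == 0L) return(empty)

  key <- paste(long$rsid, long$gene_id, sep = "\r")
  agg <- lapply(split(long, key), function(d) {
    data.frame(
      rsid = d$rsid[1L], gene_id = d$gene_id[1L],
      snp_fragment = d$snp_fragment[1L],
      gene_fragments = paste(sort(unique(d$gene_fragment)), collapse = ","),
      n_sources = length(unique(d$source)),
      sources = paste(sort(unique(d$source)), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$rsid, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
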