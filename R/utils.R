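#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, then
#' restores the caller's RNG state, so generator functions are reproducible
#' without clobbering the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank-based inverse-normal transform
#'
#' Maps a numeric vector to normal scores `qnorm((rank - 0.5) / n)` using
#' average ranks for ties; `NA`s are preserved in place. This is the
#' per-gene, per-tissue normalization applied to expression before eQTL
#' regression (standard practice in large expression atlases).
#'
#' @param x numeric vector.
#' @return numeric vector of normal scores, same length as `x`.
#' @export
#' @examples
#' inverse_normal_transform(c(3, 1, 2))
inverse_normal_transform <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  out <- rep(NA_real_, length(x))
  if (n > 0) {
    out[ok] <- stats::qnorm((rank(x[ok], ties.method = "average") - 0.5) / n)
  }
  out
}

# short stable hash of an R object (provenance headers); md5 of its
# deparsed form so it does not depend on serialization version
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(x), tf)
  unname(tools::md5sum(tf))
}

#' Write a table with a provenance header
#'
#' Writes a tab-delimited file preceded by `#`-prefixed header lines
#' recording the package version and a hash of the generating
#' configuration, so outputs are traceable to the run that produced them.
#'
#' @param x data frame.
#' @param path output path.
#' @param config optional configuration object to hash into the header.
#' @return `path`, invisibly.
#' @export
write_output_table <- function(x, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# speqtl %s", as.character(utils::packageVersion("speqtl"))), con)
  if (!is.null(config)) {
    if (is.list(config)) config$out_dir <- NULL  # identity of the analysis, not of the run
    writeLines(sprintf("# config_hash: %s", config_hash(config)), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_output_table()]
#' @param path file path.
#' @return data frame (comment lines dropped).
#' @export
read_output_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
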