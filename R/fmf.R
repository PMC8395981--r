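#' Normalize raw match counts to FMF
#'
#' Converts the raw pairwise match-event counts into frequencies of matching
#' fragments (FMF) with the per-10-kb convention: each raw count is first
#' divided by the product of the two section sizes expressed in chunk units
#' (`w(X) = len(X) / chunk_size`, real-valued), giving a match density per
#' 10 kb x 10 kb of sequence; densities are then rescaled by one global
#' constant so that the mean over all unordered off-diagonal section pairs
#' equals 1. The global constant does not affect rank-based statistics
#' downstream. If no pair has any match, all FMF values are 0 and the
#' `all_zero` flag is set.
#'
#' @param raw A `pair_match_table` from [build_match_tables()].
#' @param ss Optional extracted `section_set` supplying section lengths
#'   (defaults to the lengths recorded in `raw`).
#' @param chunk_size Chunk size in nt (default 10000).
#' @return An `fmf_matrix`: list with `values` (symmetric N x N, zero
#'   diagonal), `L`, `chunk_size`, `normalization_constant` (the mean
#'   density divided out; `NA` when all-zero) and `all_zero`.
#' @export
normalize_fmf <- function(raw, ss = NULL, chunk_size = 10000) {
  stopifnot(inherits(raw, "pair_match_table"), chunk_size > 0)
  lens <- if (is.null(ss)) raw$section_lengths else ss$end - ss$start
  if (any(lens <= 0)) stop("zero-length section")
  w <- lens / chunk_size
  d <- raw$counts / outer(w, w)
  diag(d) <- 0
  up <- upper.tri(d)
  mu <- mean(d[up])
  if (all(raw$counts == 0)) {
    values <- raw$counts * 0
    mu <- NA_real_
    all_zero <- TRUE
  } else {
    values <- d / mu
    all_zero <- FALSE
  }
  structure(list(values = values, sections = raw$sections, L = raw$L,
                 chunk_size = chunk_size, normalization_constant = mu,
                 all_zero = all_zero),
            class = "fmf_matrix")
}

#' Per-section FMF totals
#'
#' `FMF_TOT(A)` is the sum of FMF values between section A and every other
#' section.
#'
#' @param m An `fmf_matrix`.
#' @return Named numeric vector over sections.
#' @export
fmf_tot <- function(m) {
  stopifnot(inherits(m, "fmf_matrix"))
  rowSums(m$values)
}

#' @export
print.fmf_matrix <- function(x, ...) {
  cat(sprintf("<fmf_matrix> %d sections, L = %d, chunk = %g nt%s\n",
              length(x$sections), x$L, x$chunk_size,
              if (x$all_zero) " [all zero]" else ""))
  if (!x$all_zero)
    cat(sprintf("  off-diagonal mean = %.9f (normalization constant %.6g)\n",
                mean(x$values[upper.tri(x$values)]), x$normalization_constant))
  invisible(x)
}

#' Write an FMF matrix as labeled TSV
#'
#' @param m An `fmf_matrix`.
#' @param path Output path. Full symmetric matrix with a label header row
#'   and column, `%.6g` values.
#' @export
write_fmf <- function(m, path) {
  stopifnot(inherits(m, "fmf_matrix"))
  v <- matrix(sprintf("%.6g", m$values), nrow(m$values),
              dimnames = dimnames(m$values))
  utils::write.table(v, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
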