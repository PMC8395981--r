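#' Construct an FEC matrix
#'
#' Frequencies of ectopic contacts: a symmetric matrix of non-negative
#' integer contact counts per section pair, as scored from squashed
#' polytene-chromosome preparations. Self-contacts are undefined; diagonal
#' entries are forced to zero.
#'
#' @param counts Symmetric integer matrix with section labels as dimnames.
#' @param strain Text tag for the fly strain the counts come from.
#' @return A `fec_matrix` object.
#' @export
fec_matrix <- function(counts, strain = "unknown") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("FEC matrix needs section labels as dimnames")
  if (!identical(rownames(counts), colnames(counts)))
    stop("FEC row and column labels differ")
  if (any(counts < 0)) stop("negative FEC count")
  if (any(counts != round(counts))) stop("non-integer FEC count")
  asym <- which(counts != t(counts), arr.ind = TRUE)
  if (nrow(asym))
    stop("asymmetric FEC cells: ",
         paste(sprintf("(%s,%s)", rownames(counts)[asym[, 1]],
                       colnames(counts)[asym[, 2]]), collapse = ", "))
  if (any(diag(counts) != 0)) {
    warning("non-zero diagonal FEC entries ignored (forced to 0)")
    diag(counts) <- 0
  }
  structure(list(counts = counts, sections = rownames(counts), strain = strain),
            class = "fec_matrix")
}

#' Read an FEC matrix from labeled TSV
#'
#' Expects a full symmetric matrix with section labels as both header row
#' and first column. Symmetry must be exact; asymmetric cells raise an error
#' naming the offenders. When a `section_set` is supplied the labels are
#' validated against it: any mismatch is an error unless `subset = TRUE`,
#' which intersects the two label sets explicitly.
#'
#' @param path Path to the TSV.
#' @param strain Strain tag to attach.
#' @param sections Optional `section_set` (or character vector of labels)
#'   to validate against.
#' @param subset Logical; allow intersecting with `sections` instead of
#'   erroring on label mismatch.
#' @return A `fec_matrix`.
#' @export
read_fec <- function(path, strain = "unknown", sections = NULL, subset = FALSE) {
  if (!file.exists(path)) stop("FEC file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cell in FEC matrix")
  if (!is.null(sections)) {
    labs <- if (inherits(sections, "section_set")) sections$label else sections
    extra <- setdiff(rownames(m), labs)
    missing <- setdiff(labs, rownames(m))
    if (length(extra) || length(missing)) {
      if (!subset)
        stop("FEC labels do not match the section set",
             if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")),
             if (length(missing)) paste0("; absent: ", paste(missing, collapse = ", ")))
      keep <- intersect(labs, rownames(m))
      if (length(keep) < 2L) stop("fewer than 2 sections after subsetting")
      m <- m[keep, keep, drop = FALSE]
    } else {
      m <- m[labs, labs, drop = FALSE]
    }
  }
  fec_matrix(m, strain = strain)
}

#' Write an FEC matrix as labeled TSV
#'
#' Inverse of [read_fec()]; integer counts round-trip exactly.
#'
#' @param m A `fec_matrix`.
#' @param path Output path.
#' @export
write_fec <- function(m, path) {
  stopifnot(inherits(m, "fec_matrix"))
  utils::write.table(m$counts, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Per-section FEC totals
#'
#' Number of ectopic contacts between a given section and all others
#' (row sums excluding the diagonal, which is zero by construction).
#'
#' @param m A `fec_matrix`.
#' @return Named numeric vector.
#' @export
fec_tot <- function(m) {
  stopifnot(inherits(m, "fec_matrix"))
  rowSums(m$counts)
}

#' Binarize an FEC matrix
#'
#' Replaces exact contact counts with presence (1) / absence (0) indicators.
#' Idempotent.
#'
#' @param m A `fec_matrix`.
#' @return A `fec_matrix` with entries in `{0, 1}`.
#' @export
binarize <- function(m) {
  stopifnot(inherits(m, "fec_matrix"))
  fec_matrix((m$counts > 0) * 1L, strain = m$strain)
}

#' Chromatin feature index per section
#'
#' Given binary indicators for chromatin features predisposing sections to
#' ectopic pairing (by convention five features: hybridization sites of
#' mobile-element probes, ectopic conjugation, weak points, late replication,
#' giant palindromes), computes per section the feature sum `F_SUM` and the
#' index `Ind = F_SUM / 10`.
#'
#' @param table Data.frame with a `label` column and one 0/1 column per
#'   feature.
#' @return The input with `F_SUM` and `Ind` columns appended, classed
#'   `feature_table`.
#' @export
feature_index <- function(table) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  feats <- setdiff(names(table), c("label", "F_SUM", "Ind"))
  if (length(feats) == 0L) stop("no feature columns")
  fm <- as.matrix(table[feats])
  if (!all(fm %in% c(0, 1))) stop("feature indicators must be 0 or 1")
  table$F_SUM <- as.integer(rowSums(fm))
  table$Ind <- table$F_SUM / 10
  class(table) <- c("feature_table", "data.frame")
  table
}

#' @export
print.fec_matrix <- function(x, ...) {
  cat(sprintf("<fec_matrix> strain %s: %d sections, %g contacts total\n",
              x$strain, length(x$sections), sum(x$counts) / 2))
  invisible(x)
}
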