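#' Read a chromosome sequence from a FASTA file
#'
#' Reads one record from a FASTA file and normalizes it for fragment matching:
#' the sequence is lowercased and any base outside `{a,c,g,t,n}` (ambiguity
#' codes such as `r`, `y`, `s`) is mapped to `n` with a warning. Fragments
#' containing `n` are never enumerated downstream, so ambiguous positions
#' simply create small gaps in the fragment sampling.
#'
#' @param path Path to a FASTA file.
#' @param record Which record to use when the file holds several: a 1-based
#'   index or a record name. Defaults to the first record.
#' @return An object of class `chromosome_seq`: a list with elements `name`
#'   (record identifier) and `sequence` (lowercase DNA string over
#'   `{a,c,g,t,n}`).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">toy", "ACGTACGT"), fa)
#' chrom <- read_fasta(fa)
#' nchar(chrom$sequence)
#' @export
read_fasta <- function(path, record = 1L) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("cannot parse FASTA '", path, "': ",
                                            conditionMessage(e)))
  if (length(recs) == 0L) stop("no sequence records in FASTA file: ", path)
  if (is.character(record)) {
    i <- match(record, sub("\\s.*$", "", names(recs)))
    if (is.na(i)) stop("record '", record, "' not found in ", path)
  } else {
    i <- as.integer(record)
    if (i < 1L || i > length(recs)) stop("record index out of range: ", record)
  }
  seq <- tolower(as.character(recs[[i]]))
  if (nchar(seq) == 0L) stop("empty sequence record in FASTA file: ", path)
  bad <- gsub("[acgtn]", "", seq)
  if (nchar(bad) > 0L) {
    warning(sprintf("%d non-acgtn base(s) mapped to 'n' (codes: %s)",
                    nchar(bad), paste(unique(strsplit(bad, "")[[1]]), collapse = "")))
    seq <- gsub("[^acgtn]", "n", seq)
  }
  chromosome_seq(sub("\\s.*$", "", names(recs)[i]), seq)
}

#' Construct a chromosome sequence object
#'
#' @param name Text identifier.
#' @param sequence Lowercase DNA string over `{a,c,g,t,n}`.
#' @return A `chromosome_seq` object.
#' @export
chromosome_seq <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("chromosome sequence must be non-empty")
  if (grepl("[^acgtn]", sequence))
    stop("chromosome sequence restricted to {a,c,g,t,n} after normalization")
  structure(list(name = name, sequence = sequence), class = "chromosome_seq")
}

#' @export
print.chromosome_seq <- function(x, ...) {
  cat(sprintf("<chromosome_seq> %s: %s nt\n", x$name,
              format(nchar(x$sequence), big.mark = ",")))
  invisible(x)
}

#' Construct a section set
#'
#' A section set is the ordered list of cytological sections of one
#' chromosome: labels with 0-based half-open genomic intervals, optionally
#' carrying extracted sequences. Sections are sorted by start and must not
#' overlap.
#'
#' @param label Character vector of unique section labels (e.g. `"11A"`).
#' @param start,end Integer vectors; 0-based inclusive start, exclusive end.
#' @param sequence Optional character vector of section sequences.
#' @return A `section_set`: a data.frame with columns `label`, `start`,
#'   `end` and `sequence` (NA until [extract_sections()] fills it).
#' @export
section_set <- function(label, start, end, sequence = NULL) {
  label <- as.character(label)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(label) < 2L) stop("a section_set needs at least 2 sections")
  if (anyNA(start) || anyNA(end)) stop("non-integer section coordinates")
  if (any(start < 0L)) stop("negative section start")
  bad <- which(start >= end)
  if (length(bad))
    stop("inverted/empty interval for section(s): ", paste(label[bad], collapse = ", "))
  if (anyDuplicated(label))
    stop("duplicate section labels: ",
         paste(unique(label[duplicated(label)]), collapse = ", "))
  if (is.null(sequence)) sequence <- rep(NA_character_, length(label))
  o <- order(start)
  df <- data.frame(label = label[o], start = start[o], end = end[o],
                   sequence = sequence[o], stringsAsFactors = FALSE)
  ov <- which(df$start[-1] < df$end[-nrow(df)])
  if (length(ov))
    stop("overlapping sections: ",
         paste(sprintf("%s/%s", df$label[ov], df$label[ov + 1L]), collapse = ", "))
  class(df) <- c("section_set", "data.frame")
  df
}

#' Read a section-border table
#'
#' The native format is a header-bearing TSV with columns
#' `label`, `start`, `end` (0-based half-open, BED-style arithmetic).
#' With `bed = TRUE` a headerless BED3+name file
#' (`chrom`, `start`, `end`, `name`) is accepted instead; the `chrom`
#' column is ignored (one chromosome per run).
#'
#' @param path Path to the table.
#' @param bed Logical; read BED3+name instead of the native TSV.
#' @return A `section_set` without sequences, sorted by start and validated
#'   for overlaps.
#' @export
read_section_table <- function(path, bed = FALSE) {
  if (!file.exists(path)) stop("section table not found: ", path)
  if (bed) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4L) stop("BED section table needs 4 columns (chrom,start,end,name)")
    df <- data.frame(label = as.character(df[[4]]), start = df[[2]], end = df[[3]])
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("label", "start", "end")
    if (!all(need %in% names(df)))
      stop("section table must have header columns: label, start, end")
  }
  section_set(df$label, df$start, df$end)
}

#' Write a section table
#'
#' Inverse of [read_section_table()]; coordinates round-trip exactly.
#'
#' @param ss A `section_set`.
#' @param path Output path.
#' @export
write_section_table <- function(ss, path) {
  stopifnot(inherits(ss, "section_set"))
  utils::write.table(ss[, c("label", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract section sequences from a chromosome
#'
#' Pure substring extraction: section `[start, end)` receives
#' `substr(chrom, start + 1, end)`.
#'
#' @param chrom A `chromosome_seq`.
#' @param ss A `section_set`.
#' @return The `section_set` with the `sequence` column filled.
#' @export
extract_sections <- function(chrom, ss) {
  stopifnot(inherits(chrom, "chromosome_seq"), inherits(ss, "section_set"))
  n <- nchar(chrom$sequence)
  bad <- which(ss$end > n)
  if (length(bad))
    stop("section(s) beyond chromosome end (", n, " nt): ",
         paste(sprintf("%s [%d,%d)", ss$label[bad], ss$start[bad], ss$end[bad]),
               collapse = ", "))
  ss$sequence <- substring(chrom$sequence, ss$start + 1L, ss$end)
  ss
}

#' @export
print.section_set <- function(x, ...) {
  has_seq <- !anyNA(x$sequence)
  cat(sprintf("<section_set> %d sections spanning [%d, %d)%s\n",
              nrow(x), min(x$start), max(x$end),
              if (has_seq) ", sequences extracted" else ""))
  print.data.frame(utils::head(data.frame(label = x$label, start = x$start,
                                          end = x$end, len = x$end - x$start), 6))
  if (nrow(x) > 6) cat("  ... and", nrow(x) - 6, "more\n")
  invisible(x)
}

# internal: sections must carry sequences
.require_sequences <- function(ss) {
  if (anyNA(ss$sequence))
    stop("section sequences not extracted; call extract_sections() first")
  invisible(ss)
}
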