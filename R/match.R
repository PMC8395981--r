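#' Matching configuration
#'
#' Bundles the fragment length and the microsatellite-exclusion rules used by
#' fragment enumeration and pair matching. The default repeat rules flag a
#' fragment that contains, at any offset, a run of at least four identical
#' nucleotides, three identical dinucleotides or two identical trinucleotides.
#'
#' @param L Fragment length in nt (window width; step is always 1 nt).
#' @param exclude_repeats Logical; drop fragments matching a repeat rule.
#' @param repeat_rules List of `c(motif_length, min_consecutive_units)` pairs.
#' @return A `match_config` list.
#' @export
match_config <- function(L, exclude_repeats = FALSE,
                         repeat_rules = list(c(1L, 4L), c(2L, 3L), c(3L, 2L))) {
  L <- as.integer(L)
  stopifnot(length(L) == 1L, L >= 1L)
  for (r in repeat_rules)
    if (length(r) != 2L || r[1] < 1L || r[2] < 2L)
      stop("each repeat rule is c(motif_length >= 1, min_consecutive_units >= 2)")
  structure(list(L = L, exclude_repeats = isTRUE(exclude_repeats),
                 repeat_rules = repeat_rules),
            class = "match_config")
}

# reverse a vector of strings (base R; no stringi dependency)
.str_rev <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
}

# reverse complement allowing n (internal; public revcomp rejects n)
.rc_raw <- function(x) .str_rev(chartr("acgtn", "tgcan", x))

#' Reverse complement
#'
#' Vectorized reverse complement over the strict alphabet `{a,c,g,t}`.
#' Fragments containing `n` are filtered out before matching, so ambiguity
#' codes are rejected here.
#'
#' @param seq Character vector of lowercase DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("aac")             # "gtt"
#' revcomp(revcomp("gattaca"))  # involution
#' @export
revcomp <- function(seq) {
  if (any(grepl("[^acgt]", seq)))
    stop("revcomp() is defined over {a,c,g,t} only")
  .rc_raw(seq)
}

#' Test fragments for simple (microsatellite-like) repeats
#'
#' A fragment is flagged when it contains, as a substring at any phase, a run
#' of at least `min_consecutive_units` identical copies of a motif of the
#' rule's length, e.g. `aaaa`, `atatat` or `acgacg` under the default rules.
#' Flagging is strand-symmetric: a fragment and its reverse complement are
#' always flagged together.
#'
#' @param frag Character vector of fragments.
#' @param rules Repeat rules as in [match_config()].
#' @return Logical vector.
#' @examples
#' is_simple_repeat(c("caaaag", "gatatatc", "acgtacgt", "aaat"))
#' @export
is_simple_repeat <- function(frag,
                             rules = list(c(1L, 4L), c(2L, 3L), c(3L, 2L))) {
  hit <- rep(FALSE, length(frag))
  for (r in rules) {
    pat <- sprintf("([acgtn]{%d})\\1{%d}", r[1], r[2] - 1L)
    hit <- hit | grepl(pat, frag, perl = TRUE)
  }
  hit
}

#' Enumerate the length-L fragments of a section
#'
#' Slides a window of `config$L` nt with a step of 1 nt over the section
#' sequence. Windows containing `n` are skipped; with
#' `config$exclude_repeats` windows flagged by [is_simple_repeat()] are
#' skipped too. A sequence shorter than `L` yields an empty enumeration
#' (not an error).
#'
#' @param sequence A section sequence (lowercase DNA string), or a single
#'   row of an extracted `section_set`.
#' @param config A [match_config()].
#' @return A data.frame with columns `offset` (0-based) and `fragment`.
#' @export
enumerate_fragments <- function(sequence, config) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  stopifnot(inherits(config, "match_config"))
  n <- nchar(sequence)
  L <- config$L
  if (n < L)
    return(data.frame(offset = integer(0), fragment = character(0)))
  win <- substring(sequence, 1:(n - L + 1L), L:n)
  keep <- !grepl("n", win, fixed = TRUE)
  if (config$exclude_repeats)
    keep <- keep & !is_simple_repeat(win, config$repeat_rules)
  data.frame(offset = which(keep) - 1L, fragment = win[keep],
             stringsAsFactors = FALSE)
}

# Canonical fragment spectrum of one sequence: named integer vector mapping
# canonical fragment (lexicographic min of window and its reverse complement)
# to the number of enumerated windows collapsing onto it. The canonical
# collapse makes pair counting strand-agnostic and deduplicates palindromes.
.kmer_spectrum <- function(sequence, config) {
  n <- nchar(sequence)
  L <- config$L
  if (n < L) return(integer(0))
  idx <- 1:(n - L + 1L)
  win <- substring(sequence, idx, idx + L - 1L)
  # windows of the reverse complement, re-reversed, are the per-window rcs
  rcwin <- rev(substring(.rc_raw(sequence), idx, idx + L - 1L))
  keep <- !grepl("n", win, fixed = TRUE)
  if (config$exclude_repeats)
    keep <- keep & !is_simple_repeat(win, config$repeat_rules)
  if (!any(keep)) return(integer(0))
  win <- win[keep]
  rcwin <- rcwin[keep]
  canon <- win
  flip <- rcwin < win
  canon[flip] <- rcwin[flip]
  r <- rle(sort(canon, method = "radix"))
  structure(r$lengths, names = r$values)
}

#' Count exact two-strand fragment matches between two sequences
#'
#' Counts ordered offset pairs `(i, j)` such that the length-L window of
#' `seqA` at `i` equals the window of `seqB` at `j` on either strand (direct
#' match or reverse complement). A palindromic fragment satisfying both
#' orientations is counted once. Filtered fragments (containing `n`, or
#' simple repeats when `config$exclude_repeats`) are excluded on both sides.
#' The count is symmetric in the two sequences and invariant under reverse
#' complementing either one.
#'
#' @param seqA,seqB Lowercase DNA strings.
#' @param config A [match_config()].
#' @return A list with `count` (integer) and `fragments` (named numeric
#'   vector: canonical fragment -> number of match events attributed to it).
#' @examples
#' count_pair_matches("aaaa", "aaaa", match_config(2))$count  # 9
#' count_pair_matches("acg", "cgt", match_config(3))$count    # 1 (rc match)
#' @export
count_pair_matches <- function(seqA, seqB, config) {
  ka <- .kmer_spectrum(seqA, config)
  kb <- .kmer_spectrum(seqB, config)
  .spectrum_pair(ka, kb)
}

# match-event counts per canonical fragment given two spectra
.spectrum_pair <- function(ka, kb) {
  if (length(ka) == 0L || length(kb) == 0L)
    return(list(count = 0, fragments = numeric(0)))
  m <- match(names(ka), names(kb))
  hit <- which(!is.na(m))
  if (length(hit) == 0L)
    return(list(count = 0, fragments = numeric(0)))
  ev <- as.numeric(ka[hit]) * as.numeric(kb[m[hit]])
  names(ev) <- names(ka)[hit]
  list(count = sum(ev), fragments = ev)
}

#' Build the pairwise match table and fragment catalog for a section set
#'
#' Runs fragment enumeration once per section and counts two-strand match
#' events for every unordered section pair, producing the symmetric raw
#' count matrix that FMF normalization consumes, plus (optionally) the
#' fragment catalog recording the number of occurrences (NO) of each
#' canonical fragment: the total match events attributed to it over all
#' section pairs.
#'
#' @param ss An extracted `section_set`.
#' @param config A [match_config()].
#' @param catalog Logical; also build the `fragment_catalog` (costs memory
#'   proportional to the distinct-fragment count).
#' @return A list of class `pair_match_table` with elements `counts`
#'   (symmetric N x N matrix, zero diagonal, dimnames = section labels),
#'   `L`, `config`, `sections` (labels) and, when requested, `catalog`.
#' @export
build_match_tables <- function(ss, config, catalog = TRUE) {
  stopifnot(inherits(ss, "section_set"), inherits(config, "match_config"))
  .require_sequences(ss)
  N <- nrow(ss)
  if (N < 2L) stop("need at least 2 sections")
  spectra <- lapply(ss$sequence, .kmer_spectrum, config = config)
  names(spectra) <- ss$label
  counts <- matrix(0, N, N, dimnames = list(ss$label, ss$label))
  # one global fragment dictionary so pair joins are integer-indexed
  all_frags <- unique(unlist(lapply(spectra, names), use.names = FALSE))
  ids <- lapply(spectra, function(s) match(names(s), all_frags))
  ks <- lapply(spectra, as.numeric)
  acc <- numeric(length(all_frags))
  for (a in seq_len(N - 1L)) {
    if (length(ids[[a]]) == 0L) next
    acc[ids[[a]]] <- ks[[a]]
    for (b in (a + 1L):N) {
      if (length(ids[[b]]) == 0L) next
      counts[a, b] <- counts[b, a] <- sum(acc[ids[[b]]] * ks[[b]])
    }
    acc[ids[[a]]] <- 0
  }
  out <- structure(list(counts = counts, L = config$L, config = config,
                        sections = ss$label, section_lengths = ss$end - ss$start),
                   class = "pair_match_table")
  if (catalog) out$catalog <- .build_catalog(spectra, config)
  out
}

# NO per canonical fragment over all unordered pairs:
#   NO(f) = ( (sum_s k_s)^2 - sum_s k_s^2 ) / 2
.build_catalog <- function(spectra, config) {
  frag <- unlist(lapply(spectra, names), use.names = FALSE)
  k <- unlist(lapply(spectra, as.numeric), use.names = FALSE)
  sect <- rep(names(spectra), vapply(spectra, length, integer(1)))
  if (length(frag) == 0L) {
    per_section <- data.frame(fragment = character(0), section = character(0),
                              k = numeric(0))
    no <- numeric(0)
  } else {
    per_section <- data.frame(fragment = frag, section = sect, k = k,
                              stringsAsFactors = FALSE)
    tot <- rowsum(k, frag)
    sq <- rowsum(k^2, frag)
    no <- (tot[, 1]^2 - sq[, 1]) / 2
    no <- no[no > 0]
  }
  structure(list(no = no, per_section = per_section, L = config$L,
                 config = config, scope = "all-sections"),
            class = "fragment_catalog")
}

#' @export
print.pair_match_table <- function(x, ...) {
  cat(sprintf("<pair_match_table> %d sections, L = %d, repeats %s\n",
              length(x$sections), x$L,
              if (x$config$exclude_repeats) "excluded" else "included"))
  cat(sprintf("  total match events: %g\n", sum(x$counts[upper.tri(x$counts)])))
  invisible(x)
}

#' @export
print.fragment_catalog <- function(x, ...) {
  cat(sprintf("<fragment_catalog> %d fragments with NO > 0, L = %d, scope: %s\n",
              length(x$no), x$L, x$scope))
  if (length(x$no)) {
    top <- sort(x$no, decreasing = TRUE)
    print(utils::head(data.frame(fragment = names(top), NO = unname(top)), 5))
  }
  invisible(x)
}

#' Matched fragments of one section pair
#'
#' Recovers, from a built match table, the per-pair list of canonical
#' fragments with their match-event counts (the "list of the localized
#' fragments" kept per partner section).
#'
#' @param mt A `pair_match_table` built with `catalog = TRUE`.
#' @param a,b Section labels.
#' @return Data.frame `fragment`, `count`, ordered by decreasing count.
#' @export
pair_fragments <- function(mt, a, b) {
  stopifnot(inherits(mt, "pair_match_table"))
  if (is.null(mt$catalog)) stop("match table was built with catalog = FALSE")
  ps <- mt$catalog$per_section
  ka <- ps[ps$section == a, ]
  kb <- ps[ps$section == b, ]
  if (!a %in% mt$sections || !b %in% mt$sections)
    stop("unknown section label")
  sp <- .spectrum_pair(structure(ka$k, names = ka$fragment),
                       structure(kb$k, names = kb$fragment))
  ev <- sort(sp$fragments, decreasing = TRUE)
  data.frame(fragment = names(ev), count = unname(ev), stringsAsFactors = FALSE)
}

#' Classify a fragment as a microsatellite
#'
#' Finds the shortest motif of length at most `max_motif` whose infinite
#' tandem repetition has the fragment as a prefix (the motif must actually
#' repeat: motif length < fragment length). Returns the motif, or `NA` when
#' the fragment is not microsatellite-like.
#'
#' @param frag Character vector of fragments (length >= 2 nt each).
#' @param max_motif Maximum motif length (microsatellite convention: 6).
#' @return Character vector of motifs, `NA` where none applies.
#' @examples
#' classify_microsatellite("atatatatat")          # "at"
#' classify_microsatellite("tcccagtcccagtcccag")  # "tcccag"
#' @export
classify_microsatellite <- function(frag, max_motif = 6L) {
  vapply(frag, function(f) {
    n <- nchar(f)
    if (n < 2L) return(NA_character_)
    for (m in seq_len(min(max_motif, n - 1L))) {
      motif <- substr(f, 1L, m)
      if (substr(strrep(motif, ceiling(n / m)), 1L, n) == f) return(motif)
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Export per-pair matched fragments as TSV
#'
#' @param mt A `pair_match_table` built with `catalog = TRUE`.
#' @param path Output path; columns `sectionA`, `sectionB`, `fragment`, `count`.
#' @export
write_pair_fragments <- function(mt, path) {
  stopifnot(inherits(mt, "pair_match_table"))
  labs <- mt$sections
  rows <- list()
  for (a in seq_along(labs)[-length(labs)]) {
    for (b in (a + 1L):length(labs)) {
      if (mt$counts[a, b] > 0) {
        pf <- pair_fragments(mt, labs[a], labs[b])
        if (nrow(pf))
          rows[[length(rows) + 1L]] <- data.frame(sectionA = labs[a],
                                                  sectionB = labs[b], pf)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sectionA = character(0), sectionB = character(0),
               fragment = character(0), count = numeric(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
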