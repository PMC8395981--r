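#' Rank matched fragments by number of occurrences
#'
#' Orders the catalog by decreasing NO (total match events attributed to a
#' canonical fragment over all section pairs), drops fragments with
#' `NO <= min_no`, keeps a single fragment per NO value (ties broken by
#' keeping the lexicographically smallest canonical fragment, a
#' deterministic stand-in for "the first"), and returns the top `top_k`.
#' Each kept fragment is classified as a microsatellite where
#' [classify_microsatellite()] finds a motif.
#'
#' @param catalog A `fragment_catalog` from [build_match_tables()] or
#'   [restrict_catalog()].
#' @param min_no Minimum NO (exclusive); default 10.
#' @param top_k Maximum ranking length; default 50.
#' @return A `fragment_ranking`: data.frame `rank`, `fragment`, `NO`,
#'   `motif` (NA when not microsatellite-like), with strictly decreasing NO.
#' @export
rank_fragments <- function(catalog, min_no = 10, top_k = 50L) {
  stopifnot(inherits(catalog, "fragment_catalog"))
  no <- catalog$no[catalog$no > min_no]
  if (length(no) == 0L) {
    message("no fragments with NO > ", min_no, "; empty ranking")
    out <- data.frame(rank = integer(0), fragment = character(0),
                      NO = numeric(0), motif = character(0))
  } else {
    o <- order(-no, names(no), method = "radix")
    no <- no[o]
    keep <- !duplicated(unname(no))
    no <- no[keep]
    no <- utils::head(no, top_k)
    out <- data.frame(rank = seq_along(no), fragment = names(no),
                      NO = unname(no),
                      motif = classify_microsatellite(names(no)),
                      stringsAsFactors = FALSE)
  }
  structure(out, L = catalog$L, scope = catalog$scope,
            class = c("fragment_ranking", "data.frame"))
}

#' Restrict a fragment catalog to a section subset
#'
#' Recomputes each fragment's NO counting only match events that involve the
#' given sections — by default events where at least one of the two sections
#' is in the subset (the subset being, typically, the sections with
#' significant specific FEC-FMF correlations, which anchor the events of
#' interest); with `mode = "both"` both sections must be members.
#'
#' @param catalog A `fragment_catalog`.
#' @param sections Character vector of section labels (subset).
#' @param mode `"any"` (default) or `"both"`.
#' @return A new `fragment_catalog` with recomputed NO values.
#' @export
restrict_catalog <- function(catalog, sections, mode = c("any", "both")) {
  stopifnot(inherits(catalog, "fragment_catalog"))
  mode <- match.arg(mode)
  ps <- catalog$per_section
  known <- unique(ps$section)
  unknown <- setdiff(sections, known)
  if (length(unknown))
    stop("unknown section label(s): ", paste(unknown, collapse = ", "))
  if (nrow(ps) == 0L || length(sections) == 0L) {
    out <- catalog
    out$no <- numeric(0)
    out$per_section <- ps[ps$section %in% sections, , drop = FALSE]
    out$scope <- sprintf("subset(%d, %s)", length(sections), mode)
    return(out)
  }
  # pair sums over unordered pairs via totals:
  #   all:  (T^2 - S) / 2          with T = sum k, S = sum k^2
  #   both-in: (Tin^2 - Sin) / 2
  #   at-least-one = all - both-out
  tot_all <- rowsum(ps$k, ps$fragment)
  sq_all <- rowsum(ps$k^2, ps$fragment)
  inset <- ps$section %in% sections
  frag_levels <- rownames(tot_all)
  z <- numeric(nrow(tot_all)); names(z) <- frag_levels
  tin <- z; sin <- z
  if (any(inset)) {
    t1 <- rowsum(ps$k[inset], ps$fragment[inset])
    tin[rownames(t1)] <- t1[, 1]
    s1 <- rowsum(ps$k[inset]^2, ps$fragment[inset])
    sin[rownames(s1)] <- s1[, 1]
  }
  if (mode == "both") {
    no <- (tin^2 - sin) / 2
  } else {
    tout <- tot_all[, 1] - tin
    sout <- sq_all[, 1] - sin
    no_all <- (tot_all[, 1]^2 - sq_all[, 1]) / 2
    no_out <- (tout^2 - sout) / 2
    no <- no_all - no_out
  }
  no <- no[no > 0]
  out <- catalog
  out$no <- no
  out$scope <- sprintf("subset(%d, %s)", length(sections), mode)
  out
}

#' Export a fragment ranking as FASTA
#'
#' Writes one record per ranked fragment, named `frag_<rank>_NO<NO>`, ready
#' for external annotation (e.g. a BLAST run against a nucleotide
#' collection).
#'
#' @param r A `fragment_ranking`.
#' @param path Output FASTA path.
#' @export
export_fasta <- function(r, path) {
  stopifnot(inherits(r, "fragment_ranking"))
  if (nrow(r) == 0L) {
    warning("empty ranking; writing empty FASTA")
    file.create(path)
    return(invisible(path))
  }
  ids <- sprintf("frag_%d_NO%g", r$rank, r$NO)
  xs <- Biostrings::DNAStringSet(toupper(r$fragment))
  names(xs) <- ids
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Attach biological classes to a ranking
#'
#' Microsatellites are classified internally from the fragment sequence; any
#' other class comes from a user-supplied annotation table (typically parsed
#' from BLAST output: satellite families such as 1.688/372-bp repeats,
#' specific genes, transposons, ...). Unannotated fragments are labeled
#' `"other/unknown"`.
#'
#' @param r A `fragment_ranking`.
#' @param annotation Optional data.frame with columns `fragment`, `class`.
#' @return The ranking with a `class` column.
#' @export
annotate_classes <- function(r, annotation = NULL) {
  stopifnot(inherits(r, "fragment_ranking"))
  cls <- rep("other/unknown", nrow(r))
  if (!is.null(annotation)) {
    stopifnot(all(c("fragment", "class") %in% names(annotation)))
    i <- match(r$fragment, annotation$fragment)
    cls[!is.na(i)] <- annotation$class[i[!is.na(i)]]
  }
  cls[!is.na(r$motif)] <- "microsatellite"
  r$class <- cls
  r
}

#' Write a fragment ranking as TSV
#'
#' @param r A `fragment_ranking` (optionally annotated).
#' @param path Output path; columns `rank`, `fragment`, `NO`, `class`,
#'   `motif`.
#' @export
write_ranking <- function(r, path) {
  stopifnot(inherits(r, "fragment_ranking"))
  if (!"class" %in% names(r)) r <- annotate_classes(r)
  utils::write.table(r[, c("rank", "fragment", "NO", "class", "motif")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.fragment_ranking <- function(x, ...) {
  cat(sprintf("<fragment_ranking> %d fragments, L = %s, scope: %s\n",
              nrow(x), attr(x, "L"), attr(x, "scope")))
  print.data.frame(utils::head(x, 10))
  invisible(x)
}
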