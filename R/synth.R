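#' Specify a synthetic chromosome with planted satellite monomers
#'
#' Describes a multi-section chromosome for ground-truth validation:
#' i.i.d. background bases at a given GC content, tandem arrays of satellite
#' monomers planted into chosen sections, and a Poisson contact model whose
#' intensity for a section pair is `lambda0 + lambda1 * shared(A, B)`, where
#' `shared` indicates that the pair carries a common planted monomer. The
#' defaults emulate the screening scale of the real data in miniature: 20
#' sections of 50 kb at Drosophila-like 43% GC, with 359-nt monomers (the
#' length of a classic X-chromosome satellite repeat unit) when planted.
#'
#' @param n_sections Number of sections (>= 2).
#' @param section_length Section length in nt (recycled over sections).
#' @param gc_content Fraction of g+c in the background.
#' @param monomers List of monomer descriptions, each a list with elements
#'   `sections` (integer indices of planted sections), `copies` (tandem copy
#'   number, default 10) and either `sequence` (explicit monomer) or
#'   `length` (nt of a randomly drawn monomer, default 359).
#' @param fec_baseline Poisson baseline contact rate `lambda0`.
#' @param fec_coupling Added rate `lambda1` for monomer-sharing pairs.
#' @param seed Integer seed; every randomization in the generator derives
#'   from it.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_sections = 20L, section_length = 50000L,
                       gc_content = 0.43, monomers = list(),
                       fec_baseline = 1, fec_coupling = 10, seed = 1L) {
  n_sections <- as.integer(n_sections)
  stopifnot(n_sections >= 2L, gc_content > 0, gc_content < 1,
            fec_baseline >= 0, fec_coupling >= 0)
  section_length <- rep_len(as.integer(section_length), n_sections)
  stopifnot(all(section_length > 0L))
  for (m in monomers) {
    if (is.null(m$sections) || length(m$sections) < 1L)
      stop("each monomer needs a 'sections' element")
    if (any(m$sections < 1L | m$sections > n_sections))
      stop("planted sections out of range 1..", n_sections)
  }
  structure(list(n_sections = n_sections, section_length = section_length,
                 gc_content = gc_content, monomers = monomers,
                 fec_baseline = fec_baseline, fec_coupling = fec_coupling,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

.random_dna <- function(n, gc) {
  p <- c(a = (1 - gc) / 2, c = gc / 2, g = gc / 2, t = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic chromosome with planted monomers
#'
#' Draws the background sequence, resolves monomer sequences (random ones
#' are drawn from the same RNG stream), and inserts each planted tandem
#' array at a uniformly chosen offset within its section, rejecting overlaps
#' with arrays planted earlier in the same section. Deterministic under the
#' spec seed: the same spec always yields a byte-identical genome.
#'
#' @param spec A [synth_spec()].
#' @return A list of class `synth_genome`: `chrom` (a `chromosome_seq`),
#'   `sections` (an extracted `section_set`), and `truth` (a `synth_truth`:
#'   per-section planted monomer ids, the symmetric `shared` indicator
#'   matrix, and the Poisson intensity matrix `lambda`).
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  N <- spec$n_sections
  labels <- sprintf("S%0*d", max(2L, nchar(N)), seq_len(N))
  seqs <- vapply(spec$section_length, .random_dna, character(1),
                 gc = spec$gc_content)
  monomers <- lapply(spec$monomers, function(m) {
    if (is.null(m$sequence)) {
      len <- if (is.null(m$length)) 359L else as.integer(m$length)
      m$sequence <- .random_dna(len, spec$gc_content)
    }
    if (is.null(m$copies)) m$copies <- 10L
    m
  })
  planted <- rep(list(integer(0)), N)
  occupied <- rep(list(matrix(numeric(0), ncol = 2)), N)  # [start, end) taken
  for (mi in seq_along(monomers)) {
    m <- monomers[[mi]]
    arr <- strrep(m$sequence, m$copies)
    alen <- nchar(arr)
    for (s in m$sections) {
      slen <- spec$section_length[s]
      if (alen > slen)
        stop("monomer array (", alen, " nt) exceeds section length (", slen, " nt)")
      placed <- FALSE
      for (try in 1:1000) {
        off <- sample.int(slen - alen + 1L, 1L) - 1L
        occ <- occupied[[s]]
        if (nrow(occ) == 0L ||
            all(off + alen <= occ[, 1] | off >= occ[, 2])) {
          substr(seqs[s], off + 1L, off + alen) <- arr
          occupied[[s]] <- rbind(occ, c(off, off + alen))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place monomer ", mi, " in section ", s,
             " without overlap; insertions exceed section capacity")
      planted[[s]] <- c(planted[[s]], mi)
    }
  }
  shared <- matrix(0L, N, N, dimnames = list(labels, labels))
  for (m in monomers) {
    for (a in m$sections) for (b in m$sections)
      if (a != b) shared[a, b] <- 1L
  }
  lambda <- spec$fec_baseline + spec$fec_coupling * shared
  diag(lambda) <- 0
  chrom <- chromosome_seq("synthetic_chromosome", paste(seqs, collapse = ""))
  ends <- cumsum(spec$section_length)
  ss <- section_set(labels, ends - spec$section_length, ends)
  ss <- extract_sections(chrom, ss)
  truth <- structure(list(planted = planted, shared = shared, lambda = lambda,
                          labels = labels, spec = spec),
                     class = "synth_truth")
  structure(list(chrom = chrom, sections = ss, truth = truth),
            class = "synth_genome")
}

#' Simulate an FEC matrix from planted truth
#'
#' Draws independent Poisson contact counts per unordered section pair at
#' intensity `lambda(A, B) = lambda0 + lambda1 * shared(A, B)` and
#' symmetrizes. Deterministic under the given seed.
#'
#' @param truth A `synth_truth` from [make_genome()].
#' @param seed Integer seed (defaults to the spec seed plus one so that
#'   sequence and contacts use distinct streams).
#' @param strain Strain tag for the resulting matrix.
#' @return A `fec_matrix`.
#' @export
make_fec <- function(truth, seed = NULL, strain = "synthetic") {
  stopifnot(inherits(truth, "synth_truth"))
  if (is.null(seed)) seed <- truth$spec$seed + 1L
  set.seed(seed)
  N <- length(truth$labels)
  counts <- matrix(0L, N, N, dimnames = list(truth$labels, truth$labels))
  up <- which(upper.tri(counts))
  counts[up] <- stats::rpois(length(up), truth$lambda[up])
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  fec_matrix(counts, strain = strain)
}

#' Write a complete synthetic fixture to disk
#'
#' Materializes a spec as a directory holding the chromosome FASTA, the
#' section table, an FEC matrix, the pairwise ground-truth table and a
#' manifest recording the spec parameters and seed. Every file round-trips
#' through the package readers, and rewriting from the same spec reproduces
#' identical files.
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with `files` (named vector of written paths),
#'   `genome` (the `synth_genome`) and `fec` (the `fec_matrix`).
#' @export
write_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- make_genome(spec)
  fec <- make_fec(g$truth)
  paths <- list(fasta = file.path(dir, "chromosome.fa"),
                sections = file.path(dir, "sections.tsv"),
                fec = file.path(dir, "fec.tsv"),
                truth = file.path(dir, "truth.tsv"),
                manifest = file.path(dir, "manifest.tsv"))
  xs <- Biostrings::DNAStringSet(toupper(g$chrom$sequence))
  names(xs) <- g$chrom$name
  Biostrings::writeXStringSet(xs, paths$fasta)
  write_section_table(g$sections, paths$sections)
  write_fec(fec, paths$fec)
  labs <- g$truth$labels
  idx <- which(upper.tri(g$truth$shared), arr.ind = TRUE)
  truth_df <- data.frame(sectionA = labs[idx[, 1]], sectionB = labs[idx[, 2]],
                         shared = g$truth$shared[idx],
                         lambda = g$truth$lambda[idx])
  utils::write.table(truth_df, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  man <- data.frame(
    key = c("n_sections", "section_length", "gc_content", "fec_baseline",
            "fec_coupling", "seed", "n_monomers"),
    value = c(spec$n_sections, paste(unique(spec$section_length), collapse = ","),
              spec$gc_content, spec$fec_baseline, spec$fec_coupling, spec$seed,
              length(spec$monomers)))
  utils::write.table(man, paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(files = paths, genome = g, fec = fec))
}
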