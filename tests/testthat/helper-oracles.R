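# Independent oracles, deliberately naive and separate from the package's
# fast paths.

# reverse complement, written from scratch
rc_oracle <- function(s) {
  vapply(strsplit(chartr("acgt", "tgca", s), ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
}

# all length-L windows of a sequence, optionally filtered like the package
windows_oracle <- function(seq, L, exclude_repeats = FALSE) {
  n <- nchar(seq)
  if (n < L) return(character(0))
  w <- substring(seq, 1:(n - L + 1), L:n)
  w <- w[!grepl("n", w, fixed = TRUE)]
  if (exclude_repeats) {
    bad <- grepl("(.)\\1{3}", w, perl = TRUE) |
      grepl("(..)\\1{2}", w, perl = TRUE) |
      grepl("(...)\\1{1}", w, perl = TRUE)
    w <- w[!bad]
  }
  w
}

# brute-force O(|A||B|) two-strand match count: ordered offset pairs (i, j)
# matching forward or reverse-complement, palindromic double-hits counted once
count_oracle <- function(seqA, seqB, L, exclude_repeats = FALSE) {
  wa <- windows_oracle(seqA, L, exclude_repeats)
  wb <- windows_oracle(seqB, L, exclude_repeats)
  if (length(wa) == 0 || length(wb) == 0) return(0)
  fwd <- outer(wa, wb, "==")
  rc <- outer(wa, rc_oracle(wb), "==")
  sum(fwd | rc)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("a", "c", "g", "t"), n, replace = TRUE, prob = p),
        collapse = "")
}

# exact two-sided Mann-Whitney p by enumeration over all rank assignments
# (tie-free inputs only)
mw_exact_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_obs <- sum(outer(x, y, ">"))
  idx <- utils::combn(n + m, n)
  us <- apply(idx, 2, function(i) {
    xs <- pooled[i]; ys <- pooled[-i]
    sum(outer(xs, ys, ">"))
  })
  p_low <- mean(us <= u_obs)
  p_high <- mean(us >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# hand-computed 2x2 chi-square: sum (O - E)^2 / E over the four cells
chisq_oracle <- function(k1, n1, k2, n2) {
  obs <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  stat <- sum((obs - expd)^2 / expd)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# tiny extracted section set from explicit sequences
toy_sections <- function(seqs, labels = sprintf("S%02d", seq_along(seqs))) {
  lens <- nchar(seqs)
  ends <- cumsum(lens)
  chrom <- chromosome_seq("toy", paste(seqs, collapse = ""))
  extract_sections(chrom, section_set(labels, ends - lens, ends))
}

# symmetric random FEC matrix over given labels
random_fec <- function(labels, lambda = 2, strain = "toy") {
  N <- length(labels)
  m <- matrix(0L, N, N, dimnames = list(labels, labels))
  up <- which(upper.tri(m))
  m[up] <- stats::rpois(length(up), lambda)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  fec_matrix(m, strain = strain)
}
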