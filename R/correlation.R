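#' Spearman rank correlation with validity flagging
#'
#' Spearman rho computed as the Pearson correlation of midranks (average
#' ranks for ties — FEC counts are small integers, so ties are the norm),
#' with a two-sided p-value from the t approximation on `n - 2` degrees of
#' freedom. An estimate is invalid — `rho` and `p` are `NA` — when the
#' sample is shorter than `min_n` or either vector is constant.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_n Minimum sample size for a valid estimate (default 5).
#' @return A list with `rho`, `p`, `n`, `valid`.
#' @export
spearman_corr <- function(x, y, min_n = 5L) {
  if (length(x) != length(y)) stop("length mismatch between x and y")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_n || length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p = NA_real_, n = n, valid = FALSE))
  rho <- stats::cor(rank(x), rank(y))
  if (!is.finite(rho))
    return(list(rho = NA_real_, p = NA_real_, n = n, valid = FALSE))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, valid = TRUE)
}

# align an fec_matrix and fmf_matrix on identical section sets
.align_fec_fmf <- function(fec, fmf) {
  stopifnot(inherits(fec, "fec_matrix"), inherits(fmf, "fmf_matrix"))
  if (!identical(sort(fec$sections), sort(fmf$sections)))
    stop("FEC and FMF section sets differ")
  list(fec = fec$counts[fmf$sections, fmf$sections], fmf = fmf$values,
       labels = fmf$sections)
}

#' Specific FEC-FMF correlations
#'
#' For each anchor section A, correlates the contact vector `FEC(A, B)` with
#' the homology vector `FMF(A, B)` over all partner sections `B != A` in
#' chromosomal order (`n = N - 1`; self-pairs are excluded since both
#' matrices have an undefined, zero diagonal).
#'
#' @param fec A `fec_matrix`.
#' @param fmf An `fmf_matrix` over the same sections.
#' @param min_n Passed to [spearman_corr()].
#' @return A `corr_set`: data.frame with columns `anchor`, `rho`, `p`, `n`,
#'   `valid`; attribute `type = "specific"`.
#' @export
specific_correlations <- function(fec, fmf, min_n = 5L) {
  al <- .align_fec_fmf(fec, fmf)
  N <- length(al$labels)
  res <- lapply(seq_len(N), function(a)
    spearman_corr(al$fec[a, -a], al$fmf[a, -a], min_n = min_n))
  out <- data.frame(anchor = al$labels,
                    rho = vapply(res, `[[`, numeric(1), "rho"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    n = vapply(res, `[[`, integer(1), "n"),
                    valid = vapply(res, `[[`, logical(1), "valid"),
                    stringsAsFactors = FALSE)
  structure(out, type = "specific", class = c("corr_set", "data.frame"))
}

#' Unspecific FEC-FMF correlations
#'
#' The permutation-style control: for every ordered pair of different
#' sections (A, B), correlates `FEC(A, C)` with `FMF(B, C)` over the common
#' partners `C` outside `{A, B}` (`n = N - 2`), so both vectors are indexed
#' by the same partner set. There are `N * (N - 1)` estimates.
#'
#' @inheritParams specific_correlations
#' @return A `corr_set` with columns `anchor_fec`, `anchor_fmf`, `rho`, `p`,
#'   `n`, `valid`; attribute `type = "unspecific"`.
#' @export
unspecific_correlations <- function(fec, fmf, min_n = 5L) {
  al <- .align_fec_fmf(fec, fmf)
  N <- length(al$labels)
  pairs <- expand.grid(a = seq_len(N), b = seq_len(N))
  pairs <- pairs[pairs$a != pairs$b, ]
  res <- mapply(function(a, b) {
    keep <- setdiff(seq_len(N), c(a, b))
    spearman_corr(al$fec[a, keep], al$fmf[b, keep], min_n = min_n)
  }, pairs$a, pairs$b, SIMPLIFY = FALSE)
  out <- data.frame(anchor_fec = al$labels[pairs$a],
                    anchor_fmf = al$labels[pairs$b],
                    rho = vapply(res, `[[`, numeric(1), "rho"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    n = vapply(res, `[[`, integer(1), "n"),
                    valid = vapply(res, `[[`, logical(1), "valid"),
                    stringsAsFactors = FALSE)
  structure(out, type = "unspecific", class = c("corr_set", "data.frame"))
}

#' Summarize a correlation set into R and P
#'
#' `R` is the mean rho over statistically significant estimates
#' (`p < alpha` among valid ones) with standard error `sd / sqrt(n_signif)`;
#' `P` is the proportion of significant estimates among valid ones with the
#' binomial standard error `sqrt(P * (1 - P) / n_valid)`. With no valid
#' estimates `P` is `NA`; with no significant ones `R` is `NA`.
#'
#' @param cs A `corr_set`.
#' @param alpha Significance threshold on the raw (uncorrected) p-value.
#' @param adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()] before thresholding (default `"none"`, matching the
#'   raw-p convention of the screening design).
#' @return A one-row data.frame: `R`, `R_se`, `P`, `P_se`, `n_signif`,
#'   `n_valid`.
#' @export
summarize_correlations <- function(cs, alpha = 0.05, adjust = "none") {
  stopifnot(inherits(cs, "corr_set") || is.data.frame(cs))
  valid <- cs[cs$valid & !is.na(cs$p), , drop = FALSE]
  n_valid <- nrow(valid)
  p <- stats::p.adjust(valid$p, method = adjust)
  sig <- valid[p < alpha, , drop = FALSE]
  n_signif <- nrow(sig)
  R <- if (n_signif >= 1L) mean(sig$rho) else NA_real_
  R_se <- if (n_signif >= 2L) stats::sd(sig$rho) / sqrt(n_signif) else NA_real_
  P <- if (n_valid >= 1L) n_signif / n_valid else NA_real_
  P_se <- if (n_valid >= 1L) sqrt(P * (1 - P) / n_valid) else NA_real_
  data.frame(R = R, R_se = R_se, P = P, P_se = P_se,
             n_signif = n_signif, n_valid = n_valid)
}
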