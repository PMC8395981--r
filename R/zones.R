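#' Enumerate sliding chromosome zones of length D
#'
#' A zone is a window of `D` consecutive sections; windows advance by one
#' section, giving `N - D + 1` zones for `N` sections.
#'
#' @param N Number of sections.
#' @param D Zone length in sections, `2 <= D <= N`.
#' @return Data.frame with columns `zone`, `start`, `end` (1-based section
#'   indices, inclusive).
#' @examples
#' nrow(enumerate_zones(119, 30))  # 90
#' @export
enumerate_zones <- function(N, D) {
  N <- as.integer(N); D <- as.integer(D)
  if (D > N) stop("zone length D = ", D, " exceeds section count N = ", N)
  if (D < 2L) stop("zone length must be at least 2 sections")
  start <- seq_len(N - D + 1L)
  data.frame(zone = start, start = start, end = start + D - 1L)
}

# specific correlations restricted to an index subset (anchor and partners
# both inside idx); F/M are aligned plain matrices
.spec_sub <- function(F, M, idx, min_n) {
  lapply(idx, function(a) {
    keep <- setdiff(idx, a)
    spearman_corr(F[a, keep], M[a, keep], min_n = min_n)
  })
}

.unspec_sub <- function(F, M, idx, min_n) {
  out <- vector("list", length(idx) * (length(idx) - 1L))
  k <- 0L
  for (a in idx) for (b in idx) {
    if (a == b) next
    keep <- setdiff(idx, c(a, b))
    k <- k + 1L
    out[[k]] <- spearman_corr(F[a, keep], M[b, keep], min_n = min_n)
  }
  out
}

.summ_list <- function(res, alpha) {
  df <- data.frame(rho = vapply(res, `[[`, numeric(1), "rho"),
                   p = vapply(res, `[[`, numeric(1), "p"),
                   valid = vapply(res, `[[`, logical(1), "valid"))
  summarize_correlations(df, alpha = alpha)
}

#' Distance-zone sweep of the FEC-FMF correlation
#'
#' Recomputes the specific and unspecific R/P summaries inside every sliding
#' zone of `D` consecutive sections, for each zone length in `D` and each
#' supplied FMF matrix (one per fragment length). Within a zone, specific
#' anchors are zone members with partners restricted to the zone
#' (`n = D - 1`) and unspecific pairs lie entirely within the zone
#' (`n = D - 2`). Per zone length the zone-level R and P values form
#' samplings of size `N - D + 1`; their means give the difference curves
#' `R_DIFF = mean R_SP - mean R_UN` and `P_DIFF` analogously.
#'
#' @param fec A `fec_matrix`.
#' @param fmf An `fmf_matrix` or a list of them (one per fragment length L).
#' @param D Integer vector of zone lengths (default `10:(N-3)` clipped to
#'   valid range, emulating the dense-D screening design).
#' @param alpha Significance threshold.
#' @param min_n Minimum sample size for a valid Spearman estimate.
#' @param unspecific Logical; also compute the unspecific control (the
#'   expensive part — `D * (D - 1)` estimates per zone).
#' @return A `zone_sweep` object: list with `zones` (long data.frame: `L`,
#'   `D`, `zone_start`, `R_SP`, `R_UN`, `P_SP`, `P_UN`, valid counts) and
#'   `by_d` (per-(L, D) aggregate with `n_zones` and the DIFF columns).
#'   Zones where all estimates are invalid contribute `NA` (excluded from
#'   the per-D means, counted in `n_zones_missing`).
#' @export
zone_sweep <- function(fec, fmf, D = NULL, alpha = 0.05, min_n = 5L,
                       unspecific = TRUE) {
  if (inherits(fmf, "fmf_matrix")) fmf <- list(fmf)
  rows <- list()
  for (fm in fmf) {
    al <- .align_fec_fmf(fec, fm)
    N <- length(al$labels)
    Dv <- if (is.null(D)) seq(min(10L, N), N) else as.integer(D)
    Dv <- Dv[Dv >= 2L & Dv <= N]
    if (length(Dv) == 0L) stop("no valid zone lengths in D")
    for (d in Dv) {
      z <- enumerate_zones(N, d)
      for (i in seq_len(nrow(z))) {
        idx <- z$start[i]:z$end[i]
        sp <- .summ_list(.spec_sub(al$fec, al$fmf, idx, min_n), alpha)
        if (unspecific) {
          un <- .summ_list(.unspec_sub(al$fec, al$fmf, idx, min_n), alpha)
        } else {
          un <- data.frame(R = NA_real_, P = NA_real_,
                           n_signif = NA_integer_, n_valid = NA_integer_)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          L = fm$L, D = d, zone_start = z$start[i],
          R_SP = sp$R, R_UN = un$R, P_SP = sp$P, P_UN = un$P,
          n_valid_SP = sp$n_valid, n_valid_UN = un$n_valid)
      }
    }
  }
  zones <- do.call(rbind, rows)
  agg <- lapply(split(zones, list(zones$L, zones$D), drop = TRUE), function(g) {
    data.frame(L = g$L[1], D = g$D[1], n_zones = nrow(g),
               n_zones_missing_SP = sum(is.na(g$P_SP)),
               R_SP = mean(g$R_SP, na.rm = TRUE),
               R_UN = mean(g$R_UN, na.rm = TRUE),
               P_SP = mean(g$P_SP, na.rm = TRUE),
               P_UN = mean(g$P_UN, na.rm = TRUE))
  })
  by_d <- do.call(rbind, agg)
  by_d$R_DIFF <- by_d$R_SP - by_d$R_UN
  by_d$P_DIFF <- by_d$P_SP - by_d$P_UN
  by_d <- by_d[order(by_d$L, by_d$D), ]
  rownames(by_d) <- NULL
  structure(list(zones = zones, by_d = by_d, alpha = alpha,
                 strain = fec$strain),
            class = "zone_sweep")
}

#' @export
print.zone_sweep <- function(x, ...) {
  cat(sprintf("<zone_sweep> strain %s: L in {%s}, D in [%d, %d]\n",
              x$strain, paste(unique(x$by_d$L), collapse = ", "),
              min(x$by_d$D), max(x$by_d$D)))
  print(utils::head(x$by_d, 8))
  invisible(x)
}

#' Plot zone-sweep difference curves
#'
#' Draws `R_DIFF` (or `P_DIFF`) against zone length D, one line per
#' fragment length.
#'
#' @param x A `zone_sweep`.
#' @param which `"R_DIFF"` or `"P_DIFF"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.zone_sweep <- function(x, which = c("R_DIFF", "P_DIFF"), ...) {
  which <- match.arg(which)
  Ls <- sort(unique(x$by_d$L))
  Ds <- sort(unique(x$by_d$D))
  m <- sapply(Ls, function(l) {
    g <- x$by_d[x$by_d$L == l, ]
    g[[which]][match(Ds, g$D)]
  })
  graphics::matplot(Ds, m, type = "l", lty = 1, xlab = "zone length D (sections)",
                    ylab = which, main = sprintf("strain %s", x$strain), ...)
  graphics::abline(h = 0, col = "grey70")
  graphics::legend("topright", legend = paste0("L", Ls), lty = 1,
                   col = seq_along(Ls), bty = "n")
  invisible(x)
}

#' Write zone-sweep tables as TSV
#'
#' @param x A `zone_sweep`.
#' @param path_zones,path_by_d Output paths for the per-zone table and the
#'   per-D aggregate (either may be `NULL` to skip).
#' @export
write_zone_sweep <- function(x, path_zones = NULL, path_by_d = NULL) {
  stopifnot(inherits(x, "zone_sweep"))
  if (!is.null(path_zones))
    utils::write.table(cbind(strain = x$strain, x$zones), path_zones,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_by_d))
    utils::write.table(cbind(strain = x$strain, x$by_d), path_by_d,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
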