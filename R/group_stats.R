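#' Two-sided Mann-Whitney U test
#'
#' Compares two samplings of R (or P) values. Uses exact enumeration when
#' both groups are small (`min(n, m) <= 8`) and tie-free, and otherwise the
#' normal approximation with the midrank tie correction (no continuity
#' correction), i.e. the classical large-sample U test.
#'
#' @param x,y Numeric samplings (non-empty).
#' @return List with `U` (statistic for the first sample) and `p`
#'   (two-sided).
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("empty sampling in Mann-Whitney comparison")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = FALSE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # degenerate: pooled sample constant
  list(U = unname(wt$statistic), p = min(p, 1))
}

#' Chi-square test for two sample proportions
#'
#' Compares two proportions `k1/n1` and `k2/n2` with the 2x2 chi-square test
#' on one degree of freedom, by default without the Yates continuity
#' correction.
#'
#' @param k1,n1,k2,n2 Successes and totals of the two groups (`n >= 1`).
#' @param correct Logical; apply the continuity correction.
#' @return List with `statistic` and `p`.
#' @export
chisq_two_proportions <- function(k1, n1, k2, n2, correct = FALSE) {
  if (n1 < 1L || n2 < 1L) stop("group size must be at least 1")
  if (k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) stop("counts out of range")
  if (k1 / n1 == k2 / n2)
    return(list(statistic = 0, p = 1))
  pt <- suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2),
                                          correct = correct))
  list(statistic = unname(pt$statistic), p = pt$p.value)
}

#' Compare R and P across screening conditions
#'
#' The automated comparison layer: within a fitted screen, conditions that
#' differ in exactly one factor (strain, correlation type, or repeat
#' filtering) are compared at each fragment length, and within each
#' condition every fragment length is compared against the L = 50 reference
#' (when present). R samplings (all valid rho values of a condition) are
#' compared with the two-sided Mann-Whitney U test; P values are compared as
#' proportions `n_signif / n_valid` with the two-proportion chi-square test.
#'
#' @param x A `homology_screen` or `zone_sweep` object.
#' @param ... Method-specific arguments.
#' @return A data.frame, one row per comparison: the fixed condition, the
#'   varied factor and its two levels, test name, statistic, p, and a
#'   significance flag at `alpha`.
#' @export
compare_all <- function(x, ...) UseMethod("compare_all")

# one MW + one chi-square row pair for two corr_sets
.compare_pair <- function(cs_a, cs_b, meta, alpha) {
  ra <- cs_a$rho[cs_a$valid]
  rb <- cs_b$rho[cs_b$valid]
  sa <- summarize_correlations(cs_a, alpha = alpha)
  sb <- summarize_correlations(cs_b, alpha = alpha)
  rows <- list()
  if (length(ra) && length(rb)) {
    mw <- mann_whitney_u(ra, rb)
    rows$R <- cbind(meta, test = "mann_whitney_R", statistic = mw$U, p = mw$p,
                    computable = TRUE)
  } else {
    rows$R <- cbind(meta, test = "mann_whitney_R", statistic = NA_real_,
                    p = NA_real_, computable = FALSE)
  }
  if (sa$n_valid >= 1L && sb$n_valid >= 1L) {
    cq <- chisq_two_proportions(sa$n_signif, sa$n_valid, sb$n_signif, sb$n_valid)
    rows$P <- cbind(meta, test = "chisq_P", statistic = cq$statistic, p = cq$p,
                    computable = TRUE)
  } else {
    rows$P <- cbind(meta, test = "chisq_P", statistic = NA_real_, p = NA_real_,
                    computable = FALSE)
  }
  do.call(rbind, rows)
}

#' @describeIn compare_all Compare conditions of a whole-chromosome length
#'   sweep: one-factor contrasts (strain, type, filter) at every L, plus the
#'   L-versus-L50 contrasts within each condition.
#' @param alpha Significance threshold for the flag column.
#' @param reference_L Fragment length used as the within-condition reference
#'   (default 50; skipped when absent from the sweep).
#' @export
compare_all.homology_screen <- function(x, alpha = 0.05, reference_L = 50L, ...) {
  g <- x$grid
  out <- list()
  # uniform row schema; the varied factor's own column is NA
  meta_row <- function(strain, L, filter, type, varied, a, b)
    data.frame(strain = strain, L = L, filter = filter, type = type,
               varied = varied, level_a = as.character(a),
               level_b = as.character(b), stringsAsFactors = FALSE)
  factors <- c("strain", "type", "filter")
  for (fac in factors) {
    lv <- unique(g[[fac]])
    if (length(lv) < 2L) next
    others <- setdiff(c("strain", "type", "filter", "L"), fac)
    combos <- unique(g[others])
    for (i in seq_len(nrow(combos))) {
      for (ia in seq_len(length(lv) - 1L)) for (ib in (ia + 1L):length(lv)) {
        sel <- rep(TRUE, nrow(g))
        for (o in others) sel <- sel & g[[o]] == combos[[o]][i]
        ka <- which(sel & g[[fac]] == lv[ia])
        kb <- which(sel & g[[fac]] == lv[ib])
        if (length(ka) != 1L || length(kb) != 1L) next
        fill <- function(col) if (fac == col) NA else combos[[col]][i]
        meta <- meta_row(fill("strain"), combos[["L"]][i], fill("filter"),
                         fill("type"), fac, lv[ia], lv[ib])
        out[[length(out) + 1L]] <-
          .compare_pair(x$detail[[g$key[ka]]], x$detail[[g$key[kb]]],
                        meta, alpha)
      }
    }
  }
  # L-wise contrasts against the reference length within each condition
  if (reference_L %in% g$L) {
    conds <- unique(g[c("strain", "type", "filter")])
    for (i in seq_len(nrow(conds))) {
      sel <- g$strain == conds$strain[i] & g$type == conds$type[i] &
        g$filter == conds$filter[i]
      kref <- which(sel & g$L == reference_L)
      if (length(kref) != 1L) next
      for (k in which(sel & g$L != reference_L)) {
        meta <- meta_row(conds$strain[i], NA, conds$filter[i], conds$type[i],
                         "L", g$L[k], reference_L)
        out[[length(out) + 1L]] <-
          .compare_pair(x$detail[[g$key[k]]], x$detail[[g$key[kref]]],
                        meta, alpha)
      }
    }
  }
  if (length(out) == 0L) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$signif <- !is.na(res$p) & res$p < alpha
  res
}

#' @describeIn compare_all Compare zone-level R and P samplings between two
#'   zone sweeps (e.g. two strains, or filtered vs unfiltered), and the
#'   specific-vs-unspecific samplings within one sweep; each (L, D) cell is
#'   tested independently with the Mann-Whitney U test.
#' @param y Optional second `zone_sweep` to contrast against `x`.
#' @export
compare_all.zone_sweep <- function(x, y = NULL, alpha = 0.05, ...) {
  out <- list()
  cells <- unique(x$zones[c("L", "D")])
  for (i in seq_len(nrow(cells))) {
    g <- x$zones[x$zones$L == cells$L[i] & x$zones$D == cells$D[i], ]
    for (stat in c("R", "P")) {
      a <- g[[paste0(stat, "_SP")]]
      b <- g[[paste0(stat, "_UN")]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      computable <- length(a) > 0L && length(b) > 0L
      mw <- if (computable) mann_whitney_u(a, b) else list(U = NA_real_, p = NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        L = cells$L[i], D = cells$D[i], varied = "type",
        level_a = "specific", level_b = "unspecific",
        test = paste0("mann_whitney_", stat),
        statistic = mw$U, p = mw$p, computable = computable)
    }
    if (!is.null(y)) {
      h <- y$zones[y$zones$L == cells$L[i] & y$zones$D == cells$D[i], ]
      if (nrow(h) == 0L) next
      for (type in c("SP", "UN")) for (stat in c("R", "P")) {
        a <- g[[paste0(stat, "_", type)]]
        b <- h[[paste0(stat, "_", type)]]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        computable <- length(a) > 0L && length(b) > 0L
        mw <- if (computable) mann_whitney_u(a, b) else list(U = NA_real_, p = NA_real_)
        out[[length(out) + 1L]] <- data.frame(
          L = cells$L[i], D = cells$D[i], varied = "sweep",
          level_a = paste0(x$strain, "_", type),
          level_b = paste0(y$strain, "_", type),
          test = paste0("mann_whitney_", stat),
          statistic = mw$U, p = mw$p, computable = computable)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$signif <- !is.na(res$p) & res$p < alpha
  res
}
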