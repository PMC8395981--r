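#' Screen FEC against fragment homology across fragment lengths
#'
#' The main analysis: for every fragment length L and repeat-filter regime,
#' counts exact two-strand fragment matches between all section pairs,
#' normalizes them to FMF, and correlates FMF with the observed ectopic
#' contact frequencies (FEC) of one or more strains — the specific set (one
#' Spearman estimate per anchor section) and the unspecific control (one per
#' ordered section pair). Each condition is summarized by R (mean
#' significant rho) and P (proportion significant among valid estimates).
#'
#' @param sections An extracted `section_set` (see [extract_sections()]), or
#'   a `synth_genome` from [make_genome()].
#' @param fec A `fec_matrix`, or a named list of them (one per strain).
#' @param L Integer vector of fragment lengths (default 10-60 nt, step 5).
#' @param exclude_repeats Logical vector of filter regimes to run (default
#'   both off and on).
#' @param alpha Significance threshold for the P summaries.
#' @param chunk_size FMF normalization chunk in nt.
#' @param min_n Minimum sample size for a valid Spearman estimate.
#' @param unspecific Logical; compute the unspecific control (quadratic in
#'   the section count).
#' @param keep_catalogs Logical; retain the fragment catalog of each
#'   (L, filter) cell for downstream ranking (memory-hungry at large L).
#' @return An object of class `homology_screen` with components:
#'   \describe{
#'     \item{summary}{long data.frame: `strain`, `L`, `filter`, `type`, `R`,
#'       `R_se`, `P`, `P_se`, `n_signif`, `n_valid`.}
#'     \item{detail}{list of `corr_set` objects keyed by condition.}
#'     \item{grid}{condition index into `detail`.}
#'     \item{sig}{per-section significance table for the specific sets
#'       (sections x conditions, logical).}
#'     \item{fmf}{list of `fmf_matrix` objects keyed by `L<L>_filter<0|1>`.}
#'     \item{catalogs}{fragment catalogs (same keys), when requested.}
#'   }
#' @examples
#' \donttest{
#' g <- make_genome(synth_spec(n_sections = 8, section_length = 3000, seed = 7))
#' fec <- make_fec(g$truth)
#' scr <- homology_screen(g, fec, L = c(10, 15), unspecific = FALSE)
#' summary(scr)
#' }
#' @export
homology_screen <- function(sections, fec, L = seq(10L, 60L, 5L),
                            exclude_repeats = c(FALSE, TRUE), alpha = 0.05,
                            chunk_size = 10000, min_n = 5L,
                            unspecific = TRUE, keep_catalogs = FALSE) {
  if (inherits(sections, "synth_genome")) sections <- sections$sections
  stopifnot(inherits(sections, "section_set"))
  .require_sequences(sections)
  if (inherits(fec, "fec_matrix")) {
    fec <- stats::setNames(list(fec), fec$strain)
  }
  if (is.null(names(fec)))
    names(fec) <- vapply(fec, `[[`, character(1), "strain")
  types <- c("specific", if (unspecific) "unspecific")
  fmf_list <- list()
  catalogs <- list()
  detail <- list()
  grid <- list()
  summ <- list()
  for (filt in exclude_repeats) {
    for (l in L) {
      cfg <- match_config(l, exclude_repeats = filt)
      mt <- build_match_tables(sections, cfg, catalog = keep_catalogs)
      fm <- normalize_fmf(mt, chunk_size = chunk_size)
      key_lf <- sprintf("L%d_filter%d", l, as.integer(filt))
      fmf_list[[key_lf]] <- fm
      if (keep_catalogs) catalogs[[key_lf]] <- mt$catalog
      for (st in names(fec)) {
        for (ty in types) {
          cs <- if (ty == "specific") {
            specific_correlations(fec[[st]], fm, min_n = min_n)
          } else {
            unspecific_correlations(fec[[st]], fm, min_n = min_n)
          }
          key <- sprintf("%s_%s_%s", st, key_lf, ty)
          detail[[key]] <- cs
          grid[[length(grid) + 1L]] <-
            data.frame(strain = st, L = l, filter = filt, type = ty, key = key)
          summ[[length(summ) + 1L]] <-
            cbind(data.frame(strain = st, L = l, filter = filt, type = ty),
                  summarize_correlations(cs, alpha = alpha))
        }
      }
    }
  }
  grid <- do.call(rbind, grid)
  summary_df <- do.call(rbind, summ)
  rownames(summary_df) <- NULL
  # per-section significance of the specific sets (Fig.5-style output)
  spec_keys <- grid[grid$type == "specific", ]
  sig <- sapply(spec_keys$key, function(k) {
    cs <- detail[[k]]
    cs$valid & !is.na(cs$p) & cs$p < alpha
  })
  rownames(sig) <- sections$label
  structure(list(summary = summary_df, detail = detail, grid = grid,
                 sig = sig, fmf = fmf_list,
                 catalogs = if (keep_catalogs) catalogs,
                 sections = sections$label, alpha = alpha,
                 call = match.call()),
            class = "homology_screen")
}

#' @export
print.homology_screen <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<homology_screen> %d sections; strains: %s\n",
              length(x$sections), paste(unique(g$strain), collapse = ", ")))
  cat(sprintf("  L in {%s}; repeat filter: %s; types: %s; alpha = %g\n",
              paste(sort(unique(g$L)), collapse = ", "),
              paste(unique(g$filter), collapse = "/"),
              paste(unique(g$type), collapse = ", "), x$alpha))
  cat(sprintf("  %d conditions summarized; use summary() for the R/P table\n",
              nrow(x$summary)))
  invisible(x)
}

#' @export
summary.homology_screen <- function(object, digits = 3, ...) {
  df <- object$summary
  num <- c("R", "R_se", "P", "P_se")
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Plot R and P against fragment length
#'
#' Two base-graphics panels: mean significant rho (R) and proportion
#' significant (P) versus fragment length, one line per strain x filter x
#' correlation type.
#'
#' @param x A `homology_screen`.
#' @param ... Ignored.
#' @export
plot.homology_screen <- function(x, ...) {
  df <- x$summary
  df$cond <- interaction(df$strain, df$filter, df$type, drop = TRUE)
  Ls <- sort(unique(df$L))
  conds <- levels(df$cond)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (stat in c("R", "P")) {
    m <- sapply(conds, function(cd) {
      g <- df[df$cond == cd, ]
      g[[stat]][match(Ls, g$L)]
    })
    graphics::matplot(Ls, m, type = "b", pch = 16, lty = 1,
                      xlab = "fragment length L (nt)", ylab = stat,
                      main = stat)
    if (stat == "P") graphics::abline(h = x$alpha, col = "grey60", lty = 2)
    graphics::legend("topright", legend = conds, col = seq_along(conds),
                     lty = 1, pch = 16, cex = 0.7, bty = "n")
  }
  invisible(x)
}

#' Write the length-sweep summary as TSV
#'
#' Long format, one row per strain x L x filter x type condition; optionally
#' also the per-section significance table.
#'
#' @param x A `homology_screen`.
#' @param path Output path for the summary.
#' @param path_sig Optional output path for the per-section significance
#'   table.
#' @export
write_sweep <- function(x, path, path_sig = NULL) {
  stopifnot(inherits(x, "homology_screen"))
  utils::write.table(x$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(path_sig))
    utils::write.table(x$sig * 1L, path_sig, sep = "\t", quote = FALSE,
                       col.names = NA)
  invisible(x)
}

#' Sections with significant specific correlations
#'
#' Convenience accessor: the labels of sections whose specific FEC-FMF
#' correlation is significant under a given condition — the subsets that
#' feed [restrict_catalog()].
#'
#' @param x A `homology_screen`.
#' @param strain,L,filter Condition selectors.
#' @return Character vector of section labels.
#' @export
significant_sections <- function(x, strain, L, filter = FALSE) {
  stopifnot(inherits(x, "homology_screen"))
  key <- sprintf("%s_L%d_filter%d_specific", strain, L, as.integer(filter))
  if (!key %in% colnames(x$sig)) stop("no such condition: ", key)
  x$sections[x$sig[, key]]
}
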