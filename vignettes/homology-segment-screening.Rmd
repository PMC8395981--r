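---
title: "Screening ectopic-contact frequencies against fragment homology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening ectopic-contact frequencies against fragment homology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homseg)
```

## The measurement model

`homseg` asks whether the ectopic-contact frequencies (FEC) of polytene
chromosome sections can be predicted from exact sequence homology between
them. The unit of homology is a *fragment*: a window of length $L$
nucleotides slid with a step of 1 nt over a section's sequence. For a pair
of sections $(A, B)$ the raw match count $M(A,B)$ is the number of ordered
window-position pairs $(i, j)$ for which the window of $A$ at $i$ equals
the window of $B$ at $j$ either directly or as its reverse complement.
Three conventions pin the count down exactly:

* a palindromic fragment satisfies both orientations at once and is counted
  **once** — this keeps $M$ symmetric in $(A, B)$ and makes the bookkeeping
  below exact;
* windows containing `n` (including all non-ACGT codes, which are mapped to
  `n` on input with a warning) are never enumerated;
* with the repeat filter on, any window containing a run of at least four
  identical nucleotides, three identical dinucleotides or two identical
  trinucleotides — at any phase — is excluded *on both sides* of the
  comparison. These rules capture the bulk of microsatellite-driven
  matching; the motif-length ceiling of classical microsatellites (6 nt)
  is used separately, by the fragment classifier.

Internally each section is reduced to its *canonical fragment spectrum*:
windows are collapsed to the lexicographic minimum of the window and its
reverse complement, and counted. The match count is then the inner product
of two spectra. Per canonical class this equals the naive double-loop count
(for a non-palindromic class with forward counts $a_c, b_c$ and
reverse-complement counts $a_r, b_r$ the events are
$(a_c + a_r)(b_c + b_r)$; for a palindromic class $a_c b_c$), so the
strand-collapse gives the two-strand semantics for free. A naive
$O(|A||B|)$ oracle lives in the test suite and the equivalence is exercised
on a thousand random sequence pairs.

The same spectra define the *fragment catalog*: the number of occurrences
(NO) of a canonical fragment is the total count of match events attributed
to it across all section pairs, so that $\sum_f \mathrm{NO}(f)$ equals the
total match count — a conservation law the tests assert.

## FMF normalization

Raw counts scale with the product of section lengths, so they are first
converted to densities per $10\,\mathrm{kb} \times 10\,\mathrm{kb}$ of
sequence: $d(A,B) = M(A,B) / (w_A w_B)$ with $w_X = \mathrm{len}(X) /
10^4$, real-valued (no rounding to whole chunks, which would create
discontinuities for short sections). Densities are then rescaled by a
single global constant so that the mean over all unordered section pairs is
exactly 1; the stated mean-one convention fixes the scale, while the
per-pair density corrects for unequal section lengths. The phrase "average
per 10-kb chunk equals one" admits more than one reading (per-chunk vs
per-pair averaging); the per-pair reading implemented here reproduces the
stated property exactly and is isolated in a single function
(`normalize_fmf()`), so an alternative convention would be a one-line
change. Because every downstream statistic is rank-based, the global
constant is irrelevant to the correlations — a property the tests verify by
rescaling. If no pair has any match (routine at $L \gtrsim 25$ on
non-repetitive sequence), the FMF matrix is all zero and flagged; such
conditions produce invalid correlation estimates rather than zeros.

## Correlation screening

For anchor section $A$, the specific estimate correlates
$\mathrm{FEC}(A, B)$ with $\mathrm{FMF}(A, B)$ over the $N - 1$ partners
$B \neq A$; the unspecific control correlates $\mathrm{FEC}(A, \cdot)$ with
$\mathrm{FMF}(B, \cdot)$, $B \neq A$, over the $N - 2$ common partners, so
both vectors always describe the same partner set. Self-pairs are excluded
throughout: both matrices have an undefined (zero) diagonal, so a
per-section sample size of $N - 1$ is used even where the source screening
design quotes the full section count; the difference is one rank pair and
does not move any conclusion.

Spearman rho is computed as the Pearson correlation of midranks (FEC values
are small integers; ties are the norm, and midranks are the standard
convention), with a two-sided p-value from the $t$ approximation on
$n - 2$ degrees of freedom. An estimate is *invalid* when $n <$ `min_n`
(default 5 — below that the $t$ approximation is meaningless, and the
smallest zone analysed at $D = 10$ still gives $n = 9$) or when either
vector is constant, the typical case being an all-zero FMF row. Invalid
estimates are excluded from the denominators; this is why "no signal"
manifests as few valid estimates rather than as a pile of $p = 1$ values.
P-values are deliberately *not* multiple-testing corrected — the screening
convention is the raw $p < 0.05$ count, whose null behaviour is itself a
calibration check (see below) — but `summarize_correlations()` accepts a
`p.adjust` method for users who want it.

Per condition (strain × $L$ × filter × type) the summaries are $R$, the
mean rho over significant estimates (standard error $s/\sqrt{n}$), and
$P$, the significant fraction among valid estimates (binomial standard
error). `homology_screen()` runs the grid — default $L = 10, 15, \dots,
60$ nt, both filter regimes, both correlation types, any number of strains
— and returns a classed object with `print`, `summary` and `plot` methods
plus the per-section significance table that identifies *which* sections
carry the signal.

## Distance zones

Ectopic contacts form preferentially between nearby sections, so the
screen can be restricted to sliding zones of $D$ consecutive sections
(`zone_sweep()`): specific anchors and their partners both inside the zone
($n = D - 1$), unspecific pairs entirely inside ($n = D - 2$), one R/P
quadruple per zone, and per $D$ the across-zone samplings plus the
difference curves $R_\mathrm{DIFF} = \bar R_\mathrm{SP} - \bar
R_\mathrm{UN}$ and $P_\mathrm{DIFF}$ analogously. The window step is 1
section (the natural dense choice; configurable), giving $N - D + 1$ zones.
Zones in which every estimate is invalid contribute missing values and are
excluded from the per-$D$ means rather than recorded as zeros — at large
$L$ whole zones are routinely FMF-silent and zero-filling would bias the
curves. At $D = N$ the single zone reproduces the whole-chromosome
summaries exactly, which the tests assert as a consistency limit.

## Comparison layer

$R$ samplings are compared with the two-sided Mann-Whitney U test (exact
enumeration when both groups have at most 8 tie-free values, otherwise the
normal approximation with midrank tie correction), $P$ values with the 2×2
chi-square test for two proportions without continuity correction (the
plain chi-square named by the screening design; Yates correction is
available as a flag). The Mann-Whitney samplings use *all valid* rho values
of a condition, not only the significant ones, matching how the R samplings
are defined; `compare_all()` varies exactly one factor per contrast and
additionally contrasts every $L$ against the $L = 50$ reference within each
condition. Both tests are cross-checked in the suite against exact
enumeration and the hand-computed $\sum (O - E)^2 / E$ formula, and hold
their nominal type-I error in simulation.

## Fragment ranking

`rank_fragments()` orders the catalog by decreasing NO, drops
$\mathrm{NO} \le 10$, keeps a single fragment per NO value and truncates to
the top 50. Two details are deliberate choices where the procedure is
underdetermined: the equal-NO tie keeps the lexicographically smallest
canonical fragment ("the first" of an unspecified order made
deterministic), and NO counts *match events* (position pairs), not genome
occurrences — the former obeys the conservation law and is therefore
testable. `restrict_catalog()` recomputes NO for a section subset,
counting an event when **at least one** of its two sections is a member
(the subset is typically the anchors of significant specific correlations,
and the anchor is what the subset defines); requiring both members is
available via `mode = "both"`. Classification beyond microsatellites
(satellite families, genes, transposons) requires an external homology
search; the package exports the ranking as FASTA and merges a user-supplied
annotation table, assigning `other/unknown` to the rest.

## The synthetic generator, and what the tests do and do not show

`synth_spec()`/`make_genome()`/`make_fec()` emulate the screening setting
in miniature: i.i.d. background bases at 43% GC (the Drosophila-like
default), tandem arrays of satellite monomers (default 359 nt — the length
scale of the classic X-chromosome satellite repeat units — at 10 copies)
planted into chosen sections at uniform non-overlapping offsets, and
independent Poisson contact counts per pair with intensity $\lambda_0 +
\lambda_1 \cdot \mathrm{shared}(A,B)$. Poisson is the minimal model for
small non-negative counts aggregated over hundreds of nuclei and produces
the heavily tied, zero-inflated matrices the rank machinery must tolerate.
Default study conditions used by the validation suite: 20 sections of
50 kb, one monomer shared by 4 sections, $\lambda_0 = 1$, $\lambda_1 = 10$.

Two quantitative properties anchor the validation. *Null calibration*:
with $\lambda_1 = 0$ the contacts are independent of the sequence, and
across 100 replicate genomes (2000 section-level tests; 20 sections × 20 kb
at $L = 10$, where random matching keeps every estimate valid) the fraction
of specific tests with $p < 0.05$ must sit inside the 95% binomial band
around 0.05. *Planted recovery*: across 50 replicates of the default
planted fixture at $L = 50$, at least 90% of planted sections must be
flagged (in practice all are, with rho ≈ 0.65), while non-planted sections
stay at or below the nominal rate — at $L = 50$ their FMF rows are all
zero, so they are invalid rather than falsely significant.

What this does *not* show: real chromatin is not i.i.d. sequence plus clean
tandem arrays — dispersed repeats, transposons, under-replication of
intercalary heterochromatin and correlated contact scoring are all absent.
Passing the synthetic suite certifies the *machinery* (counting,
normalization, calibration, recovery of a known signal), not any biological
conclusion about real chromosomes.

## Numerical and scale choices

* Coordinates are 0-based half-open everywhere (BED arithmetic).
* Character collation for the canonical collapse is plain byte order over
  `{a,c,g,t}`, locale-independent in practice.
* Exact matching only: the counting model has no mismatch tolerance, and
  none is planned — approximate matching changes the statistic itself.
* One chromosome per run; multi-record FASTA files need a record selector.
* Determinism: a spec seed fixes the genome byte-for-byte; the FEC draw
  uses its own derived seed so sequence and contacts can be varied
  independently.
* Problem sizes in the shipped tests (sections × length, replicates) were
  chosen so the full suite exercises every property at the default study
  conditions while staying desk-scale: the two heavy blocks are the
  100-replicate null calibration and the 50-replicate planted recovery.
  The real-data scale (119 sections, ~23 Mb, $L$ up to 60, dense $D$
  sweeps with unspecific controls) is supported by the same code paths but
  takes hours, exactly as the original screening design reports; the
  unspecific zone sweep is the quadratic hot spot and can be disabled
  per run.

## Known limitations

* The unspecific zone sweep at dense $D$ is $O(\sum_D (N-D) D^2)$ Spearman
  fits; for exploratory work restrict `D` or set `unspecific = FALSE`.
* FMF is a whole-section summary; sub-section (per-chunk) homology maps are
  out of scope.
* The catalog holds canonical fragments as character keys; at $L = 50$ on
  tens of megabases it is memory-hungry — `build_match_tables(catalog =
  FALSE)` and `homology_screen(keep_catalogs = FALSE)` (the default) avoid
  the cost when only counts are needed.
* Significance is reported on raw p-values by design; interpret $P$ as a
  screening rate against its null calibration, not as a family-wise claim.
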