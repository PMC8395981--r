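test_that("Mann-Whitney handles identical, separated and swapped samplings", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  sep <- mann_whitney_u(c(1, 2, 3), c(101, 102, 103))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 0.1)  # exact enumeration over C(6,3) = 20 assignments
  expect_equal(mann_whitney_u(c(101, 102, 103), c(1, 2, 3))$p, sep$p)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("Mann-Whitney agrees with exact enumeration on small tie-free samples", {
  set.seed(24)
  for (i in 1:30) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    repeat {
      x <- round(rnorm(n, sd = 10), 3); y <- round(rnorm(m, sd = 10), 3)
      if (!anyDuplicated(c(x, y))) break
    }
    got <- mann_whitney_u(x, y)
    expect_equal(got$p, mw_exact_oracle(x, y), tolerance = 1e-10,
                 info = paste("rep", i))
    expect_equal(got$U, sum(outer(x, y, ">")))
  }
})

test_that("large-sample Mann-Whitney matches the tie-corrected reference", {
  set.seed(25)
  for (i in 1:30) {
    x <- rpois(sample(10:40, 1), 3)
    y <- rpois(sample(10:40, 1), 4)
    got <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  # degenerate constant pooled sample
  expect_equal(mann_whitney_u(rep(2, 5), rep(2, 7))$p, 1)
})

test_that("two-proportion chi-square matches the hand-computed 2x2 formula", {
  got <- chisq_two_proportions(30, 100, 10, 100)
  ora <- chisq_oracle(30, 100, 10, 100)
  expect_equal(got$statistic, ora$statistic, tolerance = 1e-12)
  expect_equal(got$p, ora$p, tolerance = 1e-12)

  expect_equal(chisq_two_proportions(5, 50, 2, 20)$statistic, 0)
  expect_equal(chisq_two_proportions(5, 50, 2, 20)$p, 1)

  swap <- chisq_two_proportions(10, 100, 30, 100)
  expect_equal(swap$statistic, got$statistic)
  expect_error(chisq_two_proportions(1, 0, 2, 10), "at least 1")
  expect_error(chisq_two_proportions(11, 10, 2, 10), "out of range")

  set.seed(26)
  for (i in 1:50) {
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    if (k1 / n1 == k2 / n2) next
    if (k1 + k2 == 0 || k1 + k2 == n1 + n2) next
    got <- chisq_two_proportions(k1, n1, k2, n2)
    ora <- chisq_oracle(k1, n1, k2, n2)
    expect_equal(got$statistic, ora$statistic, tolerance = 1e-8)
    expect_equal(got$p, ora$p, tolerance = 1e-6)
  }
})

test_that("both tests hold their nominal type-I error under the null", {
  set.seed(27)
  reps <- 2000
  mw_hits <- 0; chi_hits <- 0
  for (i in 1:reps) {
    if (mann_whitney_u(rnorm(15), rnorm(15))$p < 0.05) mw_hits <- mw_hits + 1
    k1 <- rbinom(1, 60, 0.3); k2 <- rbinom(1, 60, 0.3)
    if (chisq_two_proportions(k1, 60, k2, 60)$p < 0.05) chi_hits <- chi_hits + 1
  }
  ci <- 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mw_hits / reps - 0.05), ci + 0.01)
  expect_lt(abs(chi_hits / reps - 0.05), ci + 0.015)  # discreteness slack
})

test_that("compare_all contrasts one factor at a time across a screen", {
  set.seed(28)
  ss <- toy_sections(replicate(7, random_dna(250)))
  fec_a <- random_fec(ss$label, lambda = 3, strain = "wild")
  fec_b <- random_fec(ss$label, lambda = 3, strain = "mutant")
  scr <- homology_screen(ss, list(wild = fec_a, mutant = fec_b),
                         L = c(3, 50) * 1L, exclude_repeats = c(FALSE, TRUE),
                         unspecific = TRUE, min_n = 4)
  cmp <- compare_all(scr)
  expect_true(all(cmp$varied %in% c("strain", "type", "filter", "L")))
  expect_true(all(cmp$test %in% c("mann_whitney_R", "chisq_P")))
  # every one-factor contrast appears twice (R and P rows)
  n_strain <- sum(cmp$varied == "strain")
  expect_equal(n_strain, 2 * 2 * 2 * 2)  # types x filters x Ls x {R,P}
  # identical inputs -> p = 1 everywhere
  scr_same <- homology_screen(ss, list(a = fec_a, b = fec_a), L = 3L,
                              exclude_repeats = FALSE, unspecific = FALSE,
                              min_n = 4)
  cmp_same <- compare_all(scr_same)
  strain_rows <- cmp_same[cmp_same$varied == "strain" & cmp_same$computable, ]
  expect_true(all(strain_rows$p == 1))
})

test_that("compare_all on zone sweeps tests each (L, D) cell independently", {
  set.seed(29)
  ss <- toy_sections(replicate(9, random_dna(300)))
  mt <- build_match_tables(ss, match_config(3), catalog = FALSE)
  fm <- normalize_fmf(mt)
  fec_a <- random_fec(ss$label, lambda = 3, strain = "wild")
  fec_b <- random_fec(ss$label, lambda = 3, strain = "mutant")
  zs_a <- zone_sweep(fec_a, fm, D = c(6, 7), min_n = 4)
  zs_b <- zone_sweep(fec_b, fm, D = c(6, 7), min_n = 4)
  cmp <- compare_all(zs_a, zs_b)
  expect_true(all(cmp$L == 3))
  expect_setequal(unique(cmp$D), c(6, 7))
  expect_true(all(cmp$test %in% c("mann_whitney_R", "mann_whitney_P")))
  # self-comparison rows are p = 1 on computable cells
  cmp_self <- compare_all(zs_a, zs_a)
  self_rows <- cmp_self[cmp_self$varied == "sweep" & cmp_self$computable, ]
  expect_true(all(self_rows$p == 1))
})
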