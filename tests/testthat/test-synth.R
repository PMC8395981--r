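test_that("genome generation is deterministic and respects the layout", {
  spec <- synth_spec(n_sections = 6, section_length = 3000, gc_content = 0.4,
                     monomers = list(list(length = 100, copies = 4,
                                          sections = c(2, 4))),
                     seed = 33)
  g1 <- make_genome(spec)
  g2 <- make_genome(spec)
  expect_identical(g1$chrom$sequence, g2$chrom$sequence)
  expect_equal(nchar(g1$chrom$sequence), 6 * 3000)
  expect_equal(nrow(g1$sections), 6)
  expect_equal(unique(nchar(g1$sections$sequence)), 3000)
  expect_equal(g1$truth$shared[2, 4], 1L)
  expect_equal(sum(g1$truth$shared), 2L)  # one symmetric sharing pair
  expect_equal(g1$truth$lambda[2, 4],
               spec$fec_baseline + spec$fec_coupling)
  expect_equal(g1$truth$lambda[1, 3], spec$fec_baseline)

  g3 <- make_genome(synth_spec(n_sections = 6, section_length = 3000,
                               gc_content = 0.4, seed = 34))
  expect_false(identical(g1$chrom$sequence, g3$chrom$sequence))
})

test_that("a pure random genome has essentially no long-fragment matches", {
  g <- make_genome(synth_spec(n_sections = 5, section_length = 4000, seed = 35))
  mt <- build_match_tables(g$sections, match_config(50), catalog = FALSE)
  expect_true(all(mt$counts == 0))
})

test_that("planted tandem arrays guarantee the geometric match lower bound", {
  copies <- 5; mlen <- 359; L <- 50
  spec <- synth_spec(n_sections = 4, section_length = 10000,
                     monomers = list(list(length = mlen, copies = copies,
                                          sections = c(1, 3))),
                     seed = 36)
  g <- make_genome(spec)
  mt <- build_match_tables(g$sections, match_config(L), catalog = FALSE)
  # identical arrays of (copies * mlen) nt: every window of one array
  # reappears in the other at all phase-compatible offsets; the coarse
  # per-copy bound is copies^2 * (mlen - L + 1)
  expect_gte(mt$counts[1, 3], copies^2 * (mlen - L + 1))
  expect_equal(mt$counts[1, 2], 0)

  # oversized insertion is rejected
  expect_error(make_genome(synth_spec(n_sections = 3, section_length = 1000,
                                      monomers = list(list(length = 359,
                                                           copies = 5,
                                                           sections = 1)),
                                      seed = 1)),
               "exceeds section length")
})

test_that("simulated FEC follows the coupled Poisson intensities", {
  spec <- synth_spec(n_sections = 10, section_length = 1000,
                     monomers = list(list(length = 50, copies = 2,
                                          sections = c(1, 2))),
                     fec_baseline = 2, fec_coupling = 8, seed = 37)
  g <- make_genome(spec)
  f1 <- make_fec(g$truth, seed = 100)
  f2 <- make_fec(g$truth, seed = 100)
  expect_identical(f1$counts, f2$counts)
  expect_identical(f1$counts, t(f1$counts))

  # Monte-Carlo mean vs closed-form intensity
  sims <- sapply(1:400, function(i) {
    fc <- make_fec(g$truth, seed = 1000 + i)
    c(fc$counts[1, 2], fc$counts[3, 4])
  })
  m_coupled <- mean(sims[1, ]); m_base <- mean(sims[2, ])
  expect_lt(abs(m_coupled - 10), 3 * sqrt(10 / 400))
  expect_lt(abs(m_base - 2), 3 * sqrt(2 / 400))

  # lambda0 = 0 with large coupling: contacts only between sharing pairs
  spec0 <- synth_spec(n_sections = 6, section_length = 500,
                      monomers = list(list(length = 40, copies = 2,
                                           sections = c(2, 5))),
                      fec_baseline = 0, fec_coupling = 20, seed = 38)
  g0 <- make_genome(spec0)
  f0 <- make_fec(g0$truth)
  nonzero <- which(f0$counts > 0, arr.ind = TRUE)
  expect_true(all(g0$truth$shared[nonzero] == 1L))
})

test_that("fixtures round-trip through every reader and reproduce by seed", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- synth_spec(n_sections = 5, section_length = 2000,
                     monomers = list(list(length = 80, copies = 3,
                                          sections = c(1, 4))),
                     seed = 39)
  fx1 <- write_fixture(spec, dir1)
  fx2 <- write_fixture(spec, dir2)
  for (f in c("chromosome.fa", "sections.tsv", "fec.tsv", "truth.tsv",
              "manifest.tsv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
  chrom <- read_fasta(file.path(dir1, "chromosome.fa"))
  ss <- extract_sections(chrom, read_section_table(file.path(dir1, "sections.tsv")))
  expect_identical(ss$sequence, fx1$genome$sections$sequence)
  fec <- read_fec(file.path(dir1, "fec.tsv"), sections = ss)
  expect_identical(fec$counts, fx1$fec$counts)
  truth <- read.delim(file.path(dir1, "truth.tsv"))
  expect_equal(nrow(truth), choose(5, 2))
  expect_true(all(truth$shared %in% 0:1))
  expect_equal(sum(truth$shared), 1)
})
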