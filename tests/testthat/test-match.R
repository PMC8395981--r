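test_that("revcomp complements, reverses, and is an involution", {
  expect_identical(revcomp("acgt"), "acgt")  # palindrome
  expect_identical(revcomp("aac"), "gtt")
  expect_identical(revcomp(revcomp("gattaca")), "gattaca")
  expect_error(revcomp("acgn"), "\\{a,c,g,t\\}")
  set.seed(1)
  frs <- replicate(50, random_dna(sample(2:30, 1)))
  expect_identical(revcomp(revcomp(frs)), frs)
  expect_identical(revcomp(frs), rc_oracle(frs))
})

test_that("simple-repeat rules flag runs at any phase", {
  expect_true(is_simple_repeat("caaaag"))       # internal aaaa run
  expect_true(is_simple_repeat("gatatatc"))     # atatat
  expect_true(is_simple_repeat("acgacgt"))      # acgacg
  expect_false(is_simple_repeat("acgtacgt"))    # unit length 4 not covered
  expect_false(is_simple_repeat("aaat"))        # run of 3 < 4
  expect_false(is_simple_repeat("gattaca"))
  # strand symmetry: a fragment and its reverse complement flag together
  set.seed(2)
  frs <- replicate(300, random_dna(sample(6:20, 1)))
  expect_identical(is_simple_repeat(frs), is_simple_repeat(revcomp(frs)))
})

test_that("fragment enumeration slides 1 nt and applies the filters", {
  cfg <- match_config(4)
  fr <- enumerate_fragments("acgta", cfg)
  expect_identical(fr$offset, c(0L, 1L))
  expect_identical(fr$fragment, c("acgt", "cgta"))

  expect_identical(nrow(enumerate_fragments("acnta", cfg)), 0L)
  expect_identical(nrow(enumerate_fragments("aaaaa", match_config(4, TRUE))), 0L)
  expect_identical(nrow(enumerate_fragments("acg", cfg)), 0L)  # shorter than L

  # unfiltered window count is len - L + 1
  set.seed(3)
  s <- random_dna(100)
  expect_identical(nrow(enumerate_fragments(s, match_config(7))), 94L)
})

test_that("pair match counting matches hand-derived toy cases", {
  expect_equal(count_pair_matches("aaaa", "aaaa", match_config(2))$count, 9)
  expect_equal(count_pair_matches("at", "at", match_config(2))$count, 1)
  expect_equal(count_pair_matches("acg", "cgt", match_config(3))$count, 1)
  expect_equal(count_pair_matches("acgt", "tttt", match_config(4))$count, 0)
})

test_that("fast counting equals the naive oracle on random pairs", {
  set.seed(4)
  for (rep in 1:60) {
    L <- sample(2:12, 1)
    a <- random_dna(sample(20:200, 1), gc = runif(1, 0.3, 0.7))
    b <- random_dna(sample(20:200, 1), gc = runif(1, 0.3, 0.7))
    filt <- rep %% 2 == 0
    expect_equal(count_pair_matches(a, b, match_config(L, filt))$count,
                 count_oracle(a, b, L, filt),
                 info = sprintf("rep %d L %d filt %s", rep, L, filt))
  }
})

test_that("counts are symmetric, orientation-invariant and L/filter monotone", {
  set.seed(6)
  for (rep in 1:25) {
    L <- sample(2:8, 1)
    a <- random_dna(sample(30:120, 1))
    b <- random_dna(sample(30:120, 1))
    cfg <- match_config(L)
    c_ab <- count_pair_matches(a, b, cfg)$count
    expect_equal(c_ab, count_pair_matches(b, a, cfg)$count)
    expect_equal(c_ab, count_pair_matches(a, revcomp(b), cfg)$count)
    expect_gte(c_ab, count_pair_matches(a, b, match_config(L + 1L))$count)
    expect_gte(c_ab, count_pair_matches(a, b, match_config(L, TRUE))$count)
  }
})

test_that("match tables are symmetric with the NO conservation law", {
  ss <- toy_sections(c("aaaa", "aaaa", "cccc"))
  mt <- build_match_tables(ss, match_config(2))
  expect_equal(mt$counts[1, 2], 9)
  expect_equal(mt$counts[1, 3], 0)
  expect_equal(mt$counts[2, 3], 0)
  expect_equal(unname(mt$catalog$no["aa"]), 9)

  # random sections: symmetry, zero diagonal, conservation
  set.seed(7)
  ss2 <- toy_sections(replicate(5, random_dna(sample(80:150, 1))))
  mt2 <- build_match_tables(ss2, match_config(3))
  expect_identical(mt2$counts, t(mt2$counts))
  expect_true(all(diag(mt2$counts) == 0))
  expect_equal(sum(mt2$catalog$no), sum(mt2$counts[upper.tri(mt2$counts)]))

  # permuting section order permutes counts identically
  perm <- c(3, 1, 5, 2, 4)
  ss3 <- toy_sections(ss2$sequence[perm], labels = ss2$label[perm])
  mt3 <- build_match_tables(ss3, match_config(3), catalog = FALSE)
  labs <- ss2$label
  expect_equal(mt3$counts[labs, labs], mt2$counts[labs, labs])

  # homopolymeric sections under the filter: everything excluded
  ss4 <- toy_sections(c("aaaaaaaa", "aaaaaaaa", "tttttttt"))
  mt4 <- build_match_tables(ss4, match_config(4, exclude_repeats = TRUE))
  expect_true(all(mt4$counts == 0))
  expect_error(build_match_tables(ss4[1, ], match_config(2)))
})

test_that("per-pair fragment lists are recoverable and consistent", {
  set.seed(8)
  ss <- toy_sections(replicate(4, random_dna(120)))
  mt <- build_match_tables(ss, match_config(3))
  pf <- pair_fragments(mt, "S01", "S02")
  expect_equal(sum(pf$count), mt$counts["S01", "S02"])
  direct <- count_pair_matches(ss$sequence[1], ss$sequence[2], match_config(3))
  expect_equal(sort(unname(direct$fragments[pf$fragment])), sort(pf$count))
  expect_error(pair_fragments(mt, "S01", "nope"), "unknown")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pair_fragments(mt, tsv)
  back <- read.delim(tsv)
  expect_equal(sum(back$count), sum(mt$counts[upper.tri(mt$counts)]))
})

test_that("microsatellite classification finds the shortest repeating motif", {
  expect_identical(classify_microsatellite("atatatatat"), "at")
  expect_identical(classify_microsatellite("tcccagtcccagtcccag"), "tcccag")
  expect_identical(classify_microsatellite("gattacagatt"), NA_character_)
  expect_identical(classify_microsatellite("aaaaaa"), "a")
  # exhaustive cross-check on random fragments: motif found iff some prefix
  # motif of length <= 6 tiles the fragment
  set.seed(9)
  for (i in 1:100) {
    f <- random_dna(sample(4:14, 1))
    got <- classify_microsatellite(f)
    tiles <- function(m) {
      substr(strrep(m, ceiling(nchar(f) / nchar(m))), 1, nchar(f)) == f
    }
    cands <- vapply(seq_len(min(6, nchar(f) - 1)),
                    function(m) tiles(substr(f, 1, m)), logical(1))
    if (any(cands)) {
      expect_identical(got, substr(f, 1, which(cands)[1]))
    } else {
      expect_identical(got, NA_character_)
    }
  }
})
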