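# Alignment summaries: pairwise distances, allele counting, theta_pi.

test_that("pairwise distance counts differing positions", {
  expect_identical(pairwise_dist("ACGT", "ACGT"), 0L)
  expect_identical(pairwise_dist("ACGT", "ACGA"), 1L)
  expect_identical(pairwise_dist("acgt", "ACGA"), 1L)   # case-insensitive
  expect_identical(pairwise_dist("ACGU", "ACGT"), 0L)   # U treated as T
  expect_identical(pairwise_dist("ACGT", "TGCA"), 4L)
  # symmetry
  expect_identical(pairwise_dist("AAGT", "ACGT"), pairwise_dist("ACGT", "AAGT"))
})

test_that("comparison policies handle non-ACGT characters", {
  expect_identical(pairwise_dist("AC-T", "ACGT"), 0L)             # gap skipped
  expect_identical(pairwise_dist("ACNT", "ACGA", policy = "pairwise-deletion"), 1L)
  expect_error(pairwise_dist("AC-T", "ACGT", policy = "strict"), "non-ACGT")
  expect_error(pairwise_dist("ACG", "ACGT"), "length")
})

test_that("theta_pi follows the selected denominator convention", {
  two <- c(x = "AAATTTGG", y = "AAATTTCC")  # 2 diffs... check: positions 7,8
  s_paper <- summarize_alignment(two, convention = "paper")
  expect_equal(s_paper$theta_pi, 2 * 2 / (2 * 3))
  s_taj <- summarize_alignment(two, convention = "tajima")
  expect_equal(s_taj$theta_pi, 2 * 2 / (2 * 1))
  # three differing sites between a single pair, as a direct read of the formula
  three <- c(x = "AAATTT", y = "AACTCC")
  expect_equal(summarize_alignment(three, convention = "paper")$theta_pi, 1.0)
  expect_equal(summarize_alignment(three, convention = "tajima")$theta_pi, 3.0)
})

test_that("allele count is the number of distinct full-length sequences", {
  four <- c(a = "ACGT", b = "ACGT", c = "AGGT", d = "AGGT")
  expect_identical(summarize_alignment(four)$m, 2L)
  # gap characters participate in identity
  gapped <- c(a = "AC-T", b = "ACGT")
  expect_identical(summarize_alignment(gapped)$m, 2L)
  # case and U/T normalisation collapse alleles
  mixed <- c(a = "ACGT", b = "acgu")
  expect_identical(summarize_alignment(mixed)$m, 1L)
})

test_that("summary is invariant to reordering and invariant columns", {
  aln <- example_alignment()
  s1 <- summarize_alignment(aln)
  s2 <- summarize_alignment(rev(aln))
  expect_equal(s1$theta_pi, s2$theta_pi)
  expect_identical(s1$m, s2$m)
  # appending an identical (invariant) column changes L only
  longer <- vapply(aln, function(s) paste0(s, "G"), character(1))
  s3 <- summarize_alignment(longer)
  expect_equal(s3$theta_pi, s1$theta_pi)
  expect_identical(s3$m, s1$m)
  expect_identical(s3$L, s1$L + 1L)
  expect_lte(s1$m, s1$n)
})

test_that("FASTA round trip through the reader", {
  path <- write_fasta(example_alignment(), tempfile(fileext = ".fasta"))
  tbl <- read_alignment(path)
  expect_identical(nrow(tbl), 5L)
  expect_identical(tbl$sequence[1], "ACGTACGT")
  s <- summarize_alignment(tbl)
  expect_identical(s$n, 5L)
  expect_identical(s$m, 3L)
  expect_identical(s$L, 8L)
  # 10 pairs; diffs: a1-a3 1, a1-a4 2, a2-a3 1, a2-a4 2, a3-a4 1, a5 same as a1/a2
  # pairs with a5: a5-a3 1, a5-a4 2 -> total = 1+2+1+2+1+1+2 = 10
  expect_equal(s$theta_pi, 2 * 10 / (5 * 6))
})

test_that("degenerate and malformed alignments are reported", {
  expect_error(summarize_alignment(c(a = "ACGT")), "at least 2")
  expect_error(summarize_alignment(c(a = "ACGT", b = "ACG")), "equal length")
  expect_warning(summarize_alignment(c(a = "ACGT", a = "ACGA")), "duplicate")
  expect_error(alignment_fs(c(a = "ACGT", b = "ACGT")), "identical")
})

test_that("alignment_fs chains the summary into the statistic", {
  res <- alignment_fs(example_alignment())
  expect_identical(res$n, 5L)
  expect_identical(res$m, 3L)
  ref <- fu_fs(5, 3, res$theta_pi)
  expect_equal(res$fs, ref$fs, tolerance = 1e-12)
})
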