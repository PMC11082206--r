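make_cnv <- function(ratio, chrom = "chr1", n = 200, bin = 5000) {
  starts <- seq(0, by = bin, length.out = n)
  cnv_profile(tibble::tibble(chrom = chrom, start = starts, end = starts + bin,
                             ratio = ratio))
}

one_sv <- function(sign1, sign2, pos1 = 1e5, pos2 = 5e5, type = "unclassified") {
  sv_records(tibble::tibble(chrom1 = "chr1", pos1 = pos1, chrom2 = "chr1",
                            pos2 = pos2, sign1 = sign1, sign2 = sign2,
                            sv_type = type))
}

test_that("orientation plus copy-ratio thresholds drive dup/del calls", {
  expect_equal(classify_intra_sv(one_sv("+", "-"), make_cnv(0.5)), "deletion")
  expect_equal(classify_intra_sv(one_sv("-", "+"), make_cnv(2.0)), "duplication")
  expect_equal(classify_intra_sv(one_sv("+", "+"), make_cnv(2.0)), "duplication")
  expect_equal(classify_intra_sv(one_sv("-", "-"), make_cnv(2.0)), "duplication")
  expect_equal(classify_intra_sv(one_sv("+", "-"), make_cnv(1.0)), "unclassified")
  # ratios at the thresholds are strict
  expect_equal(classify_intra_sv(one_sv("-", "+"), make_cnv(1.35)), "unclassified")
  expect_equal(classify_intra_sv(one_sv("+", "-"), make_cnv(0.65)), "unclassified")

  inter <- sv_records(tibble::tibble(chrom1 = "chr1", pos1 = 1, chrom2 = "chr2",
                                     pos2 = 1, sign1 = "+", sign2 = "-"))
  expect_error(classify_intra_sv(inter, make_cnv(1)), "intrachromosomal")
})

test_that("shuffled nulls preserve span and chromosome, and are uniform", {
  genome <- tibble::tibble(chrom = c("chrS1", "chrS2"), length = c(1e7, 1e7))
  svs <- sv_records(tibble::tibble(
    chrom1 = c("chrS1", "chrS1"), pos1 = c(2e6, 4e6),
    chrom2 = c("chrS1", "chrS2"), pos2 = c(3e6, 1e6),
    sign1 = "+", sign2 = "-", sv_type = c("deletion", "translocation")
  ))
  nulls <- shuffle_svs(svs, genome, n_sets = 50, seed = 7)
  expect_length(nulls, 50)
  for (x in nulls) {
    expect_equal(x$pos2[1] - x$pos1[1], 1e6)          # span preserved exactly
    expect_equal(x$chrom1, svs$chrom1)                # chromosomes preserved
    expect_equal(x$chrom2, svs$chrom2)
  }

  # uniform placement: chi-square on the position histogram of 1000 nulls
  one <- svs[1, ]
  nl <- shuffle_svs(one, genome, n_sets = 1000, seed = 3)
  pos <- vapply(nl, function(x) x$pos1, numeric(1))
  h <- table(cut(pos, breaks = seq(0, 9e6, length.out = 10)))
  expect_gt(stats::chisq.test(h)$p.value, 0.01)

  too_big <- sv_records(tibble::tibble(chrom1 = "chrS1", pos1 = 0, chrom2 = "chrS1",
                                       pos2 = 2e7, sign1 = "+", sign2 = "-"))
  expect_error(shuffle_svs(too_big, genome), "exceeds")
})

test_that("Benjamini-Yekutieli adjustment matches a hand-rolled step-up", {
  expect_equal(adjust_by(0.03), 0.03)                # H(1) = 1
  expect_equal(adjust_by(rep(1, 5)), rep(1, 5))

  # hand-computed: p = (.01, .02, .03), H(3) = 11/6 -> all q = 0.055
  expect_equal(adjust_by(c(0.01, 0.02, 0.03)), rep(0.055, 3), tolerance = 1e-12)

  set.seed(12)
  for (k in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(adjust_by(p), brute_force_by(p), tolerance = 1e-12)
  }
  expect_error(adjust_by(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("enrichment ranks are uniform when real equals null", {
  genome <- tibble::tibble(chrom = "chrS1", length = 1e7)
  prop <- random_property_track(genome, seed = 21)
  svs <- make_sv_set(synthetic_spec(seed = 31, genome = genome), 20)$svs
  # real identical to a duplicated null set: nothing to detect
  res <- breakpoint_enrichment(svs, list(svs, svs), prop, side_seed = 2)
  expect_gt(res$p_value, 0.05)
  expect_true(res$statistic >= 0 && res$statistic <= 1)
  expect_error(breakpoint_enrichment(svs[0, ], list(svs), prop), "empty")
})

test_that("loop matching honours the strict 50 kbp midpoint rule", {
  loops <- tibble::tibble(
    chrom1 = "chr1", start1 = c(1e5, 3e5), end1 = c(1.1e5, 3.1e5),
    chrom2 = "chr1", start2 = c(6e5, 8e5), end2 = c(6.1e5, 8.1e5)
  )
  expect_equal(nrow(match_loops(loops, loops)), 2)

  shift <- function(x, by) dplyr::mutate(x, start1 = start1 + by, end1 = end1 + by)
  expect_equal(nrow(match_loops(loops, shift(loops, 50000))), 0)   # = tol: no
  expect_equal(nrow(match_loops(loops, shift(loops, 49999))), 2)   # < tol: yes
  expect_equal(nrow(match_loops(loops, shift(loops, 10000))), 2)

  # greedy matching is one-to-one
  dup_b <- dplyr::bind_rows(loops, shift(loops, 1000))
  m <- match_loops(loops, dup_b)
  expect_equal(nrow(m), 2)
  expect_equal(anyDuplicated(m$b_index), 0)
})

test_that("Jaccard similarity follows the matched-set formula", {
  loops <- tibble::tibble(
    chrom1 = "chr1", start1 = seq(1e5, 1e6, length.out = 10), end1 = seq(1e5, 1e6, length.out = 10) + 1e4,
    chrom2 = "chr1", start2 = seq(2e6, 3e6, length.out = 10), end2 = seq(2e6, 3e6, length.out = 10) + 1e4
  )
  expect_equal(jaccard_similarity(loops, loops), 1)

  far <- dplyr::mutate(loops, start1 = start1 + 1e6, end1 = end1 + 1e6)
  expect_equal(jaccard_similarity(loops, far), 0)

  half <- dplyr::bind_rows(loops[1:5, ],
                           dplyr::mutate(loops[6:10, ], start1 = start1 + 2e5,
                                         end1 = end1 + 2e5))
  expect_equal(jaccard_similarity(loops, half), 5 / 15)

  expect_error(jaccard_similarity(loops[0, ], loops[0, ]), "empty")

  # SV matcher: same rule on both breakpoints plus type agreement
  svs <- make_sv_set(synthetic_spec(seed = 5), 10)$svs
  expect_equal(jaccard_similarity(svs, svs, matcher = match_svs), 1)
})
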