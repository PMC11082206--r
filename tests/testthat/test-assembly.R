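test_that("effective distances follow the topology", {
  expect_equal(circular_distance(0, 9, 10, "circular"), 1)
  expect_equal(circular_distance(2, 7, 10, "circular"), 5)
  expect_equal(circular_distance(0, 9, 10, "linear"), 9)
  expect_error(circular_distance(0, 10, 10, "linear"), "indices")
})

test_that("the ecDNA-like case assembles to the expected geometry", {
  segs <- tibble::tibble(
    chrom = c("chr8", "chr12"),
    start = c(127710000, 57700000),
    end = c(127780000, 58155000),
    orientation = "forward"
  )
  asm <- assemble_hybrid(segs, topology = "circular", buffer_bp = 80000,
                         bin_size = 5000)
  # 70 kbp + 455 kbp + 80 kbp buffer = 605 kbp = 121 bins at 5 kbp
  expect_equal(asm$n_bins, 121)
  expect_equal(asm$segments$n_bins, c(14L, 91L, 16L))
  expect_true(asm$segments$is_buffer[3])
  expect_true(all(is.na(asm$bin_map$ref_start[asm$bin_map$is_buffer])))
})

test_that("bin mapping round-trips and handles orientation", {
  # identity assembly: hybrid bin i maps back to reference bin i
  one <- assemble_hybrid(tibble::tibble(chrom = "chr1", start = 0, end = 5e4),
                         topology = "linear", bin_size = 5000)
  bm <- hybrid_to_reference(one)
  expect_equal(bm$ref_start, seq(0, 45000, by = 5000))
  expect_equal(reference_to_hybrid(one, rep("chr1", 10), bm$ref_start),
               1:10)

  # inversion: the middle segment maps in reverse order
  inv <- assemble_hybrid(tibble::tibble(
    chrom = "chr1", start = c(0, 5e4, 1e5), end = c(5e4, 1e5, 1.5e5),
    orientation = c("forward", "reverse", "forward")
  ), topology = "linear", bin_size = 5000)
  mid <- inv$bin_map[inv$bin_map$segment == 2, ]
  expect_equal(mid$ref_start, rev(seq(5e4, 95000, by = 5000)))

  # reversing a segment twice restores the original mapping
  fwd2 <- assemble_hybrid(tibble::tibble(
    chrom = "chr1", start = c(0, 5e4, 1e5), end = c(5e4, 1e5, 1.5e5),
    orientation = "forward"
  ), topology = "linear", bin_size = 5000)
  twice <- inv$bin_map$ref_start[inv$bin_map$segment == 2]
  expect_equal(rev(twice), fwd2$bin_map$ref_start[fwd2$bin_map$segment == 2])

  # round trip for every non-buffer bin of a circular assembly
  circ <- assemble_hybrid(tibble::tibble(
    chrom = c("a", "b"), start = c(0, 1e5), end = c(5e4, 2e5),
    orientation = c("forward", "reverse")
  ), topology = "circular", buffer_bp = 80000, bin_size = 5000)
  nb <- circ$bin_map[!circ$bin_map$is_buffer, ]
  back <- reference_to_hybrid(circ, nb$chrom, nb$ref_start)
  expect_equal(back, nb$hybrid_bin)

  # inconsistent orientation signs are rejected
  bad <- sv_records(tibble::tibble(chrom1 = "a", pos1 = 1e4, chrom2 = "a",
                                   pos2 = 5e4, sign1 = "-", sign2 = "+",
                                   sv_type = "deletion"))
  expect_error(assemble_hybrid(tibble::tibble(chrom = "a", start = 0, end = 5e4),
                               svs = bad), "inconsistent")
})

test_that("circular predictions are rotation-invariant and buffers inert", {
  asm <- assemble_hybrid(tibble::tibble(chrom = "c", start = 0, end = 5e5),
                         topology = "circular", buffer_bp = 0, bin_size = 5000)
  P <- predict_neo_contacts(asm, matrix(1, 100, 1))
  rot <- function(m, k) {
    idx <- ((seq_len(nrow(m)) - 1 + k) %% nrow(m)) + 1
    m[idx, idx]
  }
  for (k in c(1, 17, 50)) {
    expect_lte(max(abs(unclass(P) - rot(unclass(P), k))), 1e-12)
  }
  expect_equal(P[1, 100], P[1, 2])

  # buffer rows never rise above the distance-decay baseline
  fix <- myc_like_fixture()
  pred <- predict_neo_contacts(fix$assembly, fix$binding)
  n <- fix$assembly$n_bins
  d <- abs(outer(0:(n - 1), 0:(n - 1), "-")); d <- pmin(d, n - d)
  base <- pmax(d, 1)^(-1); diag(base) <- 1
  buf <- fix$assembly$bin_map$is_buffer
  expect_equal(unclass(pred)[buf, ], base[buf, ], ignore_attr = TRUE)

  # missing binding rows are an error
  expect_error(predict_neo_contacts(fix$assembly, fix$binding[1:50, , drop = FALSE]),
               "binding information")
})

test_that("joining segments creates contacts the unjoined control lacks", {
  fix <- myc_like_fixture()
  joined <- predict_neo_contacts(fix$assembly, fix$binding)
  unjoined <- predict_unjoined_contacts(fix$assembly, fix$binding)
  p <- fix$promoter
  for (e in fix$enhancers) {
    expect_gt(joined[p, e], unjoined[p, e])
  }
  # within-segment contacts agree between the two
  expect_equal(joined[fix$enhancers[1], fix$enhancers[2]],
               unjoined[fix$enhancers[1], fix$enhancers[2]])
})

test_that("candidate neoloops are picked from observed-over-expected peaks", {
  # homogeneous polymer: no candidates
  asm <- assemble_hybrid(tibble::tibble(chrom = "c", start = 0, end = 2.5e5),
                         topology = "circular", buffer_bp = 0, bin_size = 5000)
  P <- predict_neo_contacts(asm, matrix(1, 50, 1))
  expect_equal(nrow(call_candidate_neoloops(P, asm)), 0)

  fix <- myc_like_fixture()
  pred <- predict_neo_contacts(fix$assembly, fix$binding)
  cands <- call_candidate_neoloops(pred, fix$assembly, z_threshold = 2)
  expect_gt(nrow(cands), 0)
  top <- cands[1, ]
  expect_true(top$crosses_breakpoint)
  expect_true(top$anchor1 == fix$promoter && top$anchor2 %in% fix$enhancers)

  # an absurd threshold empties the list
  expect_equal(nrow(call_candidate_neoloops(pred, fix$assembly, z_threshold = 1e6)), 0)
})
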