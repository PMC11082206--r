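test_that("toy polymers follow the requested class layout", {
  spec <- synthetic_spec(seed = 1, n_beads = 100, n_classes = 3)
  poly <- make_toy_polymer(spec)
  cls <- apply(poly$binding, 1, which.max)
  # three contiguous blocks of ~33 beads, one class each
  expect_equal(length(rle(cls)$lengths), 3)
  expect_true(all(rle(cls)$lengths >= 32))
  expect_true(all(rowSums(poly$binding) == 1))

  one <- make_toy_polymer(synthetic_spec(seed = 1, n_beads = 20, n_classes = 1))
  expect_true(all(one$binding[, 1] == 1))

  inter <- make_toy_polymer(synthetic_spec(seed = 1, n_beads = 12, n_classes = 3,
                                           class_layout = "interleaved"))
  expect_equal(apply(inter$binding, 1, which.max), rep(1:3, 4))

  # determinism: same spec, same binding table
  expect_identical(make_toy_polymer(spec)$binding, poly$binding)
})

test_that("ground-truth matrices reflect the planted structure", {
  spec <- synthetic_spec(seed = 2, n_beads = 60, n_classes = 2)
  poly <- make_toy_polymer(spec)
  hic <- make_ground_truth_hic(poly, "meanfield")
  expect_s3_class(hic, "contact_matrix")
  expect_identical(attr(hic, "ground_truth"), poly)

  # zero binding -> pure distance decay
  empty <- polymer_model(matrix(0, 30, 1))
  base <- make_ground_truth_hic(empty, "meanfield")
  d <- abs(outer(0:29, 0:29, "-"))
  expect_equal(unclass(base), pmax(d, 1)^(-1), ignore_attr = TRUE)

  # block polymer: within-block contacts exceed cross-block at equal distance
  cls <- apply(poly$binding, 1, which.max)
  same <- outer(cls, cls, "==")
  d <- abs(outer(seq_len(60), seq_len(60), "-"))
  sel <- d == 5
  expect_gt(mean(hic[sel & same]), mean(hic[sel & !same]))

  # sbs mode with a fixed seed is reproducible
  short <- sbs_config(n_steps = 800, sample_every = 80, seed = 9)
  m1 <- make_ground_truth_hic(poly, "sbs", short)
  m2 <- make_ground_truth_hic(poly, "sbs", short)
  expect_identical(unclass(m1), unclass(m2))
})

test_that("class tracks carry the planted class signal", {
  spec <- synthetic_spec(seed = 3, n_beads = 1000, n_classes = 2)
  poly <- make_toy_polymer(spec)

  clean <- make_class_tracks(poly, noise = 0, seed = 1)
  expect_equal(clean[[1]]$value, as.numeric(poly$binding[, 1] > 0))
  ind <- binned_track(clean[[1]]$value, kind = "indicator")
  ct <- class_track_correlation((poly$binding[, 1] > 0) * 1, ind)
  expect_equal(ct$corr, 1)

  # heavy noise washes the correlation out
  noisy <- make_class_tracks(poly, noise = 50, seed = 4)
  b <- binarize_track(noisy[[1]], "quantile", q = 0.5)
  ct2 <- class_track_correlation((poly$binding[, 1] > 0) * 1, b)
  expect_lt(abs(ct2$corr), 0.1)
})

test_that("synthetic SV sets respect orientation conventions and CNV truth", {
  spec <- synthetic_spec(seed = 11)
  out <- make_sv_set(spec, 40)
  svs <- out$svs

  dup <- svs[svs$sv_type == "duplication", ]
  expect_true(all(paste0(dup$sign1, dup$sign2) %in% c("-+", "++", "--")))
  del <- svs[svs$sv_type == "deletion", ]
  expect_true(all(paste0(del$sign1, del$sign2) == "+-"))

  # CNV ratios by construction: 0.5 inside deletions, 2.0 inside duplications
  for (k in which(svs$sv_type == "deletion")) {
    lo <- min(svs$pos1[k], svs$pos2[k]); hi <- max(svs$pos1[k], svs$pos2[k])
    sel <- out$cnv$chrom == svs$chrom1[k] & out$cnv$start >= lo & out$cnv$end <= hi
    expect_true(all(out$cnv$ratio[sel] == 0.5))
  }

  # round trip: the classifier recovers every planted dup/del label
  intra <- svs[svs$sv_type %in% c("duplication", "deletion"), ]
  expect_equal(classify_intra_sv(intra, out$cnv), intra$sv_type)

  # reproducibility
  out2 <- make_sv_set(spec, 40)
  expect_identical(out2$svs$pos1, svs$pos1)
})
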