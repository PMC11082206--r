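test_that("binarization rules behave as documented", {
  t <- binned_track(1:10)
  b <- binarize_track(t, "quantile", q = 0.5)
  expect_equal(sum(b$value), 5)            # distinct values: exactly half
  expect_true(all(b$value %in% c(0, 1)))

  peaks <- tibble::tibble(chrom = "chr1", start = c(0, 20000), end = c(5000, 30000))
  bp <- binarize_track(t, "peaks", peaks = peaks)
  expect_equal(sum(bp$value), 3)           # bins 1, 5, 6 overlap the peaks

  # idempotent on indicator input
  expect_identical(binarize_track(b, "quantile"), b)

  expect_warning(binarize_track(binned_track(rep(0, 5)), "quantile"), "all-zero")
})

test_that("indicator correlation and conditional probability invert exactly", {
  # closed forms
  on <- rep(c(1, 0), each = 5)
  expect_equal(class_track_correlation(on, on)$corr, 1)
  expect_equal(class_track_correlation(on, 1 - on)$corr, -1)
  ind <- rep(c(1, 0, 1, 0), 5); jnd <- rep(c(1, 1, 0, 0), 5)
  expect_equal(class_track_correlation(ind, jnd)$corr, 0)  # independence

  expect_equal(conditional_probability(0, 0.3, 0.6), 0.3)
  expect_equal(conditional_probability(1, 0.5, 0.5), 1)
  expect_error(conditional_probability(0.5, 0.5, 0), "p_t")
  expect_error(class_track_correlation(rep(1, 4), c(0, 1, 1, 0)), "degenerate")

  # brute-force count oracle on random indicator pairs
  set.seed(10)
  for (k in 1:20) {
    ci <- stats::rbinom(300, 1, runif(1, 0.2, 0.8))
    ti <- stats::rbinom(300, 1, runif(1, 0.2, 0.8))
    if (mean(ci) %in% c(0, 1) || mean(ti) %in% c(0, 1)) next
    ct <- class_track_correlation(ci, ti)
    expect_equal(conditional_probability(ct$corr, ct$p_c, ct$p_t),
                 sum(ci & ti) / sum(ti), tolerance = 1e-12)
    # algebraic consistency: P(C|T) * P_T reconstructs the joint exactly
    expect_equal(conditional_probability(ct$corr, ct$p_c, ct$p_t) * ct$p_t,
                 ct$p_joint, tolerance = 1e-12)
  }
})

test_that("transfer sums conditional probabilities over included couples", {
  # single couple with P(C|T) = 0.8: profile equals 0.8 x indicator
  cls <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 1, 0), ncol = 1)
  trk <- binned_track(c(1, 1, 0, 0, 1, 1, 0, 0, 1, 0), kind = "indicator")
  model <- build_transfer_model(cls, list(t1 = trk))
  expect_equal(model$p_c_given_t, 0.8)
  target <- binned_track(c(1, 0, 1, 0), kind = "indicator")
  prof <- transfer_classes(model, list(t1 = target))
  expect_equal(profile_matrix(prof)[, 1], c(0.8, 0, 0.8, 0))

  # couples at or below the threshold contribute nothing
  model$corr <- 0.15
  model$included <- model$corr > attr(model, "threshold")
  expect_error(transfer_classes(model, list(t1 = target)), "no \\(class, track\\) couple")

  # profiles stay within [0, 1] even when multiple couples fire
  cls2 <- cbind(c(1, 1, 1, 0, 0, 0, 1, 0))
  tA <- binned_track(c(1, 1, 1, 0, 0, 0, 1, 0), kind = "indicator")
  tB <- binned_track(c(1, 1, 1, 0, 0, 0, 0, 1), kind = "indicator")
  m2 <- suppressWarnings(build_transfer_model(cls2, list(a = tA, b = tB)))
  tgt <- list(a = binned_track(c(1, 1, 0), kind = "indicator"),
              b = binned_track(c(1, 0, 0), kind = "indicator"))
  p2 <- suppressWarnings(transfer_classes(m2, tgt))
  expect_true(all(p2$probability >= 0 & p2$probability <= 1))
})

test_that("noise-free synthetic tracks transfer the planted classes", {
  src <- make_toy_polymer(synthetic_spec(seed = 3, n_beads = 120, n_classes = 3))
  tgt <- make_toy_polymer(synthetic_spec(seed = 9, n_beads = 90, n_classes = 3,
                                         class_layout = "interleaved"))
  as_ind <- function(tr) binned_track(tr$value, kind = "indicator")
  src_tracks <- lapply(make_class_tracks(src, 0, seed = 1), as_ind)
  tgt_tracks <- lapply(make_class_tracks(tgt, 0, seed = 2), as_ind)
  model <- suppressWarnings(build_transfer_model(src, src_tracks))
  prof <- transfer_classes(model, tgt_tracks)
  P <- profile_matrix(prof)
  for (c in 1:3) {
    expect_gte(stats::cor(P[, c], (tgt$binding[, c] > 0) * 1), 0.9)
  }
})
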