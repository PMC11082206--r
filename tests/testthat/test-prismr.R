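test_that("Gaussian smoothing preserves constants, symmetry and the kernel", {
  const <- contact_matrix(matrix(1, 15, 15))
  sm <- smooth_matrix(const, 1)
  inner <- unclass(sm)[6:10, 6:10]
  expect_equal(inner, matrix(1, 5, 5), tolerance = 1e-10)

  set.seed(1)
  x <- matrix(rnorm(100), 10); x <- x %*% t(x)
  sx <- smooth_matrix(contact_matrix(x - min(x) + 1), 0.8)
  expect_equal(max(abs(sx - t(sx))), 0)

  # unit impulse -> separable discretized Gaussian kernel (closed form)
  n <- 21; sigma <- 1
  imp <- matrix(0, n, n); imp[11, 11] <- 1
  sm2 <- smooth_matrix(contact_matrix(imp), sigma)
  h <- ceiling(4 * sigma)
  k <- exp(-(-h:h)^2 / (2 * sigma^2)); k <- k / sum(k)
  for (a in -2:2) for (b in -2:2) {
    expect_equal(sm2[11 + a, 11 + b], k[a + h + 1] * k[b + h + 1],
                 tolerance = 1e-12)
  }
  expect_error(smooth_matrix(const, -1), "sigma")
  expect_identical(smooth_matrix(const, 0), const)
})

test_that("mean-field reconstruction follows the decay-plus-affinity model", {
  # zero binding: exactly the power-law baseline
  empty <- polymer_model(matrix(0, 25, 2))
  P <- reconstruct_meanfield(empty)
  d <- abs(outer(0:24, 0:24, "-"))
  expect_equal(unclass(P), pmax(d, 1)^(-1), ignore_attr = TRUE)

  # a shared class strictly raises the pair contact
  b <- matrix(0, 25, 2); b[c(3, 20), 1] <- 1
  P2 <- reconstruct_meanfield(polymer_model(b))
  expect_gt(P2[3, 20], P[3, 20])
  expect_equal(P2[4, 20], P[4, 20])

  # circular topology: ends are neighbours
  ring <- polymer_model(matrix(1, 100, 1), topology = "circular")
  Pr <- reconstruct_meanfield(ring)
  expect_equal(Pr[1, 100], Pr[1, 2])
})

test_that("distance-corrected correlation removes the decay trend", {
  set.seed(4)
  a <- matrix(rnorm(400), 20); a <- abs(a %*% t(a))
  expect_equal(distance_corrected_correlation(a, a), 1)

  # adding a per-diagonal constant changes nothing
  d <- abs(outer(1:20, 1:20, "-"))
  b <- a + matrix(10 / (d + 1), 20, 20)
  expect_equal(distance_corrected_correlation(a, b), 1, tolerance = 1e-10)

  # independent matrices decorrelate
  set.seed(5)
  r1 <- matrix(rnorm(10000), 100); r1 <- r1 + t(r1)
  r2 <- matrix(rnorm(10000), 100); r2 <- r2 + t(r2)
  expect_lt(abs(distance_corrected_correlation(r1, r2)), 0.1)

  expect_error(distance_corrected_correlation(a, matrix(0, 5, 5)), "shape")
})

test_that("monomer rescaling interpolates contact profiles", {
  spec <- synthetic_spec(seed = 6, n_beads = 100, n_classes = 2)
  hic <- make_ground_truth_hic(make_toy_polymer(spec), "meanfield")

  expect_identical(rescale_monomer(hic, 1), hic)

  half <- rescale_monomer(hic, 2)
  expect_equal(dim(half), c(50, 50))
  expect_equal(attr(half, "bin_size"), 10000)
  # scale 2 equals 2x2 block averaging
  block <- matrix(0, 50, 50)
  for (I in 1:50) for (J in 1:50) {
    block[I, J] <- mean(hic[(2 * I - 1):(2 * I), (2 * J - 1):(2 * J)])
  }
  expect_equal(unclass(half), block, ignore_attr = TRUE, tolerance = 1e-12)

  # round trip on a smooth matrix
  smooth <- smooth_matrix(hic, 2)
  rt <- rescale_monomer(rescale_monomer(smooth, 2), 0.5)
  ut <- upper.tri(rt, diag = FALSE)
  expect_gt(stats::cor(unclass(rt)[ut], unclass(smooth)[ut]), 0.995)

  expect_error(rescale_monomer(hic, 50), "fewer than 3")
  expect_error(rescale_monomer(hic, 0), "scale")
})

test_that("simulated annealing behaves at its limits", {
  spec <- synthetic_spec(seed = 7, n_beads = 40, n_classes = 2)
  poly <- make_toy_polymer(spec)
  hic <- make_ground_truth_hic(poly, "meanfield")

  # identical seed, identical fit
  cfg <- prismr_config(n_classes = 2, n_iter = 2000, seed = 3)
  f1 <- sa_fit(hic, cfg)
  f2 <- sa_fit(hic, cfg)
  expect_identical(f1$polymer$binding, f2$polymer$binding)

  # overwhelming sparsity penalty empties the table
  big <- prismr_config(n_classes = 2, n_iter = 3000, lambda = 10, seed = 1)
  expect_equal(sum(sa_fit(hic, big)$polymer$binding), 0)

  # the optimizer is no worse than the generating truth
  cfg2 <- prismr_config(n_classes = 2, n_iter = 10000, seed = 2)
  fit <- sa_fit(hic, cfg2)
  expect_lte(fit$cost, prismr_cost(hic, poly, cfg2) * 1.05)

  # running-best cost trace is non-increasing
  expect_true(all(diff(fit$trace$best_cost) <= 0))

  gl <- glance(fit)
  expect_equal(gl$n_classes, 2)
  expect_equal(gl$total_sites, sum(fit$polymer$binding))
  td <- tidy(fit)
  expect_true(all(td$multiplicity > 0))
})

test_that("lambda selection finds the plateau edge", {
  spec <- synthetic_spec(seed = 8, n_beads = 40, n_classes = 2)
  hic <- make_ground_truth_hic(make_toy_polymer(spec), "meanfield")
  cfg <- prismr_config(n_classes = 2, n_iter = 6000, seed = 4)

  sel <- select_lambda(hic, c(1e-6, 1e-5, 1e-4, 1e-2), cfg)
  expect_true(sel$lambda %in% c(1e-6, 1e-5, 1e-4))
  expect_true(all(sel$diagnostics$fidelity_cost[sel$diagnostics$lambda <= sel$lambda] <=
                    1.1 * sel$diagnostics$fidelity_cost[1]))

  expect_error(select_lambda(hic, c(1e-5, 1e-4), cfg), "at least 3")
})

test_that("class-count selection stops when extra classes stop paying", {
  # homogeneous target: one class suffices
  homog <- make_ground_truth_hic(polymer_model(matrix(1, 40, 1)), "meanfield")
  cfg <- prismr_config(n_classes = 1, n_iter = 5000, seed = 5)
  sel <- select_n_classes(homog, 1:3, cfg)
  expect_equal(sel$n_classes, 1)

  # threshold 0 never stops early
  sel0 <- select_n_classes(homog, 1:3, cfg, threshold = 0)
  expect_equal(sel0$n_classes, 3)

  expect_error(select_n_classes(homog, c(3, 2, 1), cfg), "increasing")
})
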