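test_that("ensemble contact counting matches a brute-force re-count", {
  poly <- polymer_model(matrix(1, 10, 1))
  ens <- run_sbs(poly, sbs_config(n_steps = 2000, sample_every = 100, seed = 2))
  cm <- contacts_from_ensemble(ens, contact_radius = 2)
  expect_equal(unclass(cm),
               brute_force_contacts(ens$conformations, 2),
               ignore_attr = TRUE)
  expect_true(all(cm >= 0 & cm <= 1))
  expect_equal(max(abs(cm - t(cm))), 0)
})

test_that("contact frequencies follow the definition on hand-built ensembles", {
  near <- matrix(0, 4, 3)                    # all beads within any radius > 0
  far <- diag(c(100, 200, 300, 400)) %*% matrix(1, 4, 3)
  fake <- structure(list(
    conformations = list(near), polymer = polymer_model(matrix(0, 4, 1)),
    config = sbs_config(contact_radius = 3.5)
  ), class = "structure_ensemble")
  expect_true(all(contacts_from_ensemble(fake) == 1))

  fake$conformations <- list(near, far)      # contact in exactly one of two
  cm <- contacts_from_ensemble(fake)
  expect_equal(cm[1, 4], 0.5)

  fake$conformations <- list()
  expect_error(contacts_from_ensemble(fake), "empty")
})

test_that("sampling is seed-deterministic and bonded chains stay intact", {
  poly <- polymer_model(matrix(c(1, 0), 12, 2, byrow = TRUE))
  cfg <- sbs_config(n_steps = 1500, sample_every = 150, seed = 31)
  e1 <- run_sbs(poly, cfg)
  e2 <- run_sbs(poly, cfg)
  expect_identical(e1$conformations, e2$conformations)

  bonds <- sapply(e1$conformations, function(x) {
    max(sqrt(rowSums((x[-1, ] - x[-nrow(x), ])^2)))
  })
  expect_true(all(bonds < 2))

  ring <- polymer_model(matrix(1, 12, 1), topology = "circular")
  er <- run_sbs(ring, sbs_config(n_steps = 1500, sample_every = 150, seed = 5))
  closing <- sapply(er$conformations, function(x) sqrt(sum((x[1, ] - x[12, ])^2)))
  expect_true(all(closing < 2))
})

test_that("contact probability decays with separation for a neutral chain", {
  poly <- polymer_model(matrix(1, 20, 1))
  ens <- run_sbs(poly, sbs_config(interaction_energy = 0, n_steps = 30000,
                                  sample_every = 30, seed = 8))
  cm <- contacts_from_ensemble(ens)
  prof <- sapply(1:19, function(d) mean(cm[cbind(1:(20 - d), (1 + d):20)]))
  # monotone within sampling error: allow small inversions, demand large trend
  expect_gt(prof[2], prof[10])
  expect_gt(prof[10] + 0.05, prof[19])
  expect_lt(sum(diff(prof) > 0.05), 2)
})

test_that("triplet colocalization matches its closed forms and a brute force", {
  ind <- function(pa, pb, pab) list(p_a = pa, p_b = pb, p_ab = pab)
  expect_equal(triplet_colocalization(ind(0.4, 0.5, 0.2)), 0)   # independence
  expect_equal(triplet_colocalization(ind(0.5, 0.5, 0.5)), 1)   # co-occurrence
  expect_error(triplet_colocalization(ind(0, 0.5, 0)), "degenerate")
  expect_error(triplet_colocalization(ind(1, 0.5, 0.5)), "degenerate")

  # ensemble estimate equals the per-conformation indicator correlation
  poly <- polymer_model(matrix(1, 12, 1))
  ens <- run_sbs(poly, sbs_config(interaction_energy = 2, n_steps = 6000,
                                  sample_every = 30, seed = 13))
  st <- ensemble_contact_stats(ens, target_bead = 1, region_a = 5:6,
                               region_b = 10:12, contact_radius = 2)
  got <- triplet_colocalization(st)
  brute <- stats::cor(st$indicators$in_a * 1, st$indicators$in_b * 1)
  expect_equal(got, brute, tolerance = 1e-12)
  expect_true(st$p_ab <= min(st$p_a, st$p_b))
})

test_that("in-silico expression reproduces hand-computed log-ratios", {
  conf <- function(d) {
    # target at origin, two peaks at distance d and 2d along x
    rbind(c(0, 0, 0), c(d, 0, 0), c(2 * d, 0, 0))
  }
  fake <- structure(list(
    conformations = list(conf(1), conf(2), conf(4)),
    polymer = polymer_model(matrix(0, 3, 1)),
    config = sbs_config()
  ), class = "structure_ensemble")
  sums <- c(1 + 1 / 2, 1 / 2 + 1 / 4, 1 / 4 + 1 / 8)
  est <- insilico_expression(fake, target_bead = 1, peak_beads = 2:3)
  expect_equal(est$sum_inv_distance, sums)
  expect_equal(est$log_ratio, log(sums / mean(sums)))
  expect_equal(attr(est, "F"), mean(sums))

  # explicit normalizer closed forms
  est2 <- insilico_expression(fake, 1, 2:3, F = sums[1])
  expect_equal(est2$log_ratio[1], 0)
  est3 <- insilico_expression(fake, 1, 2:3, F = sums[1] / exp(1))
  expect_equal(est3$log_ratio[1], 1)

  expect_error(insilico_expression(fake, 1, integer(0)), "non-empty")
  expect_error(insilico_expression(fake, 1, c(1, 2)), "must not be a peak")
})

test_that("binder concentration converts through the box volume", {
  # 200 nmol/L in a (10 x 50 nm)^3 box -> 15 binders
  expect_equal(binders_from_concentration(200, 10, 50), 15L)
  expect_equal(binders_from_concentration(400, 10, 50), 30L)
})
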