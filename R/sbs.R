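#' Configuration for SBS ensemble sampling
#'
#' Physical and numerical parameters of the strings-and-binders sampler, in
#' reduced units (bead diameter = 1, kT = 1). Two integrators target the same
#' Boltzmann ensemble: Metropolis Monte Carlo on continuous coordinates (the
#' reference, default) and Langevin dynamics integrated with a velocity-Verlet
#' (BAOAB) scheme (the fidelity option, which also yields dynamics).
#'
#' Binder counts: the physical binder concentration is converted to particle
#' counts through the simulation-box volume. With the defaults (box side 10
#' bead diameters, bead diameter 50 nm) 200 nmol/L maps to 15 binders per
#' class; set `n_binders_per_class` to bypass the conversion.
#'
#' @param interaction_energy binder-to-binding-site attraction depth, kT units
#'   (default 4).
#' @param binder_concentration nmol/L (default 200).
#' @param n_binders_per_class explicit binder count per class; `NULL` derives
#'   it from the concentration via [binders_from_concentration()].
#' @param integrator `"metropolis"` or `"langevin"`.
#' @param n_steps MC sweeps or MD steps.
#' @param sample_every record a conformation every this many sweeps/steps.
#' @param equilibration fraction of recorded frames discarded as burn-in
#'   (default 0.5).
#' @param contact_radius two beads are "in contact" within this many bead
#'   diameters (default 3.5).
#' @param box_side confinement box side, bead diameters.
#' @param bead_diameter_nm physical bead diameter used only for the
#'   concentration-to-count conversion (default 50 nm for a 5 kbp bead).
#' @param mc_step maximum MC displacement per axis.
#' @param dt,friction Langevin time step and friction.
#' @param bond_k,bond_r0 harmonic bond stiffness and rest length.
#' @param wall_k soft-wall stiffness.
#' @param seed integer seed.
#' @return an `sbs_config` list.
#' @export
sbs_config <- function(interaction_energy = 4, binder_concentration = 200,
                       n_binders_per_class = NULL,
                       integrator = c("metropolis", "langevin"),
                       n_steps = 20000, sample_every = 20,
                       equilibration = 0.5,
                       contact_radius = 3.5, box_side = 10,
                       bead_diameter_nm = 50,
                       mc_step = 0.3, dt = 0.005, friction = 1,
                       bond_k = 50, bond_r0 = 1, wall_k = 10,
                       seed = 1L) {
  integrator <- match.arg(integrator)
  if (interaction_energy < 0) abort("`interaction_energy` must be >= 0.")
  if (n_steps <= 0) abort("`n_steps` must be > 0.")
  if (contact_radius <= 0) abort("`contact_radius` must be > 0.")
  if (equilibration < 0 || equilibration >= 1) abort("`equilibration` must be in [0, 1).")
  structure(
    list(
      interaction_energy = interaction_energy,
      binder_concentration = binder_concentration,
      n_binders_per_class = n_binders_per_class,
      integrator = integrator,
      n_steps = as.integer(n_steps), sample_every = as.integer(sample_every),
      equilibration = equilibration,
      contact_radius = contact_radius, box_side = box_side,
      bead_diameter_nm = bead_diameter_nm,
      mc_step = mc_step, dt = dt, friction = friction,
      bond_k = bond_k, bond_r0 = bond_r0, wall_k = wall_k,
      seed = as.integer(seed)
    ),
    class = "sbs_config"
  )
}

#' Convert a binder concentration to a particle count
#'
#' @param concentration nmol/L.
#' @param box_side box side in bead diameters.
#' @param bead_diameter_nm bead diameter in nm.
#' @return integer binder count for the box volume.
#' @export
binders_from_concentration <- function(concentration, box_side = 10,
                                       bead_diameter_nm = 50) {
  vol_l <- (box_side * bead_diameter_nm * 1e-9)^3 * 1000
  max(1L, as.integer(round(concentration * 1e-9 * 6.02214076e23 * vol_l)))
}

#' Sample a 3D conformational ensemble of an SBS polymer
#'
#' Runs the configured sampler on a binding-site-decorated chain plus
#' diffusing binders: binders of class `c` attract beads carrying sites of
#' class `c` with depth `interaction_energy` (scaled by the site
#' multiplicity), which bridges same-class beads and folds the chain.
#' Circular polymers are bonded into a ring. The first `equilibration`
#' fraction of recorded frames is discarded so the ensemble reflects the
#' steady state.
#'
#' @param polymer a [polymer_model()].
#' @param config an [sbs_config()].
#' @return a `structure_ensemble`: list with `conformations` (list of
#'   `n_beads x 3` matrices), `polymer`, `config`, `accept_rate`.
#' @export
run_sbs <- function(polymer, config = sbs_config()) {
  if (!is_polymer_model(polymer)) abort("`polymer` must be a polymer_model.")
  n <- polymer$n_beads
  M <- polymer$n_classes
  n_bind <- config$n_binders_per_class %||%
    binders_from_concentration(config$binder_concentration, config$box_side,
                               config$bead_diameter_nm)
  set.seed(config$seed)

  # initial chain: ring for circular topology, confined random walk otherwise
  if (polymer$topology == "circular") {
    r <- n * config$bond_r0 / (2 * pi)
    th <- 2 * pi * (seq_len(n) - 1) / n
    beads <- cbind(r * cos(th), r * sin(th), 0)
  } else {
    half <- config$box_side / 2 - 0.5
    beads <- matrix(0, n, 3)
    for (i in seq_len(n)[-1]) {
      step <- rnorm(3)
      beads[i, ] <- pmin(pmax(beads[i - 1, ] + config$bond_r0 * step / sqrt(sum(step^2)),
                              -half), half)
    }
  }
  binders <- matrix(runif(3 * n_bind * M, -config$box_side / 2, config$box_side / 2),
                    ncol = 3)
  X0 <- rbind(beads, binders)
  binder_class <- rep(seq_len(M), each = n_bind) - 1L

  res <- if (config$integrator == "metropolis") {
    sbs_mc_cpp(X0, polymer$binding, binder_class, config$interaction_energy,
               polymer$topology == "circular", config$box_side,
               config$n_steps, config$sample_every, config$mc_step,
               config$bond_k, config$bond_r0, config$wall_k)
  } else {
    sbs_ld_cpp(X0, polymer$binding, binder_class, config$interaction_energy,
               polymer$topology == "circular", config$box_side,
               config$n_steps, config$sample_every, config$dt, config$friction,
               config$bond_k, config$bond_r0, config$wall_k)
  }

  frames <- res$frames
  n_frames <- dim(frames)[3]
  keep <- seq_len(n_frames) > floor(config$equilibration * n_frames)
  conformations <- lapply(which(keep), function(k) frames[, , k])
  structure(
    list(conformations = conformations, polymer = polymer, config = config,
         accept_rate = res$accept_rate),
    class = "structure_ensemble"
  )
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf(
    "<structure_ensemble> %d conformations x %d beads | %s | %s sampler\n",
    length(x$conformations), x$polymer$n_beads, x$polymer$topology,
    x$config$integrator
  ))
  invisible(x)
}

#' Contact-frequency matrix of a conformational ensemble
#'
#' Two beads are in contact in a conformation when their Euclidean distance
#' is at most `contact_radius` bead diameters; the matrix holds per-pair
#' contact frequencies over the ensemble (diagonal = 1).
#'
#' @param ensemble a `structure_ensemble` from [run_sbs()].
#' @param contact_radius override of the config's radius.
#' @return a `contact_matrix` with entries in `[0, 1]`.
#' @export
contacts_from_ensemble <- function(ensemble, contact_radius = NULL) {
  if (length(ensemble$conformations) == 0) abort("empty ensemble.")
  r <- contact_radius %||% ensemble$config$contact_radius
  n <- nrow(ensemble$conformations[[1]])
  acc <- matrix(0, n, n)
  for (xyz in ensemble$conformations) {
    d <- as.matrix(stats::dist(xyz))
    acc <- acc + (d <= r)
  }
  P <- acc / length(ensemble$conformations)
  diag(P) <- 1
  contact_matrix(P, chrom = "ensemble", start = 0,
                 bin_size = ensemble$polymer$bin_size)
}

#' Target-vs-region contact statistics of an ensemble
#'
#' For a target bead `X` and two bead regions `A` and `B`, estimates the
#' frequencies with which `X` contacts `A`, `B`, and both simultaneously
#' (a conformation counts as a contact with a region when the target is within
#' `contact_radius` of at least one of its beads).
#'
#' @param ensemble a `structure_ensemble`.
#' @param target_bead target bead index (1-based).
#' @param region_a,region_b bead index vectors.
#' @param contact_radius override of the config's radius.
#' @return an `ensemble_contact_stats` tibble-backed object with `p_a`, `p_b`,
#'   `p_ab` and the per-conformation indicators.
#' @export
ensemble_contact_stats <- function(ensemble, target_bead, region_a, region_b,
                                   contact_radius = NULL) {
  r <- contact_radius %||% ensemble$config$contact_radius
  hit <- function(xyz, region) {
    d2 <- colSums((t(xyz[region, , drop = FALSE]) - xyz[target_bead, ])^2)
    any(d2 <= r^2)
  }
  ia <- vapply(ensemble$conformations, hit, logical(1), region = region_a)
  ib <- vapply(ensemble$conformations, hit, logical(1), region = region_b)
  structure(
    list(
      p_a = mean(ia), p_b = mean(ib), p_ab = mean(ia & ib),
      indicators = tibble(conformation = seq_along(ia), in_a = ia, in_b = ib),
      contact_radius = r
    ),
    class = "ensemble_contact_stats"
  )
}

#' Triplet colocalization score
#'
#' Correlation-style score of how much more often a target colocalizes with
#' two regions simultaneously than expected from independent pairwise
#' contacts: `(P_XAB - P_XA * P_XB) / sqrt(P_XA (1-P_XA) P_XB (1-P_XB))`.
#' 0 under independence, 1 under perfect co-occurrence, bounded in `[-1, 1]`.
#'
#' @param stats an [ensemble_contact_stats()] result, or a list with `p_a`,
#'   `p_b`, `p_ab`.
#' @return scalar in `[-1, 1]`.
#' @export
triplet_colocalization <- function(stats) {
  pa <- stats$p_a; pb <- stats$p_b; pab <- stats$p_ab
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    abort("degenerate marginal contact frequency (0 or 1): score undefined.")
  }
  if (pab > min(pa, pb) + 1e-12) abort("p_ab exceeds a marginal; invalid stats.")
  (pab - pa * pb) / sqrt(pa * (1 - pa) * pb * (1 - pb))
}

#' In-silico single-allele expression from an ensemble
#'
#' Scores transcriptional output of a target bead from its 3D proximity to a
#' set of regulatory (peak) beads: per conformation, computes
#' `log(sum_i 1/d(target, i) / F)` over peak beads `i` with natural log.
#' `F = "auto"` uses the ensemble mean of the inverse-distance sum, centring
#' the mean log-ratio near 0; because of the normalization the score is
#' invariant to the ensemble's length unit.
#'
#' @param ensemble a `structure_ensemble`.
#' @param target_bead target bead index.
#' @param peak_beads indices of regulatory beads (must not contain the
#'   target).
#' @param F normalizer: positive number or `"auto"`.
#' @return an `expression_estimate`: tibble of per-conformation sums and
#'   log-ratios plus the `F` used (attribute `F`).
#' @export
insilico_expression <- function(ensemble, target_bead, peak_beads, F = "auto") {
  if (length(peak_beads) == 0) abort("`peak_beads` must be non-empty.")
  if (target_bead %in% peak_beads) abort("target bead must not be a peak bead.")
  sums <- vapply(ensemble$conformations, function(xyz) {
    d <- sqrt(colSums((t(xyz[peak_beads, , drop = FALSE]) - xyz[target_bead, ])^2))
    if (any(d == 0)) abort("coincident beads give zero distance.")
    sum(1 / d)
  }, numeric(1))
  Fv <- if (identical(F, "auto")) mean(sums) else F
  if (!is.numeric(Fv) || Fv <= 0) abort("`F` must be positive.")
  out <- tibble(
    conformation = seq_along(sums),
    sum_inv_distance = sums,
    log_ratio = log(sums / Fv)
  )
  attr(out, "F") <- Fv
  class(out) <- c("expression_estimate", class(out))
  out
}
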