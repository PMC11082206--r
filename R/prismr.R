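#' Configuration for simulated-annealing binding-site inference
#'
#' Controls the regularized, multi-proposal simulated annealing (SA) that
#' infers binding-site class multiplicities along a polymer from a Hi-C
#' contact matrix.
#'
#' At every SA iteration, `proposals_per_iteration` tentative single-site
#' modifications (add / remove / swap one site on a random bead) are generated
#' and all evaluated; the best one is then submitted to a Metropolis
#' accept/reject at the current temperature. The cost being minimized is
#' `||normalize(target) - normalize(reconstruction)|| + lambda * total sites`,
#' where both matrices are normalized to unit upper-triangle sum so shapes,
#' not depths, are compared, and `lambda` penalizes total binding-site
#' abundance to curb overfitting.
#'
#' @param n_classes number of binding-site classes `M`.
#' @param lambda sparsity-regularization weight (>= 0).
#' @param proposals_per_iteration tentative modifications evaluated per
#'   iteration (>= 1).
#' @param n_iter SA iterations.
#' @param t0 initial temperature, on the scale of the (unit-normalized) cost.
#' @param cooling geometric cooling factor per iteration.
#' @param smoothing_sigma Gaussian pre-smoothing of the target, in bins
#'   (default 0.5; 0 disables).
#' @param monomer_scale_candidates bead-length multipliers to scan; the target
#'   is resampled to each candidate monomer length and the best-fitting scale
#'   retained (default `1`, no scan).
#' @param max_multiplicity cap on per-bead per-class multiplicity.
#' @param cost_norm `"L1"` (default) or `"L2"` matrix distance.
#' @param decay [decay_params()] of the mean-field reconstruction.
#' @param init `"random"` (default) starts the anneal from one site of a
#'   random class per bead — shared-site affinities only react to same-class
#'   pairs, so an empty start has no gradient to climb; `"empty"` starts bare.
#' @param seed integer seed; the fit is bit-reproducible given the seed.
#' @param trace_every record the running-best cost every this many iterations.
#' @return a `prismr_config` list.
#' @export
prismr_config <- function(n_classes, lambda = 1e-5,
                          proposals_per_iteration = 8,
                          n_iter = 20000, t0 = 0.05, cooling = 0.9997,
                          smoothing_sigma = 0.5,
                          monomer_scale_candidates = 1,
                          max_multiplicity = 5,
                          cost_norm = c("L1", "L2"),
                          decay = decay_params(),
                          init = c("random", "empty"),
                          seed = 1L, trace_every = 100) {
  init <- match.arg(init)
  cost_norm <- match.arg(cost_norm)
  if (lambda < 0) abort("`lambda` must be >= 0.")
  if (n_classes < 1) abort("`n_classes` must be >= 1.")
  if (proposals_per_iteration < 1) abort("`proposals_per_iteration` must be >= 1.")
  if (smoothing_sigma < 0) abort("`smoothing_sigma` must be >= 0.")
  if (any(monomer_scale_candidates <= 0)) abort("monomer scales must be > 0.")
  structure(
    list(
      n_classes = as.integer(n_classes), lambda = lambda,
      proposals_per_iteration = as.integer(proposals_per_iteration),
      n_iter = as.integer(n_iter), t0 = t0, cooling = cooling,
      smoothing_sigma = smoothing_sigma,
      monomer_scale_candidates = monomer_scale_candidates,
      max_multiplicity = as.integer(max_multiplicity),
      cost_norm = cost_norm, decay = decay, init = init,
      seed = as.integer(seed), trace_every = as.integer(trace_every)
    ),
    class = "prismr_config"
  )
}

#' Gaussian smoothing of a contact matrix
#'
#' 2D Gaussian filter with standard deviation `sigma` bins, implemented as a
#' separable convolution (kernel truncated at 4 sigma, zero padding, so total
#' mass is preserved up to boundary effects) and re-symmetrized.
#'
#' @param m a `contact_matrix` (or plain symmetric matrix).
#' @param sigma kernel standard deviation in bins; 0 returns the input.
#' @return smoothed matrix of the same class.
#' @export
smooth_matrix <- function(m, sigma = 0.5) {
  if (sigma < 0) abort("`sigma` must be >= 0.")
  if (sigma == 0) return(m)
  x <- as_plain_matrix(m)
  n <- nrow(x)
  h <- ceiling(4 * sigma)
  k <- exp(-(0:h)^2 / (2 * sigma^2))
  k <- c(rev(k[-1]), k)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (off in -h:h) {
    idx <- seq_len(n)
    keep <- idx + off >= 1 & idx + off <= n
    K[cbind(idx[keep], (idx + off)[keep])] <- k[off + h + 1]
  }
  sm <- K %*% x %*% t(K)
  sm <- (sm + t(sm)) / 2
  if (is_contact_matrix(m)) rewrap_like(sm, m) else sm
}

#' Mean-field contact-map reconstruction of an SBS polymer
#'
#' Reconstructs a contact matrix from a binding-site layout without running
#' 3D simulations: `P(i,j) = p0(d_eff) * (1 + kappa * sum_c s_c *
#' min(b_ic, b_jc))`, where `p0(d) = max(d,1)^(-alpha)` is the coil-globule
#' distance-decay baseline and `d_eff` is the linear separation (linear
#' topology) or the minimal distance around the ring (circular topology, the
#' ecDNA case). Shared binding sites of the same class raise contact
#' probability multiplicatively above the baseline.
#'
#' @param polymer a [polymer_model()].
#' @param decay a [decay_params()].
#' @return a `contact_matrix` (diagonal = 1 before normalization).
#' @export
reconstruct_meanfield <- function(polymer, decay = decay_params()) {
  if (!is_polymer_model(polymer)) abort("`polymer` must be a polymer_model.")
  n <- polymer$n_beads
  idx <- seq_len(n) - 1
  d <- abs(outer(idx, idx, "-"))
  if (polymer$topology == "circular") d <- pmin(d, n - d)
  p0 <- pmax(d, 1)^(-decay$alpha)
  diag(p0) <- 1
  s <- decay$class_strength %||% rep(1, polymer$n_classes)
  s <- rep_len(s, polymer$n_classes)
  A <- matrix(0, n, n)
  for (c in seq_len(polymer$n_classes)) {
    bc <- polymer$binding[, c]
    A <- A + s[c] * outer(bc, bc, pmin)
  }
  P <- p0 * (1 + decay$kappa * A)
  contact_matrix(P, chrom = "reconstruction", start = 0, bin_size = polymer$bin_size)
}

#' Distance-corrected Pearson correlation of two contact matrices
#'
#' Subtracts the per-diagonal mean from each matrix (removing the dominant
#' distance-decay trend) and correlates the residuals over all off-diagonal
#' upper-triangle entries.
#'
#' @param a,b same-shape square symmetric matrices.
#' @return correlation in `[-1, 1]`.
#' @export
distance_corrected_correlation <- function(a, b) {
  a <- as_plain_matrix(a); b <- as_plain_matrix(b)
  if (!all(dim(a) == dim(b))) abort("matrices must have the same shape.")
  n <- nrow(a)
  center <- function(m) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    means <- vapply(split(m, d), mean, numeric(1))
    m - matrix(means[as.character(d)], n, n)
  }
  ut <- upper.tri(a, diag = FALSE)
  ra <- center(a)[ut]; rb <- center(b)[ut]
  if (sd(ra) == 0 || sd(rb) == 0) {
    abort("zero variance after distance correction; correlation undefined.")
  }
  cor(ra, rb)
}

#' Resample a contact matrix to a different monomer (bead) length
#'
#' Resamples the matrix to bead length `scale * bin_size` by bilinear
#' interpolation of contact profiles, to account for chromatin persistence
#' length: an SA fit can be run at several monomer lengths and the
#' best-fitting one retained ([prismr_config()]'s `monomer_scale_candidates`).
#' `scale = 2` on a 100-bin matrix gives a 50-bin matrix equal to 2x2 block
#' averaging.
#'
#' @param m a `contact_matrix`.
#' @param scale bead-length multiplier (> 0).
#' @return resampled `contact_matrix` with `bin_size * scale`.
#' @export
rescale_monomer <- function(m, scale) {
  if (scale <= 0) abort("`scale` must be > 0.")
  if (scale == 1) return(m)
  x <- as_plain_matrix(m)
  n <- nrow(x)
  n_new <- floor(n / scale)
  if (n_new < 3) abort("`scale` would leave fewer than 3 beads.")
  # centre of new bin I sits at source coordinate (I - 0.5) * scale + 0.5
  src <- pmin(pmax((seq_len(n_new) - 0.5) * scale + 0.5, 1), n)
  lo <- pmin(floor(src), n - 1)
  w <- src - lo
  out <- matrix(0, n_new, n_new)
  for (I in seq_len(n_new)) {
    r <- (1 - w[I]) * x[lo[I], ] + w[I] * x[lo[I] + 1, ]
    out[I, ] <- (1 - w) * r[lo] + w * r[lo + 1]
  }
  out <- (out + t(out)) / 2
  contact_matrix(out,
    chrom = attr(m, "chrom") %||% "region",
    start = attr(m, "start") %||% 0,
    bin_size = (attr(m, "bin_size") %||% 1) * scale
  )
}

# Shared preparation: smooth, then normalize upper triangle to unit sum.
prepare_target <- function(target, sigma) {
  x <- as_plain_matrix(target)
  if (nrow(x) != ncol(x)) abort("target must be square.")
  if (anyNA(x) || any(!is.finite(x))) abort("target has non-finite entries.")
  if (max(abs(x - t(x))) > 1e-8) abort("target must be symmetric.")
  if (sigma > 0) x <- as_plain_matrix(smooth_matrix(contact_matrix(x), sigma))
  ut <- upper.tri(x)
  x / sum(x[ut])
}

#' Infer binding-site classes from a contact matrix by simulated annealing
#'
#' Finds the binding-site multiplicity table whose mean-field reconstruction
#' ([reconstruct_meanfield()]) best matches the (smoothed, unit-normalized)
#' target matrix, subject to a sparsity penalty `lambda * total sites`. See
#' [prismr_config()] for the annealing scheme. When several monomer-scale
#' candidates are configured, the target is resampled to each candidate bead
#' length ([rescale_monomer()]), fitted independently, and the scale with the
#' highest distance-corrected correlation to its own target is retained.
#'
#' @param target square symmetric `contact_matrix` (raw counts are fine; the
#'   fit normalizes to unit sum).
#' @param config a [prismr_config()].
#' @param topology `"linear"` (default) or `"circular"` effective distance.
#' @return a `prismr_fit` with elements `polymer` (best [polymer_model()]),
#'   `cost`, `fidelity_cost`, `trace` (running-best cost tibble),
#'   `correlation` (distance-corrected, fit vs target), `scale` (selected
#'   monomer scale), `target` (the prepared matrix fitted against).
#' @export
sa_fit <- function(target, config, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  scales <- config$monomer_scale_candidates
  fits <- lapply(seq_along(scales), function(k) {
    tgt <- if (scales[k] == 1) target else rescale_monomer(contact_matrix(as_plain_matrix(target),
      chrom = attr(target, "chrom") %||% "region",
      start = attr(target, "start") %||% 0,
      bin_size = attr(target, "bin_size") %||% 5000
    ), scales[k])
    sa_fit_one(tgt, config, topology, scales[k])
  })
  if (length(fits) == 1) return(fits[[1]])
  corrs <- vapply(fits, function(f) f$correlation, numeric(1))
  best <- fits[[which.max(corrs)]]
  best$scan <- tibble(
    scale = scales, correlation = corrs,
    fidelity_cost = vapply(fits, function(f) f$fidelity_cost, numeric(1))
  )
  best
}

sa_fit_one <- function(target, config, topology, scale) {
  Tn <- prepare_target(target, config$smoothing_sigma)
  n <- nrow(Tn)
  idx <- seq_len(n) - 1
  d <- abs(outer(idx, idx, "-"))
  if (topology == "circular") d <- pmin(d, n - d)
  p0 <- pmax(d, 1)^(-config$decay$alpha)
  s <- rep_len(config$decay$class_strength %||% 1, config$n_classes)

  set.seed(config$seed)
  b0 <- matrix(0L, n, config$n_classes)
  if ((config$init %||% "random") == "random") {
    # spatially correlated start: random contiguous runs (~10 beads) of a
    # random class each, so same-class pairs exist and the anneal has a
    # fidelity gradient to follow from the first iteration
    breaks <- c(TRUE, runif(n - 1) < 0.1)
    run_id <- cumsum(breaks)
    run_cls <- sample.int(config$n_classes, max(run_id), replace = TRUE)
    b0[cbind(seq_len(n), run_cls[run_id])] <- 1L
  }
  res <- sa_fit_cpp(
    Tn, p0, config$decay$kappa, s, config$n_classes, config$lambda,
    config$n_iter, config$proposals_per_iteration, config$t0, config$cooling,
    config$max_multiplicity, config$cost_norm == "L2", config$trace_every, b0
  )

  bin_size <- (attr(target, "bin_size") %||% 5000)
  polymer <- polymer_model(res$binding, bin_size = bin_size, topology = topology)
  recon <- as_plain_matrix(reconstruct_meanfield(polymer, config$decay))
  corr <- tryCatch(distance_corrected_correlation(Tn, recon), error = function(e) NA_real_)

  structure(
    list(
      polymer = polymer,
      cost = res$cost,
      fidelity_cost = res$fidelity_cost,
      trace = tibble(
        iteration = res$trace_iter, best_cost = res$trace_cost,
        best_fidelity = res$trace_fid
      ),
      correlation = corr,
      scale = scale,
      config = config,
      target = contact_matrix(Tn, bin_size = bin_size)
    ),
    class = "prismr_fit"
  )
}

#' Cost of a fixed polymer against a target matrix
#'
#' Evaluates the SA objective (fidelity + `lambda` penalty) for a given
#' binding table under the identical smoothing/normalization path as
#' [sa_fit()]; useful to compare a fit against a known ground-truth polymer.
#'
#' @inheritParams sa_fit
#' @param polymer a [polymer_model()].
#' @return scalar cost.
#' @export
prismr_cost <- function(target, polymer, config) {
  Tn <- prepare_target(target, config$smoothing_sigma)
  n <- nrow(Tn)
  idx <- seq_len(n) - 1
  d <- abs(outer(idx, idx, "-"))
  if (polymer$topology == "circular") d <- pmin(d, n - d)
  p0 <- pmax(d, 1)^(-config$decay$alpha)
  s <- rep_len(config$decay$class_strength %||% 1, polymer$n_classes)
  b <- polymer$binding
  storage.mode(b) <- "integer"
  sa_cost_cpp(Tn, p0, config$decay$kappa, s, b, config$lambda,
              config$cost_norm == "L2")
}

#' @export
print.prismr_fit <- function(x, ...) {
  cat(sprintf(
    "<prismr_fit> %d beads x %d classes | cost %.4g (fidelity %.4g) | r_dc %.3f | scale %.2g\n",
    x$polymer$n_beads, x$polymer$n_classes, x$cost, x$fidelity_cost,
    x$correlation, x$scale
  ))
  invisible(x)
}

#' @export
tidy.prismr_fit <- function(x, ...) tidy(x$polymer)

#' @export
glance.prismr_fit <- function(x, ...) {
  tibble(
    n_beads = x$polymer$n_beads,
    n_classes = x$polymer$n_classes,
    total_sites = sum(x$polymer$binding),
    cost = x$cost,
    fidelity_cost = x$fidelity_cost,
    correlation = x$correlation,
    scale = x$scale
  )
}

#' @export
autoplot.prismr_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$best_cost)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "SA iteration", y = "running-best cost") +
    ggplot2::theme_minimal()
}

#' Select the sparsity weight lambda from a cost profile
#'
#' Runs [sa_fit()] at each supplied `lambda` and returns the largest value
#' whose data-fidelity cost stays within 10% of the low-lambda plateau (the
#' fidelity level at the smallest lambda): the strongest sparsity that does
#' not degrade the fit.
#'
#' @inheritParams sa_fit
#' @param lambdas at least 3 values spanning the plateau, in increasing order.
#' @param rise allowed relative rise above the plateau (default 0.10).
#' @return list with `lambda` (chosen) and `diagnostics` (tibble of lambda,
#'   fidelity cost, qualification).
#' @export
select_lambda <- function(target, lambdas, config, rise = 0.10) {
  if (length(lambdas) < 3) abort("supply at least 3 lambda values.")
  lambdas <- sort(lambdas)
  fits <- lapply(lambdas, function(l) {
    cfg <- config; cfg$lambda <- l
    sa_fit(target, cfg)
  })
  fid <- vapply(fits, function(f) f$fidelity_cost, numeric(1))
  plateau <- fid[1]
  ok <- fid <= (1 + rise) * plateau
  diagnostics <- tibble(lambda = lambdas, fidelity_cost = fid, qualifies = ok)
  if (!any(ok[-1]) && all(diff(fid) > 0)) {
    abort(c("no plateau detectable: fidelity cost rises strictly from the first lambda.",
            i = paste(utils::capture.output(print(diagnostics)), collapse = "\n")))
  }
  list(lambda = max(lambdas[ok]), diagnostics = diagnostics)
}

#' Select the number of binding-site classes M
#'
#' Runs [sa_fit()] for each candidate `M` and returns the smallest `M` whose
#' relative fidelity-cost reduction to `M + 1` falls below `threshold`
#' (i.e. adding classes stops paying).
#'
#' @inheritParams sa_fit
#' @param m_values increasing candidate class counts.
#' @param threshold minimum relative cost reduction that still justifies one
#'   more class (default 0.02). `threshold = 0` returns `max(m_values)`.
#' @return list with `n_classes` (chosen M) and `diagnostics` tibble.
#' @export
select_n_classes <- function(target, m_values, config, threshold = 0.02) {
  if (is.unsorted(m_values, strictly = TRUE)) abort("`m_values` must be strictly increasing.")
  fits <- lapply(m_values, function(m) {
    cfg <- config; cfg$n_classes <- as.integer(m)
    sa_fit(target, cfg)
  })
  fid <- vapply(fits, function(f) f$fidelity_cost, numeric(1))
  reduction <- c(pmax(0, (fid[-length(fid)] - fid[-1]) / fid[-length(fid)]), NA)
  chosen <- NA_integer_
  for (k in seq_along(m_values)[-length(m_values)]) {
    if (reduction[k] < threshold) { chosen <- m_values[k]; break }
  }
  if (is.na(chosen)) chosen <- m_values[length(m_values)]
  list(
    n_classes = chosen,
    diagnostics = tibble(m = m_values, fidelity_cost = fid,
                         relative_reduction = reduction)
  )
}
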