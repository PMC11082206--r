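# Shared fixtures and independent oracles used across the suite.

# Best class-correlation after label matching (classes are exchangeable in
# the SA fit; match by the permutation maximizing mean per-class correlation).
matched_class_correlation <- function(truth, fitted) {
  M <- ncol(truth)
  perms <- combinat_perms(M)
  suppressWarnings(max(vapply(perms, function(p) {
    mean(vapply(seq_len(M), function(c) {
      v <- fitted[, p[c]]
      if (stats::sd(v) == 0) return(-1)
      stats::cor(truth[, c], v)
    }, numeric(1)))
  }, numeric(1))))
}

combinat_perms <- function(n) {
  rec <- function(v) {
    if (length(v) == 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(rec(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  rec(seq_len(n))
}

# Independent brute-force re-count of ensemble contact frequencies.
brute_force_contacts <- function(conformations, radius) {
  n <- nrow(conformations[[1]])
  counts <- matrix(0, n, n)
  for (xyz in conformations) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        dx <- xyz[i, ] - xyz[j, ]
        if (sqrt(sum(dx^2)) <= radius) counts[i, j] <- counts[i, j] + 1
      }
    }
  }
  P <- counts / length(conformations)
  diag(P) <- 1
  P
}

# Per-pair contact frequencies with batch-mean Monte-Carlo standard errors.
pair_freqs_with_se <- function(ensemble, radius, n_batch = 10) {
  ids <- cut(seq_along(ensemble$conformations), n_batch, labels = FALSE)
  n <- nrow(ensemble$conformations[[1]])
  ut <- which(upper.tri(matrix(0, n, n)))
  f <- vapply(seq_len(n_batch), function(b) {
    acc <- matrix(0, n, n)
    sel <- which(ids == b)
    for (k in sel) {
      d <- as.matrix(stats::dist(ensemble$conformations[[k]]))
      acc <- acc + (d <= radius)
    }
    (acc / length(sel))[ut]
  }, numeric(length(ut)))
  list(mean = rowMeans(f), se = apply(f, 1, stats::sd) / sqrt(n_batch))
}

# Hand-rolled Benjamini-Yekutieli step-up (oracle for adjust_by()).
brute_force_by <- function(p) {
  m <- length(p)
  H <- sum(1 / seq_len(m))
  o <- order(p)
  q_sorted <- p[o] * m * H / seq_len(m)
  # monotonicity pass (step-up)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Synthetic MYC-like fixture: a circular hybrid of a short promoter-bearing
# segment and a longer enhancer-bearing segment plus the 80 kbp buffer, with
# promoter and enhancers sharing binding class 1.
myc_like_fixture <- function(bin_size = 5000) {
  segs <- tibble::tibble(
    chrom = c("chr8", "chr12"),
    start = c(127710000, 57700000),
    end = c(127780000, 58155000),
    orientation = "forward"
  )
  assembly <- assemble_hybrid(segs, topology = "circular", buffer_bp = 80000,
                              bin_size = bin_size)
  B <- matrix(0, assembly$n_bins, 2)
  promoter <- 7L                      # on the chr8 segment (bins 1-14)
  enhancers <- c(40L, 60L, 80L)       # on the chr12 segment (bins 15-105)
  B[promoter, 1] <- 1
  B[enhancers, 1] <- 1
  list(assembly = assembly, binding = B,
       promoter = promoter, enhancers = enhancers)
}

# Uniform random genomic property track on the synthetic genome, 1 kbp bins.
random_property_track <- function(genome, seed, bin = 1000) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(nrow(genome)), function(g) {
    starts <- seq(0, genome$length[g] - bin, by = bin)
    tibble::tibble(chrom = genome$chrom[g], start = starts, end = starts + bin,
                   value = stats::rnorm(length(starts)))
  }))
}
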