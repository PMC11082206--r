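#' Effective bin distance on a linear or circular locus
#'
#' Linear topology: `|i - j|`. Circular topology (the ecDNA case): the
#' minimal distance around the ring, `min(|i - j|, n - |i - j|)`. Indices are
#' 0-based, `0 <= i, j < n_bins`; vectorized.
#'
#' @param i,j 0-based bin indices.
#' @param n_bins total bins.
#' @param topology `"linear"` or `"circular"`.
#' @return distance in bins.
#' @export
circular_distance <- function(i, j, n_bins, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (any(i < 0 | i >= n_bins | j < 0 | j >= n_bins)) {
    abort("bin indices must lie in [0, n_bins).")
  }
  d <- abs(i - j)
  if (topology == "circular") d <- pmin(d, n_bins - d)
  d
}

#' Assemble a rearranged (hybrid) locus from oriented segments
#'
#' Concatenates ordered, oriented reference segments into a hybrid locus and
#' emits the bin-level mapping back to reference coordinates. For circular
#' topology an inert buffer segment (default 80 kbp) closes the ring between
#' the last and first segment — it carries no binding sites and no track
#' signal, and interacts only through the distance-decay baseline. Segment
#' boundaries are snapped to the bin grid by flooring (with a message).
#'
#' If an SV table is supplied, orientation signs are checked against declared
#' types (deletions must be `+-`; duplications `-+`, `++` or `--`).
#'
#' @param segments tibble with `chrom`, `start`, `end` (bp, 0-based
#'   half-open) and `orientation` (`"forward"`/`"reverse"`), in hybrid order.
#' @param svs optional [sv_records()] tibble used for consistency checks.
#' @param buffer_bp inert buffer closing a circular assembly (default 80000).
#' @param topology `"linear"` or `"circular"`.
#' @param bin_size bin width, bp.
#' @return a `hybrid_assembly`: segments (with `is_buffer`, `n_bins`),
#'   `bin_map` (per hybrid bin: source segment, chrom, reference bin start,
#'   `is_buffer`), `topology`, `bin_size`, `n_bins`.
#' @export
assemble_hybrid <- function(segments, svs = NULL, buffer_bp = 80000,
                            topology = c("linear", "circular"),
                            bin_size = 5000) {
  topology <- match.arg(topology)
  segments <- as_tibble(segments)
  if (!all(c("chrom", "start", "end") %in% names(segments))) {
    abort("`segments` needs columns chrom, start, end.")
  }
  if (!"orientation" %in% names(segments)) segments$orientation <- "forward"
  if (!all(segments$orientation %in% c("forward", "reverse"))) {
    abort("orientation must be 'forward' or 'reverse'.")
  }
  if (any(segments$end <= segments$start)) abort("segment end must exceed start.")
  snapped_start <- floor(segments$start / bin_size) * bin_size
  snapped_end <- floor(segments$end / bin_size) * bin_size
  if (any(snapped_start != segments$start) || any(snapped_end != segments$end)) {
    inform("segment boundaries snapped down to the bin grid.")
  }
  segments$start <- snapped_start
  segments$end <- snapped_end
  if (any(segments$end <= segments$start)) abort("segment shorter than one bin after snapping.")
  segments$is_buffer <- FALSE

  if (!is.null(svs)) check_sv_orientations(svs)

  if (topology == "circular" && buffer_bp > 0) {
    buf_bp <- floor(buffer_bp / bin_size) * bin_size
    segments <- bind_rows(segments, tibble(
      chrom = "buffer", start = 0, end = buf_bp,
      orientation = "forward", is_buffer = TRUE
    ))
  }
  segments$n_bins <- as.integer((segments$end - segments$start) / bin_size)

  maps <- purrr::map(seq_len(nrow(segments)), function(k) {
    nb <- segments$n_bins[k]
    ref_bin_starts <- segments$start[k] + (seq_len(nb) - 1) * bin_size
    if (segments$orientation[k] == "reverse") ref_bin_starts <- rev(ref_bin_starts)
    tibble(
      segment = k, chrom = segments$chrom[k],
      ref_start = if (segments$is_buffer[k]) rep(NA_real_, nb) else ref_bin_starts,
      orientation = segments$orientation[k],
      is_buffer = segments$is_buffer[k]
    )
  })
  bin_map <- bind_rows(maps) %>% mutate(hybrid_bin = row_number()) %>%
    select("hybrid_bin", "segment", "chrom", "ref_start", "orientation", "is_buffer")

  structure(
    list(
      segments = segments, bin_map = bin_map, topology = topology,
      bin_size = bin_size, n_bins = nrow(bin_map)
    ),
    class = "hybrid_assembly"
  )
}

check_sv_orientations <- function(svs) {
  intra <- dplyr::filter(svs, .data$chrom1 == .data$chrom2)
  bad_del <- intra$sv_type == "deletion" &
    !(intra$sign1 == "+" & intra$sign2 == "-")
  bad_dup <- intra$sv_type == "duplication" &
    (intra$sign1 == "+" & intra$sign2 == "-")
  if (any(bad_del) || any(bad_dup)) {
    abort("orientation signs inconsistent with declared sv_type.")
  }
  invisible(svs)
}

#' @export
print.hybrid_assembly <- function(x, ...) {
  cat(sprintf(
    "<hybrid_assembly> %s | %d segments (%d buffer) | %d bins @ %s bp = %s bp\n",
    x$topology, nrow(x$segments), sum(x$segments$is_buffer), x$n_bins,
    format(x$bin_size, scientific = FALSE),
    format(x$n_bins * x$bin_size, scientific = FALSE)
  ))
  invisible(x)
}

#' Map hybrid bins to reference coordinates
#'
#' @param assembly a [assemble_hybrid()] result.
#' @param hybrid_bins 1-based hybrid bin indices (default all).
#' @return tibble rows of the assembly's bin map.
#' @export
hybrid_to_reference <- function(assembly, hybrid_bins = NULL) {
  bm <- assembly$bin_map
  if (is.null(hybrid_bins)) bm else bm[hybrid_bins, , drop = FALSE]
}

#' Map reference positions to hybrid bins
#'
#' @param assembly a [assemble_hybrid()] result.
#' @param chrom,pos reference chromosome and bp position vectors.
#' @return integer hybrid bin (NA when the position is not in the assembly).
#' @export
reference_to_hybrid <- function(assembly, chrom, pos) {
  bm <- assembly$bin_map
  bs <- assembly$bin_size
  vapply(seq_along(chrom), function(k) {
    hit <- which(!bm$is_buffer & bm$chrom == chrom[k] &
                   bm$ref_start <= pos[k] & pos[k] < bm$ref_start + bs)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
}

#' Predict the contact map of a rearranged locus
#'
#' Mean-field reconstruction ([reconstruct_meanfield()]) on the hybrid
#' coordinate system: pairwise effective distances follow the assembly
#' topology (minimal circular distance on rings), binding information is
#' taken per hybrid bin, and inert buffer bins are forced to zero binding so
#' they interact only through the distance-decay baseline.
#'
#' @param assembly a [assemble_hybrid()] result.
#' @param binding per-hybrid-bin binding: an `n_bins x M` matrix (integer
#'   multiplicities or transferred class probabilities), a
#'   [transfer_classes()] profile, or a [polymer_model()] of matching length.
#'   Buffer bins may be omitted from none — the matrix must cover all hybrid
#'   bins (buffer rows are zeroed regardless).
#' @param decay a [decay_params()].
#' @return a `contact_matrix` over hybrid bins.
#' @export
predict_neo_contacts <- function(assembly, binding, decay = decay_params()) {
  B <- binding_matrix_for(assembly, binding)
  n <- assembly$n_bins
  idx <- seq_len(n) - 1
  d <- abs(outer(idx, idx, "-"))
  if (assembly$topology == "circular") d <- pmin(d, n - d)
  p0 <- pmax(d, 1)^(-decay$alpha)
  diag(p0) <- 1
  s <- rep_len(decay$class_strength %||% 1, ncol(B))
  A <- matrix(0, n, n)
  for (c in seq_len(ncol(B))) {
    A <- A + s[c] * outer(B[, c], B[, c], pmin)
  }
  P <- p0 * (1 + decay$kappa * A)
  contact_matrix(P, chrom = "hybrid", start = 0, bin_size = assembly$bin_size)
}

#' Baseline contact map with the segments left unjoined
#'
#' The two-locus control: each segment keeps its within-segment linear
#' mean-field contacts, while cross-segment contacts are zero (unjoined loci
#' on different chromosomes have no baseline cis contact). Comparing against
#' [predict_neo_contacts()] isolates what the rearrangement itself creates.
#'
#' @inheritParams predict_neo_contacts
#' @return a `contact_matrix` over the same hybrid bins.
#' @export
predict_unjoined_contacts <- function(assembly, binding, decay = decay_params()) {
  B <- binding_matrix_for(assembly, binding)
  n <- assembly$n_bins
  seg <- assembly$bin_map$segment
  idx <- seq_len(n) - 1
  d <- abs(outer(idx, idx, "-"))
  p0 <- pmax(d, 1)^(-decay$alpha)
  diag(p0) <- 1
  s <- rep_len(decay$class_strength %||% 1, ncol(B))
  A <- matrix(0, n, n)
  for (c in seq_len(ncol(B))) {
    A <- A + s[c] * outer(B[, c], B[, c], pmin)
  }
  P <- p0 * (1 + decay$kappa * A)
  same <- outer(seg, seg, "==")
  P[!same] <- 0
  diag(P) <- 1
  contact_matrix(P, chrom = "hybrid_unjoined", start = 0,
                 bin_size = assembly$bin_size)
}

binding_matrix_for <- function(assembly, binding) {
  B <- if (is_polymer_model(binding)) {
    binding$binding
  } else if (inherits(binding, "class_probability_profile")) {
    profile_matrix(binding)
  } else {
    as.matrix(binding)
  }
  if (nrow(B) != assembly$n_bins) {
    abort(sprintf(
      "binding information covers %d bins but the assembly has %d (non-buffer binding must be supplied for every bin).",
      nrow(B), assembly$n_bins
    ))
  }
  B[assembly$bin_map$is_buffer, ] <- 0
  B
}

#' Call candidate neoloops on a predicted contact map
#'
#' Observed-over-expected peak picking: pixels are z-scored within their
#' effective-distance stratum, and local maxima (3x3 neighbourhood) with
#' `z >= z_threshold` at separation `>= min_dist` bins become candidates.
#' Candidates touching buffer bins are dropped; `crosses_breakpoint` is set
#' when the two anchors map to different source segments.
#'
#' @param predicted a [predict_neo_contacts()] matrix.
#' @param assembly the matching [assemble_hybrid()] result.
#' @param z_threshold minimum stratum z-score (default 2).
#' @param min_dist minimum anchor separation in bins (default 2).
#' @return tibble of candidates sorted by decreasing score: hybrid anchors,
#'   reference coordinates, `score`, `crosses_breakpoint`.
#' @export
call_candidate_neoloops <- function(predicted, assembly, z_threshold = 2,
                                    min_dist = 2) {
  P <- as_plain_matrix(predicted)
  n <- nrow(P)
  idx <- seq_len(n) - 1
  d <- abs(outer(idx, idx, "-"))
  if (assembly$topology == "circular") d <- pmin(d, n - d)
  Z <- matrix(0, n, n)
  for (dd in unique(as.vector(d))) {
    sel <- d == dd
    v <- P[sel]
    mu <- mean(v); sg <- sd(v)
    Z[sel] <- if (is.na(sg) || sg == 0) 0 else (v - mu) / sg
  }
  buf <- assembly$bin_map$is_buffer
  seg <- assembly$bin_map$segment
  cand <- which(upper.tri(P) & d >= min_dist & Z >= z_threshold &
                  !outer(buf, buf, "|"), arr.ind = TRUE)
  if (nrow(cand) > 0) {
    keep <- vapply(seq_len(nrow(cand)), function(k) {
      i <- cand[k, 1]; j <- cand[k, 2]
      ni <- max(1, i - 1):min(n, i + 1)
      nj <- max(1, j - 1):min(n, j + 1)
      Z[i, j] >= max(Z[ni, nj])
    }, logical(1))
    cand <- cand[keep, , drop = FALSE]
  }
  bm <- assembly$bin_map
  out <- tibble(
    anchor1 = as.integer(cand[, 1]), anchor2 = as.integer(cand[, 2]),
    chrom1 = bm$chrom[cand[, 1]], ref_pos1 = bm$ref_start[cand[, 1]],
    chrom2 = bm$chrom[cand[, 2]], ref_pos2 = bm$ref_start[cand[, 2]],
    score = Z[cand],
    crosses_breakpoint = seg[cand[, 1]] != seg[cand[, 2]]
  )
  arrange(out, desc(.data$score))
}
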