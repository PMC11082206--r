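#' Specification of a synthetic study system
#'
#' Bundles the parameters from which every synthetic input — polymers with
#' planted binding classes, ground-truth contact maps, class-correlated
#' tracks, SV sets with matching CNV profiles — is generated. All generator
#' outputs are pure functions of the spec (identical seed, identical output),
#' so planted ground truth is always recoverable for testing.
#'
#' @param seed integer master seed.
#' @param n_beads polymer length in beads (>= 10).
#' @param n_classes planted number of binding classes (>= 1).
#' @param bin_size bp per bead/bin (default 5000).
#' @param class_layout `"block"` (contiguous equal blocks, one class each) or
#'   `"interleaved"` (classes cycle bead by bead).
#' @param track_noise standard deviation of the additive Gaussian noise on
#'   generated tracks.
#' @param genome toy genome for SV simulation: tibble `chrom`, `length`
#'   (default two 10 Mbp chromosomes, so the enrichment suite runs in
#'   seconds).
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L, n_beads = 100L, n_classes = 3L,
                           bin_size = 5000,
                           class_layout = c("block", "interleaved"),
                           track_noise = 0,
                           genome = tibble(chrom = c("chrS1", "chrS2"),
                                           length = c(1e7, 1e7))) {
  class_layout <- match.arg(class_layout)
  if (n_beads < 10) abort("`n_beads` must be >= 10.")
  if (n_classes < 1) abort("`n_classes` must be >= 1.")
  if (bin_size <= 0) abort("`bin_size` must be > 0.")
  if (track_noise < 0) abort("`track_noise` must be >= 0.")
  structure(
    list(seed = as.integer(seed), n_beads = as.integer(n_beads),
         n_classes = as.integer(n_classes), bin_size = bin_size,
         class_layout = class_layout, track_noise = track_noise,
         genome = as_tibble(genome)),
    class = "synthetic_spec"
  )
}

#' Polymer with planted binding classes
#'
#' Block layout: the chain is cut into `n_classes` contiguous, equally sized
#' blocks, each carrying multiplicity 1 of its own class. Interleaved layout:
#' classes cycle bead by bead. The planted table is the ground truth that
#' inference should recover.
#'
#' @param spec a [synthetic_spec()].
#' @param topology `"linear"` (default) or `"circular"`.
#' @return a [polymer_model()].
#' @export
make_toy_polymer <- function(spec, topology = "linear") {
  n <- spec$n_beads; M <- spec$n_classes
  cls <- switch(spec$class_layout,
    block = rep(seq_len(M), each = ceiling(n / M), length.out = n),
    interleaved = rep_len(seq_len(M), n),
    abort(sprintf("unknown class layout '%s'.", spec$class_layout))
  )
  binding <- matrix(0, n, M)
  binding[cbind(seq_len(n), cls)] <- 1
  polymer_model(binding, bin_size = spec$bin_size, topology = topology)
}

#' Ground-truth contact matrix for a planted polymer
#'
#' Forward model for recovery tests: `"meanfield"` runs the analytic
#' reconstruction ([reconstruct_meanfield()]), `"sbs"` samples a 3D ensemble
#' ([run_sbs()]) and counts contacts. The generating polymer travels along as
#' the `ground_truth` attribute.
#'
#' @param polymer a [polymer_model()].
#' @param mode `"meanfield"` or `"sbs"`.
#' @param config a [decay_params()] (meanfield) or [sbs_config()] (sbs);
#'   `NULL` uses defaults.
#' @return a `contact_matrix` with the polymer attached as `ground_truth`.
#' @export
make_ground_truth_hic <- function(polymer, mode = c("meanfield", "sbs"),
                                  config = NULL) {
  mode <- match.arg(mode)
  m <- if (mode == "meanfield") {
    reconstruct_meanfield(polymer, config %||% decay_params())
  } else {
    contacts_from_ensemble(run_sbs(polymer, config %||% sbs_config()))
  }
  attr(m, "ground_truth") <- polymer
  m
}

#' Class-correlated synthetic tracks
#'
#' Emulates the epigenetic tracks used as the cross-chromosome bridge: one
#' track per class with per-bin signal `weight * 1[class c at bin] +
#' N(0, noise)`. With `noise = 0` each track equals its class indicator and
#' the planted class-track correlation is exactly 1; as noise grows the
#' correlation decays to 0. The planted association (track `i` <-> class `i`)
#' is recorded in the `association` attribute.
#'
#' @param polymer a [polymer_model()] with planted classes.
#' @param noise Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param weights per-class signal weights (default all 1).
#' @param chrom chromosome label stamped on the tracks.
#' @return named list of raw [binned_track()]s, one per class.
#' @export
make_class_tracks <- function(polymer, noise = 0, seed = 1L, weights = NULL,
                              chrom = "chrS1") {
  if (noise < 0) abort("`noise` must be >= 0.")
  M <- polymer$n_classes
  w <- rep_len(weights %||% 1, M)
  set.seed(seed)
  tracks <- lapply(seq_len(M), function(c) {
    v <- w[c] * as.numeric(polymer$binding[, c] > 0) +
      rnorm(polymer$n_beads, 0, noise)
    binned_track(v, chrom = chrom, start = 0, bin_size = polymer$bin_size,
                 kind = "raw")
  })
  names(tracks) <- paste0("class", seq_len(M), "_track")
  attr(tracks, "association") <- tibble(track = names(tracks), class = seq_len(M))
  tracks
}

#' Synthetic SV set with matching CNV profile
#'
#' Draws `n_svs` SVs on the spec's toy genome with the field's orientation
#' conventions — duplications get `-+`, `++` or `--` junctions, deletions
#' `+-`, inversions `++`/`--`, translocations random signs across two
#' chromosomes — and builds the consistent copy-number profile: ratio 2.0
#' inside duplicated intervals, 0.5 inside deleted ones, 1.0 elsewhere
#' (clearly beyond the 1.35/0.65 classifier thresholds, so planted labels are
#' unambiguous). With `effect_size > 0` and a property track, breakpoint
#' positions are drawn from top-decile property bins with that probability,
#' planting an enrichment signal of known strength; `effect_size = 0` places
#' breakpoints uniformly over mappable bins.
#'
#' @param spec a [synthetic_spec()].
#' @param n_svs number of SVs.
#' @param property_tracks optional property tibble (`chrom`, `start`, `end`,
#'   `value`) used for planted enrichment.
#' @param effect_size probability that a breakpoint is forced into a
#'   top-decile property bin (default 0).
#' @param type_mix sampling weights over SV types.
#' @param span_range intrachromosomal span range, bp.
#' @return list with `svs` ([sv_records()], planted labels in `sv_type`) and
#'   `cnv` ([cnv_profile()] at `spec$bin_size`).
#' @export
make_sv_set <- function(spec, n_svs, property_tracks = NULL, effect_size = 0,
                        type_mix = c(duplication = 0.3, deletion = 0.3,
                                     inversion = 0.2, translocation = 0.2),
                        span_range = c(5e4, 5e5)) {
  genome <- spec$genome
  if (nrow(genome) == 0) abort("spec genome is empty.")
  max_span <- max(span_range)
  if (any(genome$length <= max_span)) abort("chromosomes shorter than the SV span range.")
  if (n_svs > 50 * sum(genome$length) / max_span) {
    abort("`n_svs` exceeds placeable capacity on this genome.")
  }
  set.seed(spec$seed)
  types <- sample(names(type_mix), n_svs, replace = TRUE, prob = type_mix)

  top_bins <- NULL
  if (effect_size > 0) {
    if (is.null(property_tracks)) abort("`property_tracks` required when effect_size > 0.")
    cut <- quantile(property_tracks$value, 0.9)
    top_bins <- property_tracks[property_tracks$value > cut, , drop = FALSE]
  }

  draw_pos <- function(chrom, upper) {
    if (!is.null(top_bins) && runif(1) < effect_size) {
      cand <- top_bins[top_bins$chrom == chrom & top_bins$start < upper, , drop = FALSE]
      if (nrow(cand) > 0) {
        k <- sample(nrow(cand), 1)
        return(cand$start[k] + floor(runif(1, 0, cand$end[k] - cand$start[k])))
      }
    }
    floor(runif(1, 0, upper))
  }

  # dup/del intervals are kept disjoint so painted CNV ratios (and planted
  # labels) stay unambiguous
  occupied <- list()
  overlaps_occupied <- function(chrom, lo, hi) {
    occ <- occupied[[chrom]]
    !is.null(occ) && any(occ$lo < hi & occ$hi > lo)
  }
  rows <- purrr::map(seq_len(n_svs), function(k) {
    type <- types[k]
    if (type == "translocation") {
      chroms <- sample(genome$chrom, 2, replace = nrow(genome) == 1)
      tibble(
        chrom1 = chroms[1],
        pos1 = draw_pos(chroms[1], genome$length[genome$chrom == chroms[1]]),
        chrom2 = chroms[2],
        pos2 = draw_pos(chroms[2], genome$length[genome$chrom == chroms[2]]),
        sign1 = sample(c("+", "-"), 1), sign2 = sample(c("+", "-"), 1),
        sv_type = type
      )
    } else {
      chrom <- sample(genome$chrom, 1)
      L <- genome$length[genome$chrom == chrom]
      span <- floor(runif(1, span_range[1], span_range[2]) / spec$bin_size) * spec$bin_size
      cnv_sv <- type %in% c("duplication", "deletion")
      for (try in seq_len(1000)) {
        p1 <- floor(draw_pos(chrom, L - span) / spec$bin_size) * spec$bin_size
        if (!cnv_sv || !overlaps_occupied(chrom, p1, p1 + span)) break
        if (try == 1000) abort("`n_svs` exceeds placeable capacity on this genome.")
      }
      if (cnv_sv) {
        occupied[[chrom]] <<- bind_rows(occupied[[chrom]],
                                        tibble(lo = p1, hi = p1 + span))
      }
      signs <- switch(type,
        duplication = sample(c("-+", "++", "--"), 1),
        deletion = "+-",
        inversion = sample(c("++", "--"), 1)
      )
      tibble(
        chrom1 = chrom, pos1 = p1, chrom2 = chrom, pos2 = p1 + span,
        sign1 = substr(signs, 1, 1), sign2 = substr(signs, 2, 2),
        sv_type = type
      )
    }
  })
  svs <- sv_records(bind_rows(rows))

  cnv <- purrr::map(seq_len(nrow(genome)), function(g) {
    starts <- seq(0, genome$length[g] - spec$bin_size, by = spec$bin_size)
    tibble(chrom = genome$chrom[g], start = starts,
           end = starts + spec$bin_size, ratio = 1.0)
  }) %>% bind_rows()
  for (k in seq_len(nrow(svs))) {
    if (svs$sv_type[k] %in% c("duplication", "deletion")) {
      lo <- min(svs$pos1[k], svs$pos2[k]); hi <- max(svs$pos1[k], svs$pos2[k])
      sel <- cnv$chrom == svs$chrom1[k] & cnv$start >= lo & cnv$end <= hi
      cnv$ratio[sel] <- if (svs$sv_type[k] == "duplication") 2.0 else 0.5
    }
  }
  list(svs = svs, cnv = cnv_profile(cnv))
}
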