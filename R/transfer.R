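#' Binned genomic track
#'
#' A fixed-bin signal track (RNA-seq coverage, H3K27ac, a genomic property,
#' ...) held as a tibble with `chrom`, `start`, `end`, `value` and the bin
#' size / kind recorded as attributes. `kind = "indicator"` tracks carry only
#' 0/1 values and are what the probabilistic transfer consumes.
#'
#' @param values per-bin signal.
#' @param chrom chromosome name.
#' @param start 0-based start of the first bin, bp.
#' @param bin_size bin width, bp.
#' @param kind `"raw"` or `"indicator"`.
#' @return a `binned_track` tibble.
#' @export
binned_track <- function(values, chrom = "chr1", start = 0, bin_size = 5000,
                         kind = c("raw", "indicator")) {
  kind <- match.arg(kind)
  if (anyNA(values) || any(!is.finite(values))) abort("track values must be finite.")
  if (kind == "indicator" && !all(values %in% c(0, 1))) {
    abort("indicator tracks must only hold 0/1 values.")
  }
  starts <- start + (seq_along(values) - 1) * bin_size
  out <- tibble(chrom = chrom, start = starts, end = starts + bin_size,
                value = as.numeric(values))
  attr(out, "bin_size") <- bin_size
  attr(out, "kind") <- kind
  class(out) <- c("binned_track", class(out))
  out
}

track_kind <- function(t) attr(t, "kind") %||% "raw"

#' Binarize a track into an indicator
#'
#' Turns a raw signal track into a 0/1 indicator, either by thresholding at a
#' quantile of its values (`rule = "quantile"`, default top quartile) or by
#' flagging bins overlapping supplied peak intervals (`rule = "peaks"`).
#' Indicator input is returned unchanged (idempotent).
#'
#' @param t a [binned_track()].
#' @param rule `"quantile"` or `"peaks"`.
#' @param q quantile cut (bins with value strictly above the `q`-quantile are
#'   set to 1); default 0.75.
#' @param peaks tibble/data.frame of intervals (`chrom`, `start`, `end`) for
#'   `rule = "peaks"`.
#' @return indicator `binned_track`.
#' @export
binarize_track <- function(t, rule = c("quantile", "peaks"), q = 0.75,
                           peaks = NULL) {
  rule <- match.arg(rule)
  if (track_kind(t) == "indicator") return(t)
  if (all(t$value == 0)) warn("all-zero track: indicator probabilities degenerate.")
  ind <- if (rule == "quantile") {
    as.numeric(t$value > quantile(t$value, q))
  } else {
    if (is.null(peaks)) abort("`peaks` intervals required for the peaks rule.")
    hit <- rep(FALSE, nrow(t))
    for (k in seq_len(nrow(peaks))) {
      hit <- hit | (t$chrom == peaks$chrom[k] &
                      t$start < peaks$end[k] & t$end > peaks$start[k])
    }
    as.numeric(hit)
  }
  binned_track(ind, chrom = t$chrom[1], start = t$start[1],
               bin_size = attr(t, "bin_size"), kind = "indicator")
}

as_indicator_vector <- function(x, what = "input") {
  v <- if (inherits(x, "binned_track") || is.data.frame(x)) x$value else as.numeric(x)
  if (!all(v %in% c(0, 1))) abort(sprintf("%s is not a 0/1 indicator.", what))
  v
}

#' Indicator correlation between a binding class and a track
#'
#' For indicator vectors `1_C` and `1_T` over the same bins, computes the
#' occupancy frequencies `P_C`, `P_T`, the joint `P(C ∩ T)`, and the
#' Pearson correlation of the indicators,
#' `corr = (P(C ∩ T) - P_C P_T) / sqrt(P_C (1-P_C) P_T (1-P_T))` —
#' which follows from `E(1_X) = p_X`, `var(1_X) = p_X (1 - p_X)`.
#'
#' @param c_ind,t_ind indicator vectors or indicator [binned_track()]s of the
#'   same length; both must be non-degenerate (frequency strictly inside
#'   (0, 1)).
#' @return one-row tibble with `corr`, `p_c`, `p_t`, `p_joint`.
#' @export
class_track_correlation <- function(c_ind, t_ind) {
  cv <- as_indicator_vector(c_ind, "`c_ind`")
  tv <- as_indicator_vector(t_ind, "`t_ind`")
  if (length(cv) != length(tv)) abort("indicators must have the same length.")
  p_c <- mean(cv); p_t <- mean(tv); p_joint <- mean(cv * tv)
  if (p_c %in% c(0, 1) || p_t %in% c(0, 1)) {
    abort("degenerate indicator (all 0 or all 1): correlation undefined.")
  }
  corr <- (p_joint - p_c * p_t) / sqrt(p_c * (1 - p_c) * p_t * (1 - p_t))
  tibble(corr = corr, p_c = p_c, p_t = p_t, p_joint = p_joint)
}

#' Conditional class probability given a track
#'
#' Inverts the covariance/correlation identities to get
#' `P(C|T) = P_C + corr * sqrt(P_C (1 - P_C) (1 - P_T) / P_T)`. Values
#' outside `[0, 1]` (possible only through numerical noise or inconsistent
#' inputs) are clipped with a warning.
#'
#' @param corr indicator correlation of class and track.
#' @param p_c,p_t marginal frequencies; `p_t` must be > 0.
#' @return `P(C|T)` in `[0, 1]`.
#' @export
conditional_probability <- function(corr, p_c, p_t) {
  if (any(p_t == 0)) abort("`p_t` must be > 0.")
  p <- p_c + corr * sqrt(p_c * (1 - p_c) * (1 - p_t) / p_t)
  if (any(p < -1e-12 | p > 1 + 1e-12)) {
    warn("P(C|T) outside [0, 1]; clipping.")
  }
  pmin(pmax(p, 0), 1)
}

#' Build a class-to-track transfer model on a fitted region
#'
#' Correlates every (binding class, track) couple on the source region and
#' stores the conditional probabilities `P(C|T)` needed to transfer classes
#' to an unfitted region. Couples with correlation at or below `threshold`
#' (default 0.2, one-sided as specified — negatively correlated couples are
#' also excluded) are retained in the table but flagged as not included.
#' When two source tracks themselves correlate above the threshold the
#' independence assumption used by [transfer_classes()] is shaky and a
#' warning is raised.
#'
#' @param classes a [polymer_model()] (class indicators are `multiplicity >
#'   0`) or an `n_bins x M` 0/1 indicator matrix.
#' @param tracks named list of indicator [binned_track()]s on the source
#'   region.
#' @param threshold inclusion threshold on `corr(C, T)` (strict >).
#' @return a `transfer_model` tibble with one row per couple: `class`,
#'   `track`, `corr`, `p_c`, `p_t`, `p_joint`, `p_c_given_t`, `included`.
#' @export
build_transfer_model <- function(classes, tracks, threshold = 0.2) {
  ind <- if (is_polymer_model(classes)) (classes$binding > 0) * 1 else as.matrix(classes)
  if (is.null(names(tracks))) names(tracks) <- paste0("track", seq_along(tracks))
  rows <- list()
  for (c in seq_len(ncol(ind))) {
    for (tn in names(tracks)) {
      ct <- class_track_correlation(ind[, c], tracks[[tn]])
      rows[[length(rows) + 1]] <- mutate(ct, class = c, track = tn)
    }
  }
  model <- bind_rows(rows) %>%
    mutate(
      p_c_given_t = conditional_probability(.data$corr, .data$p_c, .data$p_t),
      included = .data$corr > threshold
    ) %>%
    select("class", "track", "corr", "p_c", "p_t", "p_joint",
           "p_c_given_t", "included")
  if (length(tracks) > 1) {
    cmb <- utils::combn(names(tracks), 2)
    for (k in seq_len(ncol(cmb))) {
      tt <- class_track_correlation(tracks[[cmb[1, k]]], tracks[[cmb[2, k]]])
      if (tt$corr > threshold) {
        warn(sprintf(
          "source tracks '%s' and '%s' correlate at %.2f (> %.2f): the neglected intersection terms may matter.",
          cmb[1, k], cmb[2, k], tt$corr, threshold
        ))
      }
    }
  }
  attr(model, "threshold") <- threshold
  class(model) <- c("transfer_model", class(model))
  model
}

#' Transfer binding classes to a target region through tracks
#'
#' Estimates per-bin class probabilities on an unfitted region from its
#' (binarized) tracks: `P_C(x) = sum_i P(C|T_i) P_{T_i}(x)` over the couples
#' that passed the correlation threshold, neglecting track intersection
#' terms. Sums exceeding 1 are clipped with a warning.
#'
#' @param model a [build_transfer_model()] result.
#' @param target_tracks named list of indicator [binned_track()]s on the
#'   target region; names must match the model's track names.
#' @return a `class_probability_profile` tibble: `bin`, `class`,
#'   `probability`.
#' @export
transfer_classes <- function(model, target_tracks) {
  inc <- dplyr::filter(model, .data$included)
  if (nrow(inc) == 0) abort("no (class, track) couple passes the correlation threshold: empty profile.")
  missing <- setdiff(unique(inc$track), names(target_tracks))
  if (length(missing) > 0) {
    abort(sprintf("target tracks missing for: %s", paste(missing, collapse = ", ")))
  }
  n_bins <- length(target_tracks[[1]]$value)
  classes <- sort(unique(model$class))
  P <- matrix(0, n_bins, length(classes),
              dimnames = list(NULL, as.character(classes)))
  for (k in seq_len(nrow(inc))) {
    tv <- as_indicator_vector(target_tracks[[inc$track[k]]],
                              sprintf("target track '%s'", inc$track[k]))
    P[, as.character(inc$class[k])] <- P[, as.character(inc$class[k])] +
      inc$p_c_given_t[k] * tv
  }
  if (any(P > 1 + 1e-12)) warn("transferred probabilities exceed 1; clipping.")
  P <- pmin(P, 1)
  out <- tibble(
    bin = rep(seq_len(n_bins), times = length(classes)),
    class = rep(classes, each = n_bins),
    probability = as.vector(P)
  )
  attr(out, "matrix") <- P
  class(out) <- c("class_probability_profile", class(out))
  out
}

#' Per-bin probability matrix of a transferred profile
#'
#' @param profile a [transfer_classes()] result.
#' @return `n_bins x n_classes` matrix of `P_C(x)`.
#' @export
profile_matrix <- function(profile) {
  attr(profile, "matrix") %||%
    as.matrix(tidyr::pivot_wider(profile, names_from = "class",
                                 values_from = "probability")[, -1])
}
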