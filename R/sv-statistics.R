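#' Structural-variant breakpoint table
#'
#' Validates and classes a tibble of SV breakpoint pairs. Orientation signs
#' follow the convention that `"+"` means the segment to the *left* of the
#' breakpoint is retained in the derivative junction; sign patterns therefore
#' distinguish deletion-like (`+-`) from duplication-like (`-+`, `++`, `--`)
#' junctions.
#'
#' @param x tibble/data.frame with `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `sign1`, `sign2` and optionally `sv_type`.
#' @return an `sv_records` tibble.
#' @export
sv_records <- function(x) {
  x <- as_tibble(x)
  need <- c("chrom1", "pos1", "chrom2", "pos2", "sign1", "sign2")
  if (!all(need %in% names(x))) {
    abort(sprintf("missing columns: %s", paste(setdiff(need, names(x)), collapse = ", ")))
  }
  if (!all(c(x$sign1, x$sign2) %in% c("+", "-"))) abort("signs must be '+' or '-'.")
  if (!"sv_type" %in% names(x)) x$sv_type <- "unclassified"
  ok_types <- c("deletion", "duplication", "inversion", "translocation", "unclassified")
  if (!all(x$sv_type %in% ok_types)) {
    abort(sprintf("sv_type must be one of: %s", paste(ok_types, collapse = ", ")))
  }
  class(x) <- c("sv_records", class(x))
  x
}

#' Binned copy-number ratio profile
#'
#' @param x tibble with `chrom`, `start`, `end`, `ratio` (copy-number ratio
#'   relative to ploidy baseline: > 1 gain, < 1 loss).
#' @return a `cnv_profile` tibble.
#' @export
cnv_profile <- function(x) {
  x <- as_tibble(x)
  if (!all(c("chrom", "start", "end", "ratio") %in% names(x))) {
    abort("`x` needs columns chrom, start, end, ratio.")
  }
  if (anyNA(x$ratio) || any(!is.finite(x$ratio)) || any(x$ratio < 0)) {
    abort("ratios must be finite and >= 0.")
  }
  class(x) <- c("cnv_profile", class(x))
  x
}

#' Duplication/deletion classifier settings
#'
#' Thresholds allow for allelic heterogeneity: a heterozygous duplication in
#' a mixed population shifts the ratio well below the clonal 1.5/0.5.
#'
#' @param dup_ratio_min interval copy-ratio above which a duplication-
#'   oriented SV is called a duplication (default 1.35).
#' @param del_ratio_max interval copy-ratio below which a `+-` SV is called
#'   a deletion (default 0.65).
#' @param interval_stat `"mean"` or `"median"` of per-bin ratios.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(dup_ratio_min = 1.35, del_ratio_max = 0.65,
                              interval_stat = c("mean", "median")) {
  interval_stat <- match.arg(interval_stat)
  if (del_ratio_max >= dup_ratio_min) abort("del_ratio_max must be < dup_ratio_min.")
  structure(list(dup_ratio_min = dup_ratio_min, del_ratio_max = del_ratio_max,
                 interval_stat = interval_stat),
            class = "classifier_config")
}

interval_ratio <- function(cnv, chrom, lo, hi, stat) {
  sel <- cnv$chrom == chrom & cnv$start < hi & cnv$end > lo
  if (!any(sel)) return(NA_real_)
  if (stat == "mean") mean(cnv$ratio[sel]) else stats::median(cnv$ratio[sel])
}

#' Classify intrachromosomal SVs as duplication / deletion
#'
#' Combines breakpoint orientation with the copy-number ratio of the interval
#' between the breakpoints: duplication when the signs are `-+`, `++` or `--`
#' and the interval ratio exceeds `dup_ratio_min`; deletion when the signs
#' are `+-` and the ratio falls below `del_ratio_max`; otherwise
#' `"unclassified"` (orientation-only calls such as inversions are left to
#' upstream annotation).
#'
#' @param svs an [sv_records()] table of intrachromosomal SVs.
#' @param cnv a [cnv_profile()] covering the breakpoint intervals.
#' @param cfg a [classifier_config()].
#' @return character vector of calls, one per SV.
#' @export
classify_intra_sv <- function(svs, cnv, cfg = classifier_config()) {
  if (any(svs$chrom1 != svs$chrom2)) {
    abort("classify_intra_sv() only accepts intrachromosomal SVs.")
  }
  vapply(seq_len(nrow(svs)), function(k) {
    lo <- min(svs$pos1[k], svs$pos2[k]); hi <- max(svs$pos1[k], svs$pos2[k])
    r <- interval_ratio(cnv, svs$chrom1[k], lo, hi, cfg$interval_stat)
    signs <- paste0(svs$sign1[k], svs$sign2[k])
    if (is.na(r)) return("unclassified")
    if (signs %in% c("-+", "++", "--") && r > cfg$dup_ratio_min) return("duplication")
    if (signs == "+-" && r < cfg$del_ratio_max) return("deletion")
    "unclassified"
  }, character(1))
}

#' Distance- and chromosome-preserving shuffled SV nulls
#'
#' Builds `n_sets` randomized copies of an SV table in which every null SV
#' keeps the chromosome(s) and the breakpoint-end separation of its source SV
#' but is placed uniformly among valid positions; the null model for
#' breakpoint-vs-property enrichment.
#'
#' @param svs an [sv_records()] table.
#' @param genome tibble with `chrom`, `length` (bp).
#' @param n_sets number of null sets (default 1000).
#' @param seed integer seed.
#' @return list of `n_sets` sv_records tibbles.
#' @export
shuffle_svs <- function(svs, genome, n_sets = 1000, seed = 1L) {
  glen <- setNames(genome$length, genome$chrom)
  if (!all(c(svs$chrom1, svs$chrom2) %in% names(glen))) {
    abort("all SV chromosomes must appear in `genome`.")
  }
  intra <- svs$chrom1 == svs$chrom2
  span <- abs(svs$pos2 - svs$pos1)
  if (any(intra & span >= glen[svs$chrom1])) {
    abort("an SV span exceeds its chromosome length.")
  }
  set.seed(seed)
  lapply(seq_len(n_sets), function(s) {
    out <- svs
    for (k in seq_len(nrow(svs))) {
      if (intra[k]) {
        L <- glen[[svs$chrom1[k]]]
        p1 <- floor(runif(1, 0, L - span[k]))
        out$pos1[k] <- p1
        out$pos2[k] <- p1 + span[k]
      } else {
        out$pos1[k] <- floor(runif(1, 0, glen[[svs$chrom1[k]]]))
        out$pos2[k] <- floor(runif(1, 0, glen[[svs$chrom2[k]]]))
      }
    }
    out
  })
}

lookup_property <- function(property, chrom, pos) {
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    tr <- property[property$chrom == ch, , drop = FALSE]
    if (nrow(tr) == 0) next
    tr <- tr[order(tr$start), , drop = FALSE]
    idx <- findInterval(pos[sel], tr$start)
    hit <- idx >= 1 & idx <= nrow(tr)
    hit[hit] <- pos[sel][hit] < tr$end[idx[hit]]
    v <- rep(NA_real_, sum(sel))
    v[hit] <- tr$value[idx[hit]]
    out[sel] <- v
  }
  out
}

#' Breakpoint-vs-genomic-property enrichment test
#'
#' Tests whether SV breakpoints fall preferentially into high (or low) values
#' of a binned genomic property. One side of each real breakpoint junction is
#' sampled (seeded) to reduce dependence between observations, and the same
#' side is read from every shuffled null copy of that SV. Real and null
#' property values are pooled, rank-transformed to a 0-1 scale (average ranks
#' on ties), and the real observations' normalized ranks are compared to
#' Uniform(0, 1) with a one-sided Kolmogorov-Smirnov test. Adjust the
#' resulting p-values across a suite with [adjust_by()].
#'
#' @param real_svs an [sv_records()] table.
#' @param null_sets list of shuffled tables from [shuffle_svs()].
#' @param property binned property track: tibble with `chrom`, `start`,
#'   `end`, `value` (1 kbp bins in the reference workflow; any fixed binning
#'   works).
#' @param side_seed seed for the per-junction side choice.
#' @param direction `"greater"` tests for breakpoints in high property values
#'   (default), `"less"` for low.
#' @param property_name label carried into the result.
#' @return one-row tibble: `property`, `sv_type`, `statistic`, `p_value`,
#'   `n_real`, `n_null_sets`, `direction`.
#' @export
breakpoint_enrichment <- function(real_svs, null_sets, property,
                                  side_seed = 1L,
                                  direction = c("greater", "less"),
                                  property_name = "property") {
  direction <- match.arg(direction)
  if (nrow(real_svs) == 0) abort("empty real SV set.")
  if (length(null_sets) < 1) abort("at least one null set required.")
  set.seed(side_seed)
  side <- sample(c(1L, 2L), nrow(real_svs), replace = TRUE)

  pull_side <- function(svs) {
    chrom <- ifelse(side == 1L, svs$chrom1, svs$chrom2)
    pos <- ifelse(side == 1L, svs$pos1, svs$pos2)
    lookup_property(property, chrom, pos)
  }
  real_vals <- pull_side(real_svs)
  null_vals <- unlist(lapply(null_sets, pull_side))
  keep_real <- !is.na(real_vals)
  real_vals <- real_vals[keep_real]
  null_vals <- null_vals[!is.na(null_vals)]
  if (length(real_vals) == 0) abort("no real breakpoint overlaps the property track.")

  pooled <- c(real_vals, null_vals)
  r <- (rank(pooled, ties.method = "average") - 0.5) / length(pooled)
  real_ranks <- r[seq_along(real_vals)]
  # ks.test 'less': CDF below uniform, i.e. observations stochastically larger
  alt <- if (direction == "greater") "less" else "greater"
  ks <- suppressWarnings(ks.test(real_ranks, "punif", alternative = alt))

  tibble(
    property = property_name,
    sv_type = paste(sort(unique(real_svs$sv_type)), collapse = "+"),
    statistic = unname(ks$statistic),
    p_value = ks$p.value,
    n_real = length(real_vals),
    n_null_sets = length(null_sets),
    direction = direction
  )
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up FDR control valid under arbitrary dependence (Benjamini-Hochberg
#' critical values divided by the harmonic number `H(m)`), applied across an
#' entire suite of enrichment tests.
#'
#' @param pvalues p-values in `[0, 1]`.
#' @return adjusted q-values, same length.
#' @export
adjust_by <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BY")
}

loop_midpoints <- function(loops) {
  tibble(
    chrom1 = loops$chrom1, mid1 = (loops$start1 + loops$end1) / 2,
    chrom2 = loops$chrom2, mid2 = (loops$start2 + loops$end2) / 2
  )
}

#' Match two loop sets by anchor proximity
#'
#' Two loops are matchable when, anchor by anchor, the midpoints lie strictly
#' within `tol` bp of each other (and chromosomes agree). Matchable pairs are
#' resolved greedily nearest-first into a one-to-one matching.
#'
#' @param a,b loop tables in BEDPE-like form: `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`.
#' @param tol anchor-midpoint tolerance, bp (strict `<`; default 50000).
#' @return tibble of matched pairs: `a_index`, `b_index`, `d1`, `d2`.
#' @export
match_loops <- function(a, b, tol = 50000) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(a_index = integer(), b_index = integer(),
                  d1 = numeric(), d2 = numeric()))
  }
  ma <- loop_midpoints(a); mb <- loop_midpoints(b)
  pairs <- tidyr::expand_grid(a_index = seq_len(nrow(a)), b_index = seq_len(nrow(b))) %>%
    mutate(
      d1 = abs(ma$mid1[.data$a_index] - mb$mid1[.data$b_index]),
      d2 = abs(ma$mid2[.data$a_index] - mb$mid2[.data$b_index]),
      same_chrom = ma$chrom1[.data$a_index] == mb$chrom1[.data$b_index] &
        ma$chrom2[.data$a_index] == mb$chrom2[.data$b_index]
    ) %>%
    dplyr::filter(.data$same_chrom, .data$d1 < tol, .data$d2 < tol) %>%
    arrange(.data$d1 + .data$d2)
  greedy_one_to_one(pairs)
}

greedy_one_to_one <- function(pairs) {
  used_a <- integer(); used_b <- integer(); keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if (!(pairs$a_index[k] %in% used_a) && !(pairs$b_index[k] %in% used_b)) {
      keep[k] <- TRUE
      used_a <- c(used_a, pairs$a_index[k])
      used_b <- c(used_b, pairs$b_index[k])
    }
  }
  select(pairs[keep, , drop = FALSE], "a_index", "b_index", "d1", "d2")
}

#' Match two SV sets by breakpoint proximity
#'
#' The loop rule reused for SVs (a convention, configurable via `tol`): both
#' breakpoints strictly within `tol` bp on matching chromosomes and, when
#' both tables carry types, the same `sv_type`.
#'
#' @param a,b [sv_records()] tables.
#' @param tol breakpoint tolerance, bp (strict `<`).
#' @return tibble of matched pairs.
#' @export
match_svs <- function(a, b, tol = 50000) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(a_index = integer(), b_index = integer(),
                  d1 = numeric(), d2 = numeric()))
  }
  pairs <- tidyr::expand_grid(a_index = seq_len(nrow(a)), b_index = seq_len(nrow(b))) %>%
    mutate(
      d1 = abs(a$pos1[.data$a_index] - b$pos1[.data$b_index]),
      d2 = abs(a$pos2[.data$a_index] - b$pos2[.data$b_index]),
      ok = a$chrom1[.data$a_index] == b$chrom1[.data$b_index] &
        a$chrom2[.data$a_index] == b$chrom2[.data$b_index] &
        a$sv_type[.data$a_index] == b$sv_type[.data$b_index]
    ) %>%
    dplyr::filter(.data$ok, .data$d1 < tol, .data$d2 < tol) %>%
    arrange(.data$d1 + .data$d2)
  greedy_one_to_one(pairs)
}

#' Jaccard similarity of two interval-pair sets
#'
#' `|matched| / (|a| + |b| - |matched|)` under a tolerance-based matcher
#' ([match_loops()] for loops, [match_svs()] for SVs).
#'
#' @param a,b the two sets.
#' @param matcher matching function returning one row per matched pair.
#' @param ... passed to the matcher (e.g. `tol`).
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b, matcher = match_loops, ...) {
  if (nrow(a) == 0 && nrow(b) == 0) abort("both sets empty: Jaccard undefined.")
  m <- nrow(matcher(a, b, ...))
  m / (nrow(a) + nrow(b) - m)
}
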