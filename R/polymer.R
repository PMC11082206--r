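#' Strings-and-binders polymer model
#'
#' A bead chain in which each bead (one bead per genomic bin) carries
#' non-negative integer multiplicities of `M` binding-site classes. Beads with
#' multiplicity > 0 in class `c` attract diffusing binders of class `c`, which
#' is what folds the chain in the SBS picture.
#'
#' @param binding `n_beads x M` non-negative integer matrix of binding-site
#'   multiplicities.
#' @param bin_size genomic span of one bead, bp.
#' @param topology `"linear"` or `"circular"`. Circular chains bond bead 1 to
#'   bead `n` (ecDNA-like rings).
#' @param labels optional per-bead reference annotation (e.g. a tibble with
#'   `chrom`, `start`), recycled onto the object untouched.
#' @return a `polymer_model`.
#' @export
polymer_model <- function(binding, bin_size = 5000, topology = c("linear", "circular"),
                          labels = NULL) {
  topology <- match.arg(topology)
  if (!is.matrix(binding)) binding <- as.matrix(binding)
  if (nrow(binding) < 2) abort("a polymer needs at least 2 beads.")
  if (anyNA(binding) || any(binding < 0)) abort("binding multiplicities must be >= 0.")
  if (any(binding != round(binding))) abort("binding multiplicities must be integers.")
  storage.mode(binding) <- "double"
  structure(
    list(
      binding = binding,
      n_beads = nrow(binding),
      n_classes = ncol(binding),
      bin_size = as.numeric(bin_size),
      topology = topology,
      labels = labels
    ),
    class = "polymer_model"
  )
}

#' @export
print.polymer_model <- function(x, ...) {
  cat(sprintf(
    "<polymer_model> %d beads x %d classes | %s | %s bp/bead | %d sites total\n",
    x$n_beads, x$n_classes, x$topology,
    format(x$bin_size, scientific = FALSE), sum(x$binding)
  ))
  invisible(x)
}

#' @rdname polymer_model
#' @param x object to test.
#' @export
is_polymer_model <- function(x) inherits(x, "polymer_model")

#' Long-format binding table of a polymer
#'
#' @param x a `polymer_model`.
#' @param ... unused.
#' @return tibble with `bead`, `class`, `multiplicity` (zero rows dropped).
#' @export
tidy.polymer_model <- function(x, ...) {
  b <- x$binding
  out <- tibble(
    bead = rep(seq_len(nrow(b)), times = ncol(b)),
    class = rep(seq_len(ncol(b)), each = nrow(b)),
    multiplicity = as.vector(b)
  )
  dplyr::filter(out, .data$multiplicity > 0) %>% arrange(.data$bead, .data$class)
}

#' Binding-profile heatmap
#'
#' @param object a `polymer_model`.
#' @param ... unused.
#' @export
autoplot.polymer_model <- function(object, ...) {
  b <- object$binding
  df <- tibble(
    bead = rep(seq_len(nrow(b)), times = ncol(b)),
    class = factor(rep(seq_len(ncol(b)), each = nrow(b))),
    multiplicity = as.vector(b)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bead, y = .data$class,
                                   fill = .data$multiplicity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "bead", y = "binding class") +
    ggplot2::theme_minimal()
}

#' Distance-decay parameters of the mean-field contact model
#'
#' The mean-field reconstruction uses a power-law baseline
#' `p0(d) = max(d, 1)^(-alpha)` for the contact probability of beads at
#' (effective) separation `d` bins, modulated multiplicatively by shared
#' binding sites with gain `kappa` (see [reconstruct_meanfield()]).
#'
#' @param alpha decay exponent of the baseline (default 1, the TAD-scale
#'   effective exponent used throughout).
#' @param kappa affinity gain per shared binding-site unit (default 1).
#' @param class_strength optional per-class strength multipliers `s_c`
#'   (default all 1; recycled to the number of classes at use time).
#' @return a `decay_params` list.
#' @export
decay_params <- function(alpha = 1, kappa = 1, class_strength = NULL) {
  if (alpha < 0) abort("`alpha` must be >= 0.")
  if (kappa < 0) abort("`kappa` must be >= 0.")
  structure(list(alpha = alpha, kappa = kappa, class_strength = class_strength),
            class = "decay_params")
}
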