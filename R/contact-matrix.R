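#' Contact matrix container
#'
#' A `contact_matrix` is a square, symmetric, non-negative numeric matrix of
#' pairwise contact frequencies for a genomic window at fixed bin size,
#' carrying region metadata (`chrom`, `start`, `bin_size`) as attributes.
#' Row/column `i` covers the 0-based half-open interval
#' `[start + (i-1)*bin_size, start + i*bin_size)`.
#'
#' @param m square numeric matrix, symmetric to within `tol`.
#' @param chrom chromosome (or assembly) name.
#' @param start 0-based start coordinate in bp.
#' @param bin_size bin width in bp.
#' @param tol maximum tolerated asymmetry `max(abs(m - t(m)))`.
#' @return a `contact_matrix` object.
#' @export
contact_matrix <- function(m, chrom = "region", start = 0L, bin_size = 5000L,
                           tol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m)) abort("`m` must be a numeric matrix.")
  if (nrow(m) != ncol(m)) abort("`m` must be square.")
  if (anyNA(m) || any(!is.finite(m))) abort("`m` contains non-finite entries.")
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    abort(sprintf("`m` is asymmetric beyond tolerance (max deviation %.3g).", asym))
  }
  m <- (m + t(m)) / 2
  if (any(m < 0)) abort("contact frequencies must be non-negative.")
  structure(m,
    chrom = chrom, start = as.numeric(start), bin_size = as.numeric(bin_size),
    class = c("contact_matrix", "matrix", "array")
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> %d x %d bins | %s:%s-%s @ %s bp\n",
    nrow(x), ncol(x), attr(x, "chrom"),
    format(attr(x, "start"), scientific = FALSE),
    format(attr(x, "start") + nrow(x) * attr(x, "bin_size"), scientific = FALSE),
    format(attr(x, "bin_size"), scientific = FALSE)
  ))
  invisible(x)
}

#' @rdname contact_matrix
#' @param x object to test or coerce.
#' @export
is_contact_matrix <- function(x) inherits(x, "contact_matrix")

# Strip class/attrs down to a plain matrix.
as_plain_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "chrom") <- NULL; attr(y, "start") <- NULL; attr(y, "bin_size") <- NULL
  y
}

# Carry region metadata from `template` onto plain matrix `m`.
rewrap_like <- function(m, template, bin_size = attr(template, "bin_size")) {
  contact_matrix(m,
    chrom = attr(template, "chrom") %||% "region",
    start = attr(template, "start") %||% 0,
    bin_size = bin_size %||% 5000
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Turn a contact matrix into a long tibble
#'
#' @param x a `contact_matrix`.
#' @param ... unused.
#' @return tibble with columns `bin1`, `bin2` (1-based indices) and `contact`.
#' @export
tidy.contact_matrix <- function(x, ...) {
  n <- nrow(x)
  tibble(
    bin1 = rep(seq_len(n), times = n),
    bin2 = rep(seq_len(n), each = n),
    contact = as.vector(unclass(x))
  )
}

#' Heatmap of a contact matrix
#'
#' @param object a `contact_matrix`.
#' @param log if `TRUE` (default) colour on `log10(contact + eps)`.
#' @param ... unused.
#' @export
autoplot.contact_matrix <- function(object, log = TRUE, ...) {
  df <- tidy.contact_matrix(object)
  if (log) {
    eps <- min(df$contact[df$contact > 0], na.rm = TRUE) / 10
    df$fill <- log10(df$contact + eps)
    lab <- "log10 contact"
  } else {
    df$fill <- df$contact
    lab <- "contact"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin1, y = .data$bin2, fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin", y = "bin") +
    ggplot2::theme_minimal()
}
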