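# Readers and writers for the plain-text formats the pipeline exchanges:
# dense matrix TSV with a `#region` header, bedGraph / BED / BEDPE
# (0-based half-open throughout), SV TSV, binding-profile TSV, multi-model
# XYZ ensembles. Writers stamp provenance comment lines; readers skip any
# leading `#` comments.

provenance_lines <- function(provenance) {
  if (is.null(provenance)) return(character())
  paste0("#provenance ", paste(names(provenance), unlist(provenance),
                               sep = "=", collapse = " "))
}

#' Write / read a dense contact-matrix TSV
#'
#' The file starts with `#region chrom:start-end:binsize`, optional
#' provenance comment lines, then the tab-separated dense matrix. The reader
#' rejects NaN entries and asymmetry beyond 1e-8.
#'
#' @param m a `contact_matrix`.
#' @param path file path.
#' @param provenance optional named list stamped into a comment line.
#' @return `path`, invisibly (writer); a `contact_matrix` (reader).
#' @export
write_contact_matrix <- function(m, path, provenance = NULL) {
  if (!is_contact_matrix(m)) abort("`m` must be a contact_matrix.")
  header <- sprintf(
    "#region %s:%s-%s:%s", attr(m, "chrom"),
    format(attr(m, "start"), scientific = FALSE),
    format(attr(m, "start") + nrow(m) * attr(m, "bin_size"), scientific = FALSE),
    format(attr(m, "bin_size"), scientific = FALSE)
  )
  writeLines(c(header, provenance_lines(provenance)), path)
  utils::write.table(unclass(m), path, append = TRUE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  lines <- readLines(path)
  comments <- grep("^#", lines)
  region <- grep("^#region ", lines, value = TRUE)
  if (length(region) == 0) abort("missing `#region` header line.")
  parts <- strsplit(sub("^#region ", "", region[1]), "[:-]")[[1]]
  if (length(parts) != 4) abort("malformed `#region` header.")
  body <- if (length(comments)) lines[-comments] else lines
  vals <- strsplit(body, "\t")
  n <- length(vals)
  x <- matrix(as.numeric(unlist(vals)), n, byrow = TRUE)
  if (anyNA(x)) abort("matrix contains NaN/NA entries.")
  nbins <- (as.numeric(parts[3]) - as.numeric(parts[2])) / as.numeric(parts[4])
  if (nbins != n) abort("region header does not match the matrix bin count.")
  contact_matrix(x, chrom = parts[1], start = as.numeric(parts[2]),
                 bin_size = as.numeric(parts[4]))
}

read_tsv_body <- function(path, col_names, col_types) {
  readr::read_tsv(path, comment = "#", col_names = col_names,
                  col_types = col_types, progress = FALSE)
}

#' Write / read bedGraph tracks
#'
#' Standard 4-column bedGraph (0-based half-open). The reader rejects
#' overlapping intervals (a format violation for a binned track) and returns
#' a tibble `chrom`, `start`, `end`, `value`; single-chromosome files with a
#' constant bin width gain `binned_track` semantics.
#'
#' @param track tibble with `chrom`, `start`, `end`, `value`.
#' @param path file path.
#' @param provenance optional named list stamped into a comment line.
#' @export
write_bedgraph <- function(track, path, provenance = NULL) {
  writeLines(provenance_lines(provenance), path)
  readr::write_tsv(track[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE, append = TRUE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  x <- read_tsv_body(path, c("chrom", "start", "end", "value"), "ciid")
  if (nrow(x) == 0) abort("empty bedGraph.")
  x <- arrange(x, .data$chrom, .data$start)
  by_chrom <- split(x, x$chrom)
  for (ch in by_chrom) {
    if (nrow(ch) > 1 && any(ch$start[-1] < ch$end[-nrow(ch)])) {
      abort("overlapping bedGraph intervals (format violation).")
    }
  }
  widths <- unique(x$end - x$start)
  if (length(unique(x$chrom)) == 1 && length(widths) == 1 &&
      all(diff(x$start) == widths)) {
    return(binned_track(x$value, chrom = x$chrom[1], start = x$start[1],
                        bin_size = widths))
  }
  x
}

#' Read / write BED intervals
#'
#' @param x tibble with at least `chrom`, `start`, `end` (plus optional
#'   `name`).
#' @param path file path.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(x))
  readr::write_tsv(x[, cols], path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  first <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE, n_max = 1)
  names4 <- c("chrom", "start", "end", "name")
  x <- readr::read_tsv(path, comment = "#",
                       col_names = names4[seq_len(ncol(first))],
                       col_types = readr::cols(start = "i", end = "i",
                                               .default = "c"),
                       progress = FALSE)
  x
}

#' Read / write BEDPE interval pairs (loops, neoloop candidates)
#'
#' Six mandatory columns (`chrom1`, `start1`, `end1`, `chrom2`, `start2`,
#' `end2`); any extra columns (e.g. `score`, `crosses_breakpoint`) are
#' carried through after them.
#'
#' @param x tibble with the six BEDPE columns (extras allowed).
#' @param path file path.
#' @export
write_bedpe <- function(x, path) {
  core <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  readr::write_tsv(x[, c(core, setdiff(names(x), core))], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(path) {
  first <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE, n_max = 1)
  core <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  extra <- if (ncol(first) > 6) paste0("extra", seq_len(ncol(first) - 6)) else character()
  readr::read_tsv(path, comment = "#", col_names = c(core, extra),
                  col_types = readr::cols(start1 = "d", end1 = "d",
                                          start2 = "d", end2 = "d",
                                          .default = "c"),
                  progress = FALSE)
}

#' Read / write an SV breakpoint table
#'
#' Tab-separated `chrom1 pos1 chrom2 pos2 sign1 sign2 sv_type`. Signs follow
#' the left-flank-retained convention documented in [sv_records()].
#'
#' @param svs an [sv_records()] table.
#' @param path file path.
#' @export
write_sv_table <- function(svs, path) {
  readr::write_tsv(svs[, c("chrom1", "pos1", "chrom2", "pos2",
                           "sign1", "sign2", "sv_type")], path)
  invisible(path)
}

#' @rdname write_sv_table
#' @export
read_sv_table <- function(path) {
  x <- readr::read_tsv(path, comment = "#", col_types = "cdcdccc",
                       progress = FALSE)
  sv_records(x)
}

#' Write / read a binding-profile TSV
#'
#' Long-format `bead_index  class_id  multiplicity` with `#` header lines
#' recording the polymer geometry, so a [polymer_model()] round-trips.
#'
#' @param polymer a [polymer_model()].
#' @param path file path.
#' @export
write_binding_profile <- function(polymer, path) {
  writeLines(sprintf("#polymer n_beads=%d n_classes=%d bin_size=%s topology=%s",
                     polymer$n_beads, polymer$n_classes,
                     format(polymer$bin_size, scientific = FALSE),
                     polymer$topology), path)
  readr::write_tsv(
    setNames(tidy(polymer), c("bead_index", "class_id", "multiplicity")),
    path, append = TRUE, col_names = TRUE
  )
  invisible(path)
}

#' @rdname write_binding_profile
#' @export
read_binding_profile <- function(path) {
  header <- grep("^#polymer ", readLines(path, n = 5), value = TRUE)
  if (length(header) == 0) abort("missing `#polymer` header line.")
  kv <- strsplit(strsplit(sub("^#polymer ", "", header[1]), " ")[[1]], "=")
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  x <- readr::read_tsv(path, comment = "#", col_types = "iii", progress = FALSE)
  b <- matrix(0, as.integer(meta["n_beads"]), as.integer(meta["n_classes"]))
  b[cbind(x$bead_index, x$class_id)] <- x$multiplicity
  polymer_model(b, bin_size = as.numeric(meta["bin_size"]),
                topology = meta[["topology"]])
}

#' Write / read a conformational ensemble as multi-model XYZ
#'
#' One block per conformation: a bead-count line, a comment line, then
#' `BEAD x y z` rows.
#'
#' @param ensemble a `structure_ensemble` (writer) / file path (reader).
#' @param path file path.
#' @export
write_ensemble_xyz <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(ensemble$conformations)) {
    xyz <- ensemble$conformations[[k]]
    writeLines(c(as.character(nrow(xyz)), sprintf("conformation %d", k)), con)
    utils::write.table(cbind("BEAD", format(xyz, digits = 8)), con,
                       sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_ensemble_xyz
#' @export
read_ensemble_xyz <- function(path) {
  lines <- readLines(path)
  confs <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    block <- lines[(i + 2):(i + 1 + n)]
    vals <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    confs[[length(confs) + 1]] <-
      matrix(as.numeric(vals[, 2:4]), n, 3)
    i <- i + 2 + n
  }
  confs
}
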