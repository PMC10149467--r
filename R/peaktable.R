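#' Parse an encoded mass spectrum string
#'
#' Peak-detection software exports the unit-mass spectrum of each detected
#' peak as a single text field of whitespace-separated \code{m/z:intensity}
#' tokens (intensities are relative abundances). This parses one such field
#' into a named numeric vector: names are integer m/z values, values are
#' abundances. Intensities of duplicated m/z keys are summed.
#'
#' @param text character scalar holding the encoded spectrum.
#' @param pair_sep separator between m/z and intensity inside a token
#'   (default \code{":"}).
#' @param row optional row number used in error messages.
#' @return named numeric vector (possibly empty), names sorted by m/z.
#' @examples
#' parse_spectrum_string("73:999 147:500")
#' parse_spectrum_string("50:10 50:5")  # duplicates summed -> 15
#' @export
parse_spectrum_string <- function(text, pair_sep = ":", row = NA_integer_) {
  stopifnot(is.character(text), length(text) == 1L)
  where <- if (is.na(row)) "" else sprintf(" (row %d)", row)
  tokens <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  parts <- strsplit(tokens, pair_sep, fixed = TRUE)
  n_parts <- vapply(parts, length, integer(1))
  if (any(n_parts != 2L)) {
    bad <- tokens[n_parts != 2L][1L]
    stop(sprintf("malformed spectrum token '%s'%s: expected 'm/z%sintensity'",
                 bad, where, pair_sep), call. = FALSE)
  }
  mz <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1L)))
  int <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(mz) || anyNA(int)) {
    bad <- tokens[is.na(mz) | is.na(int)][1L]
    stop(sprintf("malformed spectrum token '%s'%s: non-numeric value",
                 bad, where), call. = FALSE)
  }
  if (any(mz <= 0) || any(mz != round(mz))) {
    stop(sprintf("invalid m/z value%s: m/z must be a positive integer", where),
         call. = FALSE)
  }
  if (any(int < 0)) {
    stop(sprintf("negative intensity%s", where), call. = FALSE)
  }
  agg <- vapply(split(int, mz), sum, numeric(1))
  agg[order(as.numeric(names(agg)))]
}

#' Encode a spectrum back to its string form
#'
#' Inverse of [parse_spectrum_string()].
#'
#' @param s named numeric vector (names = integer m/z).
#' @param pair_sep separator between m/z and intensity.
#' @return character scalar.
#' @export
format_spectrum_string <- function(s, pair_sep = ":") {
  if (length(s) == 0L) return("")
  paste(paste0(names(s), pair_sep,
               format(unname(s), digits = 12, trim = TRUE, scientific = FALSE)),
        collapse = " ")
}

#' CSV dialect for exported peak tables
#'
#' Describes the layout of a tab-separated peak-table export: column names
#' for the two retention times and the spectrum string, the field separator
#' and the separator inside \code{m/z:intensity} tokens. Exports from
#' different instrument software differ only in these names, so they are
#' configurable.
#'
#' @param sep field separator (default tab).
#' @param rt1_col,rt2_col,spectrum_col header names of the first-dimension
#'   retention time (s), second-dimension retention time (s) and spectrum
#'   columns.
#' @param label_col optional header name of a compound-label column; if the
#'   column is absent from a file it is silently skipped.
#' @param pair_sep separator inside spectrum tokens.
#' @return a list of class \code{"peak_dialect"}.
#' @export
peak_dialect <- function(sep = "\t",
                         rt1_col = "1st Dimension Time (s)",
                         rt2_col = "2nd Dimension Time (s)",
                         spectrum_col = "Spectra",
                         label_col = "Name",
                         pair_sep = ":") {
  structure(list(sep = sep, rt1_col = rt1_col, rt2_col = rt2_col,
                 spectrum_col = spectrum_col, label_col = label_col,
                 pair_sep = pair_sep),
            class = "peak_dialect")
}

#' Construct a peak table
#'
#' A peak table is the in-memory form of one exported chromatogram: one row
#' per detected peak with its two retention times (seconds), its unit-mass
#' spectrum and an optional label. Row order is preserved everywhere; the
#' peak index used by the anchor algorithms is the row index.
#'
#' @param rt1,rt2 numeric vectors of retention times in seconds (>= 0).
#' @param spectra list of spectra (named numeric vectors, see
#'   [parse_spectrum_string()]).
#' @param label optional character vector of peak labels.
#' @param sample_id non-empty sample identifier.
#' @return a data.frame of class \code{"peak_table"} with columns
#'   \code{rt1}, \code{rt2}, \code{spectrum} (list column) and \code{label},
#'   and attribute \code{sample_id}.
#' @export
peak_table <- function(rt1, rt2, spectra, label = NULL, sample_id = "sample") {
  rt1 <- as.numeric(rt1)
  rt2 <- as.numeric(rt2)
  n <- length(rt1)
  stopifnot(length(rt2) == n, length(spectra) == n)
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id))
    stop("sample_id must be a non-empty string", call. = FALSE)
  if (n > 0 && (any(rt1 < 0) || any(rt2 < 0)))
    stop("retention times must be non-negative", call. = FALSE)
  if (is.null(label)) label <- rep(NA_character_, n)
  out <- data.frame(rt1 = rt1, rt2 = rt2, label = as.character(label),
                    stringsAsFactors = FALSE)
  out$spectrum <- unname(as.list(spectra))
  out <- out[, c("rt1", "rt2", "spectrum", "label")]
  attr(out, "sample_id") <- sample_id
  class(out) <- c("peak_table", "data.frame")
  out
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> sample '%s': %d peaks\n",
              sample_id(x), nrow(x)))
  if (nrow(x) > 0) {
    show <- utils::head(data.frame(
      rt1 = x$rt1, rt2 = x$rt2,
      n_fragments = vapply(x$spectrum, length, integer(1)),
      label = x$label), 6L)
    print(show)
    if (nrow(x) > 6L) cat(sprintf("... %d more peaks\n", nrow(x) - 6L))
  }
  invisible(x)
}

#' Sample identifier of a peak table
#' @param t a \code{peak_table}.
#' @return character scalar.
#' @export
sample_id <- function(t) attr(t, "sample_id")

#' Read an exported peak table
#'
#' Reads a tab-separated peak-table export (header row plus one row per
#' detected peak) into a [peak_table()]. Retention times are taken as
#' seconds; row order is preserved.
#'
#' @param path file path.
#' @param dialect a [peak_dialect()].
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @return a \code{peak_table}.
#' @export
read_peak_table <- function(path, dialect = peak_dialect(),
                            sample_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, sep = dialect$sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "",
                          colClasses = "character")
  for (col in c(dialect$rt1_col, dialect$rt2_col, dialect$spectrum_col)) {
    if (!col %in% names(df))
      stop(sprintf("missing required column '%s' in %s", col, path),
           call. = FALSE)
  }
  n <- nrow(df)
  if (n == 0L) {
    return(peak_table(numeric(0), numeric(0), list(), sample_id = sample_id))
  }
  rt1 <- suppressWarnings(as.numeric(df[[dialect$rt1_col]]))
  rt2 <- suppressWarnings(as.numeric(df[[dialect$rt2_col]]))
  if (anyNA(rt1) || anyNA(rt2)) {
    bad <- which(is.na(rt1) | is.na(rt2))[1L]
    stop(sprintf("non-numeric retention time at data row %d", bad),
         call. = FALSE)
  }
  if (any(rt1 < 0) || any(rt2 < 0)) {
    bad <- which(rt1 < 0 | rt2 < 0)[1L]
    stop(sprintf("negative retention time at data row %d", bad), call. = FALSE)
  }
  spectra <- lapply(seq_len(n), function(i)
    parse_spectrum_string(df[[dialect$spectrum_col]][i],
                          pair_sep = dialect$pair_sep, row = i))
  label <- if (!is.null(dialect$label_col) && dialect$label_col %in% names(df))
    df[[dialect$label_col]] else NULL
  peak_table(rt1, rt2, spectra, label = label, sample_id = sample_id)
}

#' Write a peak table in the export dialect
#'
#' Inverse of [read_peak_table()]: writes the header and one row per peak,
#' with retention times printed to microsecond precision and spectra
#' re-encoded through [format_spectrum_string()].
#'
#' @param t a \code{peak_table}.
#' @param path output file path.
#' @param dialect a [peak_dialect()].
#' @return invisibly, \code{path}.
#' @export
write_peak_table <- function(t, path, dialect = peak_dialect()) {
  out <- data.frame(
    rt1 = sprintf("%.6f", t$rt1),
    rt2 = sprintf("%.6f", t$rt2),
    spec = vapply(t$spectrum, format_spectrum_string, character(1),
                  pair_sep = dialect$pair_sep),
    label = ifelse(is.na(t$label), "", t$label),
    stringsAsFactors = FALSE)
  names(out) <- c(dialect$rt1_col, dialect$rt2_col, dialect$spectrum_col,
                  if (is.null(dialect$label_col)) "Name" else dialect$label_col)
  utils::write.table(out, path, sep = dialect$sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Export the products of one alignment
#'
#' Writes the three result files of an alignment run: the anchor-point list
#' (reference and aligned retention times of every anchor with its
#' similarity and selection score), the peak map (every matched peak with
#' its original and corrected retention times), and the time-corrected peak
#' table in the same dialect as the input.
#'
#' @param result an \code{alignment_result} from [align_pair()].
#' @param dir output directory (created if missing).
#' @param dialect a [peak_dialect()] for the corrected table.
#' @return invisibly, a named character vector of the three file paths
#'   (\code{anchors}, \code{peak_map}, \code{corrected}).
#' @export
write_outputs <- function(result, dir, dialect = peak_dialect()) {
  stopifnot(inherits(result, "alignment_result"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", dir),
                  call. = FALSE)
  }
  pairs <- anchor_pairs(result$anchors)
  ref <- result$ref
  aln <- result$aligned
  cor <- result$corrected

  anchors_path <- file.path(dir, "anchor_points.csv")
  a <- data.frame(
    ref_index = pairs$ref_index, aln_index = pairs$aln_index,
    ref_rt1 = ref$rt1[pairs$ref_index], ref_rt2 = ref$rt2[pairs$ref_index],
    aln_rt1 = aln$rt1[pairs$aln_index], aln_rt2 = aln$rt2[pairs$aln_index],
    similarity = pairs$similarity, score = pairs$score)
  utils::write.table(a, anchors_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  map_path <- file.path(dir, "peak_map.csv")
  m <- cbind(a[, c("ref_index", "aln_index", "ref_rt1", "ref_rt2",
                   "aln_rt1", "aln_rt2")],
             corrected_rt1 = cor$rt1[pairs$aln_index],
             corrected_rt2 = cor$rt2[pairs$aln_index])
  utils::write.table(m, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  corrected_path <- file.path(
    dir, sprintf("corrected_%s.csv", sample_id(cor)))
  write_peak_table(cor, corrected_path, dialect)

  invisible(c(anchors = anchors_path, peak_map = map_path,
              corrected = corrected_path))
}
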