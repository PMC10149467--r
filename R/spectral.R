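#' Spectral similarity configuration
#'
#' Controls how two unit-mass spectra are compared. The optional power
#' transformation raises each intensity to \code{intensity_exponent} and
#' multiplies it by its m/z raised to \code{mz_exponent}; with the default
#' exponents (0.53 and 1.3) this up-weights heavier fragments, which helps
#' separate members of homologous series whose low-mass fragments are
#' nearly identical. After the (optional) transformation, the two spectra
#' are expanded over the union of their m/z grids and compared by Pearson
#' correlation or cosine similarity.
#'
#' @param method \code{"cosine"} or \code{"pearson"}.
#' @param transform apply the power transformation before comparing?
#' @param intensity_exponent exponent applied to intensities (default 0.53).
#' @param mz_exponent exponent applied to m/z values (default 1.3).
#' @param threshold minimum similarity, in \code{[0, 1]}, below which a peak
#'   pair is treated as "no match" by every anchor algorithm. Negative
#'   Pearson values are floored at 0 before the comparison, so thresholds
#'   live on a 0-1 scale for both methods.
#' @return a list of class \code{"similarity_config"}.
#' @export
similarity_config <- function(method = c("cosine", "pearson"),
                              transform = TRUE,
                              intensity_exponent = 0.53,
                              mz_exponent = 1.3,
                              threshold = 0.9) {
  method <- match.arg(method)
  stopifnot(isTRUE(transform) || isFALSE(transform),
            intensity_exponent > 0, mz_exponent > 0,
            threshold >= 0, threshold <= 1)
  structure(list(method = method, transform = transform,
                 intensity_exponent = intensity_exponent,
                 mz_exponent = mz_exponent, threshold = threshold),
            class = "similarity_config")
}

#' Power-transform a spectrum
#'
#' Maps each entry \eqn{(m, I)} to \eqn{(m, I^{a} m^{b})} where \eqn{a} is
#' the intensity exponent and \eqn{b} the m/z exponent of \code{cfg}. The
#' m/z keys themselves are unchanged; zero intensities stay zero.
#'
#' @param s a spectrum (named numeric vector).
#' @param cfg a [similarity_config()].
#' @return the transformed spectrum.
#' @export
transform_spectrum <- function(s, cfg = similarity_config()) {
  if (length(s) == 0L) return(s)
  mz <- as.numeric(names(s))
  stats::setNames(unname(s)^cfg$intensity_exponent * mz^cfg$mz_exponent,
                  names(s))
}

#' Expand two spectra over their common m/z grid
#'
#' Both spectra are expanded over the sorted union of their m/z keys;
#' fragments absent from one spectrum contribute zero intensity (an absent
#' mass is evidence of dissimilarity, as in library search).
#'
#' @param a,b spectra (named numeric vectors); at least one non-empty.
#' @return a list with numeric vectors \code{x}, \code{y} (same length and
#'   key order) and the grid \code{mz}.
#' @export
pair_vectors <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L)
    stop("cannot compare two empty spectra", call. = FALSE)
  grid <- sort(unique(c(as.numeric(names(a)), as.numeric(names(b)))))
  key <- as.character(grid)
  x <- y <- numeric(length(grid))
  x[match(names(a), key)] <- unname(a)
  y[match(names(b), key)] <- unname(b)
  list(x = x, y = y, mz = grid)
}

#' Spectral similarity of two peaks
#'
#' Applies the power transformation when \code{cfg$transform} is on, expands
#' both spectra over the union m/z grid, and scores them by the configured
#' method. Cosine similarity of non-negative spectra lies in \code{[0, 1]};
#' Pearson correlation lies in \code{[-1, 1]}. Degenerate inputs follow the
#' conventions: cosine with a zero-norm vector is 0; Pearson with a constant
#' vector is 0.
#'
#' @param a,b spectra (named numeric vectors).
#' @param cfg a [similarity_config()].
#' @return numeric scalar in \code{[-1, 1]}.
#' @export
spectral_similarity <- function(a, b, cfg = similarity_config()) {
  if (cfg$transform) {
    a <- transform_spectrum(a, cfg)
    b <- transform_spectrum(b, cfg)
  }
  v <- pair_vectors(a, b)
  .similarity_paired(v$x, v$y, cfg$method)
}

.similarity_paired <- function(x, y, method) {
  if (method == "cosine") {
    nx <- sqrt(sum(x^2))
    ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) return(0)
    sum(x * y) / (nx * ny)
  } else {
    if (length(x) < 2L) return(0)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }
}

# Similarity matrix between all peaks of two tables, floored at 0 so that
# threshold gating works on one 0-1 scale for both methods. Spectra are
# transformed once per table, not once per pair.
.sim_matrix <- function(ref, aln, cfg) {
  n <- nrow(ref); m <- nrow(aln)
  S <- matrix(0, n, m)
  if (n == 0L || m == 0L) return(S)
  rs <- ref$spectrum
  as_ <- aln$spectrum
  if (cfg$transform) {
    rs <- lapply(rs, transform_spectrum, cfg = cfg)
    as_ <- lapply(as_, transform_spectrum, cfg = cfg)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      v <- pair_vectors(rs[[i]], as_[[j]])
      S[i, j] <- .similarity_paired(v$x, v$y, cfg$method)
    }
  }
  pmax(S, 0)
}
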