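#' Distortion configuration for synthetic chromatogram pairs
#'
#' Describes how a distorted copy of a reference table is produced: an
#' affine warp per dimension (mimicking systematic retention-time drift
#' after column ageing or replacement), Gaussian retention-time jitter,
#' random peak dropout, spurious peak insertions, and multiplicative
#' log-normal perturbation of fragment intensities (mimicking imperfect
#' deconvolution).
#'
#' @param a1,b1 affine warp of rt1: \code{rt1' = a1 * rt1 + b1} (a1 > 0).
#' @param a2,b2 affine warp of rt2 (a2 > 0).
#' @param jitter1,jitter2 per-dimension retention-time noise sd (s), >= 0.
#' @param dropout probability that a reference peak is absent from the
#'   distorted table, in \code{[0, 1]}.
#' @param insertions number of spurious peaks appended (with fresh random
#'   spectra).
#' @param spectral_noise sd of the log-normal intensity perturbation, >= 0.
#' @param seed optional RNG seed; NULL draws from the current RNG stream.
#' @return a list of class \code{"distortion_config"}.
#' @export
distortion_config <- function(a1 = 1, b1 = 0, a2 = 1, b2 = 0,
                              jitter1 = 0, jitter2 = 0,
                              dropout = 0, insertions = 0L,
                              spectral_noise = 0, seed = NULL) {
  stopifnot(a1 > 0, a2 > 0, jitter1 >= 0, jitter2 >= 0,
            dropout >= 0, dropout <= 1, insertions >= 0,
            spectral_noise >= 0)
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2,
                 jitter1 = jitter1, jitter2 = jitter2,
                 dropout = dropout, insertions = as.integer(insertions),
                 spectral_noise = spectral_noise, seed = seed),
            class = "distortion_config")
}

# One random sparse EI-like spectrum: a dominant base fragment at intensity
# 999 plus k-1 minor fragments.
.random_spectrum <- function(mz_range, n_fragments, base_mz = NULL) {
  pool <- seq(mz_range[1L], mz_range[2L])
  if (is.null(base_mz)) base_mz <- sample(pool, 1L)
  others <- sample(setdiff(pool, base_mz), n_fragments - 1L)
  mz <- c(base_mz, others)
  int <- c(999, stats::runif(n_fragments - 1L, 10, 400))
  s <- stats::setNames(int, mz)
  s[order(as.numeric(names(s)))]
}

#' Generate a library of mutually dissimilar spectra
#'
#' Draws \code{n} sparse unit-mass spectra with distinct dominant fragments
#' and rejection-samples until every pair has raw cosine similarity below
#' \code{max_cosine}, so that synthetic compounds are spectrally
#' distinguishable the way distinct real compounds are.
#'
#' @param n number of spectra.
#' @param mz_range integer interval of allowed m/z values.
#' @param peaks_per_spectrum integer interval for the fragment count.
#' @param seed optional RNG seed.
#' @param max_cosine pairwise cosine ceiling (default 0.5).
#' @param max_tries rejection-sampling budget per spectrum.
#' @return list of \code{n} spectra.
#' @export
make_spectrum_library <- function(n, mz_range = c(40, 350),
                                  peaks_per_spectrum = c(6, 14),
                                  seed = NULL, max_cosine = 0.5,
                                  max_tries = 200L) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  raw_cos <- similarity_config(method = "cosine", transform = FALSE,
                               threshold = 0)
  pool <- seq(mz_range[1L], mz_range[2L])
  if (n > length(pool))
    stop("not enough distinct m/z values for distinct dominant fragments",
         call. = FALSE)
  base_mzs <- sample(pool, n)
  lib <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      k <- sample(seq(peaks_per_spectrum[1L], peaks_per_spectrum[2L]), 1L)
      cand <- .random_spectrum(mz_range, k, base_mz = base_mzs[i])
      sims <- if (i == 1L) 0 else vapply(
        lib[seq_len(i - 1L)], spectral_similarity, numeric(1),
        b = cand, cfg = raw_cos)
      if (max(sims) < max_cosine) {
        lib[[i]] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf(paste("could not draw spectrum %d below the pairwise",
                         "cosine ceiling %.2f within %d tries"),
                   i, max_cosine, max_tries), call. = FALSE)
  }
  lib
}

#' Generate a synthetic reference peak table
#'
#' Peaks at uniformly drawn retention times (sorted by total elution time),
#' each carrying a distinct spectrum from the library and a compound label.
#'
#' @param library list of spectra from [make_spectrum_library()].
#' @param n_peaks number of peaks (<= library size).
#' @param rt1_range,rt2_range retention-time intervals in seconds.
#' @param seed optional RNG seed.
#' @param sample_id sample identifier.
#' @return a \code{peak_table}.
#' @export
make_reference_table <- function(library, n_peaks = length(library),
                                 rt1_range = c(60, 1800),
                                 rt2_range = c(0.8, 5),
                                 seed = NULL, sample_id = "reference") {
  if (n_peaks > length(library))
    stop("n_peaks exceeds the spectrum library size", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rt1 <- stats::runif(n_peaks, rt1_range[1L], rt1_range[2L])
  rt2 <- stats::runif(n_peaks, rt2_range[1L], rt2_range[2L])
  spectra <- library[sample(length(library), n_peaks)]
  o <- order(rt1 + rt2)
  peak_table(rt1[o], rt2[o], spectra[o],
             label = sprintf("C%03d", seq_len(n_peaks)),
             sample_id = sample_id)
}

#' Distort a reference table with a known ground truth
#'
#' Applies the per-dimension affine warps and jitter, drops peaks with the
#' configured probability, appends spurious peaks with fresh random spectra,
#' perturbs retained spectra multiplicatively, and re-sorts by total elution
#' time. The returned ground truth records which aligned row each reference
#' peak became (NA for dropped peaks) and the true warp coefficients;
#' inserted peaks never appear in the correspondence.
#'
#' @param ref a \code{peak_table}.
#' @param cfg a [distortion_config()].
#' @param sample_id identifier of the distorted table.
#' @return list with \code{table} (the distorted \code{peak_table}) and
#'   \code{truth} (list with \code{correspondence}, \code{warp1 = c(a, b)},
#'   \code{warp2 = c(a, b)}).
#' @export
distort_table <- function(ref, cfg = distortion_config(),
                          sample_id = "aligned") {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- nrow(ref)
  keep <- if (n > 0) stats::runif(n) >= cfg$dropout else logical(0)
  kept <- which(keep)
  rt1 <- cfg$a1 * ref$rt1[kept] + cfg$b1 +
    stats::rnorm(length(kept), 0, cfg$jitter1)
  rt2 <- cfg$a2 * ref$rt2[kept] + cfg$b2 +
    stats::rnorm(length(kept), 0, cfg$jitter2)
  spectra <- ref$spectrum[kept]
  if (cfg$spectral_noise > 0) {
    spectra <- lapply(spectra, function(s)
      s * exp(stats::rnorm(length(s), 0, cfg$spectral_noise)))
  }
  labels <- ref$label[kept]
  if (cfg$insertions > 0L) {
    ins_rt1 <- stats::runif(cfg$insertions,
                            min(c(rt1, cfg$a1 * min(ref$rt1) + cfg$b1)),
                            max(c(rt1, cfg$a1 * max(ref$rt1) + cfg$b1)))
    ins_rt2 <- stats::runif(cfg$insertions,
                            min(c(rt2, cfg$a2 * min(ref$rt2) + cfg$b2)),
                            max(c(rt2, cfg$a2 * max(ref$rt2) + cfg$b2)))
    ins_spec <- lapply(seq_len(cfg$insertions), function(i)
      .random_spectrum(c(40, 350), sample(6:14, 1L)))
    rt1 <- c(rt1, pmax(ins_rt1, 0))
    rt2 <- c(rt2, pmax(ins_rt2, 0))
    spectra <- c(spectra, ins_spec)
    labels <- c(labels, sprintf("X%03d", seq_len(cfg$insertions)))
  }
  rt1 <- pmax(rt1, 0)
  rt2 <- pmax(rt2, 0)
  o <- order(rt1 + rt2)
  table <- peak_table(rt1[o], rt2[o], spectra[o], label = labels[o],
                      sample_id = sample_id)
  # position of each retained reference peak after the re-sort
  correspondence <- rep(NA_integer_, n)
  correspondence[kept] <- match(seq_along(kept), o)
  truth <- list(correspondence = correspondence,
                warp1 = c(a = cfg$a1, b = cfg$b1),
                warp2 = c(a = cfg$a2, b = cfg$b2))
  list(table = table, truth = truth)
}

#' Benchmark preset parameters
#'
#' \code{"same_system"} mimics two runs on the same column set: a small
#' constant offset with little jitter, rare dropout and almost no spurious
#' peaks. \code{"cross_system"} mimics runs separated by a column
#' replacement: a mild stretch plus a larger offset in both dimensions, more
#' jitter, and appreciable dropout/insertion and spectral noise.
#'
#' @param preset \code{"same_system"} or \code{"cross_system"}.
#' @return a [distortion_config()].
#' @export
benchmark_preset <- function(preset = c("same_system", "cross_system")) {
  preset <- match.arg(preset)
  if (preset == "same_system") {
    distortion_config(a1 = 1, b1 = 6, a2 = 1, b2 = 0.05,
                      jitter1 = 0.2, jitter2 = 0.01,
                      dropout = 0.02, insertions = 1L,
                      spectral_noise = 0.05)
  } else {
    distortion_config(a1 = 1.006, b1 = 8, a2 = 0.97, b2 = 0.1,
                      jitter1 = 0.5, jitter2 = 0.02,
                      dropout = 0.10, insertions = 5L,
                      spectral_noise = 0.10)
  }
}

#' Generate a benchmark chromatogram pair with ground truth
#'
#' Builds a spectrum library, a reference table of \code{n_peaks} peaks and
#' a distorted copy under the chosen preset, all from one seeded RNG stream
#' (so the same seed reproduces the bundle exactly).
#'
#' @param preset \code{"same_system"} or \code{"cross_system"}.
#' @param seed RNG seed (default 42).
#' @param n_peaks number of reference peaks (default 60).
#' @return list with \code{ref}, \code{aligned}, \code{truth} and
#'   \code{params} (the [distortion_config()] used).
#' @export
make_benchmark_pair <- function(preset = c("same_system", "cross_system"),
                                seed = 42, n_peaks = 60L) {
  preset <- match.arg(preset)
  set.seed(seed)
  cfg <- benchmark_preset(preset)
  lib <- make_spectrum_library(n_peaks)
  ref <- make_reference_table(lib, n_peaks, sample_id = "reference")
  d <- distort_table(ref, cfg, sample_id = paste0(preset, "_sample"))
  list(ref = ref, aligned = d$table, truth = d$truth, params = cfg)
}
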