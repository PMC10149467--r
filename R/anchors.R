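#' Anchor-set container
#'
#' The result of the "find anchor peaks" step: a one-to-one matching between
#' peaks of the reference table and peaks of the aligned table, each pair
#' carrying the spectral similarity that gated it and the algorithm's
#' selection score.
#'
#' @param pairs data.frame with integer columns \code{ref_index},
#'   \code{aln_index} and numeric columns \code{similarity}, \code{score}.
#' @param algorithm algorithm name.
#' @param config the configuration used (stored as-is for provenance).
#' @return an object of class \code{"anchor_set"}.
#' @export
anchor_set <- function(pairs, algorithm, config = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    pairs <- data.frame(ref_index = integer(0), aln_index = integer(0),
                        similarity = numeric(0), score = numeric(0))
  }
  pairs <- pairs[, c("ref_index", "aln_index", "similarity", "score")]
  rownames(pairs) <- NULL
  if (anyDuplicated(pairs$ref_index) || anyDuplicated(pairs$aln_index))
    stop("anchor set is not one-to-one", call. = FALSE)
  structure(list(pairs = pairs, algorithm = algorithm, config = config),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("<anchor_set> %s: %d anchor pairs\n", x$algorithm,
              nrow(x$pairs)))
  if (nrow(x$pairs) > 0) print(utils::head(x$pairs, 6L))
  invisible(x)
}

#' Anchor pairs of an anchor set
#' @param a an \code{anchor_set}.
#' @return the pairs data.frame.
#' @export
anchor_pairs <- function(a) a$pairs

#' Number of anchors
#' @param a an \code{anchor_set}.
#' @return integer count.
#' @export
n_anchors <- function(a) nrow(a$pairs)

#' Standardize retention times to z-scores
#'
#' Each dimension is standardized independently to zero mean and unit
#' sample standard deviation (n - 1 denominator). The distance-based
#' algorithms (DISCO, PAM, TNT-DA) work in this z-space, which makes them
#' insensitive to affine retention-time drift between runs.
#'
#' @param t a \code{peak_table} with at least 2 peaks.
#' @return numeric matrix with columns \code{z1}, \code{z2}.
#' @export
zscore_times <- function(t) {
  if (nrow(t) < 2L)
    stop("z-scoring needs at least 2 peaks", call. = FALSE)
  s1 <- stats::sd(t$rt1); s2 <- stats::sd(t$rt2)
  if (s1 == 0) stop("zero variance in dimension 1 retention times",
                    call. = FALSE)
  if (s2 == 0) stop("zero variance in dimension 2 retention times",
                    call. = FALSE)
  cbind(z1 = (t$rt1 - mean(t$rt1)) / s1,
        z2 = (t$rt2 - mean(t$rt2)) / s2)
}

#' Distance between two peaks in (z1, z2) space
#'
#' @param p,q numeric vectors of length 2.
#' @param metric \code{"euclidean"} or \code{"canberra"}. Canberra terms
#'   with a 0/0 denominator contribute 0.
#' @return non-negative distance.
#' @export
peak_distance <- function(p, q, metric = c("euclidean", "canberra")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    sqrt(sum((p - q)^2))
  } else {
    den <- abs(p) + abs(q)
    num <- abs(p - q)
    sum(ifelse(den == 0, 0, num / den))
  }
}

# Distances from one z-point to every row of a z-matrix.
.dists_to <- function(z, zmat, metric) {
  if (metric == "euclidean") {
    sqrt((zmat[, 1] - z[1])^2 + (zmat[, 2] - z[2])^2)
  } else {
    d1 <- abs(zmat[, 1] - z[1]) / (abs(zmat[, 1]) + abs(z[1]))
    d2 <- abs(zmat[, 2] - z[2]) / (abs(zmat[, 2]) + abs(z[2]))
    d1[is.nan(d1)] <- 0
    d2[is.nan(d2)] <- 0
    d1 + d2
  }
}

#' Neighborhood configuration for DISCO and TNT-DA
#'
#' The discrimination rule considers only the nearest fraction of aligned
#' peaks (default 20 percent of the aligned table, rounded up) as candidate
#' matches for each reference peak, measured in z-scored retention-time
#' space.
#'
#' @param fraction proportion of aligned peaks in the neighborhood
#'   (0 < fraction <= 1, default 0.20).
#' @param distance \code{"euclidean"} or \code{"canberra"}.
#' @return a list of class \code{"neighborhood_config"}.
#' @export
neighborhood_config <- function(fraction = 0.20,
                                distance = c("euclidean", "canberra")) {
  distance <- match.arg(distance)
  stopifnot(fraction > 0, fraction <= 1)
  structure(list(fraction = fraction, distance = distance),
            class = "neighborhood_config")
}

#' Candidate neighbors of one reference peak
#'
#' Both tables are z-scored on their own statistics; the
#' \code{ceiling(fraction * N)} aligned peaks nearest to the chosen
#' reference peak are returned, sorted by distance (ascending).
#'
#' @param ref,aln \code{peak_table}s (>= 2 peaks each).
#' @param ref_index index of the reference peak.
#' @param cfg a [neighborhood_config()].
#' @return integer vector of aligned-table indices.
#' @export
candidate_neighbors <- function(ref, aln, ref_index,
                                cfg = neighborhood_config()) {
  if (nrow(aln) == 0L) return(integer(0))
  zr <- zscore_times(ref)
  za <- zscore_times(aln)
  .neighbors(zr[ref_index, ], za, cfg)
}

.neighbors <- function(z, za, cfg) {
  k <- ceiling(cfg$fraction * nrow(za))
  d <- .dists_to(z, za, cfg$distance)
  order(d)[seq_len(k)]
}

# Resolve one-selection-per-reference-peak conflicts into a one-to-one
# matching: when several reference peaks claim the same aligned peak, keep
# the pair with the higher selection score; ties broken by smaller total-RT
# difference, then lower ref_index. Duplicated anchors would corrupt the
# warp fit, so this is enforced by every algorithm.
.enforce_one_to_one <- function(df) {
  if (nrow(df) <= 1L) return(df)
  o <- order(-df$score, df$trdiff, df$ref_index)
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df$aln_index), , drop = FALSE]
  df[order(df$ref_index), , drop = FALSE]
}

.finish_anchor_set <- function(df, algorithm, config) {
  if (is.null(df) || nrow(df) == 0L)
    return(anchor_set(NULL, algorithm, config))
  df <- .enforce_one_to_one(df)
  anchor_set(df[, c("ref_index", "aln_index", "similarity", "score")],
             algorithm, config)
}

.total_rt <- function(t) t$rt1 + t$rt2

# ---------------------------------------------------------------- BiPACE 2D

#' BiPACE 2D configuration
#'
#' BiPACE 2D scores each candidate pair by the product of two Gaussian
#' retention-time penalty terms (one per dimension, width parameters
#' \code{D1}, \code{D2} in seconds) and the spectral similarity. \code{T1}
#' and \code{T2} are lower cutoffs on the penalty terms: a pair whose
#' penalty in either dimension falls below its cutoff is discarded, which
#' turns the soft penalty into a search-window discrimination. A cutoff
#' \code{T} corresponds to a window of roughly \eqn{1.18 D} seconds at
#' \code{T = 0.5} and \eqn{0.14 D} at \code{T = 0.99}; the defaults use 0.5
#' so that the default windows cover the drift the tool is meant to correct.
#'
#' @param D1,D2 retention-time tolerance per dimension (s), > 0.
#' @param T1,T2 penalty-term cutoffs in (0, 1].
#' @param similarity a [similarity_config()].
#' @return a list of class \code{"bipace_config"}.
#' @export
bipace_config <- function(D1 = 100, D2 = 0.8, T1 = 0.5, T2 = 0.5,
                          similarity = similarity_config()) {
  stopifnot(D1 > 0, D2 > 0, T1 > 0, T1 <= 1, T2 > 0, T2 <= 1)
  structure(list(D1 = D1, D2 = D2, T1 = T1, T2 = T2, similarity = similarity),
            class = "bipace_config")
}

#' BiPACE 2D pair score
#'
#' \deqn{f_{2d}(p,q) = \exp(-\Delta t_1^2 / (2 D_1^2)) \cdot
#'   \exp(-\Delta t_2^2 / (2 D_2^2)) \cdot s(p,q)}
#' Returns 0 when either penalty term falls below its cutoff.
#'
#' @param p,q single-row \code{peak_table} rows or lists with \code{rt1},
#'   \code{rt2}.
#' @param cfg a [bipace_config()].
#' @param s precomputed spectral similarity of the pair.
#' @return score >= 0.
#' @export
bipace_pair_score <- function(p, q, cfg, s) {
  pen1 <- exp(-(p$rt1 - q$rt1)^2 / (2 * cfg$D1^2))
  pen2 <- exp(-(p$rt2 - q$rt2)^2 / (2 * cfg$D2^2))
  if (pen1 < cfg$T1 || pen2 < cfg$T2) return(0)
  pen1 * pen2 * s
}

#' Find anchors with BiPACE 2D (best bidirectional hits)
#'
#' Scores every reference-aligned pair with [bipace_pair_score()] (spectral
#' similarities below the threshold contribute 0) and keeps the pairs that
#' are mutual best hits: the aligned peak is the argmax of the reference
#' peak's scores and vice versa, with a positive score.
#'
#' @param ref,aln \code{peak_table}s.
#' @param cfg a [bipace_config()].
#' @return an \code{anchor_set}.
#' @export
find_anchors_bipace <- function(ref, aln, cfg = bipace_config()) {
  n <- nrow(ref); m <- nrow(aln)
  if (n == 0L || m == 0L) return(anchor_set(NULL, "bipace2d", cfg))
  S <- .sim_matrix(ref, aln, cfg$similarity)
  Sg <- S
  Sg[Sg < cfg$similarity$threshold] <- 0
  P1 <- exp(-outer(ref$rt1, aln$rt1, "-")^2 / (2 * cfg$D1^2))
  P2 <- exp(-outer(ref$rt2, aln$rt2, "-")^2 / (2 * cfg$D2^2))
  P1[P1 < cfg$T1] <- 0
  P2[P2 < cfg$T2] <- 0
  F2d <- P1 * P2 * Sg
  best_for_ref <- apply(F2d, 1L, which.max)
  best_for_aln <- apply(F2d, 2L, which.max)
  keep <- which(F2d[cbind(seq_len(n), best_for_ref)] > 0 &
                  best_for_aln[best_for_ref] == seq_len(n))
  if (length(keep) == 0L) return(anchor_set(NULL, "bipace2d", cfg))
  j <- best_for_ref[keep]
  pairs <- data.frame(ref_index = keep, aln_index = j,
                      similarity = S[cbind(keep, j)],
                      score = F2d[cbind(keep, j)])
  anchor_set(pairs, "bipace2d", cfg)
}

# -------------------------------------------------------------------- DISCO

#' Find anchors with DISCO
#'
#' Retention times of both tables are z-scored on their own statistics.
#' For each reference peak, the nearest \code{fraction} of aligned peaks
#' (Euclidean distance in z-space by default) are candidates; the candidate
#' with the highest spectral similarity at or above the threshold becomes
#' the match. One-to-one matching is enforced by selection score
#' (= similarity).
#'
#' @param ref,aln \code{peak_table}s with >= 2 peaks each.
#' @param nb a [neighborhood_config()].
#' @param sim a [similarity_config()].
#' @return an \code{anchor_set}.
#' @export
find_anchors_disco <- function(ref, aln, nb = neighborhood_config(),
                               sim = similarity_config()) {
  cfg <- list(neighborhood = nb, similarity = sim)
  if (nrow(ref) == 0L || nrow(aln) == 0L)
    return(anchor_set(NULL, "disco", cfg))
  zr <- zscore_times(ref)
  za <- zscore_times(aln)
  S <- .sim_matrix(ref, aln, sim)
  tr_ref <- .total_rt(ref); tr_aln <- .total_rt(aln)
  rows <- vector("list", nrow(ref))
  for (i in seq_len(nrow(ref))) {
    cand <- .neighbors(zr[i, ], za, nb)
    s <- S[i, cand]
    ok <- s >= sim$threshold
    if (!any(ok)) next
    pick <- which.max(ifelse(ok, s, -Inf))
    j <- cand[pick]
    rows[[i]] <- data.frame(ref_index = i, aln_index = j,
                            similarity = S[i, j], score = S[i, j],
                            trdiff = abs(tr_ref[i] - tr_aln[j]))
  }
  .finish_anchor_set(do.call(rbind, rows), "disco", cfg)
}

# -------------------------------------------------------------------- MSort

#' MSort configuration
#'
#' MSort uses a static search window in raw seconds around each reference
#' peak: aligned peaks within \code{max_shift_1} seconds in the first
#' dimension and \code{max_shift_2} seconds in the second are candidates.
#'
#' @param max_shift_1,max_shift_2 window half-widths (s), > 0.
#' @param similarity a [similarity_config()].
#' @return a list of class \code{"msort_config"}.
#' @export
msort_config <- function(max_shift_1 = 25, max_shift_2 = 0.5,
                         similarity = similarity_config()) {
  stopifnot(max_shift_1 > 0, max_shift_2 > 0)
  structure(list(max_shift_1 = max_shift_1, max_shift_2 = max_shift_2,
                 similarity = similarity),
            class = "msort_config")
}

#' Find anchors with MSort
#'
#' For each reference peak, the aligned peak inside the static window with
#' the highest spectral similarity at or above the threshold becomes the
#' match; one-to-one matching is enforced by similarity.
#'
#' @param ref,aln \code{peak_table}s.
#' @param cfg an [msort_config()].
#' @return an \code{anchor_set}.
#' @export
find_anchors_msort <- function(ref, aln, cfg = msort_config()) {
  if (nrow(ref) == 0L || nrow(aln) == 0L)
    return(anchor_set(NULL, "msort", cfg))
  S <- .sim_matrix(ref, aln, cfg$similarity)
  thr <- cfg$similarity$threshold
  tr_ref <- .total_rt(ref); tr_aln <- .total_rt(aln)
  rows <- vector("list", nrow(ref))
  for (i in seq_len(nrow(ref))) {
    cand <- which(abs(aln$rt1 - ref$rt1[i]) <= cfg$max_shift_1 &
                    abs(aln$rt2 - ref$rt2[i]) <= cfg$max_shift_2)
    if (length(cand) == 0L) next
    s <- S[i, cand]
    ok <- s >= thr
    if (!any(ok)) next
    j <- cand[which.max(ifelse(ok, s, -Inf))]
    rows[[i]] <- data.frame(ref_index = i, aln_index = j,
                            similarity = S[i, j], score = S[i, j],
                            trdiff = abs(tr_ref[i] - tr_aln[j]))
  }
  .finish_anchor_set(do.call(rbind, rows), "msort", cfg)
}

# ---------------------------------------------------------------------- PAM

#' PAM configuration
#'
#' PAM has no search window: every reference-aligned pair is scored by the
#' weighted match score of [pam_match_score()], combining the peak distance
#' in z-space with spectral similarity. The weight \code{w} shifts the
#' balance: high values prioritize peak distance, low values prioritize
#' spectral similarity.
#'
#' @param w weight in \code{[0, 1]} (default 0.8).
#' @param distance \code{"canberra"} (default) or \code{"euclidean"}.
#' @param similarity a [similarity_config()].
#' @return a list of class \code{"pam_config"}.
#' @export
pam_config <- function(w = 0.8, distance = c("canberra", "euclidean"),
                       similarity = similarity_config()) {
  distance <- match.arg(distance)
  stopifnot(w >= 0, w <= 1)
  structure(list(w = w, distance = distance, similarity = similarity),
            class = "pam_config")
}

#' PAM match score
#'
#' \deqn{M_d = w (1 + D_d)^{-1} + (1 - w) S}
#' where \eqn{D_d} is the distance between the peaks and \eqn{S} the
#' spectral similarity. Lies in \code{[0, 1]} when \eqn{S \in [0, 1]}.
#'
#' @param distance peak distance >= 0.
#' @param similarity spectral similarity in \code{[0, 1]}.
#' @param w weight in \code{[0, 1]}.
#' @return numeric score.
#' @export
pam_match_score <- function(distance, similarity, w) {
  w / (1 + distance) + (1 - w) * similarity
}

#' Find anchors with PAM
#'
#' All pairs of peaks are considered. Pairs whose spectral similarity falls
#' below the threshold are skipped before any distance computation (the
#' short-circuit that makes the exhaustive comparison tractable); the rest
#' are scored with [pam_match_score()] on z-scored coordinates and matched
#' greedily one-to-one by descending score.
#'
#' @param ref,aln \code{peak_table}s with >= 2 peaks each.
#' @param cfg a [pam_config()].
#' @return an \code{anchor_set}.
#' @export
find_anchors_pam <- function(ref, aln, cfg = pam_config()) {
  if (nrow(ref) == 0L || nrow(aln) == 0L)
    return(anchor_set(NULL, "pam", cfg))
  S <- .sim_matrix(ref, aln, cfg$similarity)
  gated <- which(S >= cfg$similarity$threshold, arr.ind = TRUE)
  if (nrow(gated) == 0L) return(anchor_set(NULL, "pam", cfg))
  zr <- zscore_times(ref)
  za <- zscore_times(aln)
  tr_ref <- .total_rt(ref); tr_aln <- .total_rt(aln)
  d <- vapply(seq_len(nrow(gated)), function(k)
    peak_distance(zr[gated[k, 1], ], za[gated[k, 2], ], cfg$distance),
    numeric(1))
  s <- S[gated]
  m <- pam_match_score(d, s, cfg$w)
  df <- data.frame(ref_index = gated[, 1], aln_index = gated[, 2],
                   similarity = s, score = m,
                   trdiff = abs(tr_ref[gated[, 1]] - tr_aln[gated[, 2]]))
  # greedy one-to-one by descending match score
  df <- df[order(-df$score, df$trdiff, df$ref_index, df$aln_index), ,
           drop = FALSE]
  used_ref <- logical(nrow(ref)); used_aln <- logical(nrow(aln))
  keep <- logical(nrow(df))
  for (k in seq_len(nrow(df))) {
    i <- df$ref_index[k]; j <- df$aln_index[k]
    if (!used_ref[i] && !used_aln[j]) {
      keep[k] <- TRUE
      used_ref[i] <- TRUE
      used_aln[j] <- TRUE
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$ref_index), , drop = FALSE]
  anchor_set(df[, c("ref_index", "aln_index", "similarity", "score")],
             "pam", cfg)
}

# ------------------------------------------------------------------- TNT-DA

#' Find anchors with TNT-DA
#'
#' Combines the DISCO discrimination rule with the PAM selection rule:
#' retention times are z-scored, each reference peak considers only the
#' nearest \code{fraction} of aligned peaks (Canberra distance by default),
#' candidates failing the spectral threshold are dropped, and the surviving
#' candidate with the highest [pam_match_score()] is the match. One-to-one
#' matching is enforced by the match score.
#'
#' @param ref,aln \code{peak_table}s with >= 2 peaks each.
#' @param nb a [neighborhood_config()]; default uses Canberra distance.
#' @param pam a [pam_config()]; default weight \code{w = 0.4} with cosine
#'   similarity (threshold 0.9) on power-transformed spectra, the settings
#'   that performed best in benchmarking.
#' @return an \code{anchor_set}.
#' @export
find_anchors_tntda <- function(ref, aln,
                               nb = neighborhood_config(distance = "canberra"),
                               pam = pam_config(w = 0.4)) {
  cfg <- list(neighborhood = nb, pam = pam)
  if (nrow(ref) == 0L || nrow(aln) == 0L)
    return(anchor_set(NULL, "tntda", cfg))
  sim <- pam$similarity
  zr <- zscore_times(ref)
  za <- zscore_times(aln)
  S <- .sim_matrix(ref, aln, sim)
  tr_ref <- .total_rt(ref); tr_aln <- .total_rt(aln)
  rows <- vector("list", nrow(ref))
  for (i in seq_len(nrow(ref))) {
    d_all <- .dists_to(zr[i, ], za, nb$distance)
    cand <- order(d_all)[seq_len(ceiling(nb$fraction * nrow(aln)))]
    s <- S[i, cand]
    ok <- s >= sim$threshold
    if (!any(ok)) next
    m <- pam_match_score(d_all[cand], s, pam$w)
    pick <- which.max(ifelse(ok, m, -Inf))
    j <- cand[pick]
    rows[[i]] <- data.frame(ref_index = i, aln_index = j,
                            similarity = S[i, j], score = m[pick],
                            trdiff = abs(tr_ref[i] - tr_aln[j]))
  }
  .finish_anchor_set(do.call(rbind, rows), "tntda", cfg)
}

# ------------------------------------------------------------ Smith-Waterman

#' Find anchors with a spectrum-aware Smith-Waterman alignment
#'
#' Both tables are sorted by total elution time (rt1 + rt2). A local
#' dynamic-programming matrix is filled with the recurrence
#' \code{max(0, diag + match/mismatch, up + gap, left + gap)}, where a cell
#' counts as a "match" when the spectral similarity of its peak pair reaches
#' the threshold. The path is traced back from the global maximum cell until
#' a zero cell; diagonal steps where the match rule held become anchor
#' pairs (reported with the original table indices).
#'
#' @param ref,aln \code{peak_table}s.
#' @param sim a [similarity_config()].
#' @param scores named numeric vector with elements \code{match},
#'   \code{mismatch}, \code{gap} (defaults +1, -1, -1).
#' @return an \code{anchor_set}.
#' @export
smith_waterman_anchors <- function(ref, aln, sim = similarity_config(),
                                   scores = c(match = 1, mismatch = -1,
                                              gap = -1)) {
  cfg <- list(similarity = sim, scores = scores)
  n <- nrow(ref); m <- nrow(aln)
  if (n == 0L || m == 0L) return(anchor_set(NULL, "smith_waterman", cfg))
  o_r <- order(.total_rt(ref))
  o_a <- order(.total_rt(aln))
  S <- .sim_matrix(ref[o_r, , drop = FALSE], aln[o_a, , drop = FALSE], sim)
  is_match <- S >= sim$threshold
  H <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (is_match[i, j]) scores[["match"]] else scores[["mismatch"]]
      H[i + 1L, j + 1L] <- max(0,
                               H[i, j] + sub,
                               H[i, j + 1L] + scores[["gap"]],
                               H[i + 1L, j] + scores[["gap"]])
    }
  }
  if (max(H) <= 0) return(anchor_set(NULL, "smith_waterman", cfg))
  start <- which(H == max(H), arr.ind = TRUE)[1L, ]
  i <- start[1L]; j <- start[2L]
  pairs <- list()
  while (i > 1L && j > 1L && H[i, j] > 0) {
    sub <- if (is_match[i - 1L, j - 1L]) scores[["match"]] else
      scores[["mismatch"]]
    if (H[i, j] == H[i - 1L, j - 1L] + sub) {
      if (is_match[i - 1L, j - 1L]) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          ref_index = o_r[i - 1L], aln_index = o_a[j - 1L],
          similarity = S[i - 1L, j - 1L], score = H[i, j])
      }
      i <- i - 1L; j <- j - 1L
    } else if (H[i, j] == H[i - 1L, j] + scores[["gap"]]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  df <- do.call(rbind, rev(pairs))
  if (is.null(df)) return(anchor_set(NULL, "smith_waterman", cfg))
  df <- df[order(df$ref_index), , drop = FALSE]
  anchor_set(df, "smith_waterman", cfg)
}

# --------------------------------------------------------------- dispatcher

#' Algorithm names supported by the aligner
#' @return character vector.
#' @export
alignment_algorithms <- function() {
  c("bipace2d", "disco", "msort", "pam", "tntda", "smith_waterman")
}

#' Default configuration for an algorithm
#'
#' Returns the documented default parameter set of one of the six anchor
#' algorithms (the values used by [align_pair()] when no configuration is
#' supplied).
#'
#' @param algorithm one of [alignment_algorithms()].
#' @return a configuration object/list for that algorithm.
#' @export
default_config <- function(algorithm) {
  switch(algorithm,
         bipace2d = bipace_config(),
         disco = list(neighborhood = neighborhood_config(),
                      similarity = similarity_config()),
         msort = msort_config(),
         pam = pam_config(),
         tntda = list(neighborhood = neighborhood_config(distance = "canberra"),
                      pam = pam_config(w = 0.4)),
         smith_waterman = list(similarity = similarity_config(),
                               scores = c(match = 1, mismatch = -1, gap = -1)),
         stop(sprintf("unknown algorithm '%s'", algorithm), call. = FALSE))
}

#' Find anchor peaks with a chosen algorithm
#'
#' Thin dispatcher over the six \code{find_anchors_*} /
#' [smith_waterman_anchors()] functions.
#'
#' @param ref,aln \code{peak_table}s.
#' @param algorithm one of [alignment_algorithms()].
#' @param config configuration object for that algorithm; defaults to
#'   [default_config()].
#' @return an \code{anchor_set}.
#' @export
find_anchors <- function(ref, aln, algorithm = "tntda", config = NULL) {
  if (!algorithm %in% alignment_algorithms())
    stop(sprintf("unknown algorithm '%s' (choose one of: %s)", algorithm,
                 paste(alignment_algorithms(), collapse = ", ")),
         call. = FALSE)
  if (is.null(config)) config <- default_config(algorithm)
  switch(algorithm,
         bipace2d = find_anchors_bipace(ref, aln, config),
         disco = find_anchors_disco(ref, aln, config$neighborhood,
                                    config$similarity),
         msort = find_anchors_msort(ref, aln, config),
         pam = find_anchors_pam(ref, aln, config),
         tntda = find_anchors_tntda(ref, aln, config$neighborhood,
                                    config$pam),
         smith_waterman = smith_waterman_anchors(ref, aln,
                                                 config$similarity,
                                                 config$scores))
}
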