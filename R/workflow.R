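#' Elution-order consistency check
#'
#' Anchors that contradict the common elution order between the two runs are
#' spurious matches and would distort the warp fit. The order is checked on
#' the total elution time (rt1 + rt2): anchors are sorted by reference total
#' time and the largest subset whose aligned total times are strictly
#' increasing is kept (a longest-increasing-subsequence computation, which
#' removes the fewest anchors possible). Removed pairs are reported via
#' \code{message()} and attached as attribute \code{"removed"}.
#'
#' @param anchors an \code{anchor_set}.
#' @param ref,aln the \code{peak_table}s the anchors refer to.
#' @return an \code{anchor_set} containing the retained pairs.
#' @export
check_elution_order <- function(anchors, ref, aln) {
  pairs <- anchor_pairs(anchors)
  if (nrow(pairs) <= 1L) {
    out <- anchors
    attr(out, "removed") <- pairs[0, ]
    return(out)
  }
  tr <- ref$rt1[pairs$ref_index] + ref$rt2[pairs$ref_index]
  ta <- aln$rt1[pairs$aln_index] + aln$rt2[pairs$aln_index]
  ord <- order(tr, ta)
  keep_in_ord <- .lis_strict(ta[ord])
  keep <- sort(ord[keep_in_ord])
  removed <- pairs[setdiff(seq_len(nrow(pairs)), keep), , drop = FALSE]
  if (nrow(removed) > 0)
    message(sprintf("elution-order check removed %d of %d anchors",
                    nrow(removed), nrow(pairs)))
  out <- anchor_set(pairs[keep, , drop = FALSE], anchors$algorithm,
                    anchors$config)
  attr(out, "removed") <- removed
  out
}

# Indices of one longest strictly increasing subsequence (O(n^2) dynamic
# program; anchor counts are small). Ties favor earlier elements.
.lis_strict <- function(y) {
  n <- length(y)
  len <- rep(1L, n)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (y[j] < y[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(len)
  out <- integer(len[i])
  k <- len[i]
  while (i > 0L) {
    out[k] <- i
    k <- k - 1L
    i <- prev[i]
  }
  out
}

#' Fit a retention-time warp from anchors
#'
#' Builds one monotone correction map per dimension from the anchor pairs
#' (aligned retention time on the x axis, reference retention time on the y
#' axis). \code{"global_linear"} fits one least-squares line per dimension;
#' \code{"piecewise_linear"} interpolates linearly through the anchor knots
#' and extrapolates with the slope of the two outermost knots on each side
#' (knots sharing an aligned retention time are averaged). A single anchor
#' falls back to a pure offset map.
#'
#' @param anchors an \code{anchor_set} with at least 1 pair (2 for
#'   \code{global_linear}).
#' @param ref,aln the \code{peak_table}s the anchors refer to.
#' @param fit_kind \code{"piecewise_linear"} (default) or
#'   \code{"global_linear"}.
#' @return an object of class \code{"warp_model"} with per-dimension maps.
#' @export
build_warp <- function(anchors, ref, aln,
                       fit_kind = c("piecewise_linear", "global_linear")) {
  fit_kind <- match.arg(fit_kind)
  pairs <- anchor_pairs(anchors)
  if (nrow(pairs) == 0L)
    stop(paste("no anchors to fit a warp from; relax the similarity",
               "threshold or widen the search window"), call. = FALSE)
  map1 <- .fit_map(aln$rt1[pairs$aln_index], ref$rt1[pairs$ref_index],
                   fit_kind, dim = 1L)
  map2 <- .fit_map(aln$rt2[pairs$aln_index], ref$rt2[pairs$ref_index],
                   fit_kind, dim = 2L)
  structure(list(dim1 = map1, dim2 = map2, fit_kind = fit_kind,
                 n_anchors = nrow(pairs)),
            class = "warp_model")
}

.fit_map <- function(x, y, fit_kind, dim) {
  # average knots with duplicated aligned RT
  ux <- sort(unique(x))
  uy <- vapply(ux, function(v) mean(y[x == v]), numeric(1))
  if (fit_kind == "global_linear") {
    if (length(ux) < 2L)
      stop(sprintf(paste("global_linear warp in dimension %d needs >= 2",
                         "anchors with distinct retention times"), dim),
           call. = FALSE)
    cf <- stats::coef(stats::lm(uy ~ ux, weights = vapply(
      ux, function(v) sum(x == v), numeric(1))))
    list(kind = "linear", a = unname(cf[2L]), b = unname(cf[1L]))
  } else {
    if (length(ux) == 1L) {
      list(kind = "linear", a = 1, b = uy - ux)
    } else {
      list(kind = "piecewise", x = ux, y = uy)
    }
  }
}

.eval_map <- function(map, x) {
  if (map$kind == "linear") return(map$a * x + map$b)
  kx <- map$x; ky <- map$y
  n <- length(kx)
  out <- stats::approx(kx, ky, xout = pmin(pmax(x, kx[1L]), kx[n]),
                       ties = "ordered")$y
  s_lo <- (ky[2L] - ky[1L]) / (kx[2L] - kx[1L])
  s_hi <- (ky[n] - ky[n - 1L]) / (kx[n] - kx[n - 1L])
  lo <- x < kx[1L]
  hi <- x > kx[n]
  out[lo] <- ky[1L] + s_lo * (x[lo] - kx[1L])
  out[hi] <- ky[n] + s_hi * (x[hi] - kx[n])
  out
}

#' @export
print.warp_model <- function(x, ...) {
  cat(sprintf("<warp_model> %s, fitted on %d anchors\n", x$fit_kind,
              x$n_anchors))
  for (d in 1:2) {
    map <- x[[paste0("dim", d)]]
    if (map$kind == "linear") {
      cat(sprintf("  dim%d: rt_corrected = %.6g * rt + %.6g\n",
                  d, map$a, map$b))
    } else {
      cat(sprintf("  dim%d: piecewise linear through %d knots [%.3g, %.3g] s\n",
                  d, length(map$x), map$x[1L], map$x[length(map$x)]))
    }
  }
  invisible(x)
}

#' Apply a warp to a peak table
#'
#' Maps every retention time through the per-dimension correction maps.
#' Spectra, labels, peak count and row order are untouched. Corrected times
#' that extrapolate below zero are clamped to 0 with a warning.
#'
#' @param t a \code{peak_table}.
#' @param w a \code{warp_model}.
#' @return the corrected \code{peak_table}.
#' @export
apply_warp <- function(t, w) {
  stopifnot(inherits(w, "warp_model"))
  rt1 <- .eval_map(w$dim1, t$rt1)
  rt2 <- .eval_map(w$dim2, t$rt2)
  n_neg <- sum(rt1 < 0) + sum(rt2 < 0)
  if (n_neg > 0) {
    warning(sprintf("%d corrected retention times below 0 were clamped to 0",
                    n_neg), call. = FALSE)
    rt1 <- pmax(rt1, 0)
    rt2 <- pmax(rt2, 0)
  }
  peak_table(rt1, rt2, t$spectrum, label = t$label,
             sample_id = sample_id(t))
}

#' Rectangular exclusion region
#'
#' Column bleed (stationary-phase degradation) produces characteristic
#' elution areas whose peaks should not take part in the alignment; they are
#' described as rectangles in (rt1, rt2) space.
#'
#' @param rt1,rt2 numeric length-2 intervals (lower <= upper), in seconds.
#' @return a list of class \code{"exclusion_region"}.
#' @export
exclusion_region <- function(rt1, rt2) {
  stopifnot(length(rt1) == 2L, length(rt2) == 2L,
            rt1[1L] <= rt1[2L], rt2[1L] <= rt2[2L])
  structure(list(rt1 = as.numeric(rt1), rt2 = as.numeric(rt2)),
            class = "exclusion_region")
}

#' Remove peaks inside exclusion regions
#'
#' Drops every peak whose (rt1, rt2) lies inside any of the given closed
#' rectangles (e.g. column-bleed areas). The number removed is reported via
#' \code{message()}.
#'
#' @param t a \code{peak_table}.
#' @param regions list of [exclusion_region()]s (may be empty or NULL).
#' @return the filtered \code{peak_table}.
#' @export
filter_exclusion_regions <- function(t, regions) {
  if (is.null(regions) || length(regions) == 0L) return(t)
  if (inherits(regions, "exclusion_region")) regions <- list(regions)
  inside <- rep(FALSE, nrow(t))
  for (r in regions) {
    inside <- inside | (t$rt1 >= r$rt1[1L] & t$rt1 <= r$rt1[2L] &
                          t$rt2 >= r$rt2[1L] & t$rt2 <= r$rt2[2L])
  }
  if (any(inside))
    message(sprintf("excluded %d peaks inside exclusion regions",
                    sum(inside)))
  out <- t[!inside, , drop = FALSE]
  attr(out, "sample_id") <- sample_id(t)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Kovats retention-index transformation
#'
#' Recalculates retention times to retention indices against a ladder of
#' reference points (e.g. n-alkane homologues identified in the run), one
#' ladder per dimension. Inside the ladder the index is linearly
#' interpolated between the bracketing ladder points (the
#' temperature-programmed linear convention); outside, the nearest segment
#' is extrapolated. Because the index scale is defined by compounds rather
#' than by the clock, two runs expressed in indices are aligned without any
#' other manipulation.
#'
#' @param t a \code{peak_table}.
#' @param ladder1,ladder2 two-column objects (retention time in seconds,
#'   index) with >= 2 rows and strictly increasing times and indices.
#' @param replace if TRUE, return a \code{peak_table} with rt1/rt2 replaced
#'   by the indices; otherwise return a data.frame with columns \code{ri1},
#'   \code{ri2}.
#' @return data.frame of indices, or a \code{peak_table} when
#'   \code{replace = TRUE}.
#' @export
kovats_index_transform <- function(t, ladder1, ladder2, replace = FALSE) {
  m1 <- .ladder_map(ladder1, 1L)
  m2 <- .ladder_map(ladder2, 2L)
  ri1 <- .eval_map(m1, t$rt1)
  ri2 <- .eval_map(m2, t$rt2)
  if (replace) {
    peak_table(ri1, ri2, t$spectrum, label = t$label,
               sample_id = sample_id(t))
  } else {
    data.frame(ri1 = ri1, ri2 = ri2)
  }
}

.ladder_map <- function(ladder, dim) {
  ladder <- as.matrix(ladder)
  if (nrow(ladder) < 2L)
    stop(sprintf("retention-index ladder for dimension %d needs >= 2 points",
                 dim), call. = FALSE)
  rt <- as.numeric(ladder[, 1L])
  idx <- as.numeric(ladder[, 2L])
  if (any(diff(rt) <= 0) || any(diff(idx) <= 0))
    stop(sprintf(paste("retention-index ladder for dimension %d must be",
                       "strictly increasing in both columns"), dim),
         call. = FALSE)
  list(kind = "piecewise", x = rt, y = idx)
}

#' Align one peak table to a reference
#'
#' Runs the full six-step workflow for one chromatogram pair: optional
#' column-bleed filtering, anchor-peak detection with the chosen algorithm,
#' the elution-order check, warp fitting from the surviving anchors, time
#' correction of the aligned table, and Kolmogorov-Smirnov diagnostics per
#' dimension before and after correction.
#'
#' @param ref reference \code{peak_table}.
#' @param aln \code{peak_table} to align.
#' @param algorithm one of [alignment_algorithms()].
#' @param config algorithm configuration (default [default_config()]).
#' @param fit_kind warp model, see [build_warp()].
#' @param exclusion_regions optional list of [exclusion_region()]s applied
#'   to both tables before anchor finding.
#' @return an object of class \code{"alignment_result"}: list with elements
#'   \code{corrected} (time-corrected table), \code{anchors} (post
#'   order-check \code{anchor_set}), \code{n_anchors_raw} (count before the
#'   order check), \code{warp}, \code{diagnostics} (data.frame with
#'   \code{dimension}, \code{ks_before}, \code{ks_after}), \code{ref},
#'   \code{aligned} and \code{algorithm}.
#' @export
align_pair <- function(ref, aln, algorithm = "tntda", config = NULL,
                       fit_kind = c("piecewise_linear", "global_linear"),
                       exclusion_regions = NULL) {
  fit_kind <- match.arg(fit_kind)
  ref <- filter_exclusion_regions(ref, exclusion_regions)
  aln <- filter_exclusion_regions(aln, exclusion_regions)
  anchors_raw <- find_anchors(ref, aln, algorithm, config)
  anchors <- check_elution_order(anchors_raw, ref, aln)
  if (n_anchors(anchors) == 0L)
    stop(sprintf(paste("alignment of '%s' to '%s' found no anchors with %s;",
                       "relax the similarity threshold or widen the",
                       "tolerance/window parameters"),
                 sample_id(aln), sample_id(ref), algorithm), call. = FALSE)
  warp <- build_warp(anchors, ref, aln, fit_kind)
  corrected <- apply_warp(aln, warp)
  ks_before <- ks_per_dimension(ref, aln)
  ks_after <- ks_per_dimension(ref, corrected)
  diagnostics <- data.frame(
    dimension = c(1L, 2L),
    ks_before = c(ks_before$d1, ks_before$d2),
    ks_after = c(ks_after$d1, ks_after$d2))
  structure(list(corrected = corrected, anchors = anchors,
                 n_anchors_raw = n_anchors(anchors_raw), warp = warp,
                 diagnostics = diagnostics, ref = ref, aligned = aln,
                 algorithm = algorithm),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> '%s' aligned to '%s' with %s\n",
              sample_id(x$aligned), sample_id(x$ref), x$algorithm))
  cat(sprintf("  anchors: %d (of %d before the elution-order check)\n",
              n_anchors(x$anchors), x$n_anchors_raw))
  d <- x$diagnostics
  for (k in 1:2)
    cat(sprintf("  K-S dim %d: %.4f before -> %.4f after\n",
                d$dimension[k], d$ks_before[k], d$ks_after[k]))
  invisible(x)
}

#' Align a dataset against a fixed reference
#'
#' Aligns every non-reference table independently to the table whose sample
#' id equals \code{ref_id}.
#'
#' @param tables list of \code{peak_table}s with unique sample ids.
#' @param ref_id sample id of the reference table.
#' @param ... passed to [align_pair()] (algorithm, config, fit_kind,
#'   exclusion_regions).
#' @return list with \code{results} (one \code{alignment_result} per
#'   non-reference table) and \code{summary} (data.frame with sample id,
#'   anchor counts and the K-S statistics before and after correction).
#' @export
align_dataset <- function(tables, ref_id, ...) {
  ids <- vapply(tables, sample_id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sample ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  if (!ref_id %in% ids)
    stop(sprintf("reference sample '%s' not found in the dataset", ref_id),
         call. = FALSE)
  ref <- tables[[which(ids == ref_id)]]
  others <- tables[ids != ref_id]
  results <- lapply(others, function(t) align_pair(ref, t, ...))
  summary <- do.call(rbind, lapply(results, function(r) data.frame(
    sample = sample_id(r$aligned),
    n_anchors_raw = r$n_anchors_raw,
    n_anchors = n_anchors(r$anchors),
    ks1_before = r$diagnostics$ks_before[1L],
    ks1_after = r$diagnostics$ks_after[1L],
    ks2_before = r$diagnostics$ks_before[2L],
    ks2_after = r$diagnostics$ks_after[2L])))
  if (is.null(summary))
    summary <- data.frame(sample = character(0), n_anchors_raw = integer(0),
                          n_anchors = integer(0), ks1_before = numeric(0),
                          ks1_after = numeric(0), ks2_before = numeric(0),
                          ks2_after = numeric(0))
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}
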