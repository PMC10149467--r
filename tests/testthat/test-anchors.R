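test_that("z-scoring standardizes each dimension with sample sd", {
  t <- peak_table(rt1 = c(1, 2, 3), rt2 = c(10, 20, 60),
                  list(c(`50` = 1), c(`60` = 1), c(`70` = 1)))
  z <- zscore_times(t)
  expect_equal(unname(z[, "z1"]), c(-1, 0, 1))
  expect_equal(mean(z[, "z1"]), 0)
  expect_equal(sd(z[, "z1"]), 1)
  expect_equal(sd(z[, "z2"]), 1)
  one <- peak_table(1, 1, list(c(`50` = 1)))
  expect_error(zscore_times(one), "at least 2")
  flat <- peak_table(c(1, 1), c(1, 2), list(c(`50` = 1), c(`60` = 1)))
  expect_error(zscore_times(flat), "dimension 1")
})

test_that("peak distances match their closed forms", {
  expect_equal(peak_distance(c(1, 2), c(1, 2), "euclidean"), 0)
  expect_equal(peak_distance(c(1, 2), c(1, 2), "canberra"), 0)
  expect_equal(peak_distance(c(0, 0), c(3, 4), "euclidean"), 5)
  expect_equal(peak_distance(c(1, 0), c(0, 1), "canberra"), 2)
  expect_equal(peak_distance(c(0, 5), c(0, 10), "canberra"), 1 / 3)
})

test_that("candidate neighborhoods follow the ceil(fraction * N) rule", {
  set.seed(3)
  lib <- make_spectrum_library(10)
  ref <- make_reference_table(lib, 10)
  aln <- copy_table(ref)
  expect_length(candidate_neighbors(ref, aln, 1,
                                    neighborhood_config(fraction = 1)), 10)
  nn <- candidate_neighbors(ref, aln, 3, neighborhood_config(fraction = 0.20))
  expect_length(nn, 2)
  # distances are non-decreasing along the returned order
  zr <- zscore_times(ref); za <- zscore_times(aln)
  d <- apply(za[nn, , drop = FALSE], 1, function(q)
    peak_distance(zr[3, ], q, "euclidean"))
  expect_true(all(diff(d) >= 0))
  expect_equal(nn[1], 3)  # nearest neighbor of a copy is the peak itself
})

test_that("BiPACE pair score follows the Gaussian-penalty closed form", {
  p <- list(rt1 = 100, rt2 = 2)
  cfg <- bipace_config(D1 = 10, D2 = 0.5, T1 = 1e-9, T2 = 1e-9)
  expect_equal(bipace_pair_score(p, p, cfg, s = 0.9), 0.9)
  q <- list(rt1 = 110, rt2 = 2)  # delta t1 = D1
  expect_equal(bipace_pair_score(p, q, cfg, s = 1), exp(-0.5))
  expect_equal(bipace_pair_score(p, q, cfg, s = 0), 0)
  # penalty below the cutoff discards the pair entirely
  tight <- bipace_config(D1 = 10, D2 = 0.5, T1 = 0.99, T2 = 0.99)
  expect_equal(bipace_pair_score(p, q, tight, s = 1), 0)
})

test_that("every algorithm returns the identity matching on an exact copy", {
  t <- tiny_table()
  aln <- copy_table(t)
  for (alg in alignment_algorithms()) {
    a <- find_anchors(t, aln, alg)
    expect_equal(n_anchors(a), nrow(t), info = alg)
    expect_equal(anchor_pairs(a)$ref_index, anchor_pairs(a)$aln_index,
                 info = alg)
    expect_true(all(anchor_pairs(a)$similarity >= 0.999), info = alg)
  }
})

test_that("BiPACE anchors equal the brute-force mutual-argmax of the f2d matrix", {
  pair <- synthetic_pair(seed = 21, n = 12)
  cfg <- bipace_config(D1 = 100, D2 = 0.8, T1 = 0.5, T2 = 0.5)
  # oracle: explicit f2d matrix from the scalar op, then mutual argmax
  n <- nrow(pair$ref); m <- nrow(pair$aligned)
  F2d <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- max(0, spectral_similarity(pair$ref$spectrum[[i]],
                                      pair$aligned$spectrum[[j]],
                                      cfg$similarity))
      if (s < cfg$similarity$threshold) s <- 0
      F2d[i, j] <- bipace_pair_score(pair$ref[i, ], pair$aligned[j, ], cfg, s)
    }
  }
  expected <- list()
  for (i in seq_len(n)) {
    j <- which.max(F2d[i, ])
    if (F2d[i, j] > 0 && which.max(F2d[, j]) == i)
      expected[[length(expected) + 1L]] <- c(i, j)
  }
  expected <- do.call(rbind, expected)
  got <- anchor_pairs(find_anchors_bipace(pair$ref, pair$aligned, cfg))
  expect_equal(nrow(got), nrow(expected))
  expect_equal(got$ref_index, expected[, 1])
  expect_equal(got$aln_index, expected[, 2])
})

test_that("MSort honors its static window", {
  t <- tiny_table()
  shifted <- shift_table(t, d1 = 30)
  expect_equal(n_anchors(find_anchors_msort(t, shifted,
    msort_config(max_shift_1 = 25, max_shift_2 = 0.5))), 0)
  recovered <- find_anchors_msort(t, shift_table(t, d1 = 10),
    msort_config(max_shift_1 = 25, max_shift_2 = 0.5))
  expect_equal(anchor_pairs(recovered)$aln_index, seq_len(nrow(t)))
})

test_that("PAM match score follows the weighted closed form", {
  expect_equal(pam_match_score(0, 0, w = 1), 1)
  expect_equal(pam_match_score(5, 0.8, w = 0), 0.8)
  expect_equal(pam_match_score(1, 0.8, w = 0.5), 0.65)
})

test_that("PAM matching equals a brute-force greedy over gated pairs", {
  pair <- synthetic_pair(seed = 8, n = 10)
  cfg <- pam_config(w = 0.6, distance = "canberra",
                    similarity = similarity_config(threshold = 0.5))
  # oracle: score all gated pairs explicitly, sort, sweep greedily
  zr <- zscore_times(pair$ref); za <- zscore_times(pair$aligned)
  rows <- list()
  for (i in seq_len(nrow(pair$ref))) {
    for (j in seq_len(nrow(pair$aligned))) {
      s <- max(0, spectral_similarity(pair$ref$spectrum[[i]],
                                      pair$aligned$spectrum[[j]],
                                      cfg$similarity))
      if (s < cfg$similarity$threshold) next
      d <- peak_distance(zr[i, ], za[j, ], "canberra")
      rows[[length(rows) + 1L]] <- data.frame(
        i = i, j = j, m = pam_match_score(d, s, cfg$w),
        trd = abs(sum(pair$ref[i, c("rt1", "rt2")]) -
                    sum(pair$aligned[j, c("rt1", "rt2")])))
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(-df$m, df$trd, df$i, df$j), ]
  used_i <- used_j <- integer(0)
  expected <- list()
  for (k in seq_len(nrow(df))) {
    if (df$i[k] %in% used_i || df$j[k] %in% used_j) next
    expected[[length(expected) + 1L]] <- c(df$i[k], df$j[k])
    used_i <- c(used_i, df$i[k]); used_j <- c(used_j, df$j[k])
  }
  expected <- do.call(rbind, expected)
  expected <- expected[order(expected[, 1]), , drop = FALSE]
  got <- anchor_pairs(find_anchors_pam(pair$ref, pair$aligned, cfg))
  expect_equal(got$ref_index, expected[, 1])
  expect_equal(got$aln_index, expected[, 2])
})

test_that("TNT-DA with w = 0 and Euclidean distance reproduces DISCO", {
  for (seed in 1:20) {
    pair <- synthetic_pair(seed, n = 15)
    nb <- neighborhood_config(fraction = 0.20, distance = "euclidean")
    sim <- similarity_config(threshold = 0.8)
    disco <- find_anchors_disco(pair$ref, pair$aligned, nb, sim)
    tnt <- find_anchors_tntda(pair$ref, pair$aligned, nb,
                              pam_config(w = 0, distance = "euclidean",
                                         similarity = sim))
    expect_equal(anchor_pairs(tnt)[, c("ref_index", "aln_index", "similarity")],
                 anchor_pairs(disco)[, c("ref_index", "aln_index", "similarity")],
                 info = paste("seed", seed))
  }
})

test_that("TNT-DA at its benchmark settings recovers a mildly distorted pair", {
  pair <- synthetic_pair(seed = 5, n = 40)
  a <- find_anchors_tntda(pair$ref, pair$aligned)
  cc <- confusion_counts(a, pair$truth$correspondence)
  prf <- precision_recall_f1(cc)
  expect_gte(prf$precision, 0.95)
  expect_gte(prf$recall, 0.95)
})

test_that("Smith-Waterman equals exhaustive monotone-path enumeration on small grids", {
  # oracle: enumerate every monotone path (start cell + moves), score it,
  # and collect the match sets of all maximum-score paths
  enumerate_best <- function(is_match, scores) {
    n <- nrow(is_match); m <- ncol(is_match)
    best <- list(score = 0, sets = list(list()))
    note <- function(score, matches) {
      if (score > best$score) best <<- list(score = score, sets = list(matches))
      else if (score == best$score && score > 0)
        best$sets[[length(best$sets) + 1L]] <<- matches
    }
    walk <- function(i, j, score, matches) {
      note(score, matches)
      if (i < n && j < m) {
        sub <- if (is_match[i + 1, j + 1]) scores[["match"]] else scores[["mismatch"]]
        walk(i + 1, j + 1, score + sub,
             if (is_match[i + 1, j + 1]) c(matches, list(c(i + 1, j + 1))) else matches)
      }
      if (i < n) walk(i + 1, j, score + scores[["gap"]], matches)
      if (j < m) walk(i, j + 1, score + scores[["gap"]], matches)
    }
    for (i0 in seq_len(n)) {
      for (j0 in seq_len(m)) {
        sub <- if (is_match[i0, j0]) scores[["match"]] else scores[["mismatch"]]
        walk(i0, j0, sub,
             if (is_match[i0, j0]) list(c(i0, j0)) else list())
      }
    }
    best
  }
  scores <- c(match = 1, mismatch = -1, gap = -1)
  sim <- similarity_config(threshold = 0.8)
  for (seed in c(2, 9, 14)) {
    pair <- synthetic_pair(seed, n = 4)
    ref <- pair$ref; aln <- pair$aligned
    o_r <- order(ref$rt1 + ref$rt2); o_a <- order(aln$rt1 + aln$rt2)
    is_match <- matrix(FALSE, nrow(ref), nrow(aln))
    for (i in seq_len(nrow(ref)))
      for (j in seq_len(nrow(aln)))
        is_match[i, j] <- max(0, spectral_similarity(
          ref$spectrum[[o_r[i]]], aln$spectrum[[o_a[j]]], sim)) >= sim$threshold
    oracle <- enumerate_best(is_match, scores)
    got <- smith_waterman_anchors(ref, aln, sim, scores)
    gp <- anchor_pairs(got)
    got_set <- lapply(seq_len(nrow(gp)), function(k)
      c(match(gp$ref_index[k], o_r), match(gp$aln_index[k], o_a)))
    got_set <- got_set[order(vapply(got_set, `[`, numeric(1), 1))]
    canon <- function(set) paste(vapply(set, paste, character(1),
                                        collapse = ","), collapse = ";")
    oracle_canons <- vapply(oracle$sets, function(s)
      canon(s[order(vapply(s, `[`, numeric(1), 1))]), character(1))
    if (oracle$score == 0) {
      expect_equal(nrow(gp), 0, info = paste("seed", seed))
    } else {
      expect_true(canon(got_set) %in% oracle_canons,
                  info = paste("seed", seed))
      expect_equal(max(anchor_pairs(got)$score), oracle$score,
                   info = paste("seed", seed))
    }
  }
})

test_that("anchor sets are one-to-one and gating is monotone in the threshold", {
  pair <- synthetic_pair(seed = 13, n = 25)
  for (alg in alignment_algorithms()) {
    counts <- numeric(0)
    for (thr in c(0.3, 0.8, 0.9)) {
      cfg <- default_config(alg)
      if (alg %in% c("bipace2d", "msort"))
        cfg$similarity$threshold <- thr
      else if (alg == "pam")
        cfg$similarity$threshold <- thr
      else if (alg == "disco")
        cfg$similarity$threshold <- thr
      else if (alg == "tntda")
        cfg$pam$similarity$threshold <- thr
      else cfg$similarity$threshold <- thr
      a <- find_anchors(pair$ref, pair$aligned, alg, cfg)
      p <- anchor_pairs(a)
      expect_false(any(duplicated(p$ref_index)), info = alg)
      expect_false(any(duplicated(p$aln_index)), info = alg)
      expect_true(all(p$similarity >= thr), info = alg)
      counts <- c(counts, n_anchors(a))
    }
    expect_true(all(diff(counts) <= 0), info = alg)
  }
})
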