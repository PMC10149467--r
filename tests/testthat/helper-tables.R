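# Small deterministic fixtures built in code.

# A tiny table with hand-written, well-separated spectra.
tiny_table <- function(sample_id = "tiny") {
  spectra <- list(
    c(`41` = 100, `57` = 999, `71` = 300),
    c(`43` = 999, `85` = 450, `99` = 120),
    c(`77` = 999, `105` = 600, `152` = 200),
    c(`59` = 999, `88` = 340, `131` = 80),
    c(`91` = 999, `119` = 500, `134` = 250))
  peak_table(rt1 = c(100, 300, 600, 900, 1200),
             rt2 = c(1.0, 1.8, 2.5, 3.2, 4.0),
             spectra, label = sprintf("P%d", 1:5), sample_id = sample_id)
}

# Copy of a table under a new sample id (identity-alignment fixture).
copy_table <- function(t, sample_id = "copy") {
  peak_table(t$rt1, t$rt2, t$spectrum, label = t$label,
             sample_id = sample_id)
}

# Shift a table's retention times by constant offsets.
shift_table <- function(t, d1 = 0, d2 = 0, sample_id = "shifted") {
  peak_table(t$rt1 + d1, t$rt2 + d2, t$spectrum, label = t$label,
             sample_id = sample_id)
}

# Affine-warp a table (no noise): rt' = a * rt + b per dimension.
affine_table <- function(t, a1 = 1, b1 = 0, a2 = 1, b2 = 0,
                         sample_id = "warped") {
  peak_table(a1 * t$rt1 + b1, a2 * t$rt2 + b2, t$spectrum, label = t$label,
             sample_id = sample_id)
}

# A moderately distorted synthetic pair for algorithm benchmarks.
synthetic_pair <- function(seed, n = 30, cfg = NULL) {
  set.seed(seed)
  lib <- make_spectrum_library(n)
  ref <- make_reference_table(lib, n)
  if (is.null(cfg))
    cfg <- distortion_config(a1 = 1.01, b1 = 4, a2 = 0.99, b2 = 0.05,
                             jitter1 = 0.3, jitter2 = 0.01)
  d <- distort_table(ref, cfg)
  list(ref = ref, aligned = d$table, truth = d$truth)
}

# Anchor recall against a ground-truth correspondence.
anchor_recall <- function(anchors, correspondence) {
  cc <- confusion_counts(anchors, correspondence)
  precision_recall_f1(cc)$recall
}
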