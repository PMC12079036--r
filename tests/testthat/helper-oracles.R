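# Independent oracles, coded from first principles and kept separate from
# the package's computation paths.

# Mann-Whitney pairwise-concordance AUC: share of (positive, negative)
# pairs ranked correctly, ties counted half.
mw_auc <- function(pos, neg) {
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Fleiss' kappa via rater-pair enumeration: per-item agreement as the share
# of agreeing unordered rater pairs, chance agreement from marginal shares.
fleiss_pairwise <- function(m) {
  r <- ncol(m)
  pairs <- utils::combn(r, 2)
  p_i <- apply(m, 1, function(row) {
    mean(row[pairs[1, ]] == row[pairs[2, ]])
  })
  p1 <- mean(m)
  p_e <- p1^2 + (1 - p1)^2
  (mean(p_i) - p_e) / (1 - p_e)
}

# Cohen's kappa for a 2x2 table via the determinant identity.
cohen_direct <- function(tp, fp, fn, tn) {
  2 * (tp * tn - fp * fn) /
    ((tp + fp) * (fp + tn) + (tp + fn) * (fn + tn))
}

# Scores that are tie-free at the 0.001 grid resolution: every score in a
# distinct open grid cell, none coinciding with a grid point, so the grid
# ROC resolves every pair and the trapezoidal AUC must equal the
# Mann-Whitney concordance exactly.
tie_free_scores <- function(n) {
  bins <- sample(0:999, n)
  (bins + runif(n, 0.05, 0.95)) / 1000
}

# Small frames fixture: two participants, mixed smile/neutral segments.
make_frames <- function(n_segments = 6, n_frames = 10, seed = 42) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_segments), function(i) {
      tibble::tibble(
        segment_id = sprintf("s%02d", i),
        participant_id = sprintf("P%d", (i %% 2) + 1),
        frame_index = seq_len(n_frames) - 1L,
        mouthSmile_L = round(runif(n_frames), 6),
        mouthSmile_R = round(runif(n_frames), 6),
        cheekSquint_L = round(runif(n_frames), 6),
        cheekSquint_R = round(runif(n_frames), 6)
      )
    })
    dplyr::bind_rows(rows)
  })
}
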