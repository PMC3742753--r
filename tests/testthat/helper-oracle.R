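# Independent reference scorer: a literal, branch-by-branch transcription of
# the published scoring routine, kept deliberately separate from the
# package's (vectorized) implementation so the two can be cross-checked.

score_oracle <- function(A1, A2, B1, B2, len_A1, len_A2, len_B1, len_B2,
                         chimeric_score,
                         chimeric_cutoff = 3.0, max_break_score = 1.5,
                         adjusted_to_max = 6.0) {
  if (len_B1 == 0) {
    fusion_score <- 0.1
  } else if ((A1 > A2 && B2 < B1 && len_A2 <= 1 && len_B2 <= 1) ||
             (A1 < A2 && B2 > B1 && len_A2 <= 1 && len_B2 <= 1)) {
    fusion_score <- 0.1
  } else if (A1 < A2 && B2 > B1 && len_A1 <= 1 && len_B1 <= 1) {
    fusion_score <- 0.1
  } else if ((A1 > A2 && B1 < B2 && len_B2 <= 1) ||
             (A1 < A2 && B1 > B2 && len_A2 <= 1)) {
    fusion_score <- 0.1
  } else {
    if (chimeric_score == adjusted_to_max) {
      fusion_score <- chimeric_score
    } else {
      fusion_score <- min(chimeric_score, chimeric_cutoff)
      break_score_A <- min(abs(A2 - A1), max_break_score)
      break_score_B <- min(abs(B2 - B1), max_break_score)
      fusion_score <- fusion_score + break_score_A + break_score_B
    }
  }
  fusion_score
}

# Random scorer inputs spanning all branches: mixed segment lengths
# (including empty B1 and single-exon segments), tied and untied means,
# chimeric values below/above the cutoff and exactly at the sentinel.
random_score_inputs <- function(n, seed) {
  set.seed(seed)
  means <- matrix(round(stats::runif(4L * n, 0, 4), 2), ncol = 4L)
  tie <- stats::runif(n) < 0.25   # force frequent mean ties (strict branches)
  means[tie, 3L] <- means[tie, 4L]
  tie_a <- stats::runif(n) < 0.25
  means[tie_a, 1L] <- means[tie_a, 2L]
  lens <- matrix(sample(0:6, 4L * n, replace = TRUE), ncol = 4L)
  lens[, 1L] <- pmax(lens[, 1L], 1L)  # len_a1 >= 1 (i >= 1)
  lens[, 4L] <- pmax(lens[, 4L], 1L)  # len_b2 >= 1 (j <= n_B)
  cv <- round(stats::runif(n, 0, 8), 2)
  cv[stats::runif(n) < 0.1] <- 6.0    # enhancement sentinel
  cv[stats::runif(n) < 0.1] <- 0.0
  data.frame(a1 = means[, 1L], a2 = means[, 2L],
             b1 = means[, 3L], b2 = means[, 4L],
             la1 = lens[, 1L], la2 = lens[, 2L],
             lb1 = lens[, 3L], lb2 = lens[, 4L], cv = cv)
}
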