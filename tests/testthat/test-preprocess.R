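test_that("normalization maps intensities onto the score scale", {
  # all intensities equal -> all scores 0 (median-centering)
  it <- intensity_table(paste0("p", 1:9), rep(500, 9))
  expect_equal(unname(normalize_scores(it)), rep(0, 9))

  # one probe 256x the median probe, negligible pseudocount -> score ~ 8
  it2 <- intensity_table(paste0("p", 1:9), c(rep(1e6, 8), 256e6))
  s <- normalize_scores(it2, normalization_config(pseudocount = 1e-6))
  expect_equal(unname(s[9]), 8, tolerance = 1e-6)

  # method = none is the identity
  s3 <- normalize_scores(it2, normalization_config(method = "none"))
  expect_equal(unname(s3), it2$intensity)

  # floor: below-median probes score 0, not negative
  it4 <- intensity_table(paste0("p", 1:5), c(1, 10, 100, 1000, 10000))
  expect_true(all(normalize_scores(it4) >= 0))

  expect_error(normalize_scores(data.frame(probe_id = character(0),
                                           intensity = numeric(0))),
               "empty")
})

test_that("half-binder filter zeroes striped rows via both printed triggers", {
  p <- scoring_params()

  # 25%-at-70% trigger: 2/8 probes >= 0.7 * 5.0 = 3.5
  hm <- chimeric_heatmap(matrix(c(5, 4, rep(1, 6)), nrow = 1))
  out <- reduce_half_binders(hm, p)
  expect_equal(unname(out$matrix[1, ]), rep(0, 8))
  expect_equal(out$row_tags, "zeroed")

  # count trigger: exactly three probes >= 3.0 in a 40-cell row
  hm2 <- chimeric_heatmap(matrix(c(3.2, 3.1, 3.0, rep(0.1, 37)), nrow = 1))
  out2 <- reduce_half_binders(hm2, p)
  expect_equal(unname(out2$matrix[1, ]), rep(0, 40))
  expect_equal(out2$row_tags, "zeroed")

  # neither trigger: one strong probe survives untouched and untagged
  hm3 <- chimeric_heatmap(matrix(c(4, rep(0.2, 7)), nrow = 1))
  out3 <- reduce_half_binders(hm3, p)
  expect_equal(out3$matrix, hm3$matrix)
  expect_equal(out3$row_tags, "none")

  # all-zero heatmap -> unchanged, no tags
  hm4 <- chimeric_heatmap(matrix(0, 3, 4))
  out4 <- reduce_half_binders(hm4, p)
  expect_equal(out4$matrix, hm4$matrix)
  expect_true(all(out4$row_tags == "none") && all(out4$col_tags == "none"))
})

test_that("moderate striping gets the weak tag with values unchanged", {
  p <- scoring_params()
  v <- c(4.0, 2.5, 2.2, rep(0.1, 5))
  # zeroing needs 2 probes >= 2.8 (has 1) or 3 probes >= 3.0 (has 1);
  # weak rule: 3/8 >= 25% of probes >= 0.5 * 4.0 = 2.0
  hm <- reduce_half_binders(chimeric_heatmap(matrix(v, nrow = 1)), p)
  expect_equal(unname(hm$matrix[1, ]), v)
  expect_equal(hm$row_tags, "weak_half_binding")
})

test_that("filter decisions are simultaneous, monotone, and idempotent", {
  p <- scoring_params()
  set.seed(11)
  for (rep in 1:25) {
    m <- matrix(round(stats::rexp(12 * 9, 1), 2), 12, 9)
    m[sample(12, 2), ] <- m[sample(12, 2), ] + 3   # some striping
    hm <- chimeric_heatmap(m)
    once <- reduce_half_binders(hm, p)
    # never increases any entry
    expect_true(all(once$matrix <= m))
    # zeroed rows/cols are all zero
    expect_true(all(once$matrix[once$row_tags == "zeroed", ] == 0))
    expect_true(all(once$matrix[, once$col_tags == "zeroed"] == 0))
    # idempotent
    expect_identical(reduce_half_binders(once, p), once)
    # order-independent: permuting rows/cols commutes with the filter
    pr <- sample(12); pc <- sample(9)
    perm <- reduce_half_binders(chimeric_heatmap(m[pr, pc]), p)
    expect_equal(perm$matrix, once$matrix[pr, pc])
    expect_equal(perm$row_tags, once$row_tags[pr])
    expect_equal(perm$col_tags, once$col_tags[pc])
  }
})

test_that("a lone outlier probe is enhanced to the printed values", {
  p <- scoring_params()

  # gap 0.9 >= 0.8, no weak tag -> cell becomes 6.0
  m <- matrix(0.2, 5, 5); m[2, 3] <- 2.0; m[4, 1] <- 1.1
  hm <- enhance_single_strong_probe(reduce_half_binders(chimeric_heatmap(m), p), p)
  expect_identical(hm$matrix[2, 3], 6.0)
  expect_equal(sum(hm$matrix != reduce_half_binders(chimeric_heatmap(m), p)$matrix), 1L)

  # max's row tagged weak -> cell becomes 3.0 instead
  v <- c(2.7, 1.8, 1.7, 0.3, 0.25, 0.2, 0.15, 0.1)
  hm2 <- reduce_half_binders(chimeric_heatmap(matrix(v, nrow = 1)), p)
  expect_equal(hm2$row_tags, "weak_half_binding")
  out2 <- enhance_single_strong_probe(hm2, p)
  expect_identical(out2$matrix[1, 1], 3.0)

  # gap 0.7 < 0.8 -> unchanged
  m3 <- matrix(0.2, 4, 4); m3[1, 1] <- 2.0; m3[4, 4] <- 1.3
  hm3 <- reduce_half_binders(chimeric_heatmap(m3), p)
  expect_equal(enhance_single_strong_probe(hm3, p)$matrix, hm3$matrix)

  # tied maxima: gap is zero, nothing modified
  m4 <- matrix(0.1, 3, 3); m4[1, 2] <- 2.5; m4[3, 1] <- 2.5
  hm4 <- reduce_half_binders(chimeric_heatmap(m4), p)
  expect_equal(enhance_single_strong_probe(hm4, p)$matrix, hm4$matrix)

  # < 2 cells -> returned unchanged
  hm5 <- chimeric_heatmap(matrix(5, 1, 1))
  expect_equal(enhance_single_strong_probe(hm5, p)$matrix, hm5$matrix)
})

test_that("enhancement modifies at most the argmax cell", {
  p <- scoring_params()
  set.seed(23)
  for (rep in 1:50) {
    m <- matrix(round(stats::rexp(8 * 6, 1), 2), 8, 6)
    hm <- reduce_half_binders(chimeric_heatmap(m), p)
    out <- enhance_single_strong_probe(hm, p)
    changed <- which(out$matrix != hm$matrix)
    expect_lte(length(changed), 1L)
    if (length(changed) == 1L) {
      expect_equal(changed, which.max(hm$matrix))
      expect_true(out$matrix[changed] %in%
                    c(p$adjusted_to_max, p$weak_adjust_value))
    }
  }
})
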