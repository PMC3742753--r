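test_that("segment means split profiles at the breakpoint", {
  s <- segment_means(c(4, 4, 0, 0), c(0, 3, 3), i = 2, j = 2)
  expect_equal(s[c("a1_mean", "a2_mean", "b1_mean", "b2_mean")],
               list(a1_mean = 4, a2_mean = 0, b1_mean = 0, b2_mean = 3))
  expect_equal(s[c("len_a1", "len_a2", "len_b1", "len_b2")],
               list(len_a1 = 2L, len_a2 = 2L, len_b1 = 1L, len_b2 = 2L))

  # j = 1 is legal: empty B1 with mean 0
  s2 <- segment_means(c(1, 2), c(5, 6, 7), i = 1, j = 1)
  expect_equal(s2$len_b1, 0L)
  expect_equal(s2$b1_mean, 0)

  expect_error(segment_means(c(1, 2), c(1, 2), i = 3, j = 1), "out of range")
})

test_that("scorer reproduces the published branch examples", {
  p <- scoring_params()
  sb <- function(...) score_breakpoint(..., params = p)

  # empty B1 -> degenerate 0.1
  expect_equal(sb(5, 0, 0, 5, 2, 2, 0, 4, 4)$fusion_score, 0.1)

  # enhanced sentinel: fusion score is the chimeric value alone
  expect_equal(sb(3, 1, 0.5, 3, 5, 5, 2, 6, 6.0)$fusion_score, 6.0)

  # equal means, chimeric 0 -> all strict comparisons false -> 0.0
  expect_equal(sb(2, 2, 2, 2, 3, 3, 3, 3, 0)$fusion_score, 0)

  # full additive branch: 2.0 + min(2.0, 1.5) + min(2.5, 1.5)
  r <- sb(3, 1, 0.5, 3, 5, 5, 2, 6, 2.0)
  expect_equal(r$fusion_score, 5.0)
  expect_equal(r$break_score_a, 1.5)
  expect_equal(r$break_score_b, 1.5)

  # chimeric above the cutoff but not the sentinel is capped at 3.0
  expect_equal(sb(2, 2, 2, 2, 3, 3, 3, 3, 10)$fusion_score, 3.0)

  # single-exon guards (branches 2-4)
  expect_equal(sb(5, 1, 5, 1, 4, 1, 4, 1, 2)$fusion_score, 0.1)  # branch 2
  expect_equal(sb(1, 5, 1, 5, 1, 4, 1, 4, 2)$fusion_score, 0.1)  # branch 3
  expect_equal(sb(5, 1, 1, 5, 4, 2, 5, 1, 2)$fusion_score, 0.1)  # branch 4a
  expect_equal(sb(1, 5, 5, 1, 4, 1, 4, 2, 2)$fusion_score, 0.1)  # branch 4b
})

test_that("production scorer agrees exactly with the literal oracle", {
  p <- scoring_params()
  inp <- random_score_inputs(20000L, seed = 101)
  got <- mapply(function(a1, a2, b1, b2, la1, la2, lb1, lb2, cv) {
    score_breakpoint(a1, a2, b1, b2, la1, la2, lb1, lb2, cv,
                     params = p)$fusion_score
  }, inp$a1, inp$a2, inp$b1, inp$b2, inp$la1, inp$la2, inp$lb1, inp$lb2,
     inp$cv)
  want <- mapply(score_oracle,
                 inp$a1, inp$a2, inp$b1, inp$b2,
                 inp$la1, inp$la2, inp$lb1, inp$lb2, inp$cv)
  expect_identical(got, want)
})

test_that("vectorized grid scorer matches per-cell scalar calls", {
  p <- scoring_params()
  set.seed(5)
  for (rep in 1:10) {
    n_a <- sample(2:9, 1); n_b <- sample(2:9, 1)
    m <- matrix(round(stats::rexp(n_a * n_b, 1), 2), n_a, n_b)
    m[sample(length(m), 2)] <- 6.0   # sentinel cells
    pa <- round(stats::runif(n_a, 0, 4), 2)
    pb <- round(stats::runif(n_b, 0, 4), 2)
    g <- fusionchip:::score_grid(m, pa, pb, p)
    for (i in seq_len(n_a)) {
      for (j in seq_len(n_b)) {
        s <- segment_means(pa, pb, i, j)
        r <- score_breakpoint(s$a1_mean, s$a2_mean, s$b1_mean, s$b2_mean,
                              s$len_a1, s$len_a2, s$len_b1, s$len_b2,
                              m[i, j], p)
        expect_equal(g$score[i, j], r$fusion_score)
      }
    }
  }
})

test_that("fusion score is bounded and monotone in the chimeric value", {
  p <- scoring_params()
  inp <- random_score_inputs(5000L, seed = 202)
  for (k in seq_len(nrow(inp))) {
    s <- score_breakpoint(inp$a1[k], inp$a2[k], inp$b1[k], inp$b2[k],
                          inp$la1[k], inp$la2[k], inp$lb1[k], inp$lb2[k],
                          inp$cv[k], p)$fusion_score
    expect_gte(s, 0)
    expect_lte(s, p$adjusted_to_max)
  }
  # below the cutoff, non-decreasing in chimeric value (profiles fixed)
  cvs <- seq(0, 3, by = 0.25)
  scores <- vapply(cvs, function(cv) {
    score_breakpoint(3, 1, 0.5, 2, 4, 4, 3, 5, cv, p)$fusion_score
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("best breakpoint selection and tie-breaks are deterministic", {
  p <- scoring_params()

  # 1x1 heatmap: only breakpoint has empty B1 -> degenerate
  hm <- chimeric_heatmap(matrix(2, 1, 1))
  expect_equal(score_fusion(hm, 1, 1, p)$fusion_score, 0.1)

  # single enhanced cell at (13, 3) wins at the sentinel
  m <- matrix(0, 13, 10); m[13, 3] <- 6.0
  r <- score_fusion(chimeric_heatmap(m), rep(2, 13), rep(1, 10), p)
  expect_equal(r$fusion_score, 6.0)
  expect_equal(c(r$exon_a, r$exon_b), c(13L, 3L))

  # constructed fixture: chimeric 2.5 + clean shifts >= 1.5 on both sides
  m2 <- matrix(0, 4, 4); m2[2, 3] <- 2.5
  pa <- c(3, 3, 1, 1); pb <- c(0.5, 0.5, 2.5, 2.5)
  r2 <- score_fusion(chimeric_heatmap(m2), pa, pb, p)
  expect_equal(r2$fusion_score, 2.5 + 1.5 + 1.5)
  expect_equal(c(r2$exon_a, r2$exon_b), c(2L, 3L))

  # zero profiles: every j >= 2 cell scores its capped chimeric value;
  # equal scores with different chimeric values -> larger chimeric wins
  m3 <- matrix(0, 2, 3); m3[1, 2] <- 3.0; m3[2, 3] <- 4.0
  r3 <- score_fusion(chimeric_heatmap(m3), rep(0, 2), rep(0, 3), p)
  expect_equal(r3$fusion_score, 3.0)
  expect_equal(c(r3$exon_a, r3$exon_b), c(2L, 3L))  # chimeric 4.0 beats 3.0

  # full tie (same score, same chimeric): smallest (i, j) lexicographically
  m4 <- matrix(1, 3, 3)
  r4 <- score_fusion(chimeric_heatmap(m4), rep(0, 3), rep(0, 3), p)
  expect_equal(c(r4$exon_a, r4$exon_b), c(1L, 2L))
})

test_that("ranking is a gap-free permutation with documented tie-breaks", {
  mk <- function(id, score, cv) {
    structure(list(fusion_id = id, fusion_score = score, exon_a = 1L,
                   exon_b = 2L, chimeric_value = cv, break_score_a = 0,
                   break_score_b = 0, variant_a = "v1", variant_b = "v1",
                   tags = ""), class = "fusion_score_result")
  }
  df <- rank_sample(list(mk("Y", 3.2, 1), mk("X", 6.0, 6), mk("Z", 0.1, 0)))
  expect_equal(df$rank, 1:3)
  expect_equal(df$fusion_id, c("X", "Y", "Z"))

  # identical scores and chimeric values -> lexicographic, stable
  df2 <- rank_sample(list(mk("B", 2, 1), mk("A", 2, 1), mk("C", 2, 2)))
  expect_equal(df2$fusion_id, c("C", "A", "B"))
  df3 <- rank_sample(list(mk("A", 2, 1), mk("C", 2, 2), mk("B", 2, 1)))
  expect_equal(df2$fusion_id, df3$fusion_id)

  expect_equal(nrow(rank_sample(list())), 0L)
})

test_that("every empty-B1 breakpoint scores exactly the degenerate constant", {
  p <- scoring_params()
  inp <- random_score_inputs(2000L, seed = 303)
  inp$lb1 <- 0L
  for (k in seq_len(nrow(inp))) {
    expect_identical(
      score_breakpoint(inp$a1[k], inp$a2[k], inp$b1[k], inp$b2[k],
                       inp$la1[k], inp$la2[k], 0L, inp$lb2[k],
                       inp$cv[k], p)$fusion_score,
      0.1)
  }
})
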