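# Breakpoint scoring. A candidate breakpoint (i, j) splits the 5' partner A
# into A1 = exons 1..i (retained) and A2 = exons i+1..nA, and the 3' partner
# B into B1 = exons 1..(j-1) and B2 = exons j..nB (retained); the chimeric
# probe at heatmap cell (i, j) interrogates the A1+B2 junction. The fusion
# score combines the capped chimeric evidence with the capped expression
# discontinuity |A2 - A1| and |B2 - B1| of the two partners, after a set of
# guard branches that score implausible segmentations at the degenerate 0.1.

#' Segment means around a candidate breakpoint
#'
#' @param profile_a,profile_b Intragenic profiles (objects from
#'   \code{\link{assemble}} or plain numeric vectors of per-exon scores).
#' @param i Last retained exon of the 5' partner (1..n_A).
#' @param j First retained exon of the 3' partner (1..n_B); \code{j = 1}
#'   yields an empty B1 segment with mean 0.
#' @return A list with a1_mean, a2_mean, b1_mean, b2_mean and the four
#'   segment lengths. Empty segments have mean 0.
#' @export
segment_means <- function(profile_a, profile_b, i, j) {
  a <- if (inherits(profile_a, "intragenic_profile")) profile_a$exon_scores
       else as.numeric(profile_a)
  b <- if (inherits(profile_b, "intragenic_profile")) profile_b$exon_scores
       else as.numeric(profile_b)
  n_a <- length(a); n_b <- length(b)
  if (i < 1L || i > n_a || j < 1L || j > n_b) {
    stop("breakpoint index out of range: (", i, ", ", j, ")", call. = FALSE)
  }
  seg_mean <- function(x) if (length(x) == 0L) 0 else mean(x)
  list(a1_mean = seg_mean(a[seq_len(i)]),
       a2_mean = seg_mean(a[seq_len(n_a) > i]),
       b1_mean = seg_mean(b[seq_len(j - 1L)]),
       b2_mean = seg_mean(b[seq_len(n_b) >= j]),
       len_a1 = i, len_a2 = n_a - i,
       len_b1 = j - 1L, len_b2 = n_b - j + 1L)
}

#' Score one candidate breakpoint
#'
#' The branch structure, in order: (1) an empty B1 segment is degenerate
#' (0.1); (2)-(4) segmentations whose expression profile contradicts a
#' detectable fusion given single-exon segments are degenerate (0.1);
#' (5) otherwise, a chimeric value equal (exactly) to \code{adjusted_to_max}
#' — the sentinel assigned by the enhancement step — is returned as the
#' fusion score on its own, and any other chimeric value is capped at
#' \code{chimeric_cutoff} and added to the two break scores
#' \code{min(|a2 - a1|, max_break_score)} and
#' \code{min(|b2 - b1|, max_break_score)}. The result never exceeds
#' \code{adjusted_to_max} (6.0).
#'
#' @param a1_mean,a2_mean,b1_mean,b2_mean Segment means (see
#'   \code{\link{segment_means}}).
#' @param len_a1,len_a2,len_b1,len_b2 Segment lengths in exons.
#' @param chimeric_value The post-filter, post-enhancement heatmap cell
#'   at (i, j).
#' @param params A \code{\link{scoring_params}}.
#' @return A list with fusion_score, break_score_a, break_score_b (the break
#'   scores are NA on degenerate/enhanced branches where they are not used).
#' @examples
#' p <- scoring_params()
#' score_breakpoint(3, 1, 0.5, 3, 5, 5, 2, 6, chimeric_value = 2, params = p)
#' @export
score_breakpoint <- function(a1_mean, a2_mean, b1_mean, b2_mean,
                             len_a1, len_a2, len_b1, len_b2,
                             chimeric_value, params = scoring_params()) {
  a1 <- a1_mean; a2 <- a2_mean; b1 <- b1_mean; b2 <- b2_mean
  deg <- list(fusion_score = params$degenerate_score,
              break_score_a = NA_real_, break_score_b = NA_real_)
  if (len_b1 == 0L) return(deg)
  if (((a1 > a2 && b2 < b1) || (a1 < a2 && b2 > b1)) &&
      len_a2 <= 1L && len_b2 <= 1L) return(deg)
  if (a1 < a2 && b2 > b1 && len_a1 <= 1L && len_b1 <= 1L) return(deg)
  if ((a1 > a2 && b1 < b2 && len_b2 <= 1L) ||
      (a1 < a2 && b1 > b2 && len_a2 <= 1L)) return(deg)
  if (chimeric_value == params$adjusted_to_max) {
    return(list(fusion_score = chimeric_value,
                break_score_a = NA_real_, break_score_b = NA_real_))
  }
  bs_a <- min(abs(a2 - a1), params$max_break_score)
  bs_b <- min(abs(b2 - b1), params$max_break_score)
  list(fusion_score = min(chimeric_value, params$chimeric_cutoff) +
         bs_a + bs_b,
       break_score_a = bs_a, break_score_b = bs_b)
}

# Vectorized scorer over the full (i, j) grid of one heatmap. Matrices of
# segment means are built from prefix sums; branch logic mirrors
# score_breakpoint element-wise, first matching branch wins.
score_grid <- function(mat, prof_a, prof_b, params) {
  n_a <- nrow(mat); n_b <- ncol(mat)
  cs_a <- cumsum(prof_a); cs_b <- cumsum(prof_b)
  i <- seq_len(n_a); j <- seq_len(n_b)
  a1 <- cs_a[i] / i
  a2 <- ifelse(i < n_a, (cs_a[n_a] - cs_a[i]) / (n_a - i), 0)
  b1 <- c(0, cs_b)[j] / pmax(j - 1L, 1L)   # empty B1 (j = 1) has mean 0
  b2 <- (cs_b[n_b] - c(0, cs_b)[j]) / (n_b - j + 1L)
  len_a1 <- i; len_a2 <- n_a - i; len_b1 <- j - 1L; len_b2 <- n_b - j + 1L

  A1 <- matrix(a1, n_a, n_b); A2 <- matrix(a2, n_a, n_b)
  B1 <- matrix(b1, n_a, n_b, byrow = TRUE)
  B2 <- matrix(b2, n_a, n_b, byrow = TRUE)
  LA1 <- matrix(len_a1, n_a, n_b); LA2 <- matrix(len_a2, n_a, n_b)
  LB1 <- matrix(len_b1, n_a, n_b, byrow = TRUE)
  LB2 <- matrix(len_b2, n_a, n_b, byrow = TRUE)

  deg1 <- LB1 == 0L
  deg2 <- ((A1 > A2 & B2 < B1) | (A1 < A2 & B2 > B1)) & LA2 <= 1L & LB2 <= 1L
  deg3 <- A1 < A2 & B2 > B1 & LA1 <= 1L & LB1 <= 1L
  deg4 <- (A1 > A2 & B1 < B2 & LB2 <= 1L) | (A1 < A2 & B1 > B2 & LA2 <= 1L)
  degenerate <- deg1 | deg2 | deg3 | deg4
  sentinel <- mat == params$adjusted_to_max

  bs_a <- pmin(abs(A2 - A1), params$max_break_score)
  bs_b <- pmin(abs(B2 - B1), params$max_break_score)
  score <- pmin(mat, params$chimeric_cutoff) + bs_a + bs_b
  score[sentinel] <- mat[sentinel]
  bs_a[sentinel] <- NA_real_; bs_b[sentinel] <- NA_real_
  score[degenerate] <- params$degenerate_score
  bs_a[degenerate] <- NA_real_; bs_b[degenerate] <- NA_real_
  list(score = score, break_score_a = bs_a, break_score_b = bs_b)
}

#' Score a candidate fusion over all breakpoints
#'
#' Evaluates \code{\link{score_breakpoint}} at every cell (i, j) of the
#' (filtered, enhanced) heatmap and returns the best breakpoint. Ties on the
#' fusion score are broken by larger chimeric value, then by smaller (i, j)
#' lexicographically.
#'
#' @param hm A \code{chimeric_heatmap}, or a \code{fusion_assembly} (the
#'   maximum over its variant pairs is taken; \code{profile_a}/\code{b} are
#'   then ignored).
#' @param profile_a,profile_b Intragenic profiles of the 5' and 3' partner.
#' @param params A \code{\link{scoring_params}}.
#' @return A list of class \code{"fusion_score_result"}: fusion_id,
#'   fusion_score, and the best breakpoint's exon_a, exon_b, chimeric_value,
#'   break_score_a, break_score_b, variant_a, variant_b, tags.
#' @export
score_fusion <- function(hm, profile_a = NULL, profile_b = NULL,
                         params = scoring_params()) {
  if (inherits(hm, "fusion_assembly")) {
    results <- lapply(hm, function(el) {
      score_fusion(el$heatmap, el$profile_a, el$profile_b, params)
    })
    ord <- order(-vapply(results, `[[`, numeric(1), "fusion_score"),
                 -vapply(results, `[[`, numeric(1), "chimeric_value"))
    return(results[[ord[1L]]])
  }
  stopifnot(inherits(hm, "chimeric_heatmap"))
  pa <- if (inherits(profile_a, "intragenic_profile")) profile_a$exon_scores
        else as.numeric(profile_a)
  pb <- if (inherits(profile_b, "intragenic_profile")) profile_b$exon_scores
        else as.numeric(profile_b)
  stopifnot(length(pa) == nrow(hm$matrix), length(pb) == ncol(hm$matrix))
  g <- score_grid(hm$matrix, pa, pb, params)
  best <- which(g$score == max(g$score), arr.ind = TRUE)
  if (nrow(best) > 1L) {
    cv <- hm$matrix[best]
    best <- best[order(-cv, best[, 1L], best[, 2L]), , drop = FALSE]
  }
  i <- best[1L, 1L]; j <- best[1L, 2L]
  tags <- character(0)
  if (hm$row_tags[i] != "none") tags <- c(tags, paste0("row:", hm$row_tags[i]))
  if (hm$col_tags[j] != "none") tags <- c(tags, paste0("col:", hm$col_tags[j]))
  structure(list(fusion_id = hm$fusion_id,
                 fusion_score = g$score[i, j],
                 exon_a = as.integer(i), exon_b = as.integer(j),
                 chimeric_value = hm$matrix[i, j],
                 break_score_a = g$break_score_a[i, j],
                 break_score_b = g$break_score_b[i, j],
                 variant_a = hm$variant_a, variant_b = hm$variant_b,
                 tags = paste(tags, collapse = ";")),
            class = "fusion_score_result")
}

#' Rank per-sample fusion results
#'
#' Orders one result per panel candidate by descending fusion score, breaking
#' ties by the best breakpoint's chimeric value (descending) and then by
#' fusion_id (lexicographic), and assigns ranks 1..K without gaps.
#'
#' @param results A list of \code{fusion_score_result} objects (one per
#'   candidate).
#' @return A data.frame with columns rank, fusion_id, fusion_score, exon_a,
#'   exon_b, chimeric_value, break_score_a, break_score_b, variant_a,
#'   variant_b, tags.
#' @export
rank_sample <- function(results) {
  cols <- c("fusion_id", "fusion_score", "exon_a", "exon_b",
            "chimeric_value", "break_score_a", "break_score_b",
            "variant_a", "variant_b", "tags")
  if (length(results) == 0L) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols) + 1L), c("rank", cols)))
    return(df)
  }
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(r[cols], stringsAsFactors = FALSE)
  }))
  ord <- order(-df$fusion_score, -df$chimeric_value, df$fusion_id,
               method = "radix")
  df <- df[ord, , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}
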