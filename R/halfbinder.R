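# Half-binder striping: one arm of a chimeric probe binding abundant cDNA on
# its own lights up a whole heatmap row or column. Such stripes are removed
# before scoring; milder striping is tagged so the enhancement step caps the
# adjustment instead of boosting to the maximum.

halfbinder_row_decision <- function(v, params) {
  mx <- max(v)
  if (mx <= 0) return("none")   # a row with max 0 is never triggered
  strong_n <- sum(v >= params$halfbinder_level_strong * mx)
  over_cut <- sum(v >= params$chimeric_cutoff)
  # the qualifying count must be >= 2: the row/column maximum is always >=
  # 70% of itself, and a lone strong probe is the true-positive signature
  # the enhancement step exists to protect, not a stripe
  if ((strong_n >= 2L &&
       strong_n / length(v) >= params$halfbinder_fraction) ||
      over_cut >= params$halfbinder_count_trigger) {
    return("zeroed")
  }
  weak_n <- sum(v >= params$halfbinder_level_weak * mx)
  if (weak_n >= 2L && weak_n / length(v) >= params$halfbinder_fraction) {
    return("weak_half_binding")
  }
  "none"
}

#' Remove half-binder striping from a chimeric heatmap
#'
#' For every row and column of the input matrix: if 25% or more of its probes
#' score at or above 70% of its maximum, or three or more probes score at or
#' above the chimeric cutoff (3.0), all values in that row/column are set
#' to 0 and it is tagged \code{"zeroed"}. Rows/columns left unfiltered where
#' 25% or more of the probes score at or above 50% of the maximum are tagged
#' \code{"weak_half_binding"} (values unchanged). All decisions are taken on
#' the input matrix simultaneously, then applied at once, so the result does
#' not depend on any processing order; the operation is idempotent.
#'
#' @param hm A \code{chimeric_heatmap} (from \code{\link{assemble}}).
#' @param params A \code{\link{scoring_params}}.
#' @return The heatmap with stripes zeroed and row/column tags set.
#' @export
reduce_half_binders <- function(hm, params = scoring_params()) {
  stopifnot(inherits(hm, "chimeric_heatmap"),
            inherits(params, "scoring_params"))
  # decisions are defined on the assembled matrix; a heatmap that has been
  # filtered once is passed through untouched, so the filter is idempotent
  if (isTRUE(hm$filtered)) return(hm)
  m <- hm$matrix
  row_tags <- vapply(seq_len(nrow(m)),
                     function(i) halfbinder_row_decision(m[i, ], params),
                     character(1))
  col_tags <- vapply(seq_len(ncol(m)),
                     function(j) halfbinder_row_decision(m[, j], params),
                     character(1))
  m[row_tags == "zeroed", ] <- 0
  m[, col_tags == "zeroed"] <- 0
  hm$matrix <- m
  hm$row_tags <- row_tags
  hm$col_tags <- col_tags
  hm$filtered <- TRUE
  hm
}
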