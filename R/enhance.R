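#' Enhance a single strong chimeric probe
#'
#' True fusions often show one chimeric probe markedly warmer than every
#' other cell of its heatmap; such a lone outlier would otherwise be
#' outweighed by the intragenic evidence. After half-binder removal, if the
#' maximum chimeric value exceeds the second largest value in the heatmap by
#' the enhancement margin (0.8) or more, the maximum cell is set to
#' \code{adjusted_to_max} (6.0) — or to \code{weak_adjust_value} (3.0) when
#' its row or column is tagged \code{"weak_half_binding"}. At most one cell
#' is modified, and only the argmax cell; if several cells share the maximum
#' the gap is zero and nothing happens. Heatmaps with fewer than two cells
#' are returned unchanged.
#'
#' @param hm A \code{chimeric_heatmap}, normally after
#'   \code{\link{reduce_half_binders}} (zeroed cells participate as 0 when
#'   the runner-up is determined).
#' @param params A \code{\link{scoring_params}}.
#' @return The (possibly) adjusted heatmap.
#' @export
enhance_single_strong_probe <- function(hm, params = scoring_params()) {
  stopifnot(inherits(hm, "chimeric_heatmap"),
            inherits(params, "scoring_params"))
  m <- hm$matrix
  if (length(m) < 2L) return(hm)
  mx <- max(m)
  if (mx <= 0) return(hm)
  idx <- which(m == mx)
  if (length(idx) > 1L) return(hm)   # tied maximum: gap is zero
  m2 <- max(m[-idx])
  if (mx - m2 < params$enhancement_margin) return(hm)
  ij <- arrayInd(idx, dim(m))
  weak <- hm$row_tags[ij[1L]] == "weak_half_binding" ||
    hm$col_tags[ij[2L]] == "weak_half_binding"
  # the sentinel must be assigned bit-exactly: the scorer later recognizes
  # an enhanced cell by exact equality with adjusted_to_max
  m[idx] <- if (weak) params$weak_adjust_value else params$adjusted_to_max
  hm$matrix <- m
  hm$enhanced <- TRUE
  hm
}
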