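#' Convert raw intensities to probe scores
#'
#' Default normalization: log2(intensity + pseudocount), centered at the
#' median over all probes of the array, with negative values floored at 0.
#' On this scale a score of x means "2^x-fold above the array median", which
#' is the scale on which the scorer's constants (cutoff 3.0, enhancement
#' margin 0.8, maximum 6.0) are meaningful; the floor keeps below-median
#' noise from producing negative chimeric scores.
#'
#' @param intensities An \code{\link{intensity_table}} (or data.frame with
#'   probe_id and intensity columns).
#' @param config A \code{\link{normalization_config}}.
#' @param reference Optional character vector of probe_ids over which the
#'   centering median is computed (default: all probes). The screening
#'   pipeline passes the intragenic probes here: exon probes track transcript
#'   abundance and form a stable reference, while junction probes are
#'   expected to be dark except at true breakpoints and are exactly the
#'   probes inflated by half-binder artifacts, so a median taken over them
#'   is not robust on artifact-heavy arrays.
#' @return A named numeric vector of probe scores (names = probe_id).
#' @examples
#' it <- intensity_table(c("p1", "p2", "p3"), c(100, 100, 100))
#' normalize_scores(it)  # all zero: median-centering
#' @export
normalize_scores <- function(intensities, config = normalization_config(),
                             reference = NULL) {
  stopifnot(inherits(config, "normalization_config"))
  x <- intensities$intensity
  if (is.null(x) || length(x) == 0L) stop("empty intensity table",
                                          call. = FALSE)
  if (any(x < 0)) stop("negative intensities", call. = FALSE)
  s <- switch(config$method,
    none = x,
    log2_only = log2(x + config$pseudocount),
    log2_median_center = {
      l <- log2(x + config$pseudocount)
      ref <- if (is.null(reference)) l else {
        keep <- intensities$probe_id %in% reference
        if (!any(keep)) l else l[keep]
      }
      pmax(l - stats::median(ref), 0)
    }
  )
  names(s) <- intensities$probe_id
  s
}
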