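#' Screen one sample against a fusion panel
#'
#' The full per-sample pipeline: normalize the array, then for every panel
#' candidate assemble the chimeric heatmap and intragenic profiles, remove
#' half-binder striping, enhance a lone strong chimeric probe, score every
#' breakpoint, and rank the candidates by fusion score.
#'
#' @param intensities An \code{\link{intensity_table}} covering all annotated
#'   probes.
#' @param annotations A \code{probe_annotation} table.
#' @param panel A \code{fusion_panel}.
#' @param params A \code{\link{scoring_params}}.
#' @param normalization A \code{\link{normalization_config}}.
#' @param halfbinder_filter,enhancement Set FALSE to ablate the half-binder
#'   filter or the single-strong-probe enhancement.
#' @param keep_heatmaps Keep the filtered per-candidate heatmaps in the
#'   returned object (for plotting); default TRUE.
#' @return An object of class \code{"fusion_screen"}: a list with
#'   \code{sample_id}, \code{results} (the ranked data.frame of
#'   \code{\link{rank_sample}}), \code{assemblies} (if kept), \code{params}.
#' @examples
#' panel <- load_panel(system.file("extdata", "toy_panel.tsv",
#'                                 package = "fusionchip"))
#' ann <- annotate_panel(panel)
#' sim <- simulate_sample(panel, ann, true_fusion = "TOY1",
#'                        true_breakpoint = c(3, 2),
#'                        config = simulation_config(seed = 7))
#' scr <- fusion_screen(sim$intensities, ann, panel)
#' scr$results[1, c("fusion_id", "fusion_score", "exon_a", "exon_b")]
#' @export
fusion_screen <- function(intensities, annotations, panel,
                          params = scoring_params(),
                          normalization = normalization_config(),
                          halfbinder_filter = TRUE,
                          enhancement = TRUE,
                          keep_heatmaps = TRUE) {
  stopifnot(inherits(params, "scoring_params"))
  # probes annotated but missing from the array are a hard error
  absent <- setdiff(unique(annotations$probe_id), intensities$probe_id)
  if (length(absent) > 0L) {
    stop("missing-probe error: ", length(absent),
         " annotated probe(s) without intensity: ",
         paste(utils::head(absent, 10L), collapse = ", "), call. = FALSE)
  }
  ig_ref <- unique(annotations$probe_id[annotations$probe_type ==
                                          "intragenic"])
  scores <- normalize_scores(intensities, normalization,
                             reference = if (length(ig_ref)) ig_ref)
  assemblies <- list()
  results <- vector("list", nrow(panel))
  for (r in seq_len(nrow(panel))) {
    fid <- panel$fusion_id[r]
    asm <- assemble(scores, annotations, fid)
    asm <- lapply(asm, function(el) {
      if (halfbinder_filter) {
        el$heatmap <- reduce_half_binders(el$heatmap, params)
      }
      if (enhancement) {
        el$heatmap <- enhance_single_strong_probe(el$heatmap, params)
      }
      el
    })
    class(asm) <- "fusion_assembly"
    attr(asm, "fusion_id") <- fid
    if (keep_heatmaps) assemblies[[fid]] <- asm
    results[[r]] <- score_fusion(asm, params = params)
  }
  structure(list(sample_id = attr(intensities, "sample_id"),
                 results = rank_sample(results),
                 assemblies = if (keep_heatmaps) assemblies else NULL,
                 params = params,
                 halfbinder_filter = halfbinder_filter,
                 enhancement = enhancement),
            class = "fusion_screen")
}

#' @export
print.fusion_screen <- function(x, n = 5L, ...) {
  cat(sprintf("Fusion screen of sample '%s': %d candidates\n",
              x$sample_id, nrow(x$results)))
  top <- utils::head(x$results, n)
  cat(sprintf("  %2d. %-22s score %-5.3g breakpoint %d-%d%s\n",
              top$rank, top$fusion_id, top$fusion_score,
              top$exon_a, top$exon_b,
              ifelse(top$tags == "", "", paste0("  [", top$tags, "]"))),
      sep = "")
  invisible(x)
}

#' @export
summary.fusion_screen <- function(object, ...) {
  res <- object$results
  out <- list(
    sample_id = object$sample_id,
    n_candidates = nrow(res),
    top_hit = res$fusion_id[1L],
    top_score = res$fusion_score[1L],
    n_at_max = sum(res$fusion_score >= object$params$adjusted_to_max),
    n_degenerate = sum(res$fusion_score <= object$params$degenerate_score),
    filters = c(halfbinder = object$halfbinder_filter,
                enhancement = object$enhancement)
  )
  class(out) <- "summary.fusion_screen"
  out
}

#' @export
print.summary.fusion_screen <- function(x, ...) {
  cat(sprintf("Sample '%s': %d candidates scored\n", x$sample_id,
              x$n_candidates))
  cat(sprintf("  top hit %s (score %.3g); %d at the score maximum, %d degenerate\n",
              x$top_hit, x$top_score, x$n_at_max, x$n_degenerate))
  cat(sprintf("  half-binder filter %s, enhancement %s\n",
              if (x$filters[["halfbinder"]]) "on" else "off",
              if (x$filters[["enhancement"]]) "on" else "off"))
  invisible(x)
}

#' @export
as.data.frame.fusion_screen <- function(x, ...) x$results

#' Plot a candidate's breakpoint heatmap and intragenic profiles
#'
#' Draws the filtered chimeric heatmap (exon of the 5' partner on the
#' vertical axis, exon of the 3' partner on the horizontal) and the per-exon
#' intragenic profiles of both partners, with the called breakpoint marked.
#'
#' @param x A \code{fusion_screen} created with \code{keep_heatmaps = TRUE}.
#' @param fusion_id Candidate to draw; defaults to the top-ranked one.
#' @param ... Ignored.
#' @return Invisibly, the plotted assembly element.
#' @export
plot.fusion_screen <- function(x, fusion_id = NULL, ...) {
  if (is.null(x$assemblies)) {
    stop("screen was run with keep_heatmaps = FALSE", call. = FALSE)
  }
  if (is.null(fusion_id)) fusion_id <- x$results$fusion_id[1L]
  asm <- x$assemblies[[fusion_id]]
  if (is.null(asm)) stop("unknown fusion_id: ", fusion_id, call. = FALSE)
  row <- x$results[x$results$fusion_id == fusion_id, ]
  key <- variant_pair_key(row$variant_a, row$variant_b)
  el <- asm[[key]]
  m <- el$heatmap$matrix
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old))
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  col = pal, xlab = sprintf("exon of %s (3')", el$profile_b$gene),
                  ylab = sprintf("exon of %s (5')", el$profile_a$gene),
                  main = sprintf("%s  (called %d-%d, score %.2f)",
                                 fusion_id, row$exon_a, row$exon_b,
                                 row$fusion_score))
  graphics::points(row$exon_b, row$exon_a, pch = 0, cex = 2)
  for (side in list(list(p = el$profile_a, brk = row$exon_a + 0.5, lab = "5'"),
                    list(p = el$profile_b, brk = row$exon_b - 0.5,
                         lab = "3'"))) {
    graphics::plot(seq_along(side$p$exon_scores), side$p$exon_scores,
                   type = "h", lwd = 4, xlab = "exon", ylab = "score",
                   main = sprintf("%s (%s partner)", side$p$gene, side$lab))
    graphics::abline(v = side$brk, lty = 2)
  }
  invisible(el)
}
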