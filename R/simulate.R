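# Synthetic arrays with the signal structure the scoring algorithm assumes:
# lognormal baseline intensities, one elevated chimeric probe (or tight 2x2
# cluster) at the true breakpoint, concordant 5'/3' intragenic shifts in
# both partners, and half-binder striping artifacts.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulate one array sample
#'
#' Every probe draws intensity 2^(baseline + effects + N(0, noise_sd)).
#' A fused sample adds the chimeric boost at the true breakpoint cell
#' (spread over a 2x2 cluster when \code{cluster_breakpoints}, mimicking
#' co-expressed transcript variants), and the intragenic shift on the
#' retained exons: 1..i of the 5' partner and j..n_B of the 3' partner —
#' the wild-type allele keeps all exons at baseline, so the fused sample
#' shows a shift in relative expression, not an on/off profile. Each
#' candidate heatmap row and column is independently struck by a half-binder
#' stripe with probability \code{halfbinder_row_prob}. Fully reproducible
#' from \code{config$seed}.
#'
#' @param panel A \code{fusion_panel}.
#' @param annotations A \code{probe_annotation} covering the panel (e.g.
#'   from \code{\link{annotate_panel}}).
#' @param true_fusion fusion_id of the injected fusion, or NULL for a
#'   fusion-negative sample.
#' @param true_breakpoint Integer c(i, j) with j >= 2, or NULL to sample an
#'   interior breakpoint (i in 2..n_A-1, j in 2..n_B-1; fusions retain
#'   multiple exons of each partner).
#' @param config A \code{\link{simulation_config}}.
#' @param sample_id Label for the generated sample.
#' @return A list with \code{intensities} (an \code{intensity_table}) and
#'   \code{truth} (injected fusion, breakpoint, boosted probe ids, striped
#'   rows/columns per candidate).
#' @export
simulate_sample <- function(panel, annotations, true_fusion = NULL,
                            true_breakpoint = NULL,
                            config = simulation_config(),
                            sample_id = "sim") {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(true_fusion) && !true_fusion %in% panel$fusion_id) {
    stop("unknown fusion_id: ", true_fusion, call. = FALSE)
  }
  probes <- unique(annotations$probe_id)
  effects <- stats::setNames(numeric(length(probes)), probes)
  truth <- list(sample_id = sample_id, true_fusion = true_fusion,
                breakpoint = NULL, boosted_probes = character(0),
                stripes = list())
  with_seed(config$seed, {
    if (!is.null(true_fusion)) {
      p <- panel[panel$fusion_id == true_fusion, ]
      n_a <- p$n_exons_a; n_b <- p$n_exons_b
      bp <- true_breakpoint
      if (is.null(bp)) {
        ri <- if (n_a >= 3L) 2:(n_a - 1L) else seq_len(n_a)
        rj <- if (n_b >= 3L) 2:(n_b - 1L) else 2L
        bp <- c(ri[sample.int(length(ri), 1L)],
                rj[sample.int(length(rj), 1L)])
      }
      bp <- as.integer(bp)
      if (bp[2L] < 2L || bp[1L] < 1L || bp[1L] > n_a || bp[2L] > n_b) {
        stop("invalid true_breakpoint (need 1 <= i <= n_A, 2 <= j <= n_B)",
             call. = FALSE)
      }
      pair <- variant_pair_key(p$variant_a, p$variant_b)
      chim <- annotations[annotations$fusion_id == true_fusion &
                          annotations$probe_type == "chimeric" &
                          annotations$variant_id == pair, , drop = FALSE]
      cells <- cbind(bp[1L], bp[2L])
      if (config$cluster_breakpoints) {
        # neighbours share the boost at 60%: a tight cluster of highly
        # expressed probes, as produced by co-expressed transcript variants
        nb <- expand.grid(i = bp[1L] + c(-1L, 0L), j = bp[2L] + c(0L, 1L))
        nb <- nb[nb$i >= 1L & nb$j <= n_b &
                 !(nb$i == bp[1L] & nb$j == bp[2L]), , drop = FALSE]
        cells <- rbind(cells, as.matrix(nb))
      }
      boost <- c(config$fusion_chimeric_boost_log2,
                 rep(0.6 * config$fusion_chimeric_boost_log2,
                     nrow(cells) - 1L))
      for (k in seq_len(nrow(cells))) {
        id <- chim$probe_id[chim$exon_a == cells[k, 1L] &
                            chim$exon_b == cells[k, 2L]]
        effects[id] <- effects[id] + boost[k]
      }
      truth$boosted_probes <- chim$probe_id[
        chim$exon_a %in% cells[, 1L] & chim$exon_b %in% cells[, 2L]]
      shift <- config$fusion_expression_shift_log2 *
        config$fused_fraction_of_transcript
      ig <- annotations[annotations$probe_type == "intragenic", , drop = FALSE]
      ida <- unique(ig$probe_id[ig$gene == p$gene_a &
                                ig$variant_id == p$variant_a &
                                !is.na(ig$exon_a) & ig$exon_a <= bp[1L]])
      idb <- unique(ig$probe_id[ig$gene == p$gene_b &
                                ig$variant_id == p$variant_b &
                                !is.na(ig$exon_b) & ig$exon_b >= bp[2L]])
      effects[ida] <- effects[ida] + shift
      effects[idb] <- effects[idb] + shift
      truth$breakpoint <- bp
    }
    if (config$halfbinder_row_prob > 0) {
      for (r in seq_len(nrow(panel))) {
        p <- panel[r, ]
        pair <- variant_pair_key(p$variant_a, p$variant_b)
        chim <- annotations[annotations$fusion_id == p$fusion_id &
                            annotations$probe_type == "chimeric" &
                            annotations$variant_id == pair, , drop = FALSE]
        hit_rows <- which(stats::runif(p$n_exons_a) <
                          config$halfbinder_row_prob)
        hit_cols <- which(stats::runif(p$n_exons_b) <
                          config$halfbinder_row_prob)
        if (length(hit_rows) + length(hit_cols) > 0L) {
          ids <- chim$probe_id[chim$exon_a %in% hit_rows |
                               chim$exon_b %in% hit_cols]
          effects[ids] <- effects[ids] + config$halfbinder_level_log2
          truth$stripes[[p$fusion_id]] <- list(rows = hit_rows,
                                               cols = hit_cols)
        }
      }
    }
    noise <- stats::rnorm(length(probes), 0, config$noise_sd_log2)
    intens <- 2 ^ (config$baseline_log2 + effects + noise)
    truth$config <- config
    list(intensities = intensity_table(probes, intens,
                                       sample_id = sample_id,
                                       annotations = annotations),
         truth = truth)
  })
}

#' Run a simulated cohort through the full pipeline
#'
#' Simulates \code{n_samples} fusion-positive samples (true fusion drawn
#' uniformly from the panel unless \code{true_fusions} is given), screens
#' each with \code{\link{fusion_screen}}, and reports the rank of the true
#' fusion per sample plus aggregate top-1 and top-3 recovery.
#'
#' @param n_samples Number of samples (>= 1).
#' @param config A \code{\link{simulation_config}}; per-sample seeds are
#'   derived from \code{config$seed}.
#' @param panel A \code{fusion_panel}.
#' @param annotations Optional \code{probe_annotation}; defaults to
#'   \code{annotate_panel(panel)}.
#' @param params,normalization,halfbinder_filter,enhancement Passed to
#'   \code{\link{fusion_screen}}.
#' @param true_fusions Optional character vector (recycled) fixing each
#'   sample's injected fusion; use NA for a fusion-negative sample.
#' @return A data.frame of class \code{"fusion_cohort"} with columns
#'   sample_id, true_fusion, rank_of_truth, top_hit, top_score, and
#'   attributes \code{top1} and \code{top3} (recovery fractions over the
#'   fusion-positive samples).
#' @export
run_cohort <- function(n_samples, config = simulation_config(), panel,
                       annotations = NULL,
                       params = scoring_params(),
                       normalization = normalization_config(),
                       halfbinder_filter = TRUE, enhancement = TRUE,
                       true_fusions = NULL) {
  stopifnot(n_samples >= 1L)
  if (is.null(annotations)) annotations <- annotate_panel(panel)
  if (is.null(true_fusions)) {
    true_fusions <- with_seed(config$seed, {
      panel$fusion_id[sample.int(nrow(panel), n_samples, replace = TRUE)]
    })
  } else {
    true_fusions <- rep_len(as.character(true_fusions), n_samples)
  }
  rows <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    cfg <- config
    cfg$seed <- as.integer((config$seed * 1009 + s * 7919) %% 2147483647)
    tf <- true_fusions[s]
    sim <- simulate_sample(panel, annotations,
                           true_fusion = if (is.na(tf)) NULL else tf,
                           config = cfg,
                           sample_id = sprintf("sim%03d", s))
    scr <- fusion_screen(sim$intensities, annotations, panel,
                         params = params, normalization = normalization,
                         halfbinder_filter = halfbinder_filter,
                         enhancement = enhancement, keep_heatmaps = FALSE)
    res <- scr$results
    rows[[s]] <- data.frame(
      sample_id = sim$truth$sample_id,
      true_fusion = tf,
      rank_of_truth = if (is.na(tf)) NA_integer_
                      else res$rank[res$fusion_id == tf],
      top_hit = res$fusion_id[1L],
      top_score = res$fusion_score[1L],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  pos <- !is.na(out$true_fusion)
  attr(out, "top1") <- if (any(pos)) mean(out$rank_of_truth[pos] <= 1L) else NA
  attr(out, "top3") <- if (any(pos)) mean(out$rank_of_truth[pos] <= 3L) else NA
  class(out) <- c("fusion_cohort", "data.frame")
  out
}

#' @export
print.fusion_cohort <- function(x, ...) {
  print.data.frame(x, ...)
  t1 <- attr(x, "top1")
  if (!is.null(t1) && !is.na(t1)) {
    cat(sprintf("top-1 recovery %.3f, top-3 recovery %.3f\n",
                t1, attr(x, "top3")))
  }
  invisible(x)
}
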