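#' Scoring parameters
#'
#' Bundle of the constants used by the breakpoint scorer, the half-binder
#' filter and the single-strong-probe enhancement. Defaults are the published
#' operating point of the method; all are overridable for ablation studies.
#'
#' @param chimeric_cutoff Cap applied to the chimeric probe score before it is
#'   combined with the break scores (default 3.0).
#' @param max_break_score Cap on each partner's expression-discontinuity term
#'   (default 1.5).
#' @param adjusted_to_max Value assigned to an enhanced single strong chimeric
#'   probe, and the supremum of the fusion score (default 6.0).
#' @param weak_adjust_value Enhancement value used instead of
#'   \code{adjusted_to_max} when the enhanced cell's row or column carries the
#'   weak half-binding tag (default 3.0).
#' @param degenerate_score Score assigned to degenerate breakpoints
#'   (default 0.1).
#' @param enhancement_margin Minimum gap between the largest and second
#'   largest heatmap cell for the enhancement to fire (default 0.8).
#' @param halfbinder_fraction Fraction of probes in a row/column that must
#'   qualify for the striping triggers (default 0.25).
#' @param halfbinder_level_strong Fraction of the row/column maximum defining
#'   a "strong" probe for the zeroing trigger (default 0.70).
#' @param halfbinder_level_weak Fraction of the row/column maximum defining a
#'   qualifying probe for the weak half-binding tag (default 0.50).
#' @param halfbinder_count_trigger Number of probes at or above
#'   \code{chimeric_cutoff} that zeroes a row/column outright (default 3).
#'
#' @return An object of class \code{"scoring_params"} (a validated list).
#' @examples
#' p <- scoring_params()
#' p$adjusted_to_max
#' @export
scoring_params <- function(chimeric_cutoff = 3.0,
                           max_break_score = 1.5,
                           adjusted_to_max = 6.0,
                           weak_adjust_value = 3.0,
                           degenerate_score = 0.1,
                           enhancement_margin = 0.8,
                           halfbinder_fraction = 0.25,
                           halfbinder_level_strong = 0.70,
                           halfbinder_level_weak = 0.50,
                           halfbinder_count_trigger = 3L) {
  p <- list(
    chimeric_cutoff = as.numeric(chimeric_cutoff),
    max_break_score = as.numeric(max_break_score),
    adjusted_to_max = as.numeric(adjusted_to_max),
    weak_adjust_value = as.numeric(weak_adjust_value),
    degenerate_score = as.numeric(degenerate_score),
    enhancement_margin = as.numeric(enhancement_margin),
    halfbinder_fraction = as.numeric(halfbinder_fraction),
    halfbinder_level_strong = as.numeric(halfbinder_level_strong),
    halfbinder_level_weak = as.numeric(halfbinder_level_weak),
    halfbinder_count_trigger = as.integer(halfbinder_count_trigger)
  )
  stopifnot(
    vapply(p[1:9], function(x) is.finite(x) && length(x) == 1L, logical(1)),
    p$halfbinder_level_weak > 0,
    p$halfbinder_level_weak < p$halfbinder_level_strong,
    p$halfbinder_level_strong <= 1,
    p$chimeric_cutoff >= 0, p$max_break_score >= 0,
    p$degenerate_score >= 0, p$enhancement_margin >= 0,
    p$adjusted_to_max >= p$chimeric_cutoff,
    p$halfbinder_fraction >= 0, p$halfbinder_fraction <= 1,
    p$halfbinder_count_trigger >= 1L
  )
  structure(p, class = "scoring_params")
}

#' Normalization configuration
#'
#' Controls the conversion of raw fluorescence intensities to probe scores.
#' The default puts the bulk of the array near zero so that the scorer's
#' printed constants (cutoff 3.0, margin 0.8, maximum 6.0) read as
#' "log2 units above the array median".
#'
#' @param method \code{"log2_median_center"} (default): log2(intensity +
#'   pseudocount), centered at the array median, negatives floored at 0;
#'   \code{"log2_only"}: log2(intensity + pseudocount), no centering or floor;
#'   \code{"none"}: raw intensities passed through.
#' @param pseudocount Added before the log transform; must be > 0.
#' @return An object of class \code{"normalization_config"}.
#' @export
normalization_config <- function(method = c("log2_median_center",
                                            "log2_only", "none"),
                                 pseudocount = 1.0) {
  method <- match.arg(method)
  pseudocount <- as.numeric(pseudocount)
  stopifnot(length(pseudocount) == 1L, is.finite(pseudocount),
            pseudocount > 0)
  structure(list(method = method, pseudocount = pseudocount),
            class = "normalization_config")
}

#' Probe design configuration
#'
#' @param arm_length Nucleotides taken from each exon for a chimeric junction
#'   probe (probe length = 2 * arm_length when both exons are long enough).
#'   Exons shorter than \code{arm_length} contribute their full sequence.
#' @param intragenic_probe_length Length of the probe centered in each exon;
#'   capped at the exon length.
#' @return An object of class \code{"design_config"}.
#' @export
design_config <- function(arm_length = 30L, intragenic_probe_length = 60L) {
  arm_length <- as.integer(arm_length)
  intragenic_probe_length <- as.integer(intragenic_probe_length)
  stopifnot(arm_length >= 10L, intragenic_probe_length >= 1L)
  structure(list(arm_length = arm_length,
                 intragenic_probe_length = intragenic_probe_length,
                 probe_length = 2L * arm_length),
            class = "design_config")
}

#' Simulation configuration
#'
#' Generative model for synthetic arrays: every probe draws a lognormal
#' intensity 2^(baseline + effects + N(0, noise_sd)) on the log2 scale. A
#' fused sample adds \code{fusion_chimeric_boost_log2} to the chimeric probe
#' at the true breakpoint (spread over a 2x2 cluster when
#' \code{cluster_breakpoints} is TRUE, mimicking transcript-variant clusters)
#' and \code{fused_fraction_of_transcript * fusion_expression_shift_log2} to
#' the intragenic probes of the retained exons (5' of A, 3' of B). Each
#' chimeric row and column is independently struck by a half-binder stripe
#' with probability \code{halfbinder_row_prob}, adding
#' \code{halfbinder_level_log2} to all its probes.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param baseline_log2 Baseline log2 intensity of every probe (default 8.0).
#' @param noise_sd_log2 SD of the log2 noise (default 0.3).
#' @param fusion_chimeric_boost_log2 Added to the true junction probe
#'   (default 5.0).
#' @param fusion_expression_shift_log2 Added to intragenic probes of the
#'   retained exons (default 2.0).
#' @param fused_fraction_of_transcript In (0, 1]; scales the intragenic shift
#'   (a tumor where only part of the transcript pool is fusion-derived shows
#'   a weaker shift). Default 1.
#' @param halfbinder_row_prob Per-row/column stripe probability (default 0.05).
#' @param halfbinder_level_log2 Stripe magnitude in log2 units (default 4.0).
#' @param cluster_breakpoints If TRUE, the chimeric boost is spread over a 2x2
#'   cluster at the breakpoint (default FALSE).
#' @return An object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(seed = 1L,
                              baseline_log2 = 8.0,
                              noise_sd_log2 = 0.3,
                              fusion_chimeric_boost_log2 = 5.0,
                              fusion_expression_shift_log2 = 2.0,
                              fused_fraction_of_transcript = 1.0,
                              halfbinder_row_prob = 0.05,
                              halfbinder_level_log2 = 4.0,
                              cluster_breakpoints = FALSE) {
  cfg <- list(
    seed = as.integer(seed),
    baseline_log2 = as.numeric(baseline_log2),
    noise_sd_log2 = as.numeric(noise_sd_log2),
    fusion_chimeric_boost_log2 = as.numeric(fusion_chimeric_boost_log2),
    fusion_expression_shift_log2 = as.numeric(fusion_expression_shift_log2),
    fused_fraction_of_transcript = as.numeric(fused_fraction_of_transcript),
    halfbinder_row_prob = as.numeric(halfbinder_row_prob),
    halfbinder_level_log2 = as.numeric(halfbinder_level_log2),
    cluster_breakpoints = isTRUE(cluster_breakpoints)
  )
  stopifnot(cfg$noise_sd_log2 > 0,
            cfg$halfbinder_row_prob >= 0, cfg$halfbinder_row_prob <= 1,
            cfg$fused_fraction_of_transcript > 0,
            cfg$fused_fraction_of_transcript <= 1)
  structure(cfg, class = "simulation_config")
}
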