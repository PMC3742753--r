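# Assembly of per-candidate score structures: one chimeric heatmap per
# transcript-variant pair plus one intragenic profile per partner.

#' Construct a chimeric heatmap from a score matrix
#'
#' Builds the exon_A x exon_B breakpoint heatmap object directly from a
#' matrix of (normalized) chimeric probe scores: cell (i, j) is the probe
#' joining exon i of the 5' partner (last retained 5' exon) to exon j of
#' the 3' partner (first retained 3' exon). Mostly useful for constructed
#' examples and ablation studies; \code{\link{assemble}} builds heatmaps
#' from annotated intensity tables.
#'
#' @param mat Numeric matrix of probe scores (rows = exons of A, columns =
#'   exons of B).
#' @param fusion_id,variant_a,variant_b Identifiers carried along.
#' @return An object of class \code{"chimeric_heatmap"} with untagged
#'   rows/columns.
#' @examples
#' hm <- chimeric_heatmap(matrix(c(5, 4, rep(1, 6)), nrow = 1))
#' reduce_half_binders(hm)$matrix
#' @export
chimeric_heatmap <- function(mat, fusion_id = "candidate",
                             variant_a = "v1", variant_b = "v1") {
  stopifnot(is.matrix(mat), is.numeric(mat), all(is.finite(mat)))
  new_chimeric_heatmap(fusion_id, variant_a, variant_b, mat)
}

new_chimeric_heatmap <- function(fusion_id, variant_a, variant_b, mat,
                                 row_tags = rep("none", nrow(mat)),
                                 col_tags = rep("none", ncol(mat))) {
  stopifnot(is.matrix(mat), length(row_tags) == nrow(mat),
            length(col_tags) == ncol(mat))
  structure(list(fusion_id = fusion_id, variant_a = variant_a,
                 variant_b = variant_b, matrix = mat,
                 row_tags = row_tags, col_tags = col_tags,
                 filtered = FALSE, enhanced = FALSE),
            class = "chimeric_heatmap")
}

new_intragenic_profile <- function(gene, variant_id, exon_scores) {
  structure(list(gene = gene, variant_id = variant_id,
                 exon_scores = as.numeric(exon_scores)),
            class = "intragenic_profile")
}

#' @export
print.chimeric_heatmap <- function(x, ...) {
  cat(sprintf("Chimeric heatmap %s (%s x %s): %d x %d exon-exon cells\n",
              x$fusion_id, x$variant_a, x$variant_b,
              nrow(x$matrix), ncol(x$matrix)))
  zr <- sum(x$row_tags == "zeroed"); zc <- sum(x$col_tags == "zeroed")
  wr <- sum(x$row_tags == "weak_half_binding")
  wc <- sum(x$col_tags == "weak_half_binding")
  cat(sprintf("  max cell %.3g; zeroed rows/cols %d/%d; weak tags %d/%d\n",
              max(x$matrix), zr, zc, wr, wc))
  invisible(x)
}

variant_pair_key <- function(variant_a, variant_b) {
  paste(variant_a, variant_b, sep = "|")
}

#' Assemble heatmap and intragenic profiles for one candidate
#'
#' Builds, for each transcript-variant pair of a candidate fusion, the
#' n_A x n_B chimeric score matrix (cell (i, j) is the probe joining exon i
#' of the 5' partner to exon j of the 3' partner, i.e. the breakpoint
#' retaining exons 1..i of A and j..n_B of B) and the per-exon intragenic
#' profiles of both partners. Raw intensities are passed through
#' \code{\link{normalize_scores}} before insertion.
#'
#' @param sample An \code{\link{intensity_table}}, or a named score vector as
#'   returned by \code{normalize_scores} (then \code{normalization} is
#'   ignored).
#' @param annotations A \code{\link{load_annotations}} table covering every
#'   exon-exon combination and every exon of both variants.
#' @param candidate A fusion_id present in \code{annotations}, or a one-row
#'   slice of a \code{fusion_panel}.
#' @param normalization A \code{\link{normalization_config}}.
#' @return A list of class \code{"fusion_assembly"}: one element per variant
#'   pair, each a list with \code{heatmap}, \code{profile_a}, \code{profile_b}.
#' @export
assemble <- function(sample, annotations, candidate,
                     normalization = normalization_config()) {
  fusion_id <- if (is.character(candidate)) candidate else candidate$fusion_id
  stopifnot(length(fusion_id) == 1L)
  scores <- if (is.numeric(sample)) sample else {
    normalize_scores(sample, normalization)
  }
  ann <- annotations[annotations$fusion_id == fusion_id, , drop = FALSE]
  if (nrow(ann) == 0L) {
    stop("assembly error: no probes annotated for candidate ", fusion_id,
         call. = FALSE)
  }
  missing <- setdiff(ann$probe_id, names(scores))
  if (length(missing) > 0L) {
    stop("assembly error: probe(s) without intensity: ",
         paste(utils::head(missing, 10L), collapse = ", "), call. = FALSE)
  }
  chim <- ann[ann$probe_type == "chimeric", , drop = FALSE]
  intr <- ann[ann$probe_type == "intragenic", , drop = FALSE]
  if (nrow(chim) == 0L) {
    stop("assembly error: no chimeric probes for ", fusion_id, call. = FALSE)
  }
  genes_a <- unique(intr$gene[!is.na(intr$exon_a)])
  genes_b <- unique(intr$gene[!is.na(intr$exon_b)])
  if (length(genes_a) != 1L || length(genes_b) != 1L) {
    stop("assembly error: candidate ", fusion_id,
         " must have intragenic probes for exactly one 5' and one 3' gene",
         call. = FALSE)
  }
  out <- list()
  for (pair in unique(chim$variant_id)) {
    pv <- strsplit(pair, "|", fixed = TRUE)[[1L]]
    if (length(pv) != 2L) {
      stop("assembly error: chimeric variant_id must be 'variant_a|variant_b'",
           call. = FALSE)
    }
    pa <- intr[!is.na(intr$exon_a) & intr$variant_id == pv[1L], , drop = FALSE]
    pb <- intr[!is.na(intr$exon_b) & intr$variant_id == pv[2L], , drop = FALSE]
    pa <- pa[!duplicated(pa$probe_id), , drop = FALSE]
    pb <- pb[!duplicated(pb$probe_id), , drop = FALSE]
    cc <- chim[chim$variant_id == pair, , drop = FALSE]
    n_a <- max(cc$exon_a); n_b <- max(cc$exon_b)
    if (nrow(cc) != n_a * n_b ||
        anyDuplicated(paste(cc$exon_a, cc$exon_b))) {
      stop("assembly error: candidate ", fusion_id, " variant pair ", pair,
           " does not cover every exon-exon combination exactly once",
           call. = FALSE)
    }
    if (nrow(pa) != n_a || !setequal(pa$exon_a, seq_len(n_a)) ||
        nrow(pb) != n_b || !setequal(pb$exon_b, seq_len(n_b))) {
      stop("assembly error: intragenic probes of ", fusion_id, " (", pair,
           ") do not cover every exon exactly once", call. = FALSE)
    }
    mat <- matrix(0, n_a, n_b,
                  dimnames = list(seq_len(n_a), seq_len(n_b)))
    mat[cbind(cc$exon_a, cc$exon_b)] <- scores[cc$probe_id]
    prof_a <- numeric(n_a); prof_a[pa$exon_a] <- scores[pa$probe_id]
    prof_b <- numeric(n_b); prof_b[pb$exon_b] <- scores[pb$probe_id]
    out[[pair]] <- list(
      heatmap = new_chimeric_heatmap(fusion_id, pv[1L], pv[2L], mat),
      profile_a = new_intragenic_profile(genes_a, pv[1L], prof_a),
      profile_b = new_intragenic_profile(genes_b, pv[2L], prof_b)
    )
  }
  structure(out, class = "fusion_assembly", fusion_id = fusion_id)
}

#' Generate the probe annotation table for a whole panel
#'
#' Creates the annotation rows a junction-probe array for \code{panel} would
#' carry: for each candidate, one chimeric probe per exon-exon combination
#' (n_A x n_B) and one intragenic probe per exon of each partner. Intragenic
#' probes are shared across candidates that involve the same (gene, variant)
#' — one physical oligo per exon — so their probe_ids repeat across fusions.
#'
#' @param panel A \code{\link{load_panel}} table.
#' @return A \code{probe_annotation} data.frame.
#' @export
annotate_panel <- function(panel) {
  chunks <- vector("list", nrow(panel) * 3L)
  k <- 0L
  for (r in seq_len(nrow(panel))) {
    p <- panel[r, ]
    pair <- variant_pair_key(p$variant_a, p$variant_b)
    grid <- expand.grid(exon_a = seq_len(p$n_exons_a),
                        exon_b = seq_len(p$n_exons_b))
    k <- k + 1L
    chunks[[k]] <- data.frame(
      probe_id = sprintf("CH|%s|%s|%d-%d", p$fusion_id, pair,
                         grid$exon_a, grid$exon_b),
      fusion_id = p$fusion_id, probe_type = "chimeric", gene = "",
      variant_id = pair, exon_a = grid$exon_a, exon_b = grid$exon_b,
      stringsAsFactors = FALSE)
    k <- k + 1L
    chunks[[k]] <- data.frame(
      probe_id = sprintf("IG|%s|%s|%d", p$gene_a, p$variant_a,
                         seq_len(p$n_exons_a)),
      fusion_id = p$fusion_id, probe_type = "intragenic", gene = p$gene_a,
      variant_id = p$variant_a, exon_a = seq_len(p$n_exons_a), exon_b = NA,
      stringsAsFactors = FALSE)
    k <- k + 1L
    chunks[[k]] <- data.frame(
      probe_id = sprintf("IG|%s|%s|%d", p$gene_b, p$variant_b,
                         seq_len(p$n_exons_b)),
      fusion_id = p$fusion_id, probe_type = "intragenic", gene = p$gene_b,
      variant_id = p$variant_b, exon_a = NA, exon_b = seq_len(p$n_exons_b),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, chunks)
  df$exon_a <- as.integer(df$exon_a)
  df$exon_b <- as.integer(df$exon_b)
  validate_annotations(df, "annotate_panel")
}
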