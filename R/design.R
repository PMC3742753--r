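# Probe design: target sequences for intragenic exon probes and chimeric
# exon-exon junction probes. FASTA records are named gene|variant|exon_index
# and hold the transcribed (sense) strand; reverse-complementation for
# physical synthesis is a synthesis-time concern, not handled here.

read_exon_fasta <- function(path, gene, variant) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  ok <- lengths(parts) == 3L
  if (!all(ok)) {
    stop("design error: FASTA records must be named gene|variant|exon_index",
         call. = FALSE)
  }
  g <- vapply(parts, `[[`, character(1), 1L)
  v <- vapply(parts, `[[`, character(1), 2L)
  e <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3L)))
  keep <- g == gene & v == variant
  if (!any(keep)) {
    stop("design error: no exon records for ", gene, "|", variant,
         " in ", path, call. = FALSE)
  }
  seqs <- seqs[keep]; e <- e[keep]
  if (any(is.na(e)) || anyDuplicated(e)) {
    stop("design error: exon indices must be unique integers", call. = FALSE)
  }
  seqs[order(e)]
}

probe_subseq <- function(seqs, starts, ends) {
  as.character(Biostrings::subseq(seqs, start = starts, end = ends))
}

#' Design junction and intragenic probe target sequences for one candidate
#'
#' Emits one intragenic probe per exon (centered in the exon, capped at the
#' exon length) and one chimeric probe per exon-exon combination, each
#' concatenating the last \code{arm_length} bases of exon i of the 5'
#' partner with the first \code{arm_length} bases of exon j of the 3'
#' partner (n_A + n_B intragenic and n_A x n_B chimeric probes in total).
#' Exons shorter than \code{arm_length} contribute their full sequence; the
#' annotation mirrors the emitted probes one for one and round-trips through
#' \code{\link{load_annotations}}.
#'
#' @param exons_a,exons_b Paths to exon FASTA files (records named
#'   \code{gene|variant|exon_index}, sense strand, A/C/G/T/N), or
#'   \code{DNAStringSet}s so named.
#' @param candidate A one-row slice of a \code{fusion_panel}.
#' @param config A \code{\link{design_config}}.
#' @return A list with \code{probes} (a named \code{DNAStringSet}) and
#'   \code{annotation} (a \code{probe_annotation} data.frame).
#' @export
design_probes <- function(exons_a, exons_b, candidate,
                          config = design_config()) {
  stopifnot(nrow(candidate) == 1L)
  get_exons <- function(x, gene, variant, n_expect) {
    s <- if (is.character(x)) read_exon_fasta(x, gene, variant) else x
    if (length(s) != n_expect) {
      stop("design error: expected ", n_expect, " exon(s) for ", gene,
           ", got ", length(s), call. = FALSE)
    }
    chars <- Biostrings::alphabetFrequency(s, baseOnly = TRUE)
    informative <- rowSums(chars[, c("A", "C", "G", "T"), drop = FALSE])
    if (any(informative == 0L)) {
      stop("design error: exon with no informative (non-N) bases in ", gene,
           call. = FALSE)
    }
    s
  }
  sa <- get_exons(exons_a, candidate$gene_a, candidate$variant_a,
                  candidate$n_exons_a)
  sb <- get_exons(exons_b, candidate$gene_b, candidate$variant_b,
                  candidate$n_exons_b)
  n_a <- length(sa); n_b <- length(sb)
  arm <- config$arm_length
  pair <- variant_pair_key(candidate$variant_a, candidate$variant_b)

  intr_one <- function(seqs, gene, variant, len) {
    w <- Biostrings::width(seqs)
    take <- pmin(w, len)
    start <- pmax(1L, (w - take) %/% 2L + 1L)
    data.frame(probe_id = sprintf("IG|%s|%s|%d", gene, variant,
                                  seq_along(seqs)),
               seq = probe_subseq(seqs, start, start + take - 1L),
               stringsAsFactors = FALSE)
  }
  ia <- intr_one(sa, candidate$gene_a, candidate$variant_a,
                 config$intragenic_probe_length)
  ib <- intr_one(sb, candidate$gene_b, candidate$variant_b,
                 config$intragenic_probe_length)

  wa <- Biostrings::width(sa); wb <- Biostrings::width(sb)
  arm_a <- pmin(wa, arm); arm_b <- pmin(wb, arm)
  suffixes <- probe_subseq(sa, wa - arm_a + 1L, wa)
  prefixes <- probe_subseq(sb, 1L, arm_b)
  grid <- expand.grid(exon_a = seq_len(n_a), exon_b = seq_len(n_b))
  chim <- data.frame(
    probe_id = sprintf("CH|%s|%s|%d-%d", candidate$fusion_id, pair,
                       grid$exon_a, grid$exon_b),
    seq = paste0(suffixes[grid$exon_a], prefixes[grid$exon_b]),
    stringsAsFactors = FALSE)

  ann <- rbind(
    data.frame(probe_id = chim$probe_id, fusion_id = candidate$fusion_id,
               probe_type = "chimeric", gene = "", variant_id = pair,
               exon_a = grid$exon_a, exon_b = grid$exon_b,
               stringsAsFactors = FALSE),
    data.frame(probe_id = ia$probe_id, fusion_id = candidate$fusion_id,
               probe_type = "intragenic", gene = candidate$gene_a,
               variant_id = candidate$variant_a,
               exon_a = seq_len(n_a), exon_b = NA_integer_,
               stringsAsFactors = FALSE),
    data.frame(probe_id = ib$probe_id, fusion_id = candidate$fusion_id,
               probe_type = "intragenic", gene = candidate$gene_b,
               variant_id = candidate$variant_b,
               exon_a = NA_integer_, exon_b = seq_len(n_b),
               stringsAsFactors = FALSE))
  ann$exon_a <- as.integer(ann$exon_a); ann$exon_b <- as.integer(ann$exon_b)
  seqs <- c(chim$seq, ia$seq, ib$seq)
  names(seqs) <- c(chim$probe_id, ia$probe_id, ib$probe_id)
  list(probes = Biostrings::DNAStringSet(seqs),
       annotation = validate_annotations(ann, "design_probes"))
}

#' @rdname design_probes
#' @param probes A named \code{DNAStringSet} as returned by
#'   \code{design_probes}.
#' @param path Output FASTA path.
#' @export
write_probe_fasta <- function(probes, path) {
  Biostrings::writeXStringSet(probes, path)
  invisible(path)
}
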