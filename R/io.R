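# Tab-delimited file formats. All files are UTF-8 TSV with a header row,
# '.' decimal separator and '#' comment lines.
#
#   panel:       fusion_id gene_a variant_a n_exons_a gene_b variant_b n_exons_b
#   annotation:  probe_id fusion_id probe_type gene variant_id exon_a exon_b
#                (empty field = absent; chimeric rows leave `gene` empty and
#                 store the variant pair as "variant_a|variant_b")
#   intensity:   probe_id intensity
#   report:      rank fusion_id fusion_score exon_a exon_b chimeric_value
#                break_score_a break_score_b tags

read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = "character",
                          fileEncoding = "UTF-8",
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("format error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv_plain <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0L) {
    rows <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

fmt_num <- function(x) {
  # fixed formatting so identical inputs give byte-identical files
  ifelse(is.na(x), "", formatC(x, format = "g", digits = 10))
}

#' Load a fusion panel
#'
#' Reads the candidate fusion list: one row per candidate, naming the 5'
#' partner (gene A), the 3' partner (gene B), their transcript variants and
#' exon counts. The array probes only the A1+B2 constellation (exons 1..i of
#' A joined to exons j..n of B).
#'
#' @param path Path to a panel TSV with columns fusion_id, gene_a, variant_a,
#'   n_exons_a, gene_b, variant_b, n_exons_b.
#' @return A data.frame of class \code{"fusion_panel"}.
#' @export
load_panel <- function(path) {
  df <- read_tsv_strict(path, c("fusion_id", "gene_a", "variant_a",
                                "n_exons_a", "gene_b", "variant_b",
                                "n_exons_b"))
  df$n_exons_a <- as.integer(df$n_exons_a)
  df$n_exons_b <- as.integer(df$n_exons_b)
  validate_panel(df, path)
}

validate_panel <- function(df, origin = "panel") {
  if (anyDuplicated(df$fusion_id)) {
    stop("validation error in ", origin, ": duplicated fusion_id: ",
         paste(unique(df$fusion_id[duplicated(df$fusion_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(is.na(df$n_exons_a)) || any(is.na(df$n_exons_b)) ||
      any(df$n_exons_a < 1L) || any(df$n_exons_b < 1L)) {
    stop("validation error in ", origin,
         ": exon counts must be positive integers", call. = FALSE)
  }
  if (any(df$gene_a == df$gene_b & df$variant_a == df$variant_b)) {
    stop("validation error in ", origin,
         ": a candidate must join two distinct partners", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("fusion_panel", "data.frame")
  df
}

#' @rdname load_panel
#' @param panel A \code{fusion_panel}.
#' @export
write_panel <- function(panel, path) {
  write_tsv_plain(as.data.frame(panel)[, c("fusion_id", "gene_a", "variant_a",
                                           "n_exons_a", "gene_b", "variant_b",
                                           "n_exons_b")], path)
}

#' Load a probe annotation table
#'
#' Maps every probe on the array to its fusion candidate, probe type and exon
#' coordinates. Chimeric probes carry both \code{exon_a} and \code{exon_b}
#' and the variant pair as \code{"variant_a|variant_b"} in \code{variant_id};
#' intragenic probes carry one gene, one variant and exactly one exon index.
#' Intragenic probes may be shared between candidates involving the same
#' (gene, variant): the same probe_id then appears in several fusions' rows.
#'
#' @param path Path to an annotation TSV with columns probe_id, fusion_id,
#'   probe_type, gene, variant_id, exon_a, exon_b (empty field = absent).
#' @return A data.frame of class \code{"probe_annotation"}.
#' @export
load_annotations <- function(path) {
  df <- read_tsv_strict(path, c("probe_id", "fusion_id", "probe_type",
                                "gene", "variant_id", "exon_a", "exon_b"))
  df$exon_a <- suppressWarnings(as.integer(ifelse(df$exon_a == "", NA,
                                                  df$exon_a)))
  df$exon_b <- suppressWarnings(as.integer(ifelse(df$exon_b == "", NA,
                                                  df$exon_b)))
  validate_annotations(df, path)
}

validate_annotations <- function(df, origin = "annotations") {
  bad_type <- setdiff(unique(df$probe_type), c("chimeric", "intragenic"))
  if (length(bad_type) > 0L) {
    stop("format error in ", origin, ": unknown probe_type ",
         paste(bad_type, collapse = ", "), call. = FALSE)
  }
  chim <- df$probe_type == "chimeric"
  if (any(chim & (is.na(df$exon_a) | is.na(df$exon_b)))) {
    stop("validation error in ", origin,
         ": chimeric probes need both exon_a and exon_b", call. = FALSE)
  }
  intr <- !chim
  one_exon <- xor(is.na(df$exon_a), is.na(df$exon_b))
  if (any(intr & !one_exon) || any(intr & df$gene == "")) {
    stop("validation error in ", origin,
         ": intragenic probes need one gene and exactly one exon index",
         call. = FALSE)
  }
  key <- paste(df$fusion_id, df$probe_type, df$gene, df$variant_id,
               df$exon_a, df$exon_b, sep = "\r")
  if (anyDuplicated(key)) {
    stop("validation error in ", origin,
         ": duplicated (fusion, type, variant, exon) annotation",
         call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("probe_annotation", "data.frame")
  df
}

#' @rdname load_annotations
#' @param annotations A \code{probe_annotation}.
#' @export
write_annotations <- function(annotations, path) {
  df <- as.data.frame(annotations)
  df$exon_a <- ifelse(is.na(df$exon_a), "", as.character(df$exon_a))
  df$exon_b <- ifelse(is.na(df$exon_b), "", as.character(df$exon_b))
  write_tsv_plain(df[, c("probe_id", "fusion_id", "probe_type", "gene",
                         "variant_id", "exon_a", "exon_b")], path)
}

#' Load a per-sample probe intensity table
#'
#' Raw fluorescence intensities, one row per probe. Loading is strict: a
#' negative intensity or an annotated probe missing from the file is an
#' error (silent imputation could fabricate breakpoints).
#'
#' @param path Path to a two-column TSV (probe_id, intensity).
#' @param annotations Optional \code{probe_annotation}; when given, every
#'   annotated probe must be present.
#' @param sample_id Sample label; defaults to the file name.
#' @return A data.frame of class \code{"intensity_table"} with columns
#'   probe_id, intensity and a \code{sample_id} attribute.
#' @export
load_intensities <- function(path, annotations = NULL,
                             sample_id = basename(path)) {
  df <- read_tsv_strict(path, c("probe_id", "intensity"))
  df$intensity <- suppressWarnings(as.numeric(df$intensity))
  intensity_table(df$probe_id, df$intensity, sample_id = sample_id,
                  annotations = annotations, origin = path)
}

#' @rdname load_intensities
#' @param probe_id,intensity Vectors building the table in memory.
#' @param origin Label used in error messages.
#' @export
intensity_table <- function(probe_id, intensity, sample_id = "sample",
                            annotations = NULL, origin = "intensities") {
  if (length(probe_id) == 0L) {
    stop("value error in ", origin, ": empty intensity table", call. = FALSE)
  }
  if (any(is.na(intensity))) {
    stop("value error in ", origin, ": non-numeric intensity", call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop("value error in ", origin, ": negative intensity for probe(s) ",
         paste(utils::head(probe_id[intensity < 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(probe_id)) {
    stop("value error in ", origin, ": duplicated probe_id", call. = FALSE)
  }
  df <- data.frame(probe_id = as.character(probe_id),
                   intensity = as.numeric(intensity),
                   stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    absent <- setdiff(unique(annotations$probe_id), df$probe_id)
    if (length(absent) > 0L) {
      stop("missing-probe error in ", origin, ": ",
           length(absent), " annotated probe(s) absent: ",
           paste(utils::head(absent, 10L), collapse = ", "),
           if (length(absent) > 10L) ", ..." else "", call. = FALSE)
    }
  }
  attr(df, "sample_id") <- sample_id
  class(df) <- c("intensity_table", "data.frame")
  df
}

#' @rdname load_intensities
#' @export
write_intensities <- function(intensities, path) {
  df <- data.frame(probe_id = intensities$probe_id,
                   intensity = fmt_num(intensities$intensity))
  write_tsv_plain(df, path)
}

#' Write a ranked fusion report
#'
#' @param results A \code{fusion_screen} object or the ranked results
#'   data.frame it contains (columns rank, fusion_id, fusion_score, exon_a,
#'   exon_b, chimeric_value, break_score_a, break_score_b, tags).
#' @param path Output TSV path.
#' @return The path, invisibly. Re-running on the same input produces a
#'   byte-identical file.
#' @export
write_report <- function(results, path) {
  if (inherits(results, "fusion_screen")) results <- results$results
  cols <- c("rank", "fusion_id", "fusion_score", "exon_a", "exon_b",
            "chimeric_value", "break_score_a", "break_score_b", "tags")
  stopifnot(all(cols %in% names(results)))
  df <- results[order(results$rank), cols]
  for (cc in c("fusion_score", "chimeric_value", "break_score_a",
               "break_score_b")) {
    df[[cc]] <- fmt_num(df[[cc]])
  }
  df$exon_a <- ifelse(is.na(df$exon_a), "", as.character(df$exon_a))
  df$exon_b <- ifelse(is.na(df$exon_b), "", as.character(df$exon_b))
  write_tsv_plain(df, path)
  invisible(path)
}
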