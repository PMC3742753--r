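test_that("probe counts follow the n_A + n_B and n_A x n_B formulas", {
  fa_a <- tempfile(fileext = ".fa"); fa_b <- tempfile(fileext = ".fa")
  write_exon_fasta(fa_a, "GA", "v1", c(80, 120), seed = 1)
  write_exon_fasta(fa_b, "GB", "v1", c(90, 70, 150), seed = 2)
  cand <- data.frame(fusion_id = "GA-GB", gene_a = "GA", variant_a = "v1",
                     n_exons_a = 2L, gene_b = "GB", variant_b = "v1",
                     n_exons_b = 3L, stringsAsFactors = FALSE)
  d <- design_probes(fa_a, fa_b, cand)
  ann <- d$annotation
  expect_equal(sum(ann$probe_type == "intragenic"), 5L)
  expect_equal(sum(ann$probe_type == "chimeric"), 6L)
  expect_equal(length(d$probes), 11L)

  # 13- and 10-exon partners -> 130 chimeric probes (13 x 10 heatmap)
  fa_c <- tempfile(fileext = ".fa"); fa_d <- tempfile(fileext = ".fa")
  write_exon_fasta(fa_c, "GC", "v1", rep(100, 13), seed = 3)
  write_exon_fasta(fa_d, "GD", "v1", rep(100, 10), seed = 4)
  cand2 <- data.frame(fusion_id = "GC-GD", gene_a = "GC", variant_a = "v1",
                      n_exons_a = 13L, gene_b = "GD", variant_b = "v1",
                      n_exons_b = 10L, stringsAsFactors = FALSE)
  d2 <- design_probes(fa_c, fa_d, cand2)
  expect_equal(sum(d2$annotation$probe_type == "chimeric"), 130L)
})

test_that("chimeric probes are suffix(exon_i of A) + prefix(exon_j of B)", {
  fa_a <- tempfile(fileext = ".fa"); fa_b <- tempfile(fileext = ".fa")
  writeLines(c(">GA|v1|1", "ACGTACGT"), fa_a)
  writeLines(c(">GB|v1|1", "TTTTGGGG"), fa_b)
  cand <- data.frame(fusion_id = "GA-GB", gene_a = "GA", variant_a = "v1",
                     n_exons_a = 1L, gene_b = "GB", variant_b = "v1",
                     n_exons_b = 1L, stringsAsFactors = FALSE)
  d <- design_probes(fa_a, fa_b, cand,
                     design_config(arm_length = 10)) # arm > exon: full exon
  chim <- as.character(d$probes[["CH|GA-GB|v1|v1|1-1"]])
  expect_equal(chim, "ACGTACGTTTTTGGGG")

  # regeneration property over random exon sets, including short exons
  fa_c <- tempfile(fileext = ".fa"); fa_d <- tempfile(fileext = ".fa")
  sa <- write_exon_fasta(fa_c, "GC", "v1", c(12, 60, 45), seed = 5)
  sb <- write_exon_fasta(fa_d, "GD", "v1", c(33, 100), seed = 6)
  cand2 <- data.frame(fusion_id = "GC-GD", gene_a = "GC", variant_a = "v1",
                      n_exons_a = 3L, gene_b = "GD", variant_b = "v1",
                      n_exons_b = 2L, stringsAsFactors = FALSE)
  cfg <- design_config(arm_length = 25)
  d2 <- design_probes(fa_c, fa_d, cand2, cfg)
  for (i in 1:3) {
    for (j in 1:2) {
      suffix <- substr(sa[i], max(1, nchar(sa[i]) - 24), nchar(sa[i]))
      prefix <- substr(sb[j], 1, min(25, nchar(sb[j])))
      expect_equal(
        as.character(d2$probes[[sprintf("CH|GC-GD|v1|v1|%d-%d", i, j)]]),
        paste0(suffix, prefix))
    }
  }
})

test_that("designed annotations round-trip and assemble end to end", {
  fa_a <- tempfile(fileext = ".fa"); fa_b <- tempfile(fileext = ".fa")
  write_exon_fasta(fa_a, "GENEA", "v1", rep(100, 5), seed = 7)
  write_exon_fasta(fa_b, "GENEB", "v1", rep(100, 4), seed = 8)
  panel <- toy_panel()[1, ]   # TOY1: GENEA (5 exons) + GENEB (4 exons)
  d <- design_probes(fa_a, fa_b, panel)

  f <- tempfile(fileext = ".tsv")
  write_annotations(d$annotation, f)
  ann <- load_annotations(f)
  expect_equal(ann, d$annotation)

  it <- intensity_table(names(d$probes), rep(200, length(d$probes)),
                        annotations = ann)
  asm <- assemble(it, ann, "TOY1")
  expect_equal(dim(asm[[1]]$heatmap$matrix), c(5L, 4L))
})

test_that("degenerate design inputs are rejected", {
  fa_a <- tempfile(fileext = ".fa"); fa_b <- tempfile(fileext = ".fa")
  writeLines(c(">GA|v1|1", "NNNNNNNNNNNNNNNNNNNN"), fa_a)
  writeLines(c(">GB|v1|1", "ACGTACGTACGTACGTACGT"), fa_b)
  cand <- data.frame(fusion_id = "GA-GB", gene_a = "GA", variant_a = "v1",
                     n_exons_a = 1L, gene_b = "GB", variant_b = "v1",
                     n_exons_b = 1L, stringsAsFactors = FALSE)
  expect_error(design_probes(fa_a, fa_b, cand), "non-N")

  # missing exon record
  cand2 <- cand; cand2$n_exons_b <- 2L
  writeLines(c(">GA|v1|1", "ACGTACGTACGTACGTACGT"), fa_a)
  expect_error(design_probes(fa_a, fa_b, cand2), "expected 2 exon")
})
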