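# Shared fixtures, built in code at test time.

toy_panel <- function() {
  load_panel(system.file("extdata", "toy_panel.tsv", package = "fusionchip"))
}

sarcoma_panel <- function() {
  load_panel(system.file("extdata", "sarcoma_panel_synthetic.tsv",
                         package = "fusionchip"))
}

# deterministic exon FASTA for probe-design tests
write_exon_fasta <- function(path, gene, variant, lengths, seed = 1) {
  set.seed(seed)
  seqs <- vapply(lengths, function(w) {
    paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("%s|%s|%d", gene, variant, seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  seqs
}

# multiply selected probes' intensities by 2^log2_boost
spike_probes <- function(intensities, probe_ids, log2_boost) {
  i <- match(probe_ids, intensities$probe_id)
  stopifnot(!anyNA(i))
  intensities$intensity[i] <- intensities$intensity[i] * 2^log2_boost
  intensities
}
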