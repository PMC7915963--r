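# Small in-code fixtures shared across tests.

tiny_batch <- function(seed = 42, n_transcripts = 8, n_reads = 2000,
                       read_length = 100, error_rate = 0.005, rate = 0.02) {
  prof <- c("3FTx" = 0.6, kunitz = 0.3, PLA2 = 0.1)
  t1 <- generate_transcriptome(n_transcripts, prof, mean_length = 600,
                               seed = seed, species_id = "spA")
  t2 <- generate_transcriptome(n_transcripts, prof, mean_length = 600,
                               seed = seed + 1000, species_id = "spB")
  r1 <- simulate_reads(t1, n_reads, read_length, error_rate, seed = seed + 1)
  r2 <- simulate_reads(t2, n_reads, read_length, error_rate, seed = seed + 2)
  list(tsets = list(spA = t1, spB = t2),
       batch = spike_contamination(list(r1, r2), rate, seed = seed + 3))
}

# a read set built directly from explicit sequences
manual_reads <- function(seqs, sample_id = "S") {
  read_set(sample_id, read_id = sprintf("r%03d", seq_along(seqs)),
           sequence = seqs, quality = strrep("I", nchar(seqs)),
           true_source = sample_id)
}
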