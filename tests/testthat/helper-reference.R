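# Reconstructs the cytology reference panel from its published per-class
# counts: 83 diploids (77 with simplex/triplex frequency in the 0-15%
# window, 6 off-type at 24-41%), 27 tetraploids (26 at 22-42%, one
# off-type at 0%), and 2 triploids -- 112 reference samples in all.
# Chloroplast counts place 74 of the 83 diploids in the 7-8 window and 9
# in the 9-10 grey area; 26 of 27 tetraploids fall at 12-14.
reference_panel_fixture <- function() {
  st_dip <- c(seq(0, 0.12, length.out = 77), seq(0.24, 0.41, length.out = 6))
  st_tet <- c(seq(0.22, 0.42, length.out = 26), 0)
  st_tri <- c(0.16, 0.18)
  ids <- sprintf("R%03d", seq_len(112))
  st <- c(st_dip, st_tet, st_tri)
  chrom <- c(rep(24, 83), rep(48, 27), rep(36, 2))
  chl <- c(seq(7.0, 8.4, length.out = 74), seq(8.6, 9.8, length.out = 9),
           seq(11.6, 14.4, length.out = 26), 10,
           c(9.5, 10.5))
  calls <- data.frame(sample_id = ids, st_freq = st,
                      call = classify_ploidy(st),
                      stringsAsFactors = FALSE)
  metadata <- sample_metadata(data.frame(
    sample_id = ids, chromosome_count = chrom, chloroplast_count = chl,
    stringsAsFactors = FALSE))
  list(calls = calls, metadata = metadata)
}
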