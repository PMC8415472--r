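# Programmatic fixtures shared across test files.

# A random number string: random residues (plus optional gaps) encoded
# under one property.
rand_numstring <- function(L, property = "volume", gap_frac = 0, seed = 1) {
  set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  chars <- sample(aa, L, replace = TRUE)
  if (gap_frac > 0) {
    chars[sample(L, round(gap_frac * L))] <- "-"
  }
  as.numeric(encode_sequence(paste(chars, collapse = ""), property))
}

# Write a tiny Clustal-format alignment (with a conservation line).
write_clustal_fixture <- function(path) {
  writeLines(c(
    "CLUSTAL O(1.2.4) multiple sequence alignment",
    "",
    "taxA      GAVL-KDERS",
    "taxB      GAVLWKDERS",
    "taxC      GTVL-KDEHS",
    "          * **  *** "
  ), path)
  path
}

# Write a small aligned FASTA.
write_fasta_fixture <- function(path, seqs) {
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  }
  close(con)
  path
}
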