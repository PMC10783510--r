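# Reference data for the CEB25 oligonucleotide family: the ten printed
# sequences with their published classic G4Hunter scores (2 decimals) and
# N statistics. The frozen strings double-check ceb_family()'s
# programmatic construction character-for-character.
CEB_TABLE <- data.frame(
  id = c("CEBwt", "CEBm0A", "CEBm0T", "CEBm1", "CEBm2", "CEBm3", "CEBm4",
         "CEBm5", "CEBm6", "CEBm7"),
  seq = c("AAGGGTGGGTGTAAGTGTGGGTGGGT",
          "AAGGGTGGGTAAAAAAATGGGTGGGT",
          "AAGGGTGGGTTTTATTTTGGGTGGGT",
          "AAGGGTGGGTCCCAGTGTGGGTGGGT",
          "AAGGGTGGGTCCCACTGTGGGTGGGT",
          "AAGGGTGGGTCCCACCGTGGGTGGGT",
          "AAGGGTGGGTCCCACCCTGGGTGGGT",
          "AAGGGTGGGTCCCACCCTGGGTGGGTCCCA",
          "AAGGGTGGGTCCCAGTGTGGGTGGGTCCCACCCA",
          "AAGGGTGGGTCCCACCCTGGGTGGGTCCCACCCA"),
  length = c(rep(26L, 7), 30L, 34L, 34L),
  g4h = c(1.50, 1.38, 1.38, 1.12, 1.04, 0.92, 0.69, 0.30, 0.32, 0.00),
  n = c(0, 0, 0, 1, 1.33, 1.67, 2, 3, 3, 4),
  regime = c("g4_locked", "g4_locked", "g4_locked", "g4_locked",
             "switchable", "switchable", "switchable",
             "hairpin_locked", "hairpin_locked", "hairpin_locked"),
  stringsAsFactors = FALSE)

ceb_seq <- function(id) CEB_TABLE$seq[CEB_TABLE$id == id]

rand_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}
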