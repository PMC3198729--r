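# Published guide strands (antisense, 5'->3', RNA core without the dTdT
# overhang) and the RACE adapter; these anchor the sequence-regeneration
# tests.
PUBLISHED_GUIDES <- c(
  p3 = "GCUGUAGUCAGCAAUCUUU",
  p4 = "UGCUGUAGUCAGCAAUCUU",
  p5 = "AUGCUGUAGUCAGCAAUCU",
  p1314 = "UUGUCUUUCCUGGCGCUUC"
)
RACE_ADAPTER <- "ACACUCUUUCCCUACACGACGCUCUUCCGAUCU"

# Independent reverse-complement oracle: base-by-base, no Biostrings.
oracle_revcomp_rna <- function(x) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

random_locus <- function(len = 120L, seed = NULL) {
  simulate_locus(length = len, seed = seed)
}
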