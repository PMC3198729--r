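#' Simulate a random transcript with one SNV
#'
#' Generates a uniform-random sense transcript and places a single variant
#' in it. The defaults (300 nt, SNV at the midpoint) leave ample flank for
#' 19-23-nt guide windows and 52-nt reporter inserts at every alignment
#' position.
#'
#' @param length Transcript length in nt.
#' @param snv_position 1-based variant position; midpoint by default.
#' @param mut_base Mutant base; a random base differing from the wild type
#'   by default. The wild-type base is whatever the random sequence carries
#'   at `snv_position`.
#' @param transcript_id Label.
#' @param alphabet `"RNA"` (default; sense mRNA) or `"DNA"`.
#' @param seed Optional RNG seed.
#' @return An `allele_locus`.
#' @export
simulate_locus <- function(length = 300L, snv_position = NULL, mut_base = NULL,
                           transcript_id = "synthetic", alphabet = "RNA",
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  length <- as.integer(length)
  stopifnot(length >= 1L)
  alphabet <- match.arg(alphabet, c("RNA", "DNA"))
  bases <- if (alphabet == "RNA") RNA_BASES else DNA_BASES
  s <- paste(sample(bases, length, replace = TRUE), collapse = "")
  if (is.null(snv_position)) snv_position <- as.integer(ceiling(length / 2))
  wt <- substr(s, snv_position, snv_position)
  if (is.null(mut_base)) mut_base <- sample(setdiff(bases, wt), 1L)
  allele_locus(transcript_id, nt_sequence(s, alphabet), snv_position, wt, mut_base)
}

#' Reconstructed benchmark loci for the two Parkinson's disease variants
#'
#' Synthetic loci that embed the target regions reconstructed (by reverse
#' complement) from published allele-specific siRNA guide strands, padded
#' with random flanking sequence so that every alignment position and
#' insert width is in range. Only the embedded window is authentic
#' published-derived sequence; the flanks are synthetic, which is why the
#' constructors carry the `synthetic_` prefix.
#'
#' \describe{
#'   \item{`synthetic_locus_a30p()`}{alpha-synuclein A30P: a G>C change on
#'     the sense mRNA, creating a G:G purine:purine primary mismatch
#'     between a mutant-targeting guide and the wild-type allele. Embeds
#'     the 19-nt mutant window `GAAGCACCAGGAAAGACAA` (SNV at window
#'     offset 7).}
#'   \item{`synthetic_locus_g2019s()`}{LRRK2 G2019S: a G>A change on the
#'     sense mRNA (6055G>A in the CDS), creating a G:U wobble primary
#'     mismatch against the wild type. Embeds the 21-nt mutant region
#'     `AAAGAUUGCUGACUACAGCAU` (SNV at region offset 17).}
#' }
#'
#' @param flank5,flank3 Random flank lengths added either side of the
#'   embedded window.
#' @param seed Optional RNG seed for the flanks.
#' @return An `allele_locus` whose stored sequence is the wild-type allele.
#' @export
synthetic_locus_a30p <- function(flank5 = 60L, flank3 = 60L, seed = NULL) {
  embed_window_locus("SNCA_A30P_synthetic", "GAAGCACCAGGAAAGACAA",
                     snv_offset = 7L, wt_base = "G",
                     flank5 = flank5, flank3 = flank3, seed = seed)
}

#' @rdname synthetic_locus_a30p
#' @export
synthetic_locus_g2019s <- function(flank5 = 60L, flank3 = 60L, seed = NULL) {
  embed_window_locus("LRRK2_G2019S_synthetic", "AAAGAUUGCUGACUACAGCAU",
                     snv_offset = 17L, wt_base = "G",
                     flank5 = flank5, flank3 = flank3, seed = seed)
}

# mutant_window carries the mutant base at snv_offset; the locus stores the
# wild-type allele, so the embedded window is reverted at the SNV.
embed_window_locus <- function(transcript_id, mutant_window, snv_offset,
                               wt_base, flank5, flank3, seed) {
  if (!is.null(seed)) set.seed(seed)
  mut_base <- substr(mutant_window, snv_offset, snv_offset)
  wt_window <- mutant_window
  substr(wt_window, snv_offset, snv_offset) <- wt_base
  f5 <- paste(sample(RNA_BASES, flank5, replace = TRUE), collapse = "")
  f3 <- paste(sample(RNA_BASES, flank3, replace = TRUE), collapse = "")
  allele_locus(transcript_id, nt_sequence(paste0(f5, wt_window, f3), "RNA"),
               snv_position = flank5 + snv_offset, wt_base = wt_base,
               mut_base = mut_base)
}
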