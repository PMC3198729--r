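U6_PRIMER_5P <- "AAAAAA"
U6_PRIMER_LOOP_SEGMENT <- "TGGGTCAGG"
U6_PRIMER_3P <- "GGTGTTTCGTCCTTTCCACAA"

#' siRNA duplex for a design
#'
#' Renders the design as an orderable siRNA duplex: a guide (antisense)
#' strand of the L-nt RNA core plus a 3' deoxy dTdT overhang, and a
#' passenger (sense) strand that is the exact reverse complement of the
#' guide core - fully paired including at any secondary-mismatch position -
#' with its own dTdT overhang.
#'
#' @param design An `antisense_design`.
#' @return An object of class `sirna_duplex` with mixed-notation strands
#'   (e.g. `"UGCUGUAGUCAGCAAUCUUdTdT"`).
#' @export
sirna_duplex <- function(design) {
  stopifnot(inherits(design, "antisense_design"))
  guide_core <- design$guide
  passenger_core <- reverse_complement(guide_core)
  structure(list(design_id = design$design_id,
                 guide_core = guide_core,
                 passenger_core = passenger_core,
                 guide_strand = paste0(as.character(guide_core), "dTdT"),
                 passenger_strand = paste0(as.character(passenger_core), "dTdT"),
                 core_length = design$L),
            class = "sirna_duplex")
}

#' @export
print.sirna_duplex <- function(x, ...) {
  cat(sprintf("<sirna_duplex '%s'> %d-mer core + dTdT\n", x$design_id, x$core_length))
  cat("  guide     5'-", x$guide_strand, "-3'\n", sep = "")
  cat("  passenger 5'-", x$passenger_strand, "-3'\n", sep = "")
  invisible(x)
}

#' U6 reverse primer and predicted hairpin transcript
#'
#' Assembles the PCR reverse primer that appends a Pol-III short hairpin to
#' a U6 promoter template, following the five-segment scaffold
#' `5'-AAAAAA ..slotA.. TGGGTCAGG ..slotS.. GGTGTTTCGTCCTTTCCACAA-3'`, and
#' predicts the expressed hairpin transcript
#' `sense_arm + loop + antisense_arm + U-tract` with the antisense (guide)
#' species in the 3' arm.
#'
#' Because this is a reverse primer, each transcript segment appears in the
#' primer as its DNA reverse complement in reverse order. Under the default
#' `slot_mode = "architecture"` the slot contents are derived from that
#' geometry so the expressed hairpin really does carry the guide in its 3'
#' arm: slotA (the slot conventionally labelled "antisense") receives the
#' DNA reverse complement of the antisense arm, slotS receives the DNA form
#' of the guide, and the loop transcribes as the reverse complement of the
#' scaffold's fixed TGGGTCAGG segment (CCUGACCCA by default). The literal
#' reading of the slot labels - guide DNA pasted directly into slotA, which
#' would place the antisense species in the 5' arm - is available as
#' `slot_mode = "literal"`; both readings are noted in the object because
#' the scaffold's labels and the stated 3'-arm architecture cannot both be
#' taken at face value.
#'
#' @param design An `antisense_design`.
#' @param loop_rna Loop sequence of the predicted transcript (RNA 9-mer).
#'   The scaffold's fixed middle primer segment is its DNA reverse
#'   complement, so the default `"CCUGACCCA"` reproduces `TGGGTCAGG`.
#' @param slot_mode `"architecture"` (default) or `"literal"`; see Details.
#' @param terminator_us Template-encoded U count rendered at the transcript
#'   3' end (Pol-III terminator).
#' @param overhang_us Typical U overhang retained after Pol-III termination,
#'   recorded as metadata only.
#' @return An object of class `hairpin_construct`.
#' @export
u6_primer <- function(design, loop_rna = "CCUGACCCA",
                      slot_mode = c("architecture", "literal"),
                      terminator_us = 6L, overhang_us = 2L) {
  stopifnot(inherits(design, "antisense_design"))
  slot_mode <- match.arg(slot_mode)
  loop <- as_nt(loop_rna, "RNA")
  guide_rna <- as.character(design$guide)
  sense_arm_rna <- as.character(reverse_complement(design$guide))
  guide_dna <- as.character(convert_alphabet(design$guide, "DNA"))
  sense_arm_dna <- as.character(convert_alphabet(nt_sequence(sense_arm_rna, "RNA"), "DNA"))
  loop_segment <- as.character(convert_alphabet(reverse_complement(loop), "DNA"))
  if (slot_mode == "architecture") {
    slot_a <- sense_arm_dna   # reverse complement of the antisense arm, per reverse-primer geometry
    slot_s <- guide_dna
    transcript <- paste0(sense_arm_rna, as.character(loop), guide_rna,
                         strrep("U", terminator_us))
  } else {
    slot_a <- guide_dna
    slot_s <- sense_arm_dna
    transcript <- paste0(guide_rna, as.character(loop), sense_arm_rna,
                         strrep("U", terminator_us))
  }
  primer <- paste0(U6_PRIMER_5P, slot_a, loop_segment, slot_s, U6_PRIMER_3P)
  structure(list(design_id = design$design_id,
                 u6_reverse_primer = nt_sequence(primer, "DNA"),
                 predicted_transcript = nt_sequence(transcript, "RNA"),
                 loop_rna = loop,
                 slot_mode = slot_mode,
                 terminator_us = as.integer(terminator_us),
                 overhang_us = as.integer(overhang_us),
                 design_ref = design),
            class = "hairpin_construct")
}

#' @export
print.hairpin_construct <- function(x, ...) {
  cat(sprintf("<hairpin_construct '%s'> slot mode: %s\n", x$design_id, x$slot_mode))
  cat("  U6 reverse primer 5'-", as.character(x$u6_reverse_primer), "-3'\n", sep = "")
  cat("  predicted transcript 5'-", as.character(x$predicted_transcript),
      "-3'\n", sep = "")
  cat(sprintf("  (Pol-III termination typically leaves ~%d 3' U overhang)\n",
              x$overhang_us))
  invisible(x)
}

#' Dual-luciferase reporter target insert
#'
#' Extracts a sense-strand target window (52 nt by default) surrounding the
#' SNV for one allele and renders annealing oligos with XhoI/NotI-compatible
#' sticky ends for directional cloning 3' of a Renilla luciferase gene. For
#' an even width the window carries `width/2` nt of 5' flank and
#' `width/2 - 1` nt of 3' flank (SNV at window position 27 for width 52).
#' The wild-type and mutant inserts for one locus differ at exactly the SNV.
#'
#' @param locus An `allele_locus`.
#' @param allele `"wt"` or `"mut"`.
#' @param width Window width in nt; must be at least `min_guide_length`.
#' @param min_guide_length Shortest guide the insert must be able to screen.
#' @return An object of class `luciferase_insert`.
#' @export
luciferase_insert <- function(locus, allele = c("wt", "mut"), width = 52L,
                              min_guide_length = 19L) {
  stopifnot(inherits(locus, "allele_locus"))
  allele <- match.arg(allele)
  width <- as.integer(width)
  if (width < min_guide_length) {
    stop("insert width ", width, " is shorter than the guide length ",
         min_guide_length, " it must accommodate")
  }
  flank5 <- as.integer(ceiling((width - 1L) / 2))
  flank3 <- width - 1L - flank5
  snv <- locus$snv_position
  ws <- snv - flank5; we <- snv + flank3
  if (ws < 1L || we > nchar(locus$sense_sequence)) {
    stop(sprintf("insufficient flank for a %d-nt insert: need sense positions %d..%d, transcript spans 1..%d",
                 width, ws, we, nchar(locus$sense_sequence)))
  }
  window_dna <- convert_alphabet(
    nt_sequence(substr(as.character(allele_sequence(locus, allele)), ws, we),
                seq_alphabet(locus$sense_sequence)), "DNA")
  bottom_core <- as.character(reverse_complement(window_dna))
  structure(list(allele = allele,
                 window = window_dna,
                 window_start = ws, window_end = we,
                 snv_offset = flank5 + 1L,
                 width = width,
                 top_oligo = paste0("TCGAG", as.character(window_dna), "GC"),
                 bottom_oligo = paste0("GGCCGC", bottom_core, "C"),
                 transcript_id = locus$transcript_id),
            class = "luciferase_insert")
}

#' @export
print.luciferase_insert <- function(x, ...) {
  cat(sprintf("<luciferase_insert> %s allele, %d nt window %s:%d-%d (SNV at window position %d)\n",
              x$allele, x$width, x$transcript_id, x$window_start,
              x$window_end, x$snv_offset))
  cat("  top    5'-", x$top_oligo, "-3'  (XhoI end)\n", sep = "")
  cat("  bottom 5'-", x$bottom_oligo, "-3'  (NotI end)\n", sep = "")
  invisible(x)
}

#' Matched wild-type/mutant reporter insert pair
#'
#' @inheritParams luciferase_insert
#' @return List with elements `wt` and `mut`.
#' @export
luciferase_insert_pair <- function(locus, width = 52L, min_guide_length = 19L) {
  list(wt = luciferase_insert(locus, "wt", width, min_guide_length),
       mut = luciferase_insert(locus, "mut", width, min_guide_length))
}

#' Oligo order sheet
#'
#' Flattens constructs ([sirna_duplex()], [u6_primer()],
#' [luciferase_insert()]) into a TSV-ready table of orderable strands.
#' siRNA strands are listed in mixed notation (RNA core + dTdT); primers and
#' reporter oligos are DNA.
#'
#' @param constructs A construct object or list of them.
#' @return `data.frame` with columns `construct_id`, `strand`,
#'   `sequence_dna`, `length`.
#' @export
oligo_sheet <- function(constructs) {
  if (!is.list(constructs) || !is.null(attr(constructs, "class"))) {
    constructs <- list(constructs)
  }
  rows <- lapply(constructs, function(x) {
    if (inherits(x, "sirna_duplex")) {
      data.frame(construct_id = x$design_id,
                 strand = c("guide", "passenger"),
                 sequence_dna = c(x$guide_strand, x$passenger_strand),
                 stringsAsFactors = FALSE)
    } else if (inherits(x, "hairpin_construct")) {
      data.frame(construct_id = x$design_id,
                 strand = "u6_reverse_primer",
                 sequence_dna = as.character(x$u6_reverse_primer),
                 stringsAsFactors = FALSE)
    } else if (inherits(x, "luciferase_insert")) {
      data.frame(construct_id = paste0(x$transcript_id, "_", x$allele, "_insert"),
                 strand = c("top", "bottom"),
                 sequence_dna = c(x$top_oligo, x$bottom_oligo),
                 stringsAsFactors = FALSE)
    } else {
      stop("unsupported construct of class ", paste(class(x), collapse = "/"))
    }
  })
  out <- do.call(rbind, rows)
  out$length <- nchar(out$sequence_dna)
  rownames(out) <- NULL
  out
}
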