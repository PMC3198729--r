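#' @importFrom stats sd var setNames
#' @importFrom utils read.delim write.table
NULL

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

#' Nucleotide sequence with a declared alphabet
#'
#' Lightweight container for a single nucleotide sequence read 5'->3'.
#' Only concrete bases are accepted: `A`, `C`, `G` and `U` for RNA or `T`
#' for DNA. IUPAC ambiguity codes are rejected because every downstream
#' design rule is defined only on concrete bases. Input is case-insensitive;
#' the canonical form is uppercase.
#'
#' @param bases Single character string of bases, 5'->3'.
#' @param alphabet `"RNA"`, `"DNA"`, or `NULL` to auto-detect (presence of
#'   `U` implies RNA, of `T` implies DNA; a sequence with neither defaults
#'   to `default_alphabet`).
#' @param default_alphabet Alphabet used when auto-detection is inconclusive.
#' @return An object of class `nt_sequence`: a character string with an
#'   `alphabet` attribute.
#' @examples
#' nt_sequence("ugcuguagucagcaaucuu")
#' nt_sequence("ACGT")
#' @export
nt_sequence <- function(bases, alphabet = NULL, default_alphabet = "DNA") {
  stopifnot(is.character(bases), length(bases) == 1L, !is.na(bases))
  bases <- toupper(gsub("[[:space:]]", "", bases))
  has_u <- grepl("U", bases, fixed = TRUE)
  has_t <- grepl("T", bases, fixed = TRUE)
  if (has_u && has_t) {
    stop("sequence contains both U and T; RNA and DNA alphabets cannot be mixed")
  }
  if (is.null(alphabet)) {
    alphabet <- if (has_u) "RNA" else if (has_t) "DNA" else
      match.arg(default_alphabet, c("DNA", "RNA"))
  }
  alphabet <- match.arg(alphabet, c("RNA", "DNA"))
  valid <- if (alphabet == "RNA") RNA_BASES else DNA_BASES
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% valid)
  if (length(bad) > 0L) {
    stop(sprintf("invalid %s base '%s' at position %d", alphabet,
                 chars[bad[1L]], bad[1L]))
  }
  structure(bases, alphabet = alphabet, class = "nt_sequence")
}

as_nt <- function(x, alphabet = NULL) {
  if (inherits(x, "nt_sequence")) {
    if (!is.null(alphabet) && attr(x, "alphabet") != alphabet) {
      return(convert_alphabet(x, alphabet))
    }
    return(x)
  }
  s <- nt_sequence(as.character(x))
  if (!is.null(alphabet)) s <- convert_alphabet(s, alphabet)
  s
}

#' @export
print.nt_sequence <- function(x, ...) {
  cat(sprintf("<%s %d nt> 5'-%s-3'\n", attr(x, "alphabet"), nchar(x),
              as.character(x)))
  invisible(x)
}

#' @export
as.character.nt_sequence <- function(x, ...) {
  attributes(x) <- NULL
  x
}

#' Alphabet of a nucleotide sequence
#' @param s An `nt_sequence`.
#' @return `"RNA"` or `"DNA"`.
#' @export
seq_alphabet <- function(s) {
  stopifnot(inherits(s, "nt_sequence"))
  attr(s, "alphabet")
}

#' Reverse complement
#'
#' Returns the 5'->3' reverse complement in the same alphabet
#' (A-U or A-T, G-C). `reverse_complement()` is an involution.
#'
#' @param s An `nt_sequence` (or character string, auto-detected).
#' @return An `nt_sequence` in the same alphabet.
#' @examples
#' reverse_complement(nt_sequence("UGCUGUAGUCAGCAAUCUU"))
#' @export
reverse_complement <- function(s) {
  s <- as_nt(s)
  alph <- seq_alphabet(s)
  if (nchar(s) == 0L) return(s)
  x <- if (alph == "RNA") {
    Biostrings::reverseComplement(Biostrings::RNAString(as.character(s)))
  } else {
    Biostrings::reverseComplement(Biostrings::DNAString(as.character(s)))
  }
  nt_sequence(as.character(x), alphabet = alph)
}

#' Convert between RNA and DNA alphabets
#'
#' Swaps U and T; all other bases (and the strand reading direction) are
#' unchanged. Converting to the sequence's current alphabet is the identity.
#'
#' @param s An `nt_sequence`.
#' @param to Target alphabet, `"RNA"` or `"DNA"`.
#' @return An `nt_sequence` in the target alphabet.
#' @export
convert_alphabet <- function(s, to) {
  s <- as_nt(s)
  to <- match.arg(to, c("RNA", "DNA"))
  if (seq_alphabet(s) == to) return(s)
  out <- if (to == "RNA") chartr("T", "U", as.character(s))
         else chartr("U", "T", as.character(s))
  nt_sequence(out, alphabet = to)
}

#' Read a FASTA file
#'
#' Reads single- or multi-record FASTA. The alphabet of each record is
#' auto-detected (U implies RNA, T implies DNA, neither falls back to
#' `default_alphabet`); a record containing both U and T, characters
#' outside `{A,C,G,T,U}`, duplicate record ids, or an empty file are
#' all rejected.
#'
#' @param path Path to a FASTA file.
#' @param default_alphabet Alphabet assumed for records with neither U nor T.
#' @return Named list of `nt_sequence` objects; names are record ids (the
#'   first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path, default_alphabet = "DNA") {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("malformed or empty FASTA '", path,
                                            "': ", conditionMessage(e)))
  if (length(recs) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- lapply(seq_along(recs), function(i) {
    s <- as.character(recs[[i]])
    tryCatch(nt_sequence(s, default_alphabet = default_alphabet),
             error = function(e) stop("record '", ids[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param records Named list of `nt_sequence` objects (or a single one).
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "nt_sequence")) records <- list(seq1 = records)
  stopifnot(length(records) > 0L, !is.null(names(records)),
            all(nzchar(names(records))))
  set <- Biostrings::BStringSet(vapply(records, as.character, character(1L)))
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

#' A transcript with one single-nucleotide variant
#'
#' Couples a sense-strand transcript sequence (5'->3') with one SNV given as
#' a 1-based position, the wild-type base and the mutant base. The stored
#' sequence is the wild-type allele; [allele_sequence()] materialises either
#' allele. Construction fails unless the sequence actually carries the
#' stated wild-type base at the stated position.
#'
#' All coordinates in this package are 1-based and inclusive on the sense
#' strand.
#'
#' @param transcript_id Label for the transcript.
#' @param sense_sequence Sense mRNA or CDS as an `nt_sequence` or string.
#' @param snv_position 1-based position of the variant.
#' @param wt_base Wild-type base at that position.
#' @param mut_base Mutant base (must differ from `wt_base`).
#' @return An object of class `allele_locus`.
#' @examples
#' allele_locus("toy", "AAAGAUUGCUGACUACGGCAU", 17, "G", "A")
#' @export
allele_locus <- function(transcript_id, sense_sequence, snv_position,
                         wt_base, mut_base) {
  s <- as_nt(sense_sequence)
  snv_position <- as.integer(snv_position)
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            nzchar(transcript_id), length(snv_position) == 1L)
  if (snv_position < 1L || snv_position > nchar(s)) {
    stop("snv_position ", snv_position, " outside sequence of length ", nchar(s))
  }
  wt_base <- toupper(wt_base); mut_base <- toupper(mut_base)
  valid <- if (seq_alphabet(s) == "RNA") RNA_BASES else DNA_BASES
  if (!(wt_base %in% valid) || !(mut_base %in% valid)) {
    stop("wt_base/mut_base must be single ", seq_alphabet(s), " bases")
  }
  if (wt_base == mut_base) stop("wt_base and mut_base must differ")
  at <- substr(as.character(s), snv_position, snv_position)
  if (at != wt_base) {
    stop(sprintf("sense sequence has '%s' at position %d, not the stated wild-type base '%s'",
                 at, snv_position, wt_base))
  }
  structure(list(transcript_id = transcript_id, sense_sequence = s,
                 snv_position = snv_position, wt_base = wt_base,
                 mut_base = mut_base),
            class = "allele_locus")
}

#' @export
print.allele_locus <- function(x, ...) {
  cat(sprintf("<allele_locus '%s'> %d nt %s; SNV %d:%s>%s (1-based, sense strand)\n",
              x$transcript_id, nchar(x$sense_sequence),
              seq_alphabet(x$sense_sequence), x$snv_position, x$wt_base,
              x$mut_base))
  invisible(x)
}

#' Materialise one allele of a locus
#'
#' @param locus An `allele_locus`.
#' @param allele `"wt"` or `"mut"`.
#' @return The sense-strand `nt_sequence` of the requested allele.
#' @export
allele_sequence <- function(locus, allele = c("wt", "mut")) {
  stopifnot(inherits(locus, "allele_locus"))
  allele <- match.arg(allele)
  s <- as.character(locus$sense_sequence)
  if (allele == "mut") substr(s, locus$snv_position, locus$snv_position) <- locus$mut_base
  nt_sequence(s, alphabet = seq_alphabet(locus$sense_sequence))
}
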