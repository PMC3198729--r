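#' The 5'RACE RNA adapter
#'
#' RNA adapter with 5' and 3' hydroxyl groups used for ligation to 5'
#' phosphate-bearing cleavage fragments. Capped full-length mRNA lacks a 5'
#' phosphate and is not ligated, which restricts the library to RISC
#' degradation products.
#'
#' @return The 33-nt adapter as an RNA `nt_sequence`.
#' @export
race_adapter <- function() {
  nt_sequence("ACACUCUUUCCCUACACGACGCUCUUCCGAUCU", "RNA")
}

#' Simulate RISC cleavage of a targeted transcript
#'
#' RISC cleaves a fully complementary target at a fixed position relative
#' to the loaded guide. The convention is parameterised by `gstar`, the
#' guide position that pairs with the 5'-most nucleotide of the 3'
#' cleavage fragment; the default `gstar = 11` places the fragment's first
#' base opposite guide position 11 (the classical cut between the target
#' bases paired to guide positions 10 and 11 corresponds to `gstar = 10`
#' under this antiparallel mapping; see the package vignette).
#'
#' @param locus An `allele_locus` targeted by the design.
#' @param design The `antisense_design` directing cleavage.
#' @param gstar Guide position paired with the fragment's 5' nucleotide.
#' @param allele Which allele is cleaved (`"mut"`: the fully complementary
#'   target, by default).
#' @return The 3' cleavage fragment (transcript suffix bearing a 5'
#'   phosphate) as an RNA `nt_sequence`, with attribute `cut_site` giving
#'   the 1-based sense coordinate of its first base.
#' @export
simulate_cleavage <- function(locus, design, gstar = 11L, allele = "mut") {
  stopifnot(inherits(locus, "allele_locus"), inherits(design, "antisense_design"))
  gstar <- as.integer(gstar)
  if (gstar < 1L || gstar > design$L) stop("gstar must be in 1..", design$L)
  cut <- guide_target_position(design, gstar)
  full <- chartr("T", "U", as.character(allele_sequence(locus, allele)))
  frag <- nt_sequence(substr(full, cut, nchar(full)), "RNA")
  attr(frag, "cut_site") <- cut
  frag
}

#' Ligate the RACE adapter onto a cleavage fragment
#'
#' Produces a simulated 5'RACE read: adapter followed by the transcript
#' fragment, truncated to `read_length`. A capped molecule (no 5'
#' phosphate) cannot be ligated, so `capped = TRUE` yields no read
#' (`NULL`).
#'
#' @param fragment Non-empty RNA fragment (e.g. from [simulate_cleavage()]).
#' @param adapter Adapter sequence; the standard adapter by default.
#' @param read_length Maximum read length (adapter included).
#' @param capped Is the molecule 5'-capped (unligatable)?
#' @param read_id Identifier for the read.
#' @return A `race_read` (list with `read_id`, `sequence`, `source`), or
#'   `NULL` when `capped`.
#' @export
ligate_adapter <- function(fragment, adapter = race_adapter(),
                           read_length = 150L, capped = FALSE,
                           read_id = "read1") {
  if (capped) return(NULL)
  fragment <- as_nt(fragment, "RNA")
  if (nchar(fragment) == 0L) stop("cannot ligate to an empty fragment")
  adapter <- as_nt(adapter, "RNA")
  seqc <- substr(paste0(as.character(adapter), as.character(fragment)),
                 1L, as.integer(read_length))
  structure(list(read_id = read_id, sequence = nt_sequence(seqc, "RNA"),
                 source = "simulated"),
            class = "race_read")
}

#' Map the adapter:transcript junction of a 5'RACE read
#'
#' Locates the adapter as a prefix of the read (allowing up to
#' `max_mismatches` substitutions, none by default), then matches the
#' remaining read sequence - which must be at least `min_anchor` nt -
#' exactly against the transcript. A unique match yields a cleavage call at
#' the sense coordinate of the first transcript base; an absent adapter,
#' too-short anchor, or an anchor matching zero or multiple transcript
#' positions yields a no-call (`NULL`).
#'
#' @param read A `race_read`, `nt_sequence`, or character string.
#' @param transcript Transcript sequence searched (sense strand); typically
#'   the mutant allele from [allele_sequence()].
#' @param adapter Adapter expected at the read 5' end.
#' @param min_anchor Minimum transcript-matching anchor length.
#' @param max_mismatches Substitutions tolerated in the adapter prefix.
#' @param design Optional `antisense_design`; when supplied, the call is
#'   annotated with the guide position paired with the fragment's first
#'   base (`guide_alignment = window_end - coordinate + 1`).
#' @param transcript_id Label recorded in the call.
#' @return A `cleavage_call` (fields `read_id`, `transcript_id`,
#'   `transcript_coordinate`, `guide_alignment`, `junction_offset`,
#'   `support`) or `NULL` for a no-call.
#' @export
map_junction <- function(read, transcript, adapter = race_adapter(),
                         min_anchor = 12L, max_mismatches = 0L,
                         design = NULL, transcript_id = "transcript") {
  read_id <- if (inherits(read, "race_read")) read$read_id else "read1"
  seqc <- if (inherits(read, "race_read")) as.character(read$sequence)
          else as.character(as_nt(read, "RNA"))
  adapter <- as.character(as_nt(adapter, "RNA"))
  min_anchor <- as.integer(min_anchor)
  if (nchar(adapter) < min_anchor) {
    stop("adapter (", nchar(adapter), " nt) shorter than min_anchor (",
         min_anchor, ")")
  }
  tx <- as.character(as_nt(transcript, "RNA"))
  if (nchar(tx) == 0L) stop("empty transcript")
  alen <- nchar(adapter)
  if (nchar(seqc) < alen + min_anchor) return(NULL)
  prefix <- substr(seqc, 1L, alen)
  mm <- sum(strsplit(prefix, "")[[1]] != strsplit(adapter, "")[[1]])
  if (mm > max_mismatches) return(NULL)
  anchor <- substr(seqc, alen + 1L, nchar(seqc))
  hits <- gregexpr(anchor, tx, fixed = TRUE)[[1]]
  if (hits[1L] == -1L || length(hits) != 1L) return(NULL)
  coord <- as.integer(hits[1L])
  ga <- if (!is.null(design)) design$window_end - coord + 1L else NA_integer_
  structure(list(read_id = read_id, transcript_id = transcript_id,
                 transcript_coordinate = coord, guide_alignment = ga,
                 junction_offset = alen + 1L, support = 1L,
                 anchor_len = nchar(anchor)),
            class = "cleavage_call")
}

#' @export
print.cleavage_call <- function(x, ...) {
  cat(sprintf("<cleavage_call '%s'> %s:%d (sense, 1-based); guide alignment %s; anchor %d nt\n",
              x$read_id, x$transcript_id, x$transcript_coordinate,
              ifelse(is.na(x$guide_alignment), "NA", x$guide_alignment),
              x$anchor_len))
  invisible(x)
}

#' Aggregate cleavage calls by coordinate
#'
#' @param calls List of `cleavage_call` objects against one transcript
#'   (no-calls, i.e. `NULL` entries, are dropped).
#' @return `data.frame` with columns `transcript_coordinate`,
#'   `guide_alignment`, `support`, ordered by support descending then
#'   coordinate ascending.
#' @export
aggregate_calls <- function(calls) {
  calls <- Filter(Negate(is.null), calls)
  if (length(calls) == 0L) {
    return(data.frame(transcript_coordinate = integer(0),
                      guide_alignment = integer(0), support = integer(0)))
  }
  stopifnot(all(vapply(calls, inherits, logical(1L), "cleavage_call")))
  tids <- unique(vapply(calls, `[[`, character(1L), "transcript_id"))
  if (length(tids) != 1L) {
    stop("calls span multiple transcripts: ", paste(tids, collapse = ", "))
  }
  coords <- vapply(calls, `[[`, integer(1L), "transcript_coordinate")
  gas <- vapply(calls, `[[`, integer(1L), "guide_alignment")
  agg <- aggregate(list(support = coords), by = list(transcript_coordinate = coords),
                   FUN = length)
  agg$guide_alignment <- gas[match(agg$transcript_coordinate, coords)]
  agg <- agg[order(-agg$support, agg$transcript_coordinate),
             c("transcript_coordinate", "guide_alignment", "support")]
  rownames(agg) <- NULL
  agg
}

#' Simulate a set of 5'RACE reads for a design
#'
#' Convenience wrapper: simulate canonical cleavage of the mutant allele,
#' ligate the adapter, and emit `n` identical reads (plus optional capped
#' molecules, which produce no reads).
#'
#' @inheritParams simulate_cleavage
#' @inheritParams ligate_adapter
#' @param n Number of reads.
#' @return List of `race_read` objects.
#' @export
simulate_race_reads <- function(locus, design, n = 1L, gstar = 11L,
                                adapter = race_adapter(), read_length = 150L,
                                allele = "mut") {
  frag <- simulate_cleavage(locus, design, gstar = gstar, allele = allele)
  lapply(seq_len(n), function(i) {
    ligate_adapter(frag, adapter = adapter, read_length = read_length,
                   read_id = sprintf("%s_read%d", design$design_id, i))
  })
}
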