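#' Classify a target:guide base pairing
#'
#' Classifies an RNA base pair, written target_base:guide_base, into one of
#' five categories that drive allele-discrimination design:
#' \itemize{
#'   \item `WATSON_CRICK` - A:U, U:A, G:C, C:G;
#'   \item `WOBBLE_GU` - G:U and U:G, the near-canonical wobble and the
#'     weakest discriminating mismatch;
#'   \item `PURINE_PURINE` - both bases purines (e.g. G:G), the most
#'     disruptive class as two double-ring bases must face each other
#'     between the backbones of the A-form helix;
#'   \item `PYRIMIDINE_PYRIMIDINE` - both bases pyrimidines and not
#'     Watson-Crick (e.g. C:C, U:U);
#'   \item `PURINE_PYRIMIDINE_MM` - the remaining non-canonical
#'     purine/pyrimidine pairs, A:C and C:A.
#' }
#' The classification is total over all 16 ordered RNA pairs and its
#' category is symmetric in the two bases.
#'
#' @param target_base Single RNA base on the target (mRNA) side.
#' @param guide_base Single RNA base on the guide (antisense) side.
#' @return An object of class `mismatch_class` with fields `category` and
#'   `pair_label` (e.g. `"G:U"`).
#' @examples
#' classify_pair("G", "G")  # purine:purine
#' classify_pair("G", "U")  # wobble
#' @export
classify_pair <- function(target_base, guide_base) {
  tb <- check_rna_base(target_base, "target_base")
  gb <- check_rna_base(guide_base, "guide_base")
  wc <- c(A = "U", U = "A", G = "C", C = "G")
  purine <- c("A", "G")
  category <- if (wc[[tb]] == gb) {
    "WATSON_CRICK"
  } else if ((tb == "G" && gb == "U") || (tb == "U" && gb == "G")) {
    "WOBBLE_GU"
  } else if (tb %in% purine && gb %in% purine) {
    "PURINE_PURINE"
  } else if (!(tb %in% purine) && !(gb %in% purine)) {
    "PYRIMIDINE_PYRIMIDINE"
  } else {
    "PURINE_PYRIMIDINE_MM"
  }
  structure(list(category = category, pair_label = paste0(tb, ":", gb)),
            class = "mismatch_class")
}

check_rna_base <- function(b, what) {
  b <- toupper(as.character(b))
  if (length(b) != 1L || !nzchar(b)) stop(what, " must be a single base")
  if (b == "T") stop(what, " 'T' is a DNA base; pair classification is defined on RNA")
  if (!b %in% RNA_BASES) stop(what, " '", b, "' is not an RNA base")
  b
}

#' @export
print.mismatch_class <- function(x, ...) {
  cat(sprintf("<mismatch_class> %s (%s)\n", x$pair_label, x$category))
  invisible(x)
}

#' Mismatch-strength lookup table
#'
#' Loads an ordinal disruption score for every ordered target:guide RNA
#' pair. Watson-Crick pairs score 0; every mismatch scores > 0, larger
#' meaning more disruptive to guide:target pairing. The packaged default
#' (`default_strength_table()`) orders the classes G:U wobble < A:C/U:C <
#' U:U < C:C/purine:purine, with G:G strongest; the per-pair values are an
#' editorial ranking consistent with published single-mismatch
#' discrimination data, not measured free energies, and can be replaced by
#' supplying a custom two-column TSV (`pair`, `score`).
#'
#' @param path Path to a TSV with columns `pair` (e.g. `"G:U"`) and `score`.
#' @return A named numeric vector of class `strength_table` covering all 16
#'   ordered pairs, with a `provenance` attribute.
#' @export
read_strength_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("pair", "score") %in% names(df)))
  all_pairs <- as.vector(outer(RNA_BASES, RNA_BASES, paste, sep = ":"))
  if (!setequal(df$pair, all_pairs) || anyDuplicated(df$pair)) {
    stop("strength table must score each of the 16 ordered RNA pairs exactly once")
  }
  scores <- stats::setNames(as.numeric(df$score), df$pair)
  wc <- c("A:U", "U:A", "G:C", "C:G")
  if (any(scores[wc] != 0)) stop("Watson-Crick pairs must score 0")
  if (any(scores[setdiff(all_pairs, wc)] <= 0)) {
    stop("every non-Watson-Crick pair must score > 0")
  }
  first <- readLines(path, n = 1L)
  attr(scores, "provenance") <- if (startsWith(first, "#")) sub("^#\\s*", "", first) else ""
  class(scores) <- "strength_table"
  scores
}

#' @rdname read_strength_table
#' @export
default_strength_table <- function() {
  read_strength_table(system.file("extdata", "strength_table.tsv",
                                  package = "asiRNA", mustWork = TRUE))
}

#' Sense-strand position paired with a guide position
#'
#' The guide anneals antiparallel to the target window, so guide position q
#' (1 = 5'-most guide nucleotide) pairs sense position
#' `window_end - q + 1`.
#'
#' @param design An `antisense_design`.
#' @param q Guide position(s) in `[1, L]`.
#' @return 1-based sense-strand coordinate(s).
#' @export
guide_target_position <- function(design, q) {
  stopifnot(inherits(design, "antisense_design"), all(q >= 1L & q <= design$L))
  design$window_end - q + 1L
}

#' Design a guide strand with the variant at a chosen guide position
#'
#' Builds the guide (antisense) strand fully complementary to the mutant
#' allele, with the SNV aligned opposite guide position `p` (P1 = the
#' 5'-most guide nucleotide). The targeted sense window is
#' `snv_position - (L - p) .. snv_position + (p - 1)` and the guide is the
#' RNA reverse complement of the mutant-allele window, so the design carries
#' zero mismatches against the mutant allele and exactly one - the primary
#' mismatch - against the wild type, at guide position `p`.
#'
#' @param locus An `allele_locus`.
#' @param p Alignment position of the variant within the guide, `1..L`.
#' @param L Guide length (19-23; 19 by default, the classical siRNA core).
#' @return An object of class `antisense_design`.
#' @examples
#' loc <- allele_locus("toy", "AAAGAUUGCUGACUACGGCAU", 17, "G", "A")
#' guide_for_position(loc, p = 4)$guide
#' @export
guide_for_position <- function(locus, p, L = 19L) {
  stopifnot(inherits(locus, "allele_locus"))
  p <- as.integer(p); L <- as.integer(L)
  if (L < 19L || L > 23L) stop("guide length L must be in 19..23, got ", L)
  if (p < 1L || p > L) stop("alignment position p must be in 1..", L, ", got ", p)
  snv <- locus$snv_position
  need5 <- L - p; need3 <- p - 1L
  avail5 <- snv - 1L
  avail3 <- nchar(locus$sense_sequence) - snv
  if (avail5 < need5 || avail3 < need3) {
    stop(sprintf(paste0("insufficient flank for p=%d, L=%d: need %d nt 5' and ",
                        "%d nt 3' of the SNV on the sense strand, have %d and %d"),
                 p, L, need5, need3, avail5, avail3))
  }
  ws <- snv - need5; we <- snv + need3
  mut_window <- substr(as.character(allele_sequence(locus, "mut")), ws, we)
  guide <- reverse_complement(nt_sequence(chartr("T", "U", mut_window), "RNA"))
  wt_rna <- chartr("T", "U", locus$wt_base)
  primary <- classify_pair(wt_rna, substr(as.character(guide), p, p))
  structure(list(design_id = paste0("p", p), guide = guide, p = p, L = L,
                 locus = locus, window_start = ws, window_end = we,
                 primary_mismatch = primary, secondary_mismatches = list()),
            class = "antisense_design")
}

#' @export
print.antisense_design <- function(x, ...) {
  cat(sprintf("<antisense_design '%s'> guide 5'-%s-3' (L=%d)\n", x$design_id,
              as.character(x$guide), x$L))
  cat(sprintf("  target %s:%d-%d (sense, 1-based); SNV opposite P%d; primary mismatch %s (%s)\n",
              x$locus$transcript_id, x$window_start, x$window_end, x$p,
              x$primary_mismatch$pair_label, x$primary_mismatch$category))
  for (sm in x$secondary_mismatches) {
    cat(sprintf("  secondary P%d %s>%s; vs wt %s, vs mut %s\n",
                sm$guide_position, sm$original_guide_base,
                sm$substituted_guide_base, sm$class_vs_wt$pair_label,
                sm$class_vs_mut$pair_label))
  }
  invisible(x)
}

#' Walk-through panel of guide designs
#'
#' One design per requested alignment position, named `p{position}`, in the
#' order requested. A walk-through panel slides the variant through
#' successive guide positions; consecutive positions yield guides that are
#' single-base shifts of each other.
#'
#' @param locus An `allele_locus`.
#' @param positions Integer vector of alignment positions (no duplicates).
#' @param L Guide length.
#' @return Named list of `antisense_design` objects.
#' @examples
#' loc <- allele_locus("toy", strrep("A", 20), 10, "A", "G")
#' # panel over P1-P16 needs >= 18 nt 5' flank; see simulate_locus()
#' @export
walkthrough_panel <- function(locus, positions, L = 19L) {
  positions <- as.integer(positions)
  if (length(positions) == 0L) stop("empty position list")
  if (anyDuplicated(positions)) {
    stop("duplicate alignment positions: ",
         paste(unique(positions[duplicated(positions)]), collapse = ", "))
  }
  designs <- lapply(positions, function(p) guide_for_position(locus, p, L))
  names(designs) <- vapply(designs, `[[`, character(1L), "design_id")
  designs
}

#' Secondary-mismatch variants of a design
#'
#' Introduces one additional guide substitution - a secondary mismatch to
#' both alleles - at a position chosen by strategy:
#' \itemize{
#'   \item `adjacent_3prime`: immediately 3' of the variant alignment in the
#'     guide (guide position `p + 1`);
#'   \item `adjacent_5prime`: guide position `p - 1`;
#'   \item `separated`: an explicit `position` away from `p`;
#'   \item `cleavage_opposite`: a `position` in `{9, 10, 11}`, opposite the
#'     predicted target cleavage site.
#' }
#' With `bases = "all"` every non-original base is emitted (always 3
#' variants); `"weakest"`/`"strongest"` select the single substitution whose
#' pairing against the mutant-allele target base scores lowest/highest in
#' the strength table (ties broken by base order A < C < G < U); a single
#' explicit base emits that variant only.
#'
#' Variant ids follow the construct-naming convention: an `adjacent_3prime`
#' variant with one explicit base is `p{p}{p+1}` (e.g. `p1314`); all other
#' variants are `p{p}_{q}{B}` with `B` the substituted guide base (e.g.
#' `p11_9C`), suffixed `:weak`/`:strong` when selected from the table.
#'
#' @param design Parent `antisense_design`.
#' @param strategy Placement strategy (see above).
#' @param position Secondary position for `separated`/`cleavage_opposite`.
#' @param bases `"all"`, `"weakest"`, `"strongest"`, or one explicit RNA base.
#' @param table A `strength_table` (used for weakest/strongest).
#' @return Named list of `antisense_design` variants.
#' @export
secondary_variants <- function(design,
                               strategy = c("adjacent_3prime", "adjacent_5prime",
                                            "separated", "cleavage_opposite"),
                               position = NULL, bases = "all",
                               table = default_strength_table()) {
  stopifnot(inherits(design, "antisense_design"))
  strategy <- match.arg(strategy)
  q <- switch(strategy,
    adjacent_3prime = design$p + 1L,
    adjacent_5prime = design$p - 1L,
    separated = {
      if (is.null(position)) stop("strategy 'separated' requires a position")
      as.integer(position)
    },
    cleavage_opposite = {
      if (is.null(position) || !position %in% c(9L, 10L, 11L)) {
        stop("strategy 'cleavage_opposite' requires position 9, 10 or 11")
      }
      as.integer(position)
    })
  if (q == design$p) {
    stop("secondary position ", q, " collides with the primary alignment p=", design$p)
  }
  if (q < 1L || q > design$L) stop("secondary position ", q, " outside guide 1..", design$L)
  guide_chr <- as.character(design$guide)
  orig <- substr(guide_chr, q, q)
  tpos <- guide_target_position(design, q)
  mut_target <- chartr("T", "U", substr(as.character(allele_sequence(design$locus, "mut")), tpos, tpos))
  wt_target <- chartr("T", "U", substr(as.character(allele_sequence(design$locus, "wt")), tpos, tpos))
  candidates <- setdiff(RNA_BASES, orig)
  suffix <- ""
  explicit <- FALSE
  if (identical(bases, "all")) {
    chosen <- candidates
  } else if (identical(bases, "weakest") || identical(bases, "strongest")) {
    scores <- vapply(candidates, function(b) {
      unclass(table)[[paste0(mut_target, ":", b)]]
    }, numeric(1L))
    pick <- if (bases == "weakest") which.min(scores) else which.max(scores)
    chosen <- candidates[pick]  # candidates already in A<C<G<U order: which.* keeps first tie
    suffix <- if (bases == "weakest") ":weak" else ":strong"
  } else {
    b <- toupper(as.character(bases))
    if (length(b) != 1L || !b %in% RNA_BASES) {
      stop("bases must be 'all', 'weakest', 'strongest' or a single RNA base")
    }
    if (b == orig) stop("explicit base '", b, "' equals the original guide base at position ", q)
    chosen <- b
    explicit <- TRUE
  }
  variants <- lapply(chosen, function(b) {
    g2 <- guide_chr
    substr(g2, q, q) <- b
    sm <- list(guide_position = q, original_guide_base = orig,
               substituted_guide_base = b,
               class_vs_wt = classify_pair(wt_target, b),
               class_vs_mut = classify_pair(mut_target, b))
    id <- if (strategy == "adjacent_3prime" && explicit) {
      sprintf("p%d%d", design$p, q)
    } else {
      sprintf("p%d_%d%s%s", design$p, q, b, suffix)
    }
    out <- design
    out$design_id <- id
    out$guide <- nt_sequence(g2, "RNA")
    out$secondary_mismatches <- c(design$secondary_mismatches, list(sm))
    out
  })
  names(variants) <- vapply(variants, `[[`, character(1L), "design_id")
  variants
}

#' Guide:target mismatch profile against one allele
#'
#' Compares the guide to the targeted window of the chosen allele position
#' by position and reports every non-Watson-Crick pairing (the G:U wobble
#' counts as a mismatch). A design with k secondary mismatches shows k
#' mismatches against the mutant allele and k + 1 against the wild type.
#'
#' @param design An `antisense_design`.
#' @param allele `"wt"` or `"mut"`.
#' @return `data.frame` with columns `guide_position`, `pair_label`,
#'   `category`, sorted by guide position.
#' @export
mismatch_profile <- function(design, allele = c("wt", "mut")) {
  stopifnot(inherits(design, "antisense_design"))
  allele <- match.arg(allele)
  target <- chartr("T", "U", as.character(allele_sequence(design$locus, allele)))
  window <- substr(target, design$window_start, design$window_end)
  guide_chr <- as.character(design$guide)
  rows <- lapply(seq_len(design$L), function(q) {
    tb <- substr(window, design$L - q + 1L, design$L - q + 1L)
    cls <- classify_pair(tb, substr(guide_chr, q, q))
    if (cls$category == "WATSON_CRICK") return(NULL)
    data.frame(guide_position = q, pair_label = cls$pair_label,
               category = cls$category, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    return(data.frame(guide_position = integer(0), pair_label = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Tabulate a design panel
#'
#' @param designs List of `antisense_design` objects (e.g. from
#'   [walkthrough_panel()] or [secondary_variants()]).
#' @return `data.frame` with one row per design: id, alignment position,
#'   guide RNA, target window coordinates, primary mismatch class,
#'   secondary-mismatch spec, and mismatch counts against each allele.
#' @export
panel_table <- function(designs) {
  if (inherits(designs, "antisense_design")) designs <- list(designs)
  stopifnot(length(designs) > 0L)
  do.call(rbind, lapply(designs, function(d) {
    sec <- if (length(d$secondary_mismatches) == 0L) "" else {
      paste(vapply(d$secondary_mismatches, function(sm) {
        sprintf("%d%s>%s", sm$guide_position, sm$original_guide_base,
                sm$substituted_guide_base)
      }, character(1L)), collapse = ";")
    }
    data.frame(design_id = d$design_id, p = d$p,
               guide_rna = as.character(d$guide),
               window_start = d$window_start, window_end = d$window_end,
               primary_class = d$primary_mismatch$pair_label,
               secondary_spec = sec,
               mm_count_wt = nrow(mismatch_profile(d, "wt")),
               mm_count_mut = nrow(mismatch_profile(d, "mut")),
               stringsAsFactors = FALSE)
  }))
}

#' Write a design panel as TSV (with provenance header) or FASTA
#'
#' @param designs List of `antisense_design` objects.
#' @param path Output path.
#' @param header Extra `# key: value` comment lines to prepend.
#' @return The path, invisibly.
#' @export
write_panel <- function(designs, path, header = character(0)) {
  tab <- panel_table(designs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# asiRNA design panel; coordinates 1-based, inclusive, sense strand",
               paste0("# ", header)[nzchar(header)]), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
panel_fasta <- function(designs, path) {
  if (inherits(designs, "antisense_design")) designs <- list(designs)
  recs <- lapply(designs, `[[`, "guide")
  names(recs) <- vapply(designs, `[[`, character(1L), "design_id")
  write_fasta(recs, path)
}
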