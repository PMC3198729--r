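test_that("walk-through guides regenerate the published LRRK2 siRNA strands", {
  loc <- synthetic_locus_g2019s(seed = 1)
  for (p in 3:5) {
    d <- guide_for_position(loc, p)
    expect_equal(as.character(d$guide), PUBLISHED_GUIDES[[paste0("p", p)]],
                 label = paste0("guide p", p))
    expect_equal(d$design_id, paste0("p", p))
    # antiparallel mapping puts the SNV opposite guide position p
    expect_equal(guide_target_position(d, d$p), loc$snv_position)
    expect_equal(d$window_end - d$window_start + 1L, d$L)
  }
  # G2019S-like primary mismatch is the G:U wobble at every position
  panel <- walkthrough_panel(loc, 1:16)
  expect_length(panel, 16)
  expect_equal(names(panel), paste0("p", 1:16))
  for (d in panel) {
    expect_equal(d$primary_mismatch$pair_label, "G:U")
    expect_equal(d$primary_mismatch$category, "WOBBLE_GU")
  }
})

test_that("guide is the exact reverse complement of the mutant window", {
  set.seed(21)
  for (i in 1:5) {
    loc <- random_locus(seed = 100 + i)
    for (p in c(1, 4, 10, 16, 19)) {
      d <- guide_for_position(loc, p)
      mut_window <- substr(as.character(allele_sequence(loc, "mut")),
                           d$window_start, d$window_end)
      expect_equal(as.character(d$guide), oracle_revcomp_rna(mut_window))
      expect_equal(nrow(mismatch_profile(d, "mut")), 0)
      prof_wt <- mismatch_profile(d, "wt")
      expect_equal(prof_wt$guide_position, p)
      expect_equal(prof_wt$category, d$primary_mismatch$category)
    }
  }
})

test_that("consecutive alignment positions give single-base-shifted guides", {
  loc <- random_locus(seed = 5)
  panel <- walkthrough_panel(loc, 1:19)
  for (p in 1:18) {
    g1 <- as.character(panel[[p]]$guide)
    g2 <- as.character(panel[[p + 1]]$guide)
    expect_equal(substr(g2, 2, 19), substr(g1, 1, 18),
                 label = sprintf("shift p%d->p%d", p, p + 1))
  }
  # and the published p3/p4/p5 triplet obeys the same sliding-window law
  expect_equal(substr(PUBLISHED_GUIDES[["p4"]], 2, 19),
               substr(PUBLISHED_GUIDES[["p3"]], 1, 18))
  expect_equal(substr(PUBLISHED_GUIDES[["p5"]], 2, 19),
               substr(PUBLISHED_GUIDES[["p4"]], 1, 18))
})

test_that("pair classification is total, symmetric in category, and matches the disease cases", {
  expect_equal(classify_pair("C", "G")$category, "WATSON_CRICK")
  expect_equal(classify_pair("G", "G")$category, "PURINE_PURINE")  # A30P vs wt
  expect_equal(classify_pair("G", "G")$pair_label, "G:G")
  expect_equal(classify_pair("G", "U")$category, "WOBBLE_GU")      # G2019S vs wt
  expect_equal(classify_pair("A", "C")$category, "PURINE_PYRIMIDINE_MM")
  expect_equal(classify_pair("U", "U")$category, "PYRIMIDINE_PYRIMIDINE")

  bases <- c("A", "C", "G", "U")
  wc <- c("A:U", "U:A", "G:C", "C:G")
  for (x in bases) for (y in bases) {
    cls <- classify_pair(x, y)
    expect_equal(cls$category, classify_pair(y, x)$category)
    expect_equal(cls$category == "WATSON_CRICK", cls$pair_label %in% wc)
  }
  expect_error(classify_pair("T", "A"), "DNA base")
})

test_that("panel construction rejects bad position lists and thin flanks", {
  loc <- random_locus(seed = 9)
  expect_error(walkthrough_panel(loc, integer(0)), "empty")
  expect_error(walkthrough_panel(loc, c(10, 11, 10)), "duplicate")
  thin <- allele_locus("thin", paste0(strrep("A", 10), "G", strrep("A", 20)),
                       11, "G", "C")
  expect_error(guide_for_position(thin, 4), "insufficient flank.*need 15 nt 5'")
  expect_error(guide_for_position(loc, 0), "must be in 1..19")
  expect_error(guide_for_position(loc, 20), "must be in 1..19")
})

test_that("the published p1314 double-mismatch construct is regenerated", {
  loc <- synthetic_locus_a30p(seed = 3)
  d13 <- guide_for_position(loc, 13)
  expect_equal(as.character(d13$guide), "UUGUCUUUCCUGGUGCUUC")
  expect_equal(d13$primary_mismatch$pair_label, "G:G")

  vars <- secondary_variants(d13, "adjacent_3prime", bases = "C")
  expect_named(vars, "p1314")
  expect_equal(as.character(vars$p1314$guide), PUBLISHED_GUIDES[["p1314"]])
  prof_wt <- mismatch_profile(vars$p1314, "wt")
  expect_equal(prof_wt$guide_position, c(13, 14))
  expect_equal(prof_wt$pair_label, c("G:G", "A:C"))
  prof_mut <- mismatch_profile(vars$p1314, "mut")
  expect_equal(prof_mut$guide_position, 14)
  expect_equal(prof_mut$pair_label, "A:C")
})

test_that("cleavage-opposite variants carry the published construct names", {
  loc <- synthetic_locus_g2019s(seed = 4)
  d11 <- guide_for_position(loc, 11)
  vars <- secondary_variants(d11, "cleavage_opposite", position = 9)
  expect_named(vars, c("p11_9A", "p11_9C", "p11_9U"))  # original guide base is G
  vars10 <- secondary_variants(d11, "adjacent_5prime")
  expect_true(all(grepl("^p11_10[ACGU]$", names(vars10))))
  expect_error(secondary_variants(d11, "cleavage_opposite", position = 8),
               "9, 10 or 11")
})

test_that("secondary variants differ from the parent at exactly one position", {
  set.seed(31)
  for (i in 1:4) {
    loc <- random_locus(seed = 200 + i)
    d <- guide_for_position(loc, sample(2:18, 1))
    q_sep <- sample(setdiff(1:19, c(d$p, d$p - 1, d$p + 1)), 1)
    for (vars in list(secondary_variants(d, "adjacent_3prime"),
                      secondary_variants(d, "separated", position = q_sep))) {
      expect_length(vars, 3)
      for (v in vars) {
        diffs <- which(strsplit(as.character(v$guide), "")[[1]] !=
                         strsplit(as.character(d$guide), "")[[1]])
        expect_equal(length(diffs), 1)
        expect_equal(diffs, v$secondary_mismatches[[1]]$guide_position)
        # k / k+1 mismatch-count invariant
        expect_equal(nrow(mismatch_profile(v, "mut")), 1)
        expect_equal(nrow(mismatch_profile(v, "wt")), 2)
        # reverting the secondary substitution recovers the mutant window
        g <- as.character(v$guide)
        sm <- v$secondary_mismatches[[1]]
        substr(g, sm$guide_position, sm$guide_position) <- sm$original_guide_base
        mut_window <- substr(as.character(allele_sequence(loc, "mut")),
                             v$window_start, v$window_end)
        expect_equal(oracle_revcomp_rna(g), mut_window)
      }
    }
  }
})

test_that("weakest/strongest selection follows the strength table with fixed tie-break", {
  tab <- default_strength_table()
  expect_length(unclass(tab), 16)
  expect_true(all(unclass(tab)[c("A:U", "U:A", "G:C", "C:G")] == 0))
  expect_true(all(unclass(tab)[setdiff(names(unclass(tab)),
                                       c("A:U", "U:A", "G:C", "C:G"))] > 0))
  # wobble weakest; C:C above A:C and U:C; G:G maximal
  s <- unclass(tab)
  expect_lt(s[["G:U"]], s[["A:C"]])
  expect_gt(s[["C:C"]], s[["A:C"]])
  expect_gt(s[["C:C"]], s[["U:C"]])
  expect_equal(unname(which.max(s)), unname(which(names(s) == "G:G")))

  loc <- synthetic_locus_g2019s(seed = 6)
  d11 <- guide_for_position(loc, 11)
  # mutant target base opposite guide position 9 is C (guide base G):
  # candidate pairings C:A (2), C:C (4), C:U (2) -> weakest ties C:A/C:U,
  # broken towards A; strongest is C:C.
  weak <- secondary_variants(d11, "cleavage_opposite", position = 9,
                             bases = "weakest")
  strong <- secondary_variants(d11, "cleavage_opposite", position = 9,
                               bases = "strongest")
  expect_named(weak, "p11_9A:weak")
  expect_named(strong, "p11_9C:strong")
  expect_equal(weak[[1]]$secondary_mismatches[[1]]$class_vs_mut$pair_label, "C:A")
  expect_equal(strong[[1]]$secondary_mismatches[[1]]$class_vs_mut$pair_label, "C:C")

  expect_error(secondary_variants(d11, "separated", position = 11), "collides")
  expect_error(secondary_variants(d11, "separated", position = 25), "outside")
})

test_that("panel tables and exports carry the design metadata", {
  loc <- synthetic_locus_a30p(seed = 8)
  panel <- walkthrough_panel(loc, 10:16)
  tab <- panel_table(panel)
  expect_equal(tab$design_id, paste0("p", 10:16))
  expect_true(all(tab$mm_count_mut == 0))
  expect_true(all(tab$mm_count_wt == 1))
  f <- tempfile(fileext = ".tsv")
  write_panel(panel, f)
  back <- read.delim(f, comment.char = "#", stringsAsFactors = FALSE)
  expect_equal(back$guide_rna, tab$guide_rna)
  fa <- tempfile(fileext = ".fa")
  panel_fasta(panel, fa)
  expect_equal(as.character(read_fasta(fa)$p13),
               as.character(panel$p13$guide))
})
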