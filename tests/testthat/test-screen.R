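test_that("luciferase normalization controls to mean 1 and is scale-invariant", {
  plate <- simulate_screen(0.5, 0.5, n = 6, cv = 0, mode = "luciferase")
  norm <- normalize_luciferase(plate)
  ctrl <- norm$normalized[norm$group == "nonspecific_control"]
  expect_equal(mean(ctrl[norm$target[norm$group == "nonspecific_control"] == "wt"]), 1)
  # noiseless: experimental ratio 0.5 against control mean 1 -> exactly 0.5
  expect_true(all(norm$normalized[norm$group == "experimental"] == 0.5))

  plate2 <- simulate_screen(0.3, 0.9, n = 6, cv = 0.15, mode = "luciferase",
                            seed = 10)
  n1 <- normalize_luciferase(plate2)
  plate2$value <- plate2$value * 37.5
  n2 <- normalize_luciferase(plate2)
  expect_equal(n2$normalized, n1$normalized)

  bad <- plate2
  bad$value[which(bad$channel == "firefly")[1]] <- 0
  expect_error(normalize_luciferase(bad), "firefly reading of zero")
  no_ctrl <- plate2[plate2$group != "nonspecific_control", ]
  expect_error(normalize_luciferase(no_ctrl), "no nonspecific_control")
})

test_that("fluorescence normalization subtracts background, floors, and keeps channels independent", {
  # worked example: raw 1100, background 100, bg-subtracted control 1000 -> 1.0
  plate <- data.frame(
    well_id = paste0("w", 1:6),
    construct_id = c("none", "nonspecific", "shRNA", "none", "nonspecific", "shRNA"),
    target = rep(c("wt", "mut"), each = 3),
    channel = rep(c("eGFP", "mCherry"), each = 3),
    group = rep(c("background", "nonspecific_control", "experimental"), 2),
    value = c(100, 1100, 1100, 100, 1100, 100),
    stringsAsFactors = FALSE)
  norm <- normalize_fluorescence(plate)
  expect_equal(norm$normalized[norm$group == "experimental" & norm$target == "wt"], 1)
  # raw equal to background floors at 0
  expect_equal(norm$normalized[norm$group == "experimental" & norm$target == "mut"], 0)

  # channel independence: changing the mutant effect leaves the wt estimate alone
  p1 <- simulate_screen(1.0, 0.2, n = 6, cv = 0.1, seed = 33)
  p2 <- simulate_screen(1.0, 0.9, n = 6, cv = 0.1, seed = 33)
  wt1 <- normalize_fluorescence(p1)
  wt2 <- normalize_fluorescence(p2)
  sel <- wt1$group == "experimental" & wt1$channel == "eGFP"
  expect_equal(wt1$normalized[sel], wt2$normalized[wt2$group == "experimental" &
                                                     wt2$channel == "eGFP"])

  flat <- plate
  flat$value[flat$group == "nonspecific_control"] <- 100
  expect_error(normalize_fluorescence(flat), "non-positive denominator")
})

test_that("discrimination arithmetic reproduces the screen's headline identities", {
  # 92% mutant vs 31% wild-type silencing -> 61-point difference
  d <- discrimination(wt_rel = 0.69, mut_rel = 0.08)
  expect_equal(d$silencing_difference, 61)
  expect_equal(d$mut_silencing, 92)
  expect_equal(d$wt_silencing, 31)

  # heterozygous screen: wt at 59%, mutant at 17% of control -> 3.47-fold,
  # i.e. the printed 3.4-fold after rounding to 1 decimal... report to 2 dp
  d2 <- discrimination(wt_rel = 0.59, mut_rel = 0.17)
  expect_equal(round(d2$fold_discrimination, 2), 3.47)
  expect_equal(round(d2$fold_discrimination, 1), 3.5)

  d3 <- discrimination(wt_rel = 0.4, mut_rel = 0.4)
  expect_equal(d3$fold_discrimination, 1)
  expect_equal(d3$silencing_difference, 0)

  # reciprocal identity of the fold
  expect_equal(discrimination(0.59, 0.17)$fold_discrimination *
                 discrimination(0.17, 0.59)$fold_discrimination, 1)

  # fully silenced mutant: infinite fold flagged, not an error
  d4 <- discrimination(wt_rel = 0.5, mut_rel = 0)
  expect_true(d4$infinite_fold)
  expect_equal(d4$fold_discrimination, Inf)
})

test_that("the unpaired two-tailed t test matches a closed-form oracle", {
  g1 <- c(0.98, 1.02, 1.05, 0.95, 1.01, 0.99)
  g2 <- c(0.55, 0.61, 0.58, 0.62, 0.57, 0.60)
  res <- ttest_unpaired_two_tailed(g1, g2)
  # independent closed-form computation (pooled variance Student's t)
  n1 <- length(g1); n2 <- length(g2)
  sp2 <- ((n1 - 1) * var(g1) + (n2 - 1) * var(g2)) / (n1 + n2 - 2)
  t_oracle <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_oracle <- 2 * pt(-abs(t_oracle), df = n1 + n2 - 2)
  expect_equal(res$t, t_oracle)
  expect_equal(res$df, n1 + n2 - 2)
  expect_equal(res$p, p_oracle)

  expect_equal(ttest_unpaired_two_tailed(c(1, 1, 1), c(1, 1, 1))$p, 1)
  set.seed(1)
  a <- rnorm(6, 0, 1e-4); b <- 1 + rnorm(6, 0, 1e-4)
  expect_lt(ttest_unpaired_two_tailed(a, b)$p, 1e-6)
  expect_error(ttest_unpaired_two_tailed(c(1, 1), c(2, 2)), "degenerate variance")
  # Welch flag uses unpooled df
  expect_lt(ttest_unpaired_two_tailed(g1, c(g2, 0.2, 0.9),
                                      equal_variance = FALSE)$df, 12)
})

test_that("simulated screens are reproducible and recover truth in the noiseless limit", {
  p1 <- simulate_screen(0.6, 0.1, seed = 7)
  p2 <- simulate_screen(0.6, 0.1, seed = 7)
  expect_identical(p1, p2)
  expect_false(identical(p1, simulate_screen(0.6, 0.1, seed = 8)))

  for (mode in c("fluorescence", "luciferase")) {
    plate <- simulate_screen(0.59, 0.17, n = 6, cv = 0, mode = mode)
    norm <- if (mode == "fluorescence") normalize_fluorescence(plate)
            else normalize_luciferase(plate)
    res <- screen_stats(norm)
    expect_equal(res$wt_rel, 0.59, tolerance = 1e-12)
    expect_equal(res$mut_rel, 0.17, tolerance = 1e-12)
    expect_equal(round(res$fold_discrimination, 2), 3.47)
  }
})

test_that("plate I/O round-trips and rejects malformed tables", {
  plate <- simulate_screen(0.5, 0.2, seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_plate(plate, f)
  back <- read_plate(f)
  expect_equal(back$value, plate$value)
  expect_equal(back$well_id, plate$well_id)
  expect_error(validate_plate <- read_plate({
    g <- tempfile(); writeLines("a\tb\n1\t2", g); g
  }), "missing columns")
  neg <- plate; neg$value[1] <- -5
  expect_error(write_plate(neg, f), "non-negative")
})

test_that("fold estimates concentrate around truth as noise shrinks", {
  folds <- vapply(1:40, function(s) {
    plate <- simulate_screen(0.75, 0.15, n = 6, cv = 0.05, seed = 4000 + s)
    res <- screen_stats(normalize_fluorescence(plate))
    res$fold_discrimination
  }, numeric(1))
  expect_lt(abs(mean(folds) - 5), 5 * 0.05)
  folds_tight <- vapply(1:10, function(s) {
    plate <- simulate_screen(0.75, 0.15, n = 6, cv = 0.005, seed = 5000 + s)
    screen_stats(normalize_fluorescence(plate))$fold_discrimination
  }, numeric(1))
  expect_lt(abs(mean(folds_tight) - 5), abs(mean(folds) - 5) + 0.05)
})
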