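#' @importFrom stats aggregate t.test rlnorm
NULL

PLATE_COLUMNS <- c("well_id", "construct_id", "target", "channel", "group", "value")

#' Read / write plate measurements
#'
#' Plates are long-format tables with one row per channel reading:
#' `well_id`, `construct_id`, `target` (`wt`/`mut`), `channel` (`renilla`,
#' `firefly`, `eGFP`, `mCherry`), `group` (`experimental`,
#' `nonspecific_control`, `background`), `value` (non-negative raw
#' luminescence/fluorescence).
#'
#' @param path TSV path.
#' @param plate A plate `data.frame`.
#' @return `read_plate`: validated `data.frame`; `write_plate`: the path.
#' @export
read_plate <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_plate(df)
}

#' @rdname read_plate
#' @export
write_plate <- function(plate, path) {
  validate_plate(plate)
  utils::write.table(plate, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_plate <- function(df) {
  missing_cols <- setdiff(PLATE_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("plate is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(df$value)) || any(df$value < 0)) {
    stop("plate values must be finite and non-negative")
  }
  df
}

#' Normalize dual-luciferase wells
#'
#' Computes the per-well Renilla:firefly ratio, then divides each
#' experimental ratio by the mean ratio of the nonspecific-control wells
#' for the same target allele. Control wells therefore normalize to mean
#' exactly 1. The normalization is scale-invariant: multiplying all raw
#' values by a constant leaves every normalized expression unchanged.
#'
#' @param wells Plate `data.frame` with paired `renilla`/`firefly` readings
#'   per well (matched on `well_id`).
#' @return `data.frame` with one row per well: `well_id`, `construct_id`,
#'   `target`, `group`, `ratio`, `normalized`.
#' @export
normalize_luciferase <- function(wells) {
  wells <- validate_plate(wells)
  ren <- wells[wells$channel == "renilla", ]
  fir <- wells[wells$channel == "firefly", ]
  if (nrow(ren) == 0L || nrow(fir) == 0L) {
    stop("luciferase plates need renilla and firefly channels")
  }
  m <- match(ren$well_id, fir$well_id)
  if (anyNA(m)) {
    stop("wells without a paired firefly reading: ",
         paste(ren$well_id[is.na(m)], collapse = ", "))
  }
  if (any(fir$value[m] == 0)) {
    stop("firefly reading of zero in well(s): ",
         paste(ren$well_id[fir$value[m] == 0], collapse = ", "))
  }
  out <- data.frame(well_id = ren$well_id, construct_id = ren$construct_id,
                    target = ren$target, group = ren$group,
                    ratio = ren$value / fir$value[m],
                    stringsAsFactors = FALSE)
  out$normalized <- NA_real_
  for (tg in unique(out$target)) {
    sel <- out$target == tg
    ctrl <- out$ratio[sel & out$group == "nonspecific_control"]
    if (length(ctrl) == 0L) stop("no nonspecific_control wells for target '", tg, "'")
    out$normalized[sel] <- out$ratio[sel] / mean(ctrl)
  }
  out
}

#' Normalize dual-fluorescence wells
#'
#' Per channel (eGFP and mCherry handled independently): subtract the mean
#' background fluorescence (cells transfected with target alone), floor
#' negative values at zero with a warning, and divide by the mean
#' background-subtracted nonspecific-control signal.
#'
#' @param wells Plate `data.frame` with fluorescence channels.
#' @return `data.frame` with one row per non-background well: `well_id`,
#'   `construct_id`, `target`, `channel`, `group`, `bg_subtracted`,
#'   `normalized`.
#' @export
normalize_fluorescence <- function(wells) {
  wells <- validate_plate(wells)
  chans <- setdiff(unique(wells$channel), c("renilla", "firefly"))
  if (length(chans) == 0L) stop("no fluorescence channels in plate")
  out <- lapply(chans, function(ch) {
    w <- wells[wells$channel == ch, ]
    bg <- w$value[w$group == "background"]
    if (length(bg) == 0L) stop("no background wells for channel '", ch, "'")
    rest <- w[w$group != "background", ]
    sub <- rest$value - mean(bg)
    if (any(sub < 0)) {
      warning(sum(sub < 0), " background-subtracted value(s) below zero in channel '",
              ch, "' floored at 0")
      sub <- pmax(sub, 0)
    }
    ctrl <- sub[rest$group == "nonspecific_control"]
    if (length(ctrl) == 0L) stop("no nonspecific_control wells for channel '", ch, "'")
    if (mean(ctrl) <= 0) {
      stop("control mean does not exceed background in channel '", ch,
           "': non-positive denominator")
    }
    data.frame(well_id = rest$well_id, construct_id = rest$construct_id,
               target = rest$target, channel = ch, group = rest$group,
               bg_subtracted = sub, normalized = sub / mean(ctrl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Unpaired two-tailed t test
#'
#' Classical two-sample Student's t test (equal variance by default; Welch
#' by flag). Two degenerate-variance conventions: identical constant groups
#' give p = 1; constant groups with different means raise an error.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param equal_variance Pool variances (Student) or not (Welch).
#' @return List with `t`, `df`, `p`.
#' @export
ttest_unpaired_two_tailed <- function(group_a, group_b, equal_variance = TRUE) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L,
            all(is.finite(group_a)), all(is.finite(group_b)))
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2L, p = 1))
    }
    stop("degenerate variance: both groups are constant with different means")
  }
  fit <- stats::t.test(group_a, group_b, var.equal = equal_variance,
                       alternative = "two.sided")
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Allele-discrimination statistics for one construct
#'
#' Summarises normalized wild-type and mutant expression (nonspecific
#' control = 1) into the screen's headline numbers: percent silencing of
#' each allele (`100 * (1 - relative expression)`), fold discrimination
#' (`wt_rel / mut_rel`; a mutant-selective effector scores > 1), the
#' silencing difference in percentage points (`mut_silencing -
#' wt_silencing`), and an unpaired two-tailed t test comparing the
#' replicate groups.
#'
#' Either supply the relative expressions directly, or replicate vectors
#' (in which case the relative expressions default to the replicate means
#' and the p-value is computed).
#'
#' @param wt_rel,mut_rel Normalized relative expression of each allele;
#'   defaults to the mean of the corresponding replicates.
#' @param wt_replicates,mut_replicates Optional per-well normalized values.
#' @param construct_id Label.
#' @param equal_variance Passed to [ttest_unpaired_two_tailed()].
#' @return An object of class `discrimination_result`.
#' @examples
#' # printed-percentage arithmetic: 92% mutant vs 31% wild-type silencing
#' d <- discrimination(wt_rel = 0.69, mut_rel = 0.08)
#' d$silencing_difference  # 61 percentage points
#' @export
discrimination <- function(wt_rel = NULL, mut_rel = NULL,
                           wt_replicates = NULL, mut_replicates = NULL,
                           construct_id = "", equal_variance = TRUE) {
  if (is.null(wt_rel)) {
    if (is.null(wt_replicates)) stop("supply wt_rel or wt_replicates")
    wt_rel <- mean(wt_replicates)
  }
  if (is.null(mut_rel)) {
    if (is.null(mut_replicates)) stop("supply mut_rel or mut_replicates")
    mut_rel <- mean(mut_replicates)
  }
  stopifnot(is.finite(wt_rel), is.finite(mut_rel), wt_rel >= 0, mut_rel >= 0)
  infinite_fold <- mut_rel == 0
  fold <- if (infinite_fold) Inf else wt_rel / mut_rel
  wt_sil <- 100 * (1 - wt_rel)
  mut_sil <- 100 * (1 - mut_rel)
  p <- NA_real_
  if (!is.null(wt_replicates) && !is.null(mut_replicates)) {
    # degenerate replicate variance (e.g. a noiseless simulation) leaves the
    # t statistic undefined; report NA rather than aborting the screen
    p <- tryCatch(
      ttest_unpaired_two_tailed(wt_replicates, mut_replicates,
                                equal_variance = equal_variance)$p,
      error = function(e) {
        if (grepl("degenerate variance", conditionMessage(e))) NA_real_
        else stop(e)
      })
  }
  structure(list(construct_id = construct_id,
                 wt_rel = wt_rel, mut_rel = mut_rel,
                 wt_silencing = wt_sil, mut_silencing = mut_sil,
                 fold_discrimination = fold,
                 infinite_fold = infinite_fold,
                 silencing_difference = mut_sil - wt_sil,
                 p_value = p,
                 wt_mean = if (is.null(wt_replicates)) wt_rel else mean(wt_replicates),
                 wt_sd = if (is.null(wt_replicates)) NA_real_ else stats::sd(wt_replicates),
                 mut_mean = if (is.null(mut_replicates)) mut_rel else mean(mut_replicates),
                 mut_sd = if (is.null(mut_replicates)) NA_real_ else stats::sd(mut_replicates),
                 n_wt = length(wt_replicates), n_mut = length(mut_replicates)),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  # percentages to 0 dp and folds to 2 dp, the field's reporting style
  cat(sprintf("<discrimination_result%s>\n",
              if (nzchar(x$construct_id)) paste0(" '", x$construct_id, "'") else ""))
  cat(sprintf("  silencing: mutant %.0f%%, wild-type %.0f%% (difference %.0f points)\n",
              x$mut_silencing, x$wt_silencing, x$silencing_difference))
  cat(sprintf("  fold discrimination (wt/mut): %s%s\n",
              if (x$infinite_fold) "Inf" else sprintf("%.2f", x$fold_discrimination),
              if (is.na(x$p_value)) "" else sprintf(" (p = %.3g, unpaired two-tailed t)",
                                                    x$p_value)))
  invisible(x)
}

#' Discrimination statistics for every construct on a normalized plate
#'
#' @param normalized Output of [normalize_luciferase()] or
#'   [normalize_fluorescence()] (the latter needs a `target` column mapping
#'   channels to alleles, as written by [simulate_screen()]).
#' @param equal_variance Passed through to the t test.
#' @return `data.frame` with one row per experimental construct.
#' @export
screen_stats <- function(normalized, equal_variance = TRUE) {
  stopifnot(all(c("construct_id", "target", "group", "normalized") %in% names(normalized)))
  exp_rows <- normalized[normalized$group == "experimental", ]
  ids <- unique(exp_rows$construct_id)
  if (length(ids) == 0L) stop("no experimental wells on the plate")
  out <- lapply(ids, function(id) {
    wt <- exp_rows$normalized[exp_rows$construct_id == id & exp_rows$target == "wt"]
    mut <- exp_rows$normalized[exp_rows$construct_id == id & exp_rows$target == "mut"]
    if (length(wt) < 2L || length(mut) < 2L) {
      stop("construct '", id, "' needs >= 2 replicate wells per allele")
    }
    d <- discrimination(wt_replicates = wt, mut_replicates = mut,
                        construct_id = id, equal_variance = equal_variance)
    data.frame(construct_id = id, n_wt = d$n_wt, n_mut = d$n_mut,
               wt_rel = d$wt_rel, mut_rel = d$mut_rel,
               wt_sd = d$wt_sd, mut_sd = d$mut_sd,
               wt_silencing = d$wt_silencing, mut_silencing = d$mut_silencing,
               fold_discrimination = d$fold_discrimination,
               silencing_difference = d$silencing_difference,
               p_value = d$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a synthetic screen plate
#'
#' Generates plate measurements for one construct screened against the
#' wild-type and mutant targets, with multiplicative log-normal noise of a
#' given coefficient of variation (mean-one noise, so `cv = 0` recovers the
#' true values exactly through the normalization pipeline). Experimental,
#' nonspecific-control and (for fluorescence) background wells are emitted
#' in the schema accepted by the plate readers.
#'
#' In fluorescence mode the wild-type allele reads out on eGFP and the
#' mutant on mCherry (the heterozygous two-colour model); in luciferase
#' mode each target allele has its own wells with paired Renilla (target)
#' and firefly (co-transfection control) readings.
#'
#' @param true_wt,true_mut True relative expression of each allele under
#'   the construct (nonspecific control = 1).
#' @param n Replicate wells per group (the screening default is 6).
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param mode `"fluorescence"` or `"luciferase"`.
#' @param background Background fluorescence level (fluorescence mode).
#' @param base_signal Control signal level above background.
#' @param construct_id Construct label for the experimental wells.
#' @param seed Optional RNG seed for reproducibility.
#' @return A plate `data.frame` (see [read_plate()]).
#' @export
simulate_screen <- function(true_wt, true_mut, n = 6L, cv = 0.1,
                            mode = c("fluorescence", "luciferase"),
                            background = 100, base_signal = 1000,
                            construct_id = "shRNA", seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(true_wt >= 0, true_mut >= 0, n >= 2L, cv >= 0,
            background >= 0, base_signal > 0)
  if (!is.null(seed)) set.seed(seed)
  noise <- function(k) {
    if (cv == 0) return(rep(1, k))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  n <- as.integer(n)
  if (mode == "fluorescence") {
    chan <- c(wt = "eGFP", mut = "mCherry")
    true <- c(wt = true_wt, mut = true_mut)
    rows <- lapply(c("wt", "mut"), function(al) {
      rbind(
        data.frame(well_id = sprintf("bg_%s_%d", al, seq_len(n)),
                   construct_id = "none", target = al, channel = chan[[al]],
                   group = "background",
                   value = background * noise(n), stringsAsFactors = FALSE),
        data.frame(well_id = sprintf("ctrl_%s_%d", al, seq_len(n)),
                   construct_id = "nonspecific", target = al, channel = chan[[al]],
                   group = "nonspecific_control",
                   value = background + base_signal * noise(n),
                   stringsAsFactors = FALSE),
        data.frame(well_id = sprintf("exp_%s_%d", al, seq_len(n)),
                   construct_id = construct_id, target = al, channel = chan[[al]],
                   group = "experimental",
                   value = background + base_signal * true[[al]] * noise(n),
                   stringsAsFactors = FALSE))
    })
  } else {
    true <- c(wt = true_wt, mut = true_mut)
    rows <- lapply(c("wt", "mut"), function(al) {
      mk <- function(prefix, cid, group, rel) {
        ids <- sprintf("%s_%s_%d", prefix, al, seq_len(n))
        fire <- base_signal * noise(n)
        rbind(
          data.frame(well_id = ids, construct_id = cid, target = al,
                     channel = "firefly", group = group, value = fire,
                     stringsAsFactors = FALSE),
          data.frame(well_id = ids, construct_id = cid, target = al,
                     channel = "renilla", group = group,
                     value = fire * rel * noise(n), stringsAsFactors = FALSE))
      }
      rbind(mk("ctrl", "nonspecific", "nonspecific_control", 1),
            mk("exp", construct_id, "experimental", true[[al]]))
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
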