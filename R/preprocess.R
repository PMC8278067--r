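#' Fastest plausible response latency
#'
#' The target faces hold a neutral expression for `neutral_hold_ms` before
#' forming a smile or frown, and mimicry responses to an unfolding
#' expression can appear no earlier than `min_mimicry_latency_ms` after its
#' onset, so the fastest response that can reflect the target's expression
#' is their sum. With the defaults this is 626 ms; faster trials are treated
#' as task non-compliance (e.g. accidental EMG threshold crossings).
#'
#' @param neutral_hold_ms Duration of the neutral lead-in, milliseconds.
#' @param min_mimicry_latency_ms Minimum mimicry latency, milliseconds.
#' @return The cutoff in milliseconds.
#' @examples
#' rt_cutoff_ms()  # 626
#' @export
rt_cutoff_ms <- function(neutral_hold_ms = 500, min_mimicry_latency_ms = 126) {
  if (neutral_hold_ms < 0 || min_mimicry_latency_ms < 0)
    stop("latencies must be non-negative")
  neutral_hold_ms + min_mimicry_latency_ms
}

#' Exclude non-compliant, outlier and no-response trials
#'
#' Applies the trial exclusion rules to a tidy record table: trials with an
#' RT strictly below `fast_cutoff_ms` are removed as non-compliance, trials
#' with an RT strictly above `slow_cutoff_ms` as slow outliers, and trials
#' without a detectable response (`NA` response/RT) are removed last. Each
#' trial is counted under exactly one reason, checked in that order;
#' boundary values are retained.
#'
#' @param records Data frame with at least columns `response` and `rt_ms`
#'   (`NA` for no-response trials).
#' @param fast_cutoff_ms Fast cutoff, default [rt_cutoff_ms()] = 626.
#' @param slow_cutoff_ms Slow cutoff, default 5000 ms.
#' @return List with elements `records` (the retained rows) and `report`
#'   (a `filter_report`).
#' @examples
#' rec <- data.frame(response = c("smile", NA), rt_ms = c(700, NA))
#' filter_trials(rec)$report
#' @export
filter_trials <- function(records, fast_cutoff_ms = rt_cutoff_ms(),
                          slow_cutoff_ms = 5000) {
  stopifnot(is.data.frame(records),
            all(c("response", "rt_ms") %in% names(records)))
  bad <- xor(is.na(records$response), is.na(records$rt_ms))
  if (any(bad))
    stop("rt_ms must be defined exactly when response is defined (rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), ")")
  has_rt <- !is.na(records$rt_ms)
  fast <- has_rt & records$rt_ms < fast_cutoff_ms
  slow <- has_rt & !fast & records$rt_ms > slow_cutoff_ms
  none <- is.na(records$response)
  keep <- !(fast | slow | none)
  report <- filter_report(n_input = nrow(records),
                          n_fast_excluded = sum(fast),
                          n_slow_excluded = sum(slow),
                          n_no_response_excluded = sum(none),
                          n_retained = sum(keep))
  list(records = records[keep, , drop = FALSE], report = report)
}

filter_report <- function(n_input, n_fast_excluded, n_slow_excluded,
                          n_no_response_excluded, n_retained) {
  rep <- list(n_input = n_input, n_fast_excluded = n_fast_excluded,
              n_slow_excluded = n_slow_excluded,
              n_no_response_excluded = n_no_response_excluded,
              n_retained = n_retained)
  stopifnot(all(unlist(rep) >= 0),
            n_retained == n_input - n_fast_excluded - n_slow_excluded -
              n_no_response_excluded)
  structure(rep, class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "Trial filter: %d input, %d retained (excluded: %d fast, %d slow, %d no-response)\n",
    x$n_input, x$n_retained, x$n_fast_excluded, x$n_slow_excluded,
    x$n_no_response_excluded))
  invisible(x)
}

#' @rdname filter_trials
#' @param report A `filter_report`.
#' @param path File path for the JSON serialization.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}

#' Add relative trial numbers within each clip condition
#'
#' Each of the four clip conditions (interactant x target expression) is
#' shown `reps_per_clip` times per block. `cond_trial_block` numbers those
#' presentations 1..reps within each block; `cond_trial` numbers them
#' across the experiment (1..2*reps, with reps+1 the first trial after the
#' reversal). Computed from the design positions, so it should be applied
#' before any trial exclusion.
#'
#' @param records Data frame with columns `participant_id`, `trial`,
#'   `block`, `interactant`, `target_expression`.
#' @return The records ordered by participant and trial, with `cond_trial`
#'   and `cond_trial_block` columns added.
#' @export
add_condition_trial <- function(records) {
  records <- records[order(records$participant_id, records$trial), ,
                     drop = FALSE]
  key <- interaction(records$participant_id, records$interactant,
                     records$target_expression, drop = TRUE)
  records$cond_trial <- stats::ave(seq_len(nrow(records)), key,
                                   FUN = seq_along)
  keyb <- interaction(key, records$block, drop = TRUE)
  records$cond_trial_block <- stats::ave(seq_len(nrow(records)), keyb,
                                         FUN = seq_along)
  rownames(records) <- NULL
  records
}

#' Per-condition behavioural summary
#'
#' Summarizes filtered records in the 2 x 2 design of congruency by target
#' expression: mean correct response (CR), mean RT and their standard
#' errors, plus per-trial-number learning curves per congruency condition.
#'
#' @param records Filtered records with columns `condition`,
#'   `target_expression`, `correct`, `rt_ms` and (for the curves)
#'   `cond_trial`.
#' @return A list of class `behaviour_summary` with data frames `cells`
#'   (one row per design cell; empty cells are flagged `available = FALSE`,
#'   not zero) and `curves`.
#' @export
summarize_behaviour <- function(records) {
  stopifnot(all(c("condition", "target_expression", "correct") %in%
                  names(records)))
  grid <- expand.grid(condition = c("congruent", "incongruent"),
                      target_expression = c("smile", "frown"),
                      stringsAsFactors = FALSE)
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- records$condition == grid$condition[i] &
      records$target_expression == grid$target_expression[i]
    n <- sum(sel)
    if (n == 0L) {
      return(data.frame(grid[i, ], n = 0L, available = FALSE,
                        mean_cr = NA_real_, se_cr = NA_real_,
                        mean_rt_ms = NA_real_, se_rt_ms = NA_real_))
    }
    cr <- records$correct[sel]
    rt <- records$rt_ms[sel]
    rt <- rt[!is.na(rt)]
    data.frame(grid[i, ], n = n, available = TRUE,
               mean_cr = mean(cr),
               se_cr = stats::sd(cr) / sqrt(n),
               mean_rt_ms = if (length(rt)) mean(rt) else NA_real_,
               se_rt_ms = if (length(rt) > 1) stats::sd(rt) / sqrt(length(rt)) else NA_real_)
  }))
  rownames(cells) <- NULL
  curves <- NULL
  if ("cond_trial" %in% names(records)) {
    agg <- stats::aggregate(correct ~ condition + cond_trial, data = records,
                            FUN = function(x) c(mean = mean(x), n = length(x),
                                                se = stats::sd(x) / sqrt(length(x))))
    curves <- data.frame(condition = agg$condition,
                         cond_trial = agg$cond_trial,
                         mean_cr = agg$correct[, "mean"],
                         se_cr = agg$correct[, "se"],
                         n = agg$correct[, "n"])
    curves <- curves[order(curves$condition, curves$cond_trial), ]
    rownames(curves) <- NULL
  }
  structure(list(cells = cells, curves = curves),
            class = "behaviour_summary")
}

#' @export
print.behaviour_summary <- function(x, ...) {
  cat("Per-cell behaviour summary:\n")
  print(x$cells, digits = 3)
  invisible(x)
}

#' Early/late block comparison around the contingency reversal
#'
#' For each congruency condition, compares mean CR on the first `window`
#' and last `window` presentations of each clip condition between block 1
#' and block 2 with paired two-sided t-tests across participants.
#' Participants lacking trials in a window are dropped pairwise and
#' counted. Zero-variance differences are flagged rather than producing an
#' error; a degenerate all-zero difference is reported as t = 0, p = 1.
#'
#' @param records Records with `cond_trial_block` (see
#'   [add_condition_trial()]), `block`, `condition`, `correct`.
#' @param window Number of per-condition trials in each window (default 3).
#' @return Data frame with one row per condition x window position.
#' @export
reversal_early_late <- function(records, window = 3L) {
  stopifnot("cond_trial_block" %in% names(records))
  reps <- max(records$cond_trial_block)
  res <- list()
  for (cond in c("congruent", "incongruent")) {
    for (win in c("first", "last")) {
      sel <- records$condition == cond &
        (if (win == "first") records$cond_trial_block <= window
         else records$cond_trial_block > reps - window)
      sub <- records[sel, , drop = FALSE]
      if (!nrow(sub)) {
        res[[length(res) + 1L]] <- data.frame(
          condition = cond, window = win, mean_block1 = NA_real_,
          mean_block2 = NA_real_, mean_diff = NA_real_, t = NA_real_,
          df = NA_real_, p = NA_real_, n_pairs = 0L, n_dropped = 0L,
          zero_variance = FALSE, stringsAsFactors = FALSE)
        next
      }
      m <- stats::aggregate(correct ~ participant_id + block, data = sub,
                            FUN = mean)
      wide <- merge(m[m$block == 1, c("participant_id", "correct")],
                    m[m$block == 2, c("participant_id", "correct")],
                    by = "participant_id", suffixes = c("_b1", "_b2"))
      n_total <- length(unique(sub$participant_id))
      n_pairs <- nrow(wide)
      d <- wide$correct_b1 - wide$correct_b2
      zero_var <- n_pairs > 1 && stats::sd(d) == 0
      if (n_pairs < 2) {
        tval <- NA_real_; df <- NA_real_; pval <- NA_real_
      } else if (zero_var) {
        if (mean(d) == 0) { tval <- 0; pval <- 1 } else { tval <- Inf; pval <- 0 }
        df <- n_pairs - 1
      } else {
        tt <- stats::t.test(wide$correct_b1, wide$correct_b2, paired = TRUE)
        tval <- unname(tt$statistic); df <- unname(tt$parameter)
        pval <- tt$p.value
      }
      res[[length(res) + 1L]] <- data.frame(
        condition = cond, window = win,
        mean_block1 = mean(wide$correct_b1), mean_block2 = mean(wide$correct_b2),
        mean_diff = mean(d), t = tval, df = df, p = pval,
        n_pairs = n_pairs, n_dropped = n_total - n_pairs,
        zero_variance = zero_var,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write / read trial records as tidy CSV
#'
#' @param records Data frame of trial records.
#' @param path File path.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("response", "artifact"), names(rec)))
    rec[[col]][rec[[col]] == ""] <- NA_character_
  rec
}
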