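#' Facial expression alphabet
#'
#' The task uses exactly two expressions: `"smile"` and `"frown"`. Both the
#' target interactants' stimuli and the participants' responses are drawn
#' from this alphabet.
#'
#' @format Character vector of length two.
#' @export
EXPRESSIONS <- c("smile", "frown")

#' Opposite of a facial expression
#'
#' `opposite_expression()` is an involution on the two-expression alphabet:
#' the opposite of a smile is a frown and vice versa.
#'
#' @param x Character vector of expressions (`"smile"`/`"frown"`); `NA`
#'   values are passed through.
#' @return Character vector of the opposite expressions.
#' @examples
#' opposite_expression(c("smile", "frown"))
#' @export
opposite_expression <- function(x) {
  bad <- !is.na(x) & !x %in% EXPRESSIONS
  if (any(bad)) stop("unknown expression: ", paste(unique(x[bad]), collapse = ", "))
  out <- ifelse(x == "smile", "frown", "smile")
  out[is.na(x)] <- NA_character_
  out
}

#' Contingency map for the two target interactants
#'
#' Each interactant carries one action rule per block: `"copy"` (respond
#' congruently) or `"oppose"` (respond incongruently). Within a block exactly
#' one interactant is assigned each rule, and the block-2 rules are the
#' block-1 rules swapped (the reversal).
#'
#' @param copy_first Which interactant (1 or 2) carries the `"copy"` rule in
#'   block 1. Exposed for counterbalancing across (synthetic) participants.
#' @return A `contingency_map` object (2 x 2 character matrix, rows =
#'   interactant, columns = block).
#' @examples
#' m <- contingency_map()
#' contingency_rule(m, interactant = 1, block = 1)
#' @export
contingency_map <- function(copy_first = 1L) {
  if (!copy_first %in% c(1L, 2L)) stop("copy_first must be 1 or 2")
  b1 <- if (copy_first == 1L) c("copy", "oppose") else c("oppose", "copy")
  m <- cbind("1" = b1, "2" = rev(b1))
  rownames(m) <- c("1", "2")
  structure(m, class = "contingency_map")
}

#' @rdname contingency_map
#' @param map A `contingency_map`.
#' @param interactant Integer vector in \{1, 2\}.
#' @param block Integer vector in \{1, 2\}.
#' @export
contingency_rule <- function(map, interactant, block) {
  if (!inherits(map, "contingency_map")) stop("map must be a contingency_map")
  if (!all(interactant %in% c(1L, 2L))) stop("unknown interactant")
  if (!all(block %in% c(1L, 2L))) stop("unknown block")
  n <- max(length(interactant), length(block))
  interactant <- rep_len(interactant, n)
  block <- rep_len(block, n)
  unclass(map)[cbind(as.character(interactant), as.character(block))]
}

#' Correct response for a trial
#'
#' Returns the punishment-avoiding response: the target expression itself
#' when the interactant's rule in that block is `"copy"`, and its opposite
#' when the rule is `"oppose"`. After the reversal (block 2) the rules are
#' swapped, so the block-2 answer is always the opposite of the block-1
#' answer for the same interactant and expression.
#'
#' @param interactant Integer vector in \{1, 2\}.
#' @param target_expression Character vector of expressions.
#' @param block Integer vector in \{1, 2\}.
#' @param contingencies A [contingency_map()].
#' @return Character vector of correct responses.
#' @examples
#' correct_response(1, "smile", 1)  # interactant 1 copies in block 1
#' correct_response(1, "smile", 2)  # reversed after block 1
#' @export
correct_response <- function(interactant, target_expression, block,
                             contingencies = contingency_map()) {
  rule <- contingency_rule(contingencies, interactant, block)
  target_expression <- rep_len(target_expression, length(rule))
  ifelse(rule == "copy", target_expression,
         opposite_expression(target_expression))
}

#' Generate a randomized trial schedule
#'
#' Builds the experiment's trial list: two blocks, each containing every
#' clip (interactant x expression, 4 clips) exactly `reps_per_clip` times in
#' random order, under the constraint that no clip occurs more than
#' `max_consecutive` times in a row (also across the block boundary).
#' Sampling is sequential from the remaining clip counts with backtracking
#' on dead ends, so the per-block counts are exact by construction.
#'
#' @param seed Optional integer seed. When supplied the schedule is a pure
#'   function of the seed; when `NULL` the current RNG stream is used.
#' @param reps_per_clip Repetitions of each of the 4 clips per block
#'   (default 12, i.e. 48 trials per block, 96 in total).
#' @param max_consecutive Maximum run length of a single clip (default 2).
#' @param participant_id Identifier stored in the schedule.
#' @param contingencies A [contingency_map()] defining congruency and the
#'   correct response for each trial.
#' @return A `trial_schedule` data frame with columns `participant_id`,
#'   `trial`, `block`, `interactant`, `target_expression`, `condition`
#'   (congruent/incongruent) and `correct_response`.
#' @examples
#' sch <- generate_schedule(seed = 1)
#' nrow(sch)       # 96
#' table(sch$block)
#' @export
generate_schedule <- function(seed = NULL, reps_per_clip = 12L,
                              max_consecutive = 2L, participant_id = 1L,
                              contingencies = contingency_map()) {
  if (reps_per_clip < 1L) stop("reps_per_clip must be >= 1")
  if (max_consecutive < 1L) stop("max_consecutive must be >= 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  clips <- data.frame(
    interactant = c(1L, 1L, 2L, 2L),
    target_expression = c("smile", "frown", "smile", "frown"),
    stringsAsFactors = FALSE
  )
  b1 <- draw_clip_sequence(reps_per_clip, max_consecutive, integer(0))
  b2 <- draw_clip_sequence(reps_per_clip, max_consecutive,
                           utils::tail(b1, max_consecutive))
  idx <- c(b1, b2)
  n <- length(idx)
  block <- rep(c(1L, 2L), each = n / 2L)
  sch <- data.frame(
    participant_id = participant_id,
    trial = seq_len(n),
    block = block,
    interactant = clips$interactant[idx],
    target_expression = clips$target_expression[idx],
    stringsAsFactors = FALSE
  )
  rule <- contingency_rule(contingencies, sch$interactant, sch$block)
  sch$condition <- ifelse(rule == "copy", "congruent", "incongruent")
  sch$correct_response <- correct_response(sch$interactant,
                                           sch$target_expression, sch$block,
                                           contingencies)
  structure(sch,
            class = c("trial_schedule", "data.frame"),
            seed = seed, reps_per_clip = reps_per_clip,
            max_consecutive = max_consecutive,
            contingencies = contingencies)
}

# Sequential randomized draw of a balanced clip sequence with run-length
# constraint; `prefix` is the tail of the previous block so the constraint
# also holds across the boundary.  Errors if backtracking exhausts the tree.
draw_clip_sequence <- function(reps, max_consecutive, prefix) {
  n <- 4L * reps
  seqv <- integer(n)
  run_of <- function(pos) {
    # current run (clip, length) just before position pos
    full <- c(prefix, seqv[seq_len(pos - 1L)])
    if (!length(full)) return(c(0L, 0L))
    last <- full[length(full)]
    len <- 1L
    while (len < length(full) && full[length(full) - len] == last) len <- len + 1L
    c(last, len)
  }
  rec <- function(pos, counts) {
    if (pos > n) return(TRUE)
    run <- run_of(pos)
    cand <- which(counts > 0L)
    cand <- cand[!(cand == run[1L] & run[2L] >= max_consecutive)]
    if (!length(cand)) return(FALSE)
    for (cl in cand[sample.int(length(cand))]) {
      seqv[pos] <<- cl
      counts2 <- counts
      counts2[cl] <- counts2[cl] - 1L
      if (rec(pos + 1L, counts2)) return(TRUE)
    }
    seqv[pos] <<- 0L
    FALSE
  }
  if (!rec(1L, rep(reps, 4L)))
    stop("scheduling error: run-length constraint unsatisfiable")
  seqv
}

#' Validate a trial schedule against the design invariants
#'
#' Checks total length, per-block clip counts and the maximum run length,
#' and that the correct responses match the contingency map. Errors on the
#' first violation; returns the schedule invisibly otherwise.
#'
#' @param schedule A `trial_schedule` from [generate_schedule()].
#' @export
validate_schedule <- function(schedule) {
  reps <- attr(schedule, "reps_per_clip") %||% max(table(
    schedule$interactant, schedule$target_expression, schedule$block))
  maxc <- attr(schedule, "max_consecutive") %||% 2L
  if (nrow(schedule) != 8L * reps) stop("schedule has wrong length")
  tab <- table(schedule$interactant, schedule$target_expression, schedule$block)
  if (any(tab != reps)) stop("unbalanced clip counts within block")
  clip <- paste(schedule$interactant, schedule$target_expression)
  runs <- rle(clip)
  if (any(runs$lengths > maxc)) stop("clip run length exceeds max_consecutive")
  cmap <- attr(schedule, "contingencies") %||% contingency_map()
  cr <- correct_response(schedule$interactant, schedule$target_expression,
                         schedule$block, cmap)
  if (!identical(cr, schedule$correct_response))
    stop("correct_response column inconsistent with contingency map")
  invisible(schedule)
}

#' Reinforcement for a response
#'
#' Returns +1 (no shock) when the response equals the trial's correct
#' response and -1 (shock) when it is the wrong expression or when no
#' response was formed (`NA`).
#'
#' @param response Character vector of responses, `NA` for no response.
#' @param correct Character vector of correct responses.
#' @return Integer vector of +1 / -1.
#' @examples
#' reinforcement(c("smile", "frown", NA), c("smile", "smile", "smile"))
#' @export
reinforcement <- function(response, correct) {
  n <- max(length(response), length(correct))
  response <- rep_len(response, n)
  correct <- rep_len(correct, n)
  ifelse(!is.na(response) & response == correct, 1L, -1L)
}

#' Write / read a trial schedule as CSV
#'
#' The serialization uses one row per trial with a mandatory header and
#' 1-based trial indices.
#'
#' @param schedule A `trial_schedule`.
#' @param path File path.
#' @export
write_schedule_csv <- function(schedule, path) {
  out <- as.data.frame(schedule)
  names(out)[names(out) == "trial"] <- "trial_index"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  sch <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(sch)[names(sch) == "trial_index"] <- "trial"
  structure(sch, class = c("trial_schedule", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
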