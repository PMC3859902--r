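#' Stimulus-response contingencies for the discrimination task
#'
#' Builds the fixed mapping that defines one subject's version of the
#' two-alternative discrimination ("fruit box") task: six discriminative
#' stimuli, six distinct outcomes, a bijective stimulus-to-outcome assignment,
#' and a correct response (`"LEFT"` or `"RIGHT"`) for each stimulus, with
#' exactly three stimuli assigned to each side. The assignment of outcomes and
#' response sides is randomized per seed, emulating across-subject
#' counterbalancing of stimulus/outcome roles; the contingencies themselves
#' never change within a session.
#'
#' Stimuli and outcomes are abstract labels (`S1..S6`, `O1..O6`); the fruit
#' icons of the original task are cosmetic and carry no structure.
#'
#' @param seed Non-negative integer seed; the map is deterministic given the
#'   seed and the global RNG state is left untouched.
#' @return An object of class `contingency_map`: a list with elements
#'   `stimuli` (character, length 6), `outcomes` (character, length 6),
#'   `correct_response` (named character, stimulus -> `"LEFT"`/`"RIGHT"`) and
#'   `outcome_of` (named character, stimulus -> outcome, a bijection).
#' @examples
#' cmap <- make_contingency(seed = 1)
#' table(cmap$correct_response)  # always 3 LEFT, 3 RIGHT
#' @export
make_contingency <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, seed == floor(seed))
  stimuli  <- paste0("S", 1:6)
  outcomes <- paste0("O", 1:6)
  withr::with_seed(seed, {
    outcome_of <- stats::setNames(sample(outcomes), stimuli)
    left_set   <- sample(stimuli, 3L)
  })
  correct <- stats::setNames(ifelse(stimuli %in% left_set, "LEFT", "RIGHT"),
                             stimuli)
  structure(
    list(stimuli = stimuli, outcomes = outcomes,
         correct_response = correct, outcome_of = outcome_of),
    class = "contingency_map"
  )
}

#' @export
print.contingency_map <- function(x, ...) {
  cat("<contingency_map> 6 stimuli, 6 outcomes\n")
  print(data.frame(stimulus = x$stimuli,
                   correct_response = unname(x$correct_response[x$stimuli]),
                   outcome = unname(x$outcome_of[x$stimuli])),
        row.names = FALSE)
  invisible(x)
}

#' Randomized 96-trial schedule
#'
#' Lays out the session as 8 blocks of 12 trials. Within each block every
#' stimulus appears exactly twice, and the order of the 12 slots is an
#' independent uniform permutation per block.
#'
#' @param contingency A [make_contingency()] object.
#' @param seed Integer seed; schedules are deterministic given the seed.
#' @return A tibble of class `task_schedule` with 96 rows and columns
#'   `trial_index` (1..96), `block` (1..8), `stimulus`, `correct_response`.
#'   The seed is stored in attribute `"seed"`.
#' @examples
#' sched <- build_schedule(make_contingency(1), seed = 7)
#' table(sched$block, sched$stimulus)  # all entries 2
#' @export
build_schedule <- function(contingency, seed) {
  stopifnot(inherits(contingency, "contingency_map"))
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == floor(seed))
  stim <- withr::with_seed(seed, {
    unlist(lapply(1:8, function(b) sample(rep(contingency$stimuli, 2L))),
           use.names = FALSE)
  })
  out <- tibble::tibble(
    trial_index = 1:96,
    block = rep(1:8, each = 12L),
    stimulus = stim,
    correct_response = unname(contingency$correct_response[stim])
  )
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("task_schedule", class(out))
  out
}

#' Validate a schedule against the task-structure invariants
#'
#' Checks the three structural invariants of the task: 96 trials; blocks of 12
#' with `block == ceiling(trial_index / 12)`; and each of the six stimuli
#' appearing exactly twice per block. Violations name the block and stimulus
#' involved where applicable.
#'
#' @param schedule A data frame with columns `trial_index`, `block`,
#'   `stimulus` (the output of [build_schedule()], or imported trial data).
#' @return Character vector of human-readable violations; `character(0)` when
#'   the schedule is valid.
#' @export
validate_schedule <- function(schedule) {
  viol <- character(0)
  need <- c("trial_index", "block", "stimulus")
  if (!all(need %in% names(schedule))) {
    return(sprintf("missing column(s): %s",
                   paste(setdiff(need, names(schedule)), collapse = ", ")))
  }
  if (nrow(schedule) != 96L)
    viol <- c(viol, sprintf("schedule has %d trials, expected 96", nrow(schedule)))
  if (!identical(as.integer(schedule$trial_index), seq_len(nrow(schedule))))
    viol <- c(viol, "trial_index is not the consecutive sequence 1..n")
  bad_block <- schedule$block != ceiling(schedule$trial_index / 12)
  if (any(bad_block))
    viol <- c(viol, sprintf("block/trial_index mismatch at trial %d",
                            schedule$trial_index[which(bad_block)[1L]]))
  stimuli <- sort(unique(schedule$stimulus))
  if (length(stimuli) != 6L)
    viol <- c(viol, sprintf("%d distinct stimuli, expected 6", length(stimuli)))
  counts <- table(factor(schedule$block, levels = sort(unique(schedule$block))),
                  schedule$stimulus)
  off <- which(counts != 2L, arr.ind = TRUE)
  if (nrow(off) > 0L) {
    viol <- c(viol, sprintf(
      "block %s: stimulus %s appears %d times, expected 2",
      rownames(counts)[off[, 1L]], colnames(counts)[off[, 2L]],
      counts[off]))
  }
  viol
}

#' Read/write schedules as delimited text
#'
#' Tab-separated export with one header row and one row per trial, columns
#' `trial_index`, `block`, `stimulus`, `correct_response`.
#'
#' @param schedule A schedule data frame.
#' @param path File path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a `task_schedule` tibble.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(
    schedule[c("trial_index", "block", "stimulus", "correct_response")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  class(out) <- c("task_schedule", class(out))
  out
}
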