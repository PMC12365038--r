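#' Standard braille stimulus patterns
#'
#' The tactile task uses five fixed braille patterns on a 4 x 2 pin grid.
#' Every pattern has exactly 4 pins raised and 4 lowered, so that all stimuli
#' deliver the same total tactile energy and differ only in spatial layout.
#'
#' @return A list of 5 pattern objects, each a list with `pattern_id`
#'   (integer 1..5) and `pins`, a 4 x 2 logical matrix (`TRUE` = pin up).
#' @examples
#' pats <- make_standard_patterns()
#' sapply(pats, function(p) sum(p$pins))  # all 4
#' @export
make_standard_patterns <- function() {
  # rows of the 4 x 2 grid listed top to bottom, left column then right
  raw <- list(
    c(1, 1, 1, 1, 0, 0, 0, 0),
    c(0, 0, 0, 0, 1, 1, 1, 1),
    c(1, 0, 1, 0, 0, 1, 0, 1),
    c(0, 1, 0, 1, 1, 0, 1, 0),
    c(1, 1, 0, 0, 0, 0, 1, 1)
  )
  lapply(seq_along(raw), function(i) {
    list(pattern_id = i,
         pins = matrix(as.logical(raw[[i]]), nrow = 4, ncol = 2))
  })
}

#' Draw the number of target presentations for one trial
#'
#' Target counts follow a gamma distribution with shape 4 and scale 0.3
#' (mean 1.2), rounded to the nearest integer and clipped to the number of
#' available probe slots (5), since at most one target can occupy each probe.
#'
#' @param n Number of draws.
#' @param shape,scale Gamma parameters.
#' @param max_count Upper clip (number of probes per trial).
#' @return Integer vector of counts in `0..max_count`.
#' @export
sample_target_count <- function(n = 1, shape = 4, scale = 0.3, max_count = 5) {
  raw <- stats::rgamma(n, shape = shape, scale = scale)
  as.integer(pmin(pmax(round(raw), 0), max_count))
}

# probe onsets (s, trial-relative) and stimulus duration (s)
.probe_onsets <- function() seq(7.0, by = 1.1, length.out = 5)
.probe_duration <- 0.26

#' Generate the braille attention task schedule
#'
#' Builds the full timed trial structure: `n_trials` 16 s task trials in a
#' randomised but exactly balanced cue order (half left, half right), with a
#' 16 s rest trial inserted after every block of `rest_every` task trials
#' (including after the final complete block). Each task trial presents a
#' target pattern bilaterally in the 1-3 s window, a visual attention cue in
#' the 4-6 s window, and five 260 ms probe stimuli starting at 7 s with 1.1 s
#' spacing. The number of target-pattern presentations on the cued hand is
#' gamma-distributed (shape 4, scale 0.3, rounded, clipped to 0..5); all
#' other probes land on a pseudo-random hand with a non-target pattern on the
#' cued hand. At (80, 10) the total schedule length is 1408 s.
#'
#' @param n_trials Even number of task trials (default 80).
#' @param rest_every One rest trial after each block of this many task trials.
#' @param seed Optional integer seed; the schedule is a deterministic
#'   function of the seed.
#' @param error_rate Probability that the simulated subject responds
#'   incorrectly to a probe (used downstream to exercise the
#'   incorrect-response exclusion path).
#' @return A `braille_schedule`: list with `trials` (data frame: `index`,
#'   `start_s`, `is_rest`, `cue`, `target_pattern_id`), `probes` (data frame:
#'   `trial_index`, `probe_index`, `onset_s` trial-relative, `hand`,
#'   `pattern_id`, `is_target`, `response_error`), `patterns`,
#'   `total_duration_s`, `n_task`, `rest_every`.
#' @export
generate_schedule <- function(n_trials = 80, rest_every = 10, seed = NULL,
                              error_rate = 0.05) {
  if (n_trials < 0 || rest_every < 1)
    stop("n_trials must be >= 0 and rest_every >= 1")
  if (n_trials %% 2L != 0L)
    stop("n_trials must be even: cue order cannot be balanced otherwise")
  if (!is.null(seed)) set.seed(seed)

  patterns <- make_standard_patterns()

  if (n_trials == 0L) {
    trials <- data.frame(index = integer(), start_s = numeric(),
                         is_rest = logical(), cue = character(),
                         target_pattern_id = integer(),
                         stringsAsFactors = FALSE)
    probes <- data.frame(trial_index = integer(), probe_index = integer(),
                         onset_s = numeric(), hand = character(),
                         pattern_id = integer(), is_target = logical(),
                         response_error = logical(), stringsAsFactors = FALSE)
    out <- list(trials = trials, probes = probes, patterns = patterns,
                total_duration_s = 0, n_task = 0L, rest_every = rest_every)
    class(out) <- "braille_schedule"
    return(out)
  }

  cues <- sample(rep(c("left", "right"), n_trials / 2L))

  is_rest <- logical(0)
  cue_seq <- character(0)
  taken <- 0L
  while (taken < n_trials) {
    blk <- min(rest_every, n_trials - taken)
    cue_seq <- c(cue_seq, cues[(taken + 1L):(taken + blk)])
    is_rest <- c(is_rest, rep(FALSE, blk))
    taken <- taken + blk
    if (blk == rest_every) {       # full block completed -> rest trial
      is_rest <- c(is_rest, TRUE)
      cue_seq <- c(cue_seq, NA_character_)
    }
  }

  n_total <- length(is_rest)
  trials <- data.frame(
    index = seq_len(n_total),
    start_s = 16 * (seq_len(n_total) - 1),
    is_rest = is_rest,
    cue = cue_seq,
    target_pattern_id = NA_integer_,
    stringsAsFactors = FALSE
  )

  onsets <- .probe_onsets()
  probe_rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    if (trials$is_rest[i]) next
    cue <- trials$cue[i]
    target <- sample.int(5L, 1L)
    trials$target_pattern_id[i] <- target
    n_targets <- sample_target_count(1L)
    target_slots <- if (n_targets > 0) sample.int(5L, n_targets) else integer(0)
    hand <- character(5)
    patt <- integer(5)
    for (p in 1:5) {
      if (p %in% target_slots) {
        hand[p] <- cue                      # targets by definition on cued hand
        patt[p] <- target
      } else {
        hand[p] <- sample(c("left", "right"), 1L)
        patt[p] <- if (hand[p] == cue) {
          sample(setdiff(1:5, target), 1L)  # avoid accidental targets
        } else {
          sample.int(5L, 1L)
        }
      }
    }
    probe_rows[[i]] <- data.frame(
      trial_index = i, probe_index = 1:5, onset_s = onsets,
      hand = hand, pattern_id = patt,
      is_target = patt == target & hand == cue,
      response_error = stats::runif(5) < error_rate,
      stringsAsFactors = FALSE
    )
  }
  probes <- do.call(rbind, probe_rows[!vapply(probe_rows, is.null, TRUE)])
  rownames(probes) <- NULL

  out <- list(trials = trials, probes = probes, patterns = patterns,
              total_duration_s = 16 * n_total, n_task = as.integer(n_trials),
              rest_every = as.integer(rest_every))
  class(out) <- "braille_schedule"
  out
}

#' @export
print.braille_schedule <- function(x, ...) {
  cat(sprintf("braille attention schedule: %d task + %d rest trials, %.0f s\n",
              x$n_task, sum(x$trials$is_rest), x$total_duration_s))
  invisible(x)
}

#' Flatten a schedule into a BIDS-style event table
#'
#' One row per timed event on the experiment clock: target presentations
#' (1-3 s), attention cues (4-6 s), probe stimuli (260 ms) split into
#' attended / non-attended by the hand-cue match, and whole rest trials.
#'
#' @param schedule A `braille_schedule`.
#' @return Data frame with columns `onset`, `duration`, `trial_type`
#'   (`target`, `cue_left`, `cue_right`, `probe_attended`,
#'   `probe_nonattended`, `rest`), `hand`, `pattern_id`, `is_target`,
#'   `response_error`, `trial_index`; onsets non-decreasing.
#' @export
schedule_to_events <- function(schedule) {
  stopifnot(inherits(schedule, "braille_schedule"))
  tr <- schedule$trials
  empty <- data.frame(onset = numeric(), duration = numeric(),
                      trial_type = character(), hand = character(),
                      pattern_id = integer(), is_target = logical(),
                      response_error = logical(), trial_index = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(tr) == 0L) return(empty)

  rows <- list()
  task <- tr[!tr$is_rest, , drop = FALSE]
  if (nrow(task) > 0) {
    rows$target <- data.frame(
      onset = task$start_s + 1, duration = 2, trial_type = "target",
      hand = NA_character_, pattern_id = task$target_pattern_id,
      is_target = NA, response_error = NA, trial_index = task$index,
      stringsAsFactors = FALSE)
    rows$cue <- data.frame(
      onset = task$start_s + 4, duration = 2,
      trial_type = paste0("cue_", task$cue),
      hand = task$cue, pattern_id = NA_integer_,
      is_target = NA, response_error = NA, trial_index = task$index,
      stringsAsFactors = FALSE)
  }
  if (!is.null(schedule$probes) && nrow(schedule$probes) > 0) {
    pb <- schedule$probes
    cue_of <- tr$cue[pb$trial_index]
    rows$probe <- data.frame(
      onset = tr$start_s[pb$trial_index] + pb$onset_s,
      duration = .probe_duration,
      trial_type = ifelse(pb$hand == cue_of, "probe_attended",
                          "probe_nonattended"),
      hand = pb$hand, pattern_id = pb$pattern_id,
      is_target = pb$is_target, response_error = pb$response_error,
      trial_index = pb$trial_index, stringsAsFactors = FALSE)
  }
  rest <- tr[tr$is_rest, , drop = FALSE]
  if (nrow(rest) > 0) {
    rows$rest <- data.frame(
      onset = rest$start_s, duration = 16, trial_type = "rest",
      hand = NA_character_, pattern_id = NA_integer_,
      is_target = NA, response_error = NA, trial_index = rest$index,
      stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$onset, ev$trial_index), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Write / read an events table as tab-separated text
#'
#' BIDS events.tsv dialect: columns `onset`, `duration`, `trial_type` first,
#' missing values encoded as `n/a`.
#'
#' @param events Event table from [schedule_to_events()].
#' @param path File path.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns the event table with types restored.
#' @export
write_events_tsv <- function(events, path) {
  first <- c("onset", "duration", "trial_type")
  events <- events[, c(first, setdiff(names(events), first)), drop = FALSE]
  out <- events
  for (j in seq_along(out)) {
    v <- as.character(out[[j]])
    v[is.na(v)] <- "n/a"
    out[[j]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  for (col in c("is_target", "response_error"))
    if (col %in% names(ev)) ev[[col]] <- as.logical(ev[[col]])
  ev
}
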