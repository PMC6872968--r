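#' Build a block task paradigm
#'
#' Constructs the timing of a blocked auditory fMRI run: an initial fixation
#' period followed by alternating task and rest blocks, with an optional
#' closing rest period. The default configuration reproduces a 402 s run:
#' 8 s fixation, eight 36 s task blocks (12 stimuli of 2.5 s with a 0.5 s
#' inter-stimulus interval) interleaved with eight 12 s rest blocks, and a
#' final 10 s of rest, sampled at TR = 2 s (201 volumes).
#'
#' @param fixation_duration seconds of initial fixation.
#' @param n_task_blocks number of task blocks.
#' @param rest_block_duration seconds per interleaved rest block.
#' @param stimulus_duration seconds per stimulus.
#' @param inter_stimulus_interval seconds between stimuli.
#' @param stimuli_per_block stimuli per task block (>= 1).
#' @param final_rest_duration seconds of rest appended after the last block.
#' @param TR repetition time in seconds.
#' @return an object of class `dfnc_paradigm`: a list with `blocks`
#'   (data.frame with `condition`, `onset`, `duration`), `TR`,
#'   `task_block_duration`, `total_duration` and `n_volumes`.
#' @examples
#' p <- make_paradigm()
#' sum(p$blocks$condition == "task")  # 8
#' p$task_block_duration              # 36
#' @export
make_paradigm <- function(fixation_duration = 8,
                          n_task_blocks = 8,
                          rest_block_duration = 12,
                          stimulus_duration = 2.5,
                          inter_stimulus_interval = 0.5,
                          stimuli_per_block = 12,
                          final_rest_duration = 10,
                          TR = 2) {
  durs <- c(fixation_duration = fixation_duration,
            rest_block_duration = rest_block_duration,
            stimulus_duration = stimulus_duration,
            inter_stimulus_interval = inter_stimulus_interval,
            TR = TR)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop_config("all durations and TR must be positive and finite")
  }
  if (final_rest_duration < 0) stop_config("final_rest_duration must be >= 0")
  if (stimuli_per_block < 1) stop_config("stimuli_per_block must be >= 1")
  if (n_task_blocks < 1) stop_config("n_task_blocks must be >= 1")

  task_dur <- stimuli_per_block * (stimulus_duration + inter_stimulus_interval)

  condition <- c("fixation",
                 rep(c("task", "rest"), n_task_blocks))
  duration <- c(fixation_duration,
                rep(c(task_dur, rest_block_duration), n_task_blocks))
  if (final_rest_duration > 0) {
    condition <- c(condition, "rest")
    duration <- c(duration, final_rest_duration)
  }
  onset <- cumsum(c(0, duration[-length(duration)]))
  total <- sum(duration)
  structure(list(
    blocks = data.frame(condition = condition, onset = onset,
                        duration = duration, stringsAsFactors = FALSE),
    TR = TR,
    stimulus_duration = stimulus_duration,
    inter_stimulus_interval = inter_stimulus_interval,
    stimuli_per_block = stimuli_per_block,
    task_block_duration = task_dur,
    total_duration = total,
    n_volumes = as.integer(floor(total / TR + 1e-9))
  ), class = "dfnc_paradigm")
}

#' @export
print.dfnc_paradigm <- function(x, ...) {
  cat("Block paradigm:", nrow(x$blocks), "blocks,",
      x$total_duration, "s total,", x$n_volumes, "volumes at TR =",
      x$TR, "s\n")
  invisible(x)
}

#' Task indicator sampled on the TR grid
#'
#' Returns a 0/1 vector of length `n_volumes`, 1 where the volume's
#' acquisition onset `(t - 1) * TR` falls inside a task block.
#'
#' @param paradigm a [make_paradigm()] object.
#' @param n_volumes number of volumes (default: paradigm's own count).
#' @return numeric 0/1 vector.
#' @export
paradigm_boxcar <- function(paradigm, n_volumes = paradigm$n_volumes) {
  stopifnot(inherits(paradigm, "dfnc_paradigm"))
  t_on <- (seq_len(n_volumes) - 1) * paradigm$TR
  box <- numeric(n_volumes)
  task <- paradigm$blocks[paradigm$blocks$condition == "task", , drop = FALSE]
  for (i in seq_len(nrow(task))) {
    box[t_on >= task$onset[i] - 1e-9 &
          t_on < task$onset[i] + task$duration[i] - 1e-9] <- 1
  }
  box
}

#' Write paradigm timing as a three-column TSV (onset, duration, condition)
#' @param paradigm a [make_paradigm()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_paradigm_tsv <- function(paradigm, path) {
  stopifnot(inherits(paradigm, "dfnc_paradigm"))
  df <- paradigm$blocks[, c("onset", "duration", "condition")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
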