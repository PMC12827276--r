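# CSV readers/writers for the pipeline's exchange dialects.  All are thin
# validated wrappers around read.csv/write.csv.

#' Read a sorted-spike table (`unit_id,time_s`)
#' @param path CSV path.
#' @return data.frame with `unit_id`, `time_s`, sorted per unit.
#' @export
read_spikes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("unit_id", "time_s") %in% names(d)))
  if (any(!is.finite(d$time_s))) stop("spike times must be finite")
  d[order(d$unit_id, d$time_s), , drop = FALSE]
}

#' Read a stimulation-trial table
#' (`trial_id,led_row,led_col,irradiance,onset_s`)
#' @param path CSV path.
#' @return data.frame validated for strictly increasing onsets and in-range
#'   LED indices.
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("trial_id", "onset_s") %in% names(d)))
  if (is.unsorted(d$onset_s, strictly = TRUE))
    stop("trial onsets must be strictly increasing")
  for (col in c("led_row", "led_col"))
    if (col %in% names(d) && any(d[[col]] < 0 | d[[col]] > 9))
      stop(col, " must lie in 0..9")
  d
}

#' Read lick timestamps (`time_s`)
#' @param path CSV path.
#' @return Sorted numeric vector of lick times.
#' @export
read_licks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("time_s" %in% names(d))
  sort(d$time_s)
}

#' Read beam-break intervals (`start_s,end_s`)
#' @param path CSV path.
#' @return data.frame with `start_s`, `end_s`.
#' @export
read_beam <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("start_s", "end_s") %in% names(d)))
  if (any(d$end_s < d$start_s)) stop("beam intervals must have end >= start")
  d
}

#' Read an L-I measurement table
#' (`led_id,current_mA,power_mW[,electrical_mW]`)
#' @param path CSV path.
#' @return data.frame of per-LED current/power samples.
#' @export
read_li_samples <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("led_id", "current_mA", "power_mW") %in% names(d)))
  if (any(d$power_mW < 0)) stop("optical powers must be >= 0")
  d
}

#' Write scored trial outcomes to CSV
#' @param outcomes data.frame from [score_headfixed()]/[score_freely()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE)
  invisible(path)
}
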