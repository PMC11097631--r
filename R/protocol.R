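# Stimulus protocols and the octave frequency axis.
#
# All tuning mathematics runs on the octave axis x = log2(f / 4 kHz), so the
# 17-tone grid becomes 0, 0.25, ..., 4 octaves and bandwidths come out in
# octaves directly.

#' Convert between kHz and the octave axis (re 4 kHz)
#' @param f_khz frequency in kHz
#' @return octaves above 4 kHz
#' @export
khz_to_oct <- function(f_khz) log2(f_khz / 4)

#' @rdname khz_to_oct
#' @param oct octaves above 4 kHz
#' @export
oct_to_khz <- function(oct) 4 * 2^oct

#' The 17-tone pure-tone grid (4-64 kHz, four steps per octave)
#' @return numeric vector of 17 frequencies in kHz
#' @export
pt_frequencies <- function() oct_to_khz(seq(0, 4, by = 0.25))

#' Pure-tone SPL levels used for frequency response areas
#' @return 30, 40, 50, 60, 70 dB SPL
#' @export
pt_spls <- function() seq(30, 70, by = 10)

#' Build a pure-tone stimulus protocol
#'
#' Events cover the full 17 frequency x 5 SPL grid with `n_rep` repetitions.
#' Tone length 250 ms followed by a 1 s pause; presentation order is
#' randomized within each repetition (seeded). A lead-in pause precedes the
#' first tone so pre-stimulus windows always exist.
#'
#' @param n_rep repetitions per frequency/SPL combination (default 10)
#' @param frame_rate imaging frame rate in Hz (default 29.76)
#' @param tone_s tone duration in seconds
#' @param pause_s pause between tones in seconds
#' @param spls SPL levels (dB); a single level gives the 70 dB-only paradigm
#' @param lead_in_s silence before the first tone
#' @param seed RNG seed controlling presentation order
#' @return object of class `stimulus_protocol`: a list with `events`
#'   (data.frame: sound_id, class, freq_khz, spl_db, onset_frame,
#'   offset_frame, rep), `frame_rate`, `n_frames`, and grid attributes
#' @export
pt_protocol <- function(n_rep = 10, frame_rate = 29.76, tone_s = 0.25,
                        pause_s = 1, spls = pt_spls(), lead_in_s = 2,
                        seed = 1L) {
  freqs <- pt_frequencies()
  combos <- expand.grid(freq_khz = freqs, spl_db = spls,
                        KEEP.OUT.ATTRS = FALSE)
  combos$sound_id <- sprintf("PT_%05.2fkHz_%02ddB", combos$freq_khz,
                             combos$spl_db)
  events <- with_seed(seed, {
    ev <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
      ord <- sample.int(nrow(combos))
      cbind(combos[ord, ], rep = r)
    }))
    ev
  })
  n_ev <- nrow(events)
  step <- tone_s + pause_s
  onsets_s <- lead_in_s + (seq_len(n_ev) - 1) * step
  events$onset_frame <- floor(onsets_s * frame_rate) + 1L
  events$offset_frame <- floor((onsets_s + tone_s) * frame_rate) + 1L
  events$class <- "PT"
  rownames(events) <- NULL
  n_frames <- ceiling((lead_in_s + n_ev * step + 2) * frame_rate)
  structure(list(events = events[, c("sound_id", "class", "freq_khz",
                                     "spl_db", "onset_frame", "offset_frame",
                                     "rep")],
                 frame_rate = frame_rate, n_frames = n_frames,
                 freqs = freqs, spls = spls, n_rep = n_rep,
                 tone_s = tone_s, pause_s = pause_s),
            class = "stimulus_protocol")
}

#' Build a generic sound protocol (AM tones, complex sounds, ...)
#'
#' Used by the ensemble stages, where sounds need no frequency/SPL grid.
#'
#' @param sound_ids character vector of sound labels
#' @param classes sound class per sound (`"PT"`, `"AM"`, `"complex"`)
#' @param n_rep repetitions
#' @param frame_rate Hz
#' @param stim_s,pause_s,lead_in_s timing in seconds
#' @param seed RNG seed for presentation order
#' @return `stimulus_protocol` object
#' @export
sound_protocol <- function(sound_ids, classes = "complex", n_rep = 10,
                           frame_rate = 29.76, stim_s = 0.55, pause_s = 1,
                           lead_in_s = 2, seed = 1L) {
  classes <- rep_len(classes, length(sound_ids))
  base <- data.frame(sound_id = sound_ids, class = classes,
                     freq_khz = NA_real_, spl_db = 70,
                     stringsAsFactors = FALSE)
  events <- with_seed(seed, do.call(rbind, lapply(seq_len(n_rep), function(r) {
    cbind(base[sample.int(nrow(base)), ], rep = r)
  })))
  step <- stim_s + pause_s
  onsets_s <- lead_in_s + (seq_len(nrow(events)) - 1) * step
  events$onset_frame <- floor(onsets_s * frame_rate) + 1L
  events$offset_frame <- floor((onsets_s + stim_s) * frame_rate) + 1L
  rownames(events) <- NULL
  structure(list(events = events[, c("sound_id", "class", "freq_khz",
                                     "spl_db", "onset_frame", "offset_frame",
                                     "rep")],
                 frame_rate = frame_rate,
                 n_frames = ceiling((lead_in_s + nrow(events) * step + 2) *
                                      frame_rate),
                 freqs = NULL, spls = NULL, n_rep = n_rep,
                 tone_s = stim_s, pause_s = pause_s),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("stimulus_protocol:", nrow(x$events), "events,",
      length(unique(x$events$sound_id)), "sounds x", x$n_rep, "reps @",
      x$frame_rate, "Hz\n")
  invisible(x)
}

# SPL gain used by the synthetic generator: monotone saturating ramp from
# 0.4 at 30 dB SPL to 1.0 at 70 dB SPL. The analysis never assumes this
# shape; only monotonicity matters for BF recovery.
spl_gain <- function(spl_db) {
  u <- (spl_db - 30) / 40
  0.4 + 0.6 * (1 - exp(-2 * u)) / (1 - exp(-2))
}
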