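# NeuronRecording container: one imaged neuron's traces plus geometry.

#' Construct a neuron recording
#'
#' Bundles the raw ROI fluorescence trace, the local neuropil trace, the
#' deconvolved spike-probability trace, and the neuron's position within its
#' field of view. All traces must have equal length and the spike-probability
#' trace must be nonnegative.
#'
#' @param raw raw ROI fluorescence per frame (a.u.)
#' @param neuropil neuropil fluorescence per frame (a.u.)
#' @param spikes deconvolved spike probability per frame (nonnegative)
#' @param position numeric (x, y) in um, FOV-local
#' @param fov_id field-of-view label
#' @param depth imaging depth (um)
#' @param frame_rate Hz
#' @param neuron_id optional identifier
#' @return object of class `neuron_recording`
#' @export
neuron_recording <- function(raw, neuropil, spikes = NULL, position = c(0, 0),
                             fov_id = "FOV1", depth = 200,
                             frame_rate = 29.76, neuron_id = NA_character_) {
  n <- length(raw)
  if (n == 0) stop("traces must be nonempty")
  if (length(neuropil) != n ||
      (!is.null(spikes) && length(spikes) != n))
    stop("all traces must have the same length")
  if (!is.null(spikes) && any(spikes < 0, na.rm = TRUE))
    stop("spike-probability trace must be nonnegative")
  if (frame_rate <= 0) stop("'frame_rate' must be > 0")
  structure(list(raw = as.numeric(raw), neuropil = as.numeric(neuropil),
                 spikes = if (is.null(spikes)) NULL else as.numeric(spikes),
                 position = as.numeric(position[1:2]), fov_id = fov_id,
                 depth = depth, frame_rate = frame_rate,
                 neuron_id = neuron_id),
            class = "neuron_recording")
}

#' @export
print.neuron_recording <- function(x, ...) {
  cat("neuron_recording", x$neuron_id, "-", length(x$raw), "frames @",
      x$frame_rate, "Hz, FOV", x$fov_id, "\n")
  invisible(x)
}
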