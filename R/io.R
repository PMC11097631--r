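# Plain-text interchange: CSV for tables and maps, JSON for schedules,
# truth records and cluster results. (No TIFF/HDF5 writer is available in
# the target environment; movies stay in memory and maps are exchanged as
# CSV.)

#' Write/read a stimulus protocol as JSON
#' @param protocol a `stimulus_protocol`
#' @param path file path
#' @export
write_protocol_json <- function(protocol, path) {
  jsonlite::write_json(list(events = protocol$events,
                            frame_rate = protocol$frame_rate,
                            n_frames = protocol$n_frames,
                            n_rep = protocol$n_rep,
                            tone_s = protocol$tone_s,
                            pause_s = protocol$pause_s),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(events = x$events, frame_rate = x$frame_rate,
                 n_frames = x$n_frames,
                 freqs = sort(unique(x$events$freq_khz)),
                 spls = sort(unique(x$events$spl_db)), n_rep = x$n_rep,
                 tone_s = x$tone_s, pause_s = x$pause_s),
            class = "stimulus_protocol")
}

#' Write a pixel best-frequency map as CSV (long format)
#' @param map a `pixel_bf_map`
#' @param path file path
#' @export
write_bf_map_csv <- function(map, path) {
  H <- map$height; W <- map$width
  df <- data.frame(row = rep(seq_len(H), times = W),
                   col = rep(seq_len(W), each = H),
                   bf_khz = as.vector(map$bf_khz),
                   norm_amp = as.vector(map$norm_amp),
                   responsive = as.vector(map$responsive))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a cluster result (labels + metrics) as JSON
#' @param result a `cluster_result`
#' @param path file path
#' @export
write_cluster_json <- function(result, path) {
  jsonlite::write_json(
    list(labels = as.list(result$labels),
         n_clusters = result$n_clusters,
         cluster_sizes = result$cluster_sizes,
         fraction_clustered = result$fraction_clustered,
         within_cor = result$within_cor,
         between_cor = result$between_cor,
         within_reliability = result$within_reliability),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
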