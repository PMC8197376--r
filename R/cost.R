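# Analytic deployment-cost model for a remote acoustic sensor connected
# over a low-rate radio link: raw media sizes, transmission times, and
# end-to-end latency under the centralized (ship the audio) and
# distributed (classify on the node, ship the result) paradigms.

#' Media and link specifications
#'
#' `media_spec()` describes an uncompressed PCM recording;
#' `link_spec()` a radio link by its raw data rate; `node_timing()` the
#' measured on-node processing times (mel front end and CNN inference)
#' and the size of one classification result message.
#'
#' @param duration_s recording duration in seconds.
#' @param sample_rate_hz sampling rate in Hz.
#' @param bits_per_sample PCM resolution.
#' @param channels channel count (1 = mono).
#' @return a `media_spec` list.
#' @examples
#' media_size(media_spec(60))           # one minute of 16-bit mono audio
#' tx_time(70, link_spec(1000))         # one result message over 1 kbps
#' @export
media_spec <- function(duration_s, sample_rate_hz = 44100,
                       bits_per_sample = 16, channels = 1) {
  stopifnot(duration_s >= 0, sample_rate_hz > 0, bits_per_sample > 0,
            channels > 0)
  structure(list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 bits_per_sample = bits_per_sample, channels = channels),
            class = "media_spec")
}

#' @rdname media_spec
#' @param data_rate_bps link data rate in bits per second.
#' @export
link_spec <- function(data_rate_bps) {
  stopifnot(data_rate_bps > 0)
  structure(list(data_rate_bps = data_rate_bps), class = "link_spec")
}

#' @rdname media_spec
#' @param preprocess_s on-node mel-spectrogram computation time (s).
#' @param cnn_exec_s on-node CNN inference time (s).
#' @param result_bytes size of one classification result message (bytes).
#' @export
node_timing <- function(preprocess_s = 0.120, cnn_exec_s = 0.160,
                        result_bytes = 70) {
  stopifnot(preprocess_s >= 0, cnn_exec_s >= 0, result_bytes >= 0)
  structure(list(preprocess_s = preprocess_s, cnn_exec_s = cnn_exec_s,
                 result_bytes = result_bytes), class = "node_timing")
}

#' Exact size of an uncompressed recording
#'
#' `duration * rate * bits/8 * channels` bytes (raw PCM payload, no
#' container overhead). One minute of 16-bit mono at 44.1 kHz is
#' 5,292,000 bytes, i.e. it rounds to 5 MB in the decimal convention.
#'
#' @param spec a [media_spec()].
#' @return payload size in bytes (exact).
#' @export
media_size <- function(spec) {
  stopifnot(inherits(spec, "media_spec"))
  spec$duration_s * spec$sample_rate_hz * spec$bits_per_sample / 8 *
    spec$channels
}

#' Transmission time of a payload over a link
#'
#' `payload_bytes * 8 * overhead / data_rate_bps` seconds. The default
#' `overhead = 1` reproduces raw-payload arithmetic; a protocol framing
#' multiplier can be supplied.
#'
#' @param payload_bytes payload size in bytes.
#' @param link a [link_spec()].
#' @param overhead multiplicative protocol-overhead factor (>= 1).
#' @return time in seconds.
#' @export
tx_time <- function(payload_bytes, link, overhead = 1) {
  stopifnot(payload_bytes >= 0, inherits(link, "link_spec"), overhead >= 1)
  payload_bytes * 8 * overhead / link$data_rate_bps
}

new_cost_report <- function(paradigm, components, audio_duration_s,
                            subtotals = NULL) {
  total <- sum(components)
  structure(list(paradigm = paradigm, components = components,
                 subtotals = subtotals, total_s = total,
                 audio_duration_s = audio_duration_s,
                 realtime_feasible = total <= audio_duration_s),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("<cost_report> %s paradigm, %g-s audio\n", x$paradigm,
              x$audio_duration_s))
  for (nm in names(x$components))
    cat(sprintf("  %-12s %12.4f s\n", nm, x$components[[nm]]))
  cat(sprintf("  %-12s %12.4f s  (%s real-time)\n", "total", x$total_s,
              if (x$realtime_feasible) "feasible in" else "NOT feasible in"))
  invisible(x)
}

#' Latency of the centralized paradigm
#'
#' The node ships the raw audio to the server over the radio link, where
#' it is processed; backbone time is treated as negligible, so the total
#' is the audio transmission time alone. The report flags whether the
#' total fits within the recording's own duration (real-time
#' feasibility).
#'
#' @param media a [media_spec()] of the shipped recording.
#' @param link a [link_spec()].
#' @param overhead protocol-overhead multiplier.
#' @return a `cost_report`.
#' @examples
#' centralized_latency(media_spec(5), link_spec(1000))
#' @export
centralized_latency <- function(media, link, overhead = 1) {
  new_cost_report("centralized",
                  c(audio_tx = tx_time(media_size(media), link, overhead)),
                  media$duration_s)
}

#' Latency of the distributed paradigm
#'
#' The node computes the mel spectrogram and runs the CNN locally, then
#' ships only the small result message: total = preprocess + inference +
#' result transmission. The on-node processing subtotal (preprocess +
#' inference) is also reported.
#'
#' @param timing a [node_timing()].
#' @param link a [link_spec()].
#' @param audio_duration_s duration of the analyzed clip (s).
#' @param overhead protocol-overhead multiplier.
#' @return a `cost_report` with a `processing` subtotal.
#' @examples
#' distributed_latency(node_timing(), link_spec(1000))
#' @export
distributed_latency <- function(timing = node_timing(), link,
                                audio_duration_s = 5, overhead = 1) {
  comp <- c(preprocess = timing$preprocess_s,
            cnn_exec = timing$cnn_exec_s,
            result_tx = tx_time(timing$result_bytes, link, overhead))
  new_cost_report("distributed", comp, audio_duration_s,
                  subtotals = c(processing = timing$preprocess_s +
                                  timing$cnn_exec_s))
}

#' Time to push a model artifact to a remote node
#'
#' Transmission time of the serialized network (topology + weights) over
#' the radio link; with a ~5 MB artifact on a 1 kbps link this is on the
#' order of half a day, which is why model updates are infrequent,
#' background operations.
#'
#' @param model_bytes artifact size in bytes (e.g. from [export_model()]).
#' @param link a [link_spec()].
#' @param overhead protocol-overhead multiplier.
#' @return time in seconds.
#' @export
model_deploy_time <- function(model_bytes, link, overhead = 1) {
  tx_time(model_bytes, link, overhead)
}
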