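# Log-mel spectrogram front end. The one hard contract: a 5-s, 44.1 kHz
# clip maps to a 128-band x 435-frame matrix. With centered frames the
# frame count is 1 + floor(220500 / hop); hop = 507 is the frozen choice
# that yields exactly 435 (no power-of-two hop does).

#' Mel front-end configuration
#'
#' Parameters of the STFT + mel filterbank + dB stage. Defaults are
#' frozen so that a 220500-sample clip yields exactly 435 frames:
#' `n_fft = 2048`, periodic Hann window, centered frames with reflection
#' padding, `hop = 507`. The mel scale is the HTK formula
#' `mel(f) = 2595 log10(1 + f/700)` with 128 triangular filters spanning
#' 0–22050 Hz. Power is reported in dB with an absolute floor.
#'
#' @param n_mels number of mel bands.
#' @param n_fft analysis window length in samples.
#' @param hop hop between frame centers in samples.
#' @param fmin,fmax filterbank frequency range in Hz.
#' @param log_floor dB clamp applied to the output (an all-zero clip maps
#'   to a matrix filled with this value).
#' @return a `mel_config` object.
#' @examples
#' mel_config()
#' @export
mel_config <- function(n_mels = 128L, n_fft = 2048L, hop = 507L,
                       fmin = 0, fmax = 22050, log_floor = -100) {
  stopifnot(n_mels >= 1, n_fft >= 4, hop >= 1, fmin >= 0, fmax > fmin)
  cfg <- list(n_mels = as.integer(n_mels), n_fft = as.integer(n_fft),
              hop = as.integer(hop), window = "hann", fmin = fmin,
              fmax = fmax, mel_variant = "htk", log_floor = log_floor)
  cfg$n_frames <- 1L + CLIP_LEN %/% cfg$hop
  structure(cfg, class = "mel_config")
}

#' @export
print.mel_config <- function(x, ...) {
  cat(sprintf(paste0("<mel_config> %d mel bands x %d frames | n_fft %d, ",
                     "hop %d, %s window, %g-%g Hz (%s mel), floor %g dB\n"),
              x$n_mels, x$n_frames, x$n_fft, x$hop, x$window, x$fmin, x$fmax,
              x$mel_variant, x$log_floor))
  invisible(x)
}

# per-config constants (frame gather indices, window, filterbank) are
# rebuilt only when the configuration changes
.mel_cache <- new.env(parent = emptyenv())

mel_constants <- function(config) {
  key <- paste(unlist(config), collapse = "|")
  hit <- .mel_cache$key
  if (identical(hit, key)) return(.mel_cache$val)
  starts <- (seq_len(config$n_frames) - 1L) * config$hop
  val <- list(
    idx = outer(seq_len(config$n_fft), starts, `+`),
    win = 0.5 - 0.5 * cos(2 * pi * (seq_len(config$n_fft) - 1) / config$n_fft),
    fb = mel_filterbank(config))
  .mel_cache$key <- key
  .mel_cache$val <- val
  val
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular filterbank (n_mels x (n_fft/2 + 1)), unit peak per filter;
# band center frequencies attached as an attribute
mel_filterbank <- function(cfg, sr = CLIP_SR) {
  n_bins <- cfg$n_fft %/% 2L + 1L
  bin_hz <- (seq_len(n_bins) - 1) * sr / cfg$n_fft
  pts <- mel_to_hz(seq(hz_to_mel(cfg$fmin), hz_to_mel(cfg$fmax),
                       length.out = cfg$n_mels + 2L))
  fb <- matrix(0, cfg$n_mels, n_bins)
  for (m in seq_len(cfg$n_mels)) {
    lo <- pts[m]; ce <- pts[m + 1]; hi <- pts[m + 2]
    up <- (bin_hz - lo) / (ce - lo)
    down <- (hi - bin_hz) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  attr(fb, "centers_hz") <- pts[2:(cfg$n_mels + 1L)]
  fb
}

#' Compute the log-mel spectrogram of a clip
#'
#' Runs the fixed front end: centered STFT (reflection padding), magnitude
#' power spectrum, triangular mel filterbank, dB with floor. Only exact
#' 5-s, 44.1 kHz clips are accepted; the output is always
#' `n_mels x 435`.
#'
#' @param clip an [audio_clip()] or a numeric vector of 220500 samples.
#' @param config a [mel_config()].
#' @return a `melspec` object; its `$matrix` is the `128 x 435` dB matrix.
#' @examples
#' sp <- compute_melspec(generate_clip("ao_standard", seed = 2))
#' dim(sp$matrix)
#' @export
compute_melspec <- function(clip, config = mel_config()) {
  if (inherits(clip, "audio_clip")) {
    if (clip$sample_rate != CLIP_SR)
      stop("clip sample rate must be ", CLIP_SR, " Hz, got ", clip$sample_rate)
    x <- clip$samples
    meta <- clip[c("label", "origin_id", "variant_tag")]
  } else {
    x <- as.numeric(clip)
    meta <- list(label = NA, origin_id = NA, variant_tag = NA)
  }
  if (length(x) != CLIP_LEN)
    stop("clip must have exactly ", CLIP_LEN,
         " samples (5 s at 44.1 kHz), got ", length(x))
  half <- config$n_fft %/% 2L
  n <- length(x)
  x_pad <- c(rev(x[2:(half + 1L)]), x, rev(x[(n - half):(n - 1L)]))
  cst <- mel_constants(config)
  frames <- matrix(x_pad[cst$idx], config$n_fft) * cst$win
  spec <- mvfft(frames)[seq_len(half + 1L), , drop = FALSE]
  power <- Re(spec)^2 + Im(spec)^2
  mel_power <- cst$fb %*% power
  db <- 10 * log10(pmax(mel_power, 10^(config$log_floor / 10)))
  structure(list(matrix = db, config = config, label = meta$label,
                 origin_id = meta$origin_id, variant_tag = meta$variant_tag),
            class = "melspec")
}

#' @export
print.melspec <- function(x, ...) {
  cat(sprintf("<melspec> %d x %d dB matrix [%.1f, %.1f] | %s / %s / %s\n",
              nrow(x$matrix), ncol(x$matrix), min(x$matrix), max(x$matrix),
              x$origin_id, x$label, x$variant_tag))
  invisible(x)
}

#' Min-max normalize a spectrogram
#'
#' Affinely rescales a dB matrix to `[0, 1]`; a constant matrix maps to
#' all zeros.
#'
#' @param spec a `melspec` or numeric matrix.
#' @return a plain numeric matrix with values in `[0, 1]`.
#' @export
normalize_spec <- function(spec) {
  m <- if (inherits(spec, "melspec")) spec$matrix else spec
  stopifnot(is.matrix(m), all(is.finite(m)))
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Export a spectrogram as a JPEG image
#'
#' Writes the spectrogram as a 435 x 128 pixel (width x height) JPEG with
#' time running left to right, low frequencies at the bottom, and
#' amplitude mapped through a dark-blue-to-red colormap, for visual
#' inspection of the dataset.
#'
#' @param spec a `melspec` or numeric matrix.
#' @param path output file path.
#' @param quality JPEG quality in `(0, 1]`.
#' @return invisibly, the path.
#' @export
export_image <- function(spec, path, quality = 0.92) {
  v <- normalize_spec(spec)
  ramp <- grDevices::colorRamp(c("#00008B", "#0000FF", "#00FFFF",
                                 "#FFFF00", "#FF0000"))
  rgb <- ramp(as.vector(v)) / 255
  h <- nrow(v); w <- ncol(v)
  img <- array(0, c(h, w, 3))
  flip <- h:1                         # row 1 of the image = highest band
  for (ch in 1:3)
    img[, , ch] <- matrix(rgb[, ch], h, w)[flip, ]
  jpeg::writeJPEG(img, path, quality = quality)
  invisible(path)
}
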