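# Seeded generator of synthetic anuran-like vocalizations. Every clip is
# 5 s of 44.1 kHz mono audio: a class-specific call structure placed at a
# random onset over a band-limited pink-noise floor at a prescribed SNR.

CLIP_SR <- 44100L
CLIP_DUR <- 5
CLIP_LEN <- 220500L  # round(44100 * 5)

#' Synthetic call signatures
#'
#' A call signature parameterizes the stylized call of one vocalization
#' class: carrier frequency, amplitude-modulation (pulse/trill) rate, call
#' duration and repetition count, linear FM sweep rate, number of
#' harmonics, and relative peak amplitude. The defaults (one per class) are
#' read from the package's `signatures.yaml` and can be retuned by the
#' user; they aim for mutual separability, not bioacoustic fidelity.
#'
#' @param carrier_freq carrier frequency in Hz, in `(0, 22050)`.
#' @param am_rate amplitude-modulation rate in Hz (0 = unpulsed burst).
#' @param call_duration duration of one call in seconds.
#' @param n_repeats number of call repetitions in the 5-s window.
#' @param fm_sweep linear frequency sweep in Hz/s (0 = none).
#' @param harmonics number of harmonic partials (>= 1).
#' @param rel_amplitude peak amplitude of the call in `[0, 1]`; 0 yields a
#'   clip of pure background noise.
#' @param n_voices number of superposed voices (used by the chorus class).
#' @return a `call_signature` list.
#' @examples
#' default_signatures()$ec_standard
#' @export
call_signature <- function(carrier_freq, am_rate = 0, call_duration = 1,
                           n_repeats = 1, fm_sweep = 0, harmonics = 1,
                           rel_amplitude = 0.8, n_voices = 1) {
  sig <- list(carrier_freq = carrier_freq, am_rate = am_rate,
              call_duration = call_duration, n_repeats = n_repeats,
              fm_sweep = fm_sweep, harmonics = harmonics,
              rel_amplitude = rel_amplitude, n_voices = n_voices)
  num <- unlist(sig)
  if (anyNA(num) || any(!is.finite(num)))
    stop("signature parameters must be finite (no NaN/Inf)")
  if (carrier_freq <= 0 || carrier_freq >= CLIP_SR / 2)
    stop("carrier_freq must lie in (0, ", CLIP_SR / 2, ") Hz")
  if (call_duration <= 0 || call_duration * n_repeats > CLIP_DUR)
    stop("call_duration * n_repeats must be positive and at most ",
         CLIP_DUR, " s")
  if (rel_amplitude < 0 || rel_amplitude > 1)
    stop("rel_amplitude must lie in [0, 1]")
  if (harmonics < 1 || n_repeats < 1 || n_voices < 1)
    stop("harmonics, n_repeats and n_voices must be >= 1")
  structure(sig, class = "call_signature")
}

#' @rdname call_signature
#' @export
default_signatures <- function() {
  path <- system.file("extdata", "signatures.yaml", package = "anurapam")
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(s) do.call(call_signature, s))
  stopifnot(identical(names(out), call_classes()))
  out
}

#' Audio clips
#'
#' An `audio_clip` is a 5-second, 44.1 kHz mono waveform in `[-1, 1]`
#' (220500 samples) carrying its class label, the identity of the original
#' recording it derives from (`origin_id`), and an augmentation-variant tag.
#'
#' @param samples numeric vector of 220500 samples in `[-1, 1]`.
#' @param label one of [call_classes()].
#' @param origin_id stable identifier of the source recording.
#' @param variant_tag `"original"` or one of the ten augmentation tags.
#' @return an `audio_clip` object.
#' @export
audio_clip <- function(samples, label, origin_id = "clip_0001",
                       variant_tag = "original") {
  samples <- as.numeric(samples)
  if (length(samples) != CLIP_LEN)
    stop("clip must have exactly ", CLIP_LEN, " samples (5 s at 44.1 kHz), got ",
         length(samples))
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("samples must be finite")
  if (max(abs(samples)) > 1 + 1e-9)
    stop("samples must lie in [-1, 1]")
  assert_class(label)
  structure(list(samples = samples, sample_rate = CLIP_SR,
                 duration = CLIP_DUR, label = label, origin_id = origin_id,
                 variant_tag = variant_tag),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %s | %s | %s | %d samples @ %d Hz, rms %.4f\n",
              x$origin_id, x$label, x$variant_tag, length(x$samples),
              x$sample_rate, sqrt(mean(x$samples^2))))
  invisible(x)
}

rms <- function(x) sqrt(mean(x^2))

# Band-limited pink noise (1/f amplitude shaping above `f_lo`, zero below),
# unit RMS. The high-pass keeps the 1/f divergence at DC from dominating
# full-clip spectra, mimicking a recorder's low-cut filter.
pink_noise <- function(n, sr = CLIP_SR, f_lo = 50) {
  white <- rnorm(n)
  k <- as.numeric(0:(n - 1))
  f_abs <- sr * pmin(k, n - k) / n
  shape <- ifelse(f_abs < f_lo, 0, 1 / sqrt(f_abs))
  x <- Re(fft(fft(white) * shape, inverse = TRUE)) / n
  x / rms(x)
}

# one call unit: (possibly FM-swept, AM-pulsed) harmonic tone with smooth
# onset/offset, unit peak
one_call <- function(sig, sr = CLIP_SR) {
  nt <- round(sig$call_duration * sr)
  tt <- (seq_len(nt) - 1) / sr
  phase <- 2 * pi * (sig$carrier_freq * tt + 0.5 * sig$fm_sweep * tt^2)
  wave <- numeric(nt)
  for (h in seq_len(sig$harmonics))
    wave <- wave + 0.3^(h - 1) * sin(h * phase + runif(1, 0, 2 * pi))
  env <- sin(pi * tt / sig$call_duration)^2          # burst envelope
  if (sig$am_rate > 0)
    env <- env * (0.5 - 0.5 * cos(2 * pi * sig$am_rate * tt))^2
  out <- wave * env
  out / max(abs(out))
}

# place n_repeats copies of a call into the 5-s window, uniformly jittered
# onset, roughly 0.3*duration gaps (shrunk if the bout would not fit)
place_calls <- function(call_wave, n_repeats, n = CLIP_LEN, sr = CLIP_SR) {
  nt <- length(call_wave)
  gap <- round(min(0.3 * nt, (n - n_repeats * nt) / max(1L, n_repeats)))
  gap <- max(0L, gap)
  span <- n_repeats * nt + (n_repeats - 1L) * gap
  onset <- floor(runif(1, 0, max(1, n - span + 1)))
  x <- numeric(n)
  for (k in seq_len(n_repeats)) {
    at <- onset + (k - 1L) * (nt + gap)
    x[(at + 1):(at + nt)] <- x[(at + 1):(at + nt)] + call_wave
  }
  x
}

synth_call <- function(label, sig, n = CLIP_LEN, sr = CLIP_SR) {
  if (sig$rel_amplitude == 0) return(numeric(n))
  if (label == "ec_chorus") {
    # several desynchronized, detuned, unequally loud voices
    x <- numeric(n)
    for (v in seq_len(sig$n_voices)) {
      vs <- sig
      vs$carrier_freq <- sig$carrier_freq * runif(1, 0.93, 1.07)
      vs$am_rate <- sig$am_rate * runif(1, 0.85, 1.15)
      w <- one_call(vs, sr)
      onset <- floor(runif(1, 0, n - length(w)))
      amp <- runif(1, 0.4, 1)
      x[(onset + 1):(onset + length(w))] <-
        x[(onset + 1):(onset + length(w))] + amp * w
    }
  } else {
    x <- place_calls(one_call(sig, sr), sig$n_repeats, n, sr)
  }
  x / max(abs(x)) * sig$rel_amplitude
}

#' Generate one synthetic clip
#'
#' Synthesizes a 5-s clip of the requested vocalization class over a
#' pink-noise floor. The SNR is defined as the ratio of the call's RMS over
#' its active support to the noise RMS, in dB. Deterministic for a fixed
#' `(label, signature, snr_db, seed)`.
#'
#' @param label one of [call_classes()].
#' @param signature a [call_signature()]; defaults to the class default.
#' @param snr_db call-to-noise ratio in dB (finite). With
#'   `rel_amplitude = 0` the clip is pure noise and `snr_db` is ignored.
#' @param seed integer seed.
#' @param origin_id identifier stored on the clip.
#' @return an [audio_clip()] with `variant_tag = "original"`.
#' @examples
#' clip <- generate_clip("ec_standard", snr_db = 20, seed = 1)
#' clip
#' @export
generate_clip <- function(label, signature = NULL, snr_db = 20, seed = 1,
                          origin_id = "clip_0001") {
  assert_class(label)
  if (is.null(signature)) signature <- default_signatures()[[label]]
  if (!inherits(signature, "call_signature"))
    signature <- do.call(call_signature, as.list(signature))
  if (!is.finite(snr_db)) stop("snr_db must be finite")
  samples <- with_seed(seed, {
    call <- synth_call(label, signature)
    noise <- pink_noise(CLIP_LEN)
    if (any(call != 0)) {
      active <- abs(call) > 0.01 * max(abs(call))
      noise_rms <- rms(call[active]) / 10^(snr_db / 20)
    } else {
      noise_rms <- 0.05
    }
    x <- call + noise * noise_rms
    peak <- max(abs(x))
    if (peak > 0.99) x <- x / peak * 0.97
    x
  })
  audio_clip(samples, label, origin_id, "original")
}

#' Generate a manifest of synthetic original recordings
#'
#' Builds a dataset manifest with one row per requested clip. Waveforms are
#' not materialized: each row stores a deterministically derived per-clip
#' seed, the jittered signature, and the drawn SNR, from which
#' [realize_clip()] reconstructs the identical waveform on demand. This
#' makes counting/splitting arithmetic instant even for large datasets.
#'
#' @param counts named integer vector of clips per class (names from
#'   [call_classes()]; unnamed vectors of length 5 are taken in that
#'   order). The study corpus uses
#'   `c(293, 74, 63, 419, 16)`.
#' @param seed master seed; per-clip seeds are derived from it.
#' @param snr_range range (dB) from which each clip's SNR is drawn.
#' @param jitter relative jitter applied to carrier/pulse-rate/duration per
#'   clip (uniform in `1 +/- jitter`).
#' @return a `data.frame` of class `anuran_manifest`.
#' @examples
#' m <- generate_dataset(c(5, 5, 5, 5, 5), seed = 1)
#' table(m$label)
#' @export
generate_dataset <- function(counts, seed = 1, snr_range = c(12, 24),
                             jitter = 0.10) {
  classes <- call_classes()
  if (is.null(names(counts))) {
    if (length(counts) != length(classes))
      stop("unnamed counts must have length ", length(classes))
    names(counts) <- classes
  }
  if (!all(names(counts) %in% classes)) stop("unknown class in counts")
  if (any(counts < 0) || anyNA(counts)) stop("counts must be >= 0")
  counts <- counts[classes[classes %in% names(counts)]]
  total <- sum(counts)
  sigs <- default_signatures()
  rows <- with_seed(seed, {
    clip_seeds <- sample.int(2147483646L, total)
    out <- vector("list", length(counts))
    k <- 0L
    for (cl in names(counts)) {
      nc <- counts[[cl]]
      if (nc == 0) { out[[cl]] <- NULL; next }
      s <- sigs[[cl]]
      jit <- function(v) v * runif(nc, 1 - jitter, 1 + jitter)
      dur <- pmin(jit(s$call_duration), CLIP_DUR / s$n_repeats)
      out[[cl]] <- data.frame(
        origin_id = sprintf("%s_%04d", cl, seq_len(nc)),
        label = cl,
        clip_seed = clip_seeds[k + seq_len(nc)],
        snr_db = round(runif(nc, snr_range[1], snr_range[2]), 2),
        carrier_freq = jit(s$carrier_freq),
        am_rate = jit(s$am_rate),
        call_duration = dur,
        n_repeats = s$n_repeats,
        fm_sweep = jit(s$fm_sweep),
        harmonics = s$harmonics,
        rel_amplitude = pmin(1, s$rel_amplitude * runif(nc, 0.85, 1.15)),
        n_voices = s$n_voices,
        variant_tag = "original",
        variant_param = NA_real_,
        variant_seed = NA_integer_,
        stringsAsFactors = FALSE)
      k <- k + nc
    }
    do.call(rbind, out[!vapply(out, is.null, TRUE)])
  })
  if (is.null(rows))
    rows <- generate_dataset(c(ec_standard = 1), seed)[0, ]  # empty template
  rownames(rows) <- NULL
  class(rows) <- c("anuran_manifest", "data.frame")
  rows
}

#' Materialize the waveform for one manifest row
#'
#' Regenerates the original clip from its stored seed and signature and, if
#' the row is an augmentation variant, applies the recorded transformation.
#'
#' @param manifest an `anuran_manifest`.
#' @param i row index.
#' @return an [audio_clip()].
#' @export
realize_clip <- function(manifest, i = 1L) {
  row <- manifest[i, , drop = FALSE]
  sig <- call_signature(row$carrier_freq, row$am_rate, row$call_duration,
                        row$n_repeats, row$fm_sweep, row$harmonics,
                        row$rel_amplitude, row$n_voices)
  clip <- generate_clip(row$label, sig, row$snr_db, row$clip_seed,
                        origin_id = row$origin_id)
  apply_variant(clip, row$variant_tag, row$variant_param, row$variant_seed)
}

#' Write a manifest's clips to WAV files
#'
#' Materializes every row of the manifest, writes one 16-bit PCM WAV per
#' clip, and a CSV manifest with the file paths alongside.
#'
#' @param manifest an `anuran_manifest`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest with a `path` column added.
#' @export
write_dataset <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    clip <- realize_clip(manifest, i)
    fn <- sprintf("%s__%s.wav", clip$origin_id, gsub("[^A-Za-z0-9_.+-]", "",
                                                     clip$variant_tag))
    paths[i] <- file.path(dir, fn)
    write_wav(clip$samples, paths[i], clip$sample_rate)
  }
  out <- manifest
  out$path <- paths
  write.csv(out, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(out)
}
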