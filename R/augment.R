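# Waveform augmentation: per original clip, exactly ten label-preserving
# variants — two white-noise injections, four circular time shifts, and
# four dynamic-range-compression gain changes.

#' Augmentation plan
#'
#' The ten-variant recipe applied to every original clip: white noise at
#' two SNR levels, four time shifts, and four dynamic-compression amounts
#' (two amplifications of the quiet content, two attenuations of the loud
#' content).
#'
#' @param noise_snrs_db two SNR levels (dB) for white-noise injection.
#' @param shifts_s four time shifts in seconds, strictly inside `(0, 5)`.
#' @param gain_amounts four signed compression amounts (fractions).
#' @param seed integer; per-(origin, variant) noise seeds derive from it.
#' @return an `augmentation_plan` object (exactly 10 recipes).
#' @examples
#' augmentation_plan()
#' @export
augmentation_plan <- function(noise_snrs_db = c(20, 10),
                              shifts_s = c(1, 1.25, 1.75, 2),
                              gain_amounts = c(0.20, 0.40, -0.20, -0.40),
                              seed = 1L) {
  if (length(noise_snrs_db) != 2L) stop("exactly 2 noise SNR levels required")
  if (length(shifts_s) != 4L) stop("exactly 4 time shifts required")
  if (any(shifts_s <= 0) || any(shifts_s >= CLIP_DUR))
    stop("shifts must lie strictly inside (0, ", CLIP_DUR, ")")
  if (length(gain_amounts) != 4L) stop("exactly 4 gain amounts required")
  shift_lab <- sub("(\\.\\d)0$", "\\1", sprintf("%.2f", shifts_s))
  tags <- c(paste0("noise_", seq_len(2)),
            paste0("shift_", shift_lab),
            paste0("gain_", ifelse(gain_amounts >= 0, "+", "-"),
                   round(abs(gain_amounts) * 100)))
  structure(list(noise_snrs_db = noise_snrs_db, shifts_s = shifts_s,
                 gain_amounts = gain_amounts, seed = as.integer(seed),
                 tags = tags),
            class = "augmentation_plan")
}

#' @export
print.augmentation_plan <- function(x, ...) {
  cat("<augmentation_plan> 10 variants per original:\n")
  cat("  noise SNR (dB):", paste(x$noise_snrs_db, collapse = ", "), "\n")
  cat("  shifts (s):    ", paste(x$shifts_s, collapse = ", "), "\n")
  cat("  gains:         ", paste(sprintf("%+d%%", round(x$gain_amounts * 100)),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Add white noise at a prescribed SNR
#'
#' Adds zero-mean Gaussian white noise scaled so that the ratio of the
#' clip's RMS to the noise RMS equals `snr_db`; the result is re-clipped to
#' `[-1, 1]`. `snr_db = Inf` is the identity.
#'
#' @param clip an [audio_clip()].
#' @param snr_db signal-to-noise ratio in dB.
#' @param seed integer seed for the noise draw.
#' @param tag variant tag recorded on the output.
#' @return an [audio_clip()] with the same `origin_id` and label.
#' @export
add_white_noise <- function(clip, snr_db, seed = 1L, tag = NULL) {
  stopifnot(inherits(clip, "audio_clip"))
  if (is.na(snr_db)) stop("snr_db must not be NA")
  if (is.infinite(snr_db) && snr_db > 0) {
    out <- clip
    out$variant_tag <- tag %||% clip$variant_tag
    return(out)
  }
  clip_rms <- rms(clip$samples)
  if (clip_rms == 0)
    stop("cannot set a finite SNR on an all-zero clip (RMS undefined)")
  noise_rms <- clip_rms / 10^(snr_db / 20)
  x <- with_seed(seed, clip$samples + rnorm(length(clip$samples), 0, noise_rms))
  audio_clip(pmax(-1, pmin(1, x)), clip$label, clip$origin_id,
             tag %||% sprintf("noise_snr%g", snr_db))
}

#' Time-shift a clip
#'
#' Rotates the waveform by `round(shift_s * 44100)` samples. The default
#' circular mode wraps the tail to the front, preserving length and total
#' energy exactly (a call near the window edge is never deleted);
#' `"zero_pad"` discards the wrapped tail and pads with silence instead.
#'
#' @param clip an [audio_clip()].
#' @param shift_s shift in seconds, in `[0, 5)`.
#' @param mode `"circular"` (default) or `"zero_pad"`.
#' @param tag variant tag recorded on the output.
#' @return an [audio_clip()].
#' @export
time_shift <- function(clip, shift_s, mode = c("circular", "zero_pad"),
                       tag = NULL) {
  stopifnot(inherits(clip, "audio_clip"))
  mode <- match.arg(mode)
  if (!is.finite(shift_s) || shift_s < 0 || shift_s >= clip$duration)
    stop("shift_s must lie in [0, ", clip$duration, ")")
  k <- as.integer(round(shift_s * clip$sample_rate))
  n <- length(clip$samples)
  x <- clip$samples
  if (k > 0) {
    head_part <- x[seq_len(n - k)]
    tail_part <- x[(n - k + 1):n]
    x <- c(if (mode == "circular") tail_part else numeric(k), head_part)
  }
  audio_clip(x, clip$label, clip$origin_id,
             tag %||% sprintf("shift_%g", shift_s))
}

# centered moving average via cumulative sums (O(n)); edge-padded with the
# boundary values so constants are preserved exactly
smooth_gain <- function(g, width) {
  half <- width %/% 2
  gp <- c(rep(g[1], half), g, rep(g[length(g)], width - half - 1))
  cs <- cumsum(gp)
  (cs[width:length(gp)] - c(0, cs[seq_len(length(gp) - width)])) / width
}

#' Dynamic-range compression
#'
#' Frame-wise compressor: the clip is cut into 50-ms frames, each frame's
#' RMS is compared with the clip's median frame RMS. For a positive
#' `amount` the quiet frames (below the threshold) are amplified by
#' `1 + amount`; for a negative `amount` the loud frames (at or above the
#' threshold) are attenuated by `1 + amount`. Per-frame gains are
#' cross-faded linearly over 10 ms so no discontinuities are introduced,
#' and the output is clipped to `[-1, 1]`. This enhances the background
#' relative to the call (or the reverse), emulating recordings at varying
#' microphone distances.
#'
#' @param clip an [audio_clip()].
#' @param amount signed fraction; the standard recipe uses
#'   `+/-0.20, +/-0.40` (0 is the identity). Other values require
#'   `allow_any = TRUE`.
#' @param frame_s compressor frame length in seconds.
#' @param fade_s gain cross-fade length in seconds.
#' @param allow_any permit amounts outside the standard set.
#' @param tag variant tag recorded on the output.
#' @return an [audio_clip()].
#' @export
dynamic_compress <- function(clip, amount, frame_s = 0.05, fade_s = 0.01,
                             allow_any = FALSE, tag = NULL) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!is.finite(amount)) stop("amount must be finite")
  standard <- c(0, 0.20, 0.40, -0.20, -0.40)
  if (!isTRUE(allow_any) && !any(abs(amount - standard) < 1e-12))
    stop("amount must be one of 0, +/-0.20, +/-0.40 (or set allow_any = TRUE)")
  x <- clip$samples
  if (amount != 0) {
    n <- length(x)
    frame_len <- round(frame_s * clip$sample_rate)
    n_frames <- ceiling(n / frame_len)
    pad <- n_frames * frame_len - n
    m <- matrix(c(x^2, numeric(pad)), frame_len, n_frames)
    frms <- sqrt(colMeans(m))
    thr <- median(frms)
    # frames at the threshold (ties, up to float jitter) count as the
    # acted-upon side: loud when attenuating, quiet when amplifying
    eps <- 1e-9 * (thr + 1)
    gains <- if (amount > 0) ifelse(frms <= thr + eps, 1 + amount, 1)
             else ifelse(frms >= thr - eps, 1 + amount, 1)
    g <- rep(gains, each = frame_len)[seq_len(n)]
    width <- 2L * (round(fade_s * clip$sample_rate) %/% 2L) + 1L
    x <- x * smooth_gain(g, width)
  }
  audio_clip(pmax(-1, pmin(1, x)), clip$label, clip$origin_id,
             tag %||% sprintf("gain_%+d", round(amount * 100)))
}

# dispatch a stored variant description onto a materialized original
apply_variant <- function(clip, tag, param = NA, seed = NA) {
  if (identical(tag, "original")) return(clip)
  if (startsWith(tag, "noise")) return(add_white_noise(clip, param, seed, tag))
  if (startsWith(tag, "shift")) return(time_shift(clip, param, tag = tag))
  if (startsWith(tag, "gain")) return(dynamic_compress(clip, param, tag = tag))
  stop("unknown variant tag: ", tag)
}

#' Augment one original clip
#'
#' Produces the ten augmentation variants of an original clip under a
#' plan: `noise_1`, `noise_2`, `shift_*` (4), `gain_*` (4). All outputs
#' share the input's `origin_id` and label. Augmenting a clip that is
#' itself a variant is rejected (it would leak augmented copies across a
#' grouped train/test split).
#'
#' @param clip an original [audio_clip()] (`variant_tag == "original"`).
#' @param plan an [augmentation_plan()].
#' @return a list of 10 [audio_clip()]s, one per recipe.
#' @export
augment_clip <- function(clip, plan = augmentation_plan()) {
  stopifnot(inherits(clip, "audio_clip"), inherits(plan, "augmentation_plan"))
  if (!identical(clip$variant_tag, "original"))
    stop("refusing to augment an already-augmented clip (variant '",
         clip$variant_tag, "')")
  out <- vector("list", 10L)
  names(out) <- plan$tags
  for (j in 1:2)
    out[[j]] <- add_white_noise(clip, plan$noise_snrs_db[j],
                                derive_seed(plan$seed, clip$origin_id, j),
                                tag = plan$tags[j])
  for (j in 1:4)
    out[[2 + j]] <- time_shift(clip, plan$shifts_s[j], tag = plan$tags[2 + j])
  for (j in 1:4)
    out[[6 + j]] <- dynamic_compress(clip, plan$gain_amounts[j],
                                     tag = plan$tags[6 + j])
  out
}

#' Augment a dataset manifest
#'
#' Expands a manifest of originals elevenfold: each original row is
#' followed by ten variant rows recording the recipe (tag, parameter, and
#' derived noise seed) from which [realize_clip()] reconstructs the
#' waveform. Per-class sizes grow exactly 11x; no audio is materialized.
#'
#' @param manifest an `anuran_manifest` containing only originals with
#'   unique `origin_id`s.
#' @param plan an [augmentation_plan()].
#' @return the expanded `anuran_manifest` (`11 * nrow(manifest)` rows).
#' @examples
#' m <- generate_dataset(c(2, 0, 0, 1, 0), seed = 1)
#' nrow(augment_dataset(m))
#' @export
augment_dataset <- function(manifest, plan = augmentation_plan()) {
  stopifnot(inherits(manifest, "data.frame"), inherits(plan, "augmentation_plan"))
  if (nrow(manifest) == 0L) return(manifest)
  if (!all(manifest$variant_tag == "original"))
    stop("manifest must contain only originals")
  if (anyDuplicated(manifest$origin_id))
    stop("duplicate origin_ids in manifest")
  n <- nrow(manifest)
  out <- manifest[rep(seq_len(n), each = 11L), , drop = FALSE]
  pos <- rep(0:10, times = n)                        # 0 = original
  out$variant_tag[pos > 0] <- plan$tags[pos[pos > 0]]
  params <- c(NA, plan$noise_snrs_db, plan$shifts_s, plan$gain_amounts)
  out$variant_param <- params[pos + 1L]
  noise_idx <- which(pos %in% 1:2)
  out$variant_seed[noise_idx] <- mapply(
    function(oid, j) derive_seed(plan$seed, oid, j),
    out$origin_id[noise_idx], pos[noise_idx])
  rownames(out) <- NULL
  class(out) <- c("anuran_manifest", "data.frame")
  out
}
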