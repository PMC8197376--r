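test_that("every 5-s clip maps to a 128 x 435 matrix", {
  sp <- compute_melspec(fix_clip())
  expect_identical(dim(sp$matrix), c(128L, 435L))
  expect_true(all(is.finite(sp$matrix)))
  expect_true(all(sp$matrix >= mel_config()$log_floor))
  # variants obey the same contract
  shifted <- time_shift(fix_clip(), 1.75)
  expect_identical(dim(compute_melspec(shifted)$matrix), c(128L, 435L))
  # malformed inputs are rejected with an explicit message
  expect_error(compute_melspec(numeric(1000)), "220500")
  bad_rate <- fix_clip(); bad_rate$sample_rate <- 22050L
  expect_error(compute_melspec(bad_rate), "sample rate")
})

test_that("an all-zero clip maps to a matrix pinned at the log floor", {
  sp <- compute_melspec(numeric(220500))
  expect_true(all(sp$matrix == mel_config()$log_floor))
})

test_that("a pure tone lights up the mel band whose center is nearest", {
  f0 <- 1500
  tone <- 0.5 * sin(2 * pi * f0 * (0:220499) / 44100)
  sp <- compute_melspec(tone)
  hottest <- which.max(rowMeans(sp$matrix))
  # independent oracle: band centers from the HTK mel formula
  cfg <- mel_config()
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  centers <- imel(seq(mel(cfg$fmin), mel(cfg$fmax),
                      length.out = cfg$n_mels + 2))[2:(cfg$n_mels + 1)]
  expect_equal(hottest, which.min(abs(centers - f0)))
})

test_that("min-max normalization is the stated affine map", {
  m <- matrix(c(-80, -40, -20, 0), 2)
  expect_equal(normalize_spec(m), (m + 80) / 80)
  expect_equal(normalize_spec(matrix(5, 3, 4)), matrix(0, 3, 4))
  v <- normalize_spec(compute_melspec(fix_clip()))
  expect_equal(range(v), c(0, 1))
})

test_that("spectrogram images round-trip through JPEG at 435 x 128 pixels", {
  sp <- compute_melspec(fix_clip())
  path <- withr::local_tempfile(fileext = ".jpg")
  export_image(sp, path)
  img <- jpeg::readJPEG(path)
  expect_identical(dim(img), c(128L, 435L, 3L))
  # an all-floor spectrogram renders as one uniform color
  flat <- withr::local_tempfile(fileext = ".jpg")
  export_image(compute_melspec(numeric(220500)), flat)
  flat_img <- jpeg::readJPEG(flat)
  expect_lt(max(apply(flat_img, 3, stats::sd)), 0.02)
  # a pure tone draws a horizontal bright band at the carrier's mel row
  f0 <- 1500
  tone_path <- withr::local_tempfile(fileext = ".jpg")
  export_image(compute_melspec(0.5 * sin(2 * pi * f0 * (0:220499) / 44100)),
               tone_path)
  tone_img <- jpeg::readJPEG(tone_path)
  red_profile <- rowMeans(tone_img[, , 1])       # red = high amplitude
  sp_tone <- compute_melspec(0.5 * sin(2 * pi * f0 * (0:220499) / 44100))
  expected_row <- 129L - which.max(rowMeans(sp_tone$matrix))  # image is flipped
  expect_lt(abs(which.max(red_profile) - expected_row), 3)
})

test_that("time shifts rotate spectrogram columns by the hop-aligned amount", {
  cfg <- mel_config()
  k <- 20L                                   # shift by exactly k hops
  shift_s <- k * cfg$hop / 44100
  clip <- fix_clip()
  sp0 <- compute_melspec(clip, cfg)$matrix
  sp1 <- compute_melspec(time_shift(clip, shift_s), cfg)$matrix
  rotated <- cbind(sp0[, (435 - k + 1):435], sp0[, 1:(435 - k)])
  interior <- (k + 4):(435 - 4)              # away from wrap/pad frames
  expect_lt(max(abs(sp1[, interior] - rotated[, interior])), 1e-6)
})

test_that("amplifying a clip never lowers any dB cell", {
  quiet <- fix_quiet_clip()
  louder <- audio_clip(quiet$samples * 3, quiet$label, quiet$origin_id)
  d <- compute_melspec(louder)$matrix - compute_melspec(quiet)$matrix
  expect_true(all(d >= -1e-9))
})
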