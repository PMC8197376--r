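test_that("white-noise injection hits the requested SNR and is seeded", {
  clip <- fix_quiet_clip()
  # infinite SNR is the identity
  same <- add_white_noise(clip, Inf, seed = 1)
  expect_identical(same$samples, clip$samples)
  # at 0 dB the added noise RMS matches the clip RMS within 1 %
  out <- add_white_noise(clip, 0, seed = 1)
  noise <- out$samples - clip$samples
  ratio <- sqrt(mean(noise^2)) / sqrt(mean(clip$samples^2))
  expect_lt(abs(ratio - 1), 0.01)
  # deterministic for a fixed seed, different for another
  expect_identical(out$samples, add_white_noise(clip, 0, seed = 1)$samples)
  expect_false(identical(out$samples, add_white_noise(clip, 0, seed = 2)$samples))
  # origin and label ride along
  expect_identical(out$origin_id, clip$origin_id)
  expect_identical(out$label, clip$label)
})

test_that("a finite SNR on an all-zero clip is rejected", {
  silent <- audio_clip(numeric(220500), "ec_standard", "silent_01")
  expect_error(add_white_noise(silent, 10), "RMS")
})

test_that("time shifts rotate, conserve energy, and invert", {
  clip <- fix_clip()
  # zero shift is the identity
  expect_identical(time_shift(clip, 0)$samples, clip$samples)
  # impulse index arithmetic: sample 1 moves to 1 + 44100
  imp <- audio_clip(c(1, numeric(220499)), "ao_standard", "imp_01")
  shifted <- time_shift(imp, 1.0)
  expect_equal(which(shifted$samples != 0), 44101L)
  # circular rotation conserves energy exactly, for every recipe shift
  for (s in c(1, 1.25, 1.75, 2))
    expect_identical(sum(time_shift(clip, s)$samples^2), sum(clip$samples^2))
  # shifting by s then by duration - s restores the input exactly
  back <- time_shift(time_shift(clip, 1.25), 5 - 1.25)
  expect_identical(back$samples, clip$samples)
  # out-of-range shifts are rejected
  expect_error(time_shift(clip, 5), "shift_s")
  expect_error(time_shift(clip, -0.1), "shift_s")
})

test_that("zero-pad shift mode silences the wrapped tail", {
  imp <- audio_clip(c(numeric(220499), 1), "ao_standard", "imp_02")
  out <- time_shift(imp, 1.0, mode = "zero_pad")
  expect_true(all(out$samples == 0))
})

test_that("dynamic compression scales loud and quiet content as advertised", {
  tt <- (0:220499) / 44100
  sine <- audio_clip(0.5 * sin(2 * pi * 1000 * tt), "ec_standard", "sine_01")
  # amount 0 is the identity
  expect_identical(dynamic_compress(sine, 0)$samples, sine$samples)
  # a constant-amplitude tone is all-loud: -40 % scales RMS by 0.6
  out <- dynamic_compress(sine, -0.40)
  ratio <- sqrt(mean(out$samples^2)) / sqrt(mean(sine$samples^2))
  expect_lt(abs(ratio - 0.6), 0.02)
  # loud call over quiet noise, +20 %: call RMS unchanged, noise RMS up 20 %
  x <- 0.01 * sin(2 * pi * 700 * tt)
  call_idx <- which(tt >= 2 & tt < 3)
  x[call_idx] <- 0.5 * sin(2 * pi * 1500 * tt[call_idx])
  clip <- audio_clip(x, "ec_standard", "mix_01")
  out <- dynamic_compress(clip, 0.20)
  seg_rms <- function(w, idx) sqrt(mean(w[idx]^2))
  mid_call <- which(tt >= 2.2 & tt < 2.8)     # away from gain cross-fades
  mid_noise <- which(tt >= 0.5 & tt < 1.8)
  expect_lt(abs(seg_rms(out$samples, mid_call) /
                  seg_rms(clip$samples, mid_call) - 1), 0.01)
  expect_lt(abs(seg_rms(out$samples, mid_noise) /
                  seg_rms(clip$samples, mid_noise) - 1.2), 0.01)
  # non-standard amounts need the override
  expect_error(dynamic_compress(sine, -0.35), "allow_any")
  expect_silent(dynamic_compress(sine, -0.35, allow_any = TRUE))
})

test_that("augmenting one original yields the ten tagged variants", {
  clip <- fix_clip()
  plan <- augmentation_plan()
  out <- augment_clip(clip, plan)
  expect_length(out, 10L)
  tags <- vapply(out, `[[`, "", "variant_tag")
  expect_setequal(tags, c("noise_1", "noise_2", "shift_1.0", "shift_1.25",
                          "shift_1.75", "shift_2.0", "gain_+20", "gain_+40",
                          "gain_-20", "gain_-40"))
  expect_true(all(vapply(out, `[[`, "", "origin_id") == clip$origin_id))
  # no two variants coincide bit-exactly
  mats <- vapply(out, function(cl) cl$samples, numeric(220500))
  expect_equal(anyDuplicated(t(mats)), 0L)
  # augmenting a variant is refused (split-leakage guard)
  expect_error(augment_clip(out[[1]], plan), "already-augmented")
})

test_that("dataset augmentation is an exact elevenfold expansion per class", {
  m <- generate_dataset(c(3, 2, 0, 4, 1), seed = 9)
  a <- augment_dataset(m)
  expect_equal(nrow(a), 11L * nrow(m))
  expect_equal(as.vector(table(a$label)[c("ec_standard", "ec_chorus",
                                          "ao_standard", "ao_distress")]),
               11L * c(3L, 2L, 4L, 1L))
  # every origin appears exactly 11 times with 11 distinct tags
  expect_true(all(table(a$origin_id) == 11L))
  expect_equal(anyDuplicated(a[, c("origin_id", "variant_tag")]), 0L)
  # empty in, empty out
  empty <- generate_dataset(rep(0, 5))
  expect_equal(nrow(augment_dataset(empty)), 0L)
  # duplicates and non-originals are rejected
  expect_error(augment_dataset(rbind(m, m[1, ])), "duplicate")
  expect_error(augment_dataset(a), "only originals")
})

test_that("lazily realized variants equal eagerly augmented waveforms", {
  m <- generate_dataset(c(1, 0, 0, 0, 0), seed = 21)
  plan <- augmentation_plan(seed = 1)
  a <- augment_dataset(m, plan)
  eager <- augment_clip(realize_clip(m, 1L), plan)
  for (i in 2:11) {
    lazy <- realize_clip(a, i)
    expect_identical(lazy$samples, eager[[a$variant_tag[i]]]$samples,
                     info = a$variant_tag[i])
  }
})
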