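# Memoized fixtures shared across test files; everything is generated in
# code, nothing is stored on disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# one default standard-call clip
fix_clip <- function() fixture("clip_ec", generate_clip("ec_standard", snr_db = 20, seed = 1))

# tiny augmented manifest: 5 origins per class, 275 clips
fix_small_aug <- function() fixture("small_aug", {
  augment_dataset(generate_dataset(rep(5L, 5L), seed = 11),
                  augmentation_plan(seed = 11))
})

# features for the tiny manifest, split by the grouped 1-in-5 rule
fix_small_features <- function() fixture("small_features", {
  sp <- split_dataset(fix_small_aug())
  list(split = sp,
       train = prepare_features(sp$train),
       test = prepare_features(sp$test))
})

# a quiet clip that survives noise addition without hitting the clipper
fix_quiet_clip <- function() fixture("quiet_clip", {
  tt <- (0:220499) / 44100
  audio_clip(0.1 * sqrt(2) * sin(2 * pi * 880 * tt), "ao_standard", "quiet_01")
})
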