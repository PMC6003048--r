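test_that("generation is fully deterministic under the seed", {
  cfg <- synth_config(n_channels = 3, n_samples = 512, seed = 9)
  a <- generate_recording(cfg, "epileptic")
  b <- generate_recording(cfg, "epileptic")
  expect_identical(a$channels[[2L]]$samples, b$channels[[2L]]$samples)
  h <- generate_recording(cfg, "healthy")
  expect_false(identical(a$channels[[1L]]$samples, h$channels[[1L]]$samples))

  cfg2 <- synth_config(n_channels = 3, n_samples = 512, seed = 10)
  expect_false(identical(a$channels[[1L]]$samples,
                         generate_recording(cfg2, "epileptic")$channels[[1L]]$samples))
})

test_that("a clean single sinusoid has one equal bar per period minimum", {
  cfg <- synth_config(
    n_channels = 1, n_samples = 4096,
    epileptic = synth_class_params(n_spikes = 0, spike_depth_mean = 0,
                                   spike_depth_sd = 0, osc_amp = 15,
                                   n_osc = 1L, osc_freq = c(4, 4),
                                   noise_sd = 0),
    seed = 3)
  rec <- generate_recording(cfg, "epileptic")
  y <- rec$channels[[1L]]$samples
  bc <- persistence_0d(piecewise_filtration(y))
  len <- with(bc$intervals, ifelse(is.infinite(death), bc$max_filter + 1, death) - birth)
  pos <- len[len > 0]
  ## one bar per strict local minimum (64 interior periods at 4 Hz x 16 s,
  ## plus possibly a locally-minimal endpoint)
  expect_identical(length(pos), oracle_local_minima(y))
  expect_gte(length(pos), 64L)
  ## bars are near-equal at twice the amplitude, up to the essential bar's
  ## m = max(F)+1 replacement and at most one truncated boundary dip
  off <- abs(pos - median(pos)) / median(pos)
  expect_lte(sum(off > 0.1), 2L)
  ## closed form under near-equal bars
  h <- normalized_persistent_entropy(bc)
  expect_equal(h, log(length(pos)) / log(max(pos)), tolerance = 0.02)
})

test_that("datasets are balanced, labeled, reproducible and pipeline-clean", {
  cfg <- synth_config(n_channels = 4, n_samples = 512)
  gen <- generate_dataset(cfg, n_per_class = 3, seed = 5)
  expect_length(gen$dataset$recordings, 6L)
  labs <- vapply(gen$dataset$recordings, function(r) r$label, character(1))
  expect_identical(sum(labs == "epileptic"), 3L)
  expect_identical(nrow(gen$manifest), 6L)

  gen2 <- generate_dataset(cfg, n_per_class = 3, seed = 5)
  expect_identical(gen$dataset$recordings[[2L]]$channels[[1L]]$samples,
                   gen2$dataset$recordings[[2L]]$channels[[1L]]$samples)
  gen3 <- generate_dataset(cfg, n_per_class = 3, seed = 6)
  expect_false(identical(gen$dataset$recordings[[2L]]$channels[[1L]]$samples,
                         gen3$dataset$recordings[[2L]]$channels[[1L]]$samples))

  empty <- generate_dataset(cfg, n_per_class = 0)
  expect_length(empty$dataset$recordings, 0L)

  ## generated recordings pass preprocessing without error
  pre <- preprocess(gen$dataset$recordings[[1L]], preprocess_config(decimation_factor = 2))
  expect_identical(n_samples(pre), 256L)
})

test_that("class separation grows with the spike-depth design gap", {
  ## three dial settings from overlapping to separable; the mean-feature
  ## gap between classes must be monotone in the dial
  gap <- function(cfg, seed) {
    gen <- generate_dataset(cfg, n_per_class = 4, seed = seed)
    pre <- lapply(gen$dataset$recordings, preprocess,
                  config = preprocess_config(decimation_factor = 4))
    f <- dataset_features(eeg_dataset(pre))
    mean(f$feature[f$label == "epileptic"]) - mean(f$feature[f$label == "healthy"])
  }
  mk <- function(w) synth_config(
    n_channels = 6, n_samples = 1024,
    epileptic = synth_class_params(n_spikes = 10 + round(30 * w),
                                   spike_depth_mean = 60 - 35 * w,
                                   spike_depth_sd = 20 - 18 * w),
    healthy = synth_class_params(n_spikes = 10 - round(4 * w),
                                 spike_depth_mean = 60 + 90 * w,
                                 spike_depth_sd = 20 + 40 * w))
  gaps <- vapply(c(0, 0.5, 1), function(w) mean(vapply(1:3, function(s)
    gap(mk(w), s), numeric(1))), numeric(1))
  expect_true(all(diff(gaps) > 0))
  expect_gt(gaps[3], 0)  # separable end: epileptic-like has the higher feature
})

test_that("dataset round-trips through the manifest on disk", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_channels = 2, n_samples = 128)
  gen <- generate_dataset(cfg, n_per_class = 2, seed = 8)
  mpath <- write_dataset(gen$dataset, dir)
  back <- read_dataset(mpath, fs = 256)
  expect_length(back$recordings, 4L)
  expect_equal(back$recordings[[1L]]$channels[[1L]]$samples,
               gen$dataset$recordings[[1L]]$channels[[1L]]$samples,
               tolerance = 1e-9)
  expect_identical(vapply(back$recordings, function(r) r$label, character(1)),
                   vapply(gen$dataset$recordings, function(r) r$label, character(1)))
})
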