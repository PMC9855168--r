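# Soundscape simulator: schedule arithmetic, song durations, phrase
# structure, determinism, labelling criterion, and spectral placement.

test_that("song durations match the configured distribution and bounds", {
  cfg <- sim_config()
  d <- sample_song_duration(10000, cfg, seed = 101)
  expect_equal(mean(d), 88.61, tolerance = 2.0 / 88.61)
  expect_true(all(d >= 10 & d <= 240))
  # degenerate sd: every draw ~ the mean
  cfg2 <- sim_config(song_duration_sd = 1e-9)
  expect_equal(sample_song_duration(50, cfg2, seed = 1), rep(88.61, 50),
               tolerance = 1e-6)
})

test_that("phrases have 2-5 notes with strictly decreasing follower f0s in range", {
  cfg <- sim_config(sample_rate = 4000)
  for (seed in 1:25) {
    ph <- synth_phrase(cfg, rate = 4000, seed = seed)
    f0 <- ph$notes$f0
    expect_gte(length(f0), 2L)
    expect_lte(length(f0), 5L)
    expect_true(all(diff(f0) < 0))
    expect_true(all(f0 >= cfg$phrase_f0_range[1] &
                    f0 <= cfg$phrase_f0_range[2]))
  }
  expect_error(synth_phrase(cfg, start_f0 = 3000, seed = 1), "f0_range")
})

test_that("phrase energy concentrates in the band of its starting f0 (FFT oracle)", {
  cfg <- sim_config(sample_rate = 16000)
  ph <- synth_phrase(cfg, start_f0 = 1000, rate = 16000, seed = 4)
  first_note <- ph$samples[seq_len(round(ph$notes$duration[1] * 16000))]
  fm <- suppressWarnings(extract_features(
    c(first_note, numeric(16000 * 20 - length(first_note))), 16000))
  expect_identical(colnames(fm)[which.max(fm[1, ])], "band_30")
})

test_that("most clean-song energy lies at the fundamentals and first harmonics", {
  cfg <- sim_config(sample_rate = 16000)
  sg <- synth_song(cfg, rate = 16000, duration = 30, seed = 9)
  p <- Mod(stats::fft(sg$samples))^2
  freq <- (seq_along(p) - 1) * 16000 / length(p)
  below <- sum(p[freq <= 2 * cfg$phrase_f0_range[2]])  # f0s + first harmonics
  expect_gt(below / sum(p[freq <= 8000]), 0.80)
})

test_that("recording labels follow the phrase-overlap criterion", {
  cfg <- sim_config(sample_rate = 4000, recording_duration = 30)
  none <- synth_recording(cfg, n_songs = 0, seed = 2)
  expect_identical(none$label, 0L)
  expect_length(none$annotations, 0L)
  one <- synth_recording(cfg, n_songs = 1, seed = 2)
  expect_identical(one$label, 1L)
  ann <- one$annotations[[1]]
  expect_gt(ann$end, ann$start)
  expect_lte(ann$end, 30 + 1e-6)
})

test_that("identical config and seed give bit-identical recordings", {
  cfg <- sim_config(seed = 5, sample_rate = 4000, recording_duration = 20)
  a <- synth_recording(cfg, n_songs = 1, seed = 77)
  b <- synth_recording(cfg, n_songs = 1, seed = 77)
  expect_identical(a$samples, b$samples)
  expect_identical(a$annotations, b$annotations)
})

test_that("the schedule yields 48 recordings per site-day on :00/:30 boundaries", {
  cfg <- sim_config(seed = 3)
  ds <- generate_dataset(cfg, n_days = 2, sites = c("A", "B"), mode = "labels")
  expect_identical(nrow(ds$labels), 2L * 2L * 48L)
  lt <- as.POSIXlt(ds$labels$start_datetime)
  expect_true(all(lt$min %in% c(0L, 30L)))
  expect_true(all(lt$sec == 0))
  per_day <- table(ds$labels$site_id, as.Date(ds$labels$start_datetime))
  expect_true(all(per_day == 48L))
})

test_that("fast mode emits 30 x 18 matrices and is reproducible", {
  cfg <- sim_config(seed = 21)
  ds1 <- generate_dataset(cfg, n_days = 1, sites = "A", mode = "fast")
  ds2 <- generate_dataset(cfg, n_days = 1, sites = "A", mode = "fast")
  expect_identical(dim(ds1$features[[1]]), c(30L, 18L))
  expect_identical(lapply(ds1$features, unclass), lapply(ds2$features, unclass))
  expect_identical(ds1$labels, ds2$labels)
})

test_that("audio mode at reduced scale produces labelled WAV recordings", {
  cfg <- sim_config(seed = 8, sample_rate = 4000, recording_duration = 4,
                    schedule_interval = 720)  # 2 slots/day to keep it light
  out <- withr::local_tempdir()
  ds <- generate_dataset(cfg, n_days = 1, sites = "A", mode = "audio",
                         p_song = 1, out_dir = out)
  expect_identical(nrow(ds$labels), 2L)
  expect_true(all(file.exists(ds$wav_paths)))
  w <- read_wav(ds$wav_paths[1])
  expect_identical(w$rate, 4000L)
  expect_identical(length(w$samples), 4L * 4000L)
})

test_that("empirical positive rates track the configured profiles over a year", {
  cfg <- sim_config(seed = 303)
  ds <- generate_dataset(cfg, n_days = 365, sites = "A", mode = "labels",
                         start_date = as.Date("2021-01-01"))
  lt <- as.POSIXlt(ds$labels$start_datetime)
  slot <- (lt$hour * 60 + lt$min) %/% 30
  week <- pmin(lt$yday %/% 7, 51)
  diel_emp <- tapply(ds$labels$label, slot, mean)
  seas_emp <- tapply(ds$labels$label, week, mean)
  expect_gt(stats::cor(diel_emp, cfg$diel_profile), 0.9)
  expect_gt(stats::cor(seas_emp, cfg$seasonal_profile), 0.9)
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(phrase_f0_range = c(500, 3000)), "2500")
  expect_error(sim_config(song_duration_sd = 0), "sd")
  expect_error(sim_config(diel_profile = rep(0.5, 24)), "48")
  expect_error(sim_config(seasonal_profile = c(rep(0.5, 51), 1.2)), "52")
  expect_error(generate_dataset(sim_config(), sites = character(0)), "nonempty")
  expect_error(generate_dataset(sim_config(), n_days = 0), "n_days")
})
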