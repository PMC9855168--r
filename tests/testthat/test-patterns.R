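# Diel/seasonal activity distributions: binning, exclusion rule,
# fold aggregation, and recovery of the simulator's profiles.

det_table <- function(times, labels) {
  data.frame(file_id = sprintf("f%04d", seq_along(labels)),
             start_datetime = as.POSIXct(times, tz = "UTC"),
             label = labels, stringsAsFactors = FALSE)
}

test_that("diel binning is exhaustive and localises positives", {
  det <- det_table(c("2020-06-01 06:00:00", "2020-06-01 06:10:00",
                     "2020-06-01 12:00:00", "2020-06-02 06:05:00"),
                   c(1, 1, 0, 1))
  d <- diel_distribution(det)
  expect_identical(d$bin_count, 48L)
  expect_equal(sum(d$bins$n_recordings), 4)
  expect_equal(d$bins$probability[d$bins$bin_index == 12], 1)  # 06:00-06:30
  expect_equal(d$bins$probability[d$bins$bin_index == 24], 0)
  expect_false(any(d$bins$excluded))
  # all-zero labels -> all sampled probabilities 0
  d0 <- diel_distribution(det_table(rep("2020-06-01 06:00:00", 3), c(0, 0, 0)))
  expect_true(all(d0$bins$probability[!is.na(d0$bins$probability)] == 0))
})

test_that("every start time maps to exactly one of 48 bins", {
  times <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC") +
    seq(0, 86399, by = 601)
  det <- data.frame(file_id = as.character(seq_along(times)),
                    start_datetime = times, label = 0)
  d <- diel_distribution(det)
  expect_identical(sum(d$bins$n_recordings), length(times))
})

test_that("the seasonal <250-recordings exclusion rule is sharp at the boundary", {
  # week 0 (Jan 1-7): 249 recordings; week 1 (Jan 8-14): 250
  t1 <- rep(as.POSIXct("2021-01-03 06:00:00", tz = "UTC"), 249)
  t2 <- rep(as.POSIXct("2021-01-10 06:00:00", tz = "UTC"), 250)
  det <- det_table(c(t1, t2), c(rep(1, 249), rep(1, 125), rep(0, 125)))
  s <- seasonal_distribution(det, min_recordings = 250)
  w0 <- s$bins[s$bins$bin_index == 0, ]
  w1 <- s$bins[s$bins$bin_index == 1, ]
  expect_true(w0$excluded)
  expect_true(is.na(w0$probability))
  expect_false(w1$excluded)
  expect_equal(w1$probability, 0.5)
  expect_identical(s$excluded_recordings, 249L)
  # accounting: sampled + excluded recordings = input rows
  expect_identical(sum(s$bins$n_recordings) + s$excluded_recordings, 499L)
})

test_that("Dec 31 of a leap year clamps into week 51", {
  det <- det_table(rep("2020-12-31 10:00:00", 300), rep(1, 300))  # yday 366
  s <- seasonal_distribution(det, min_recordings = 250)
  expect_equal(s$bins$probability[s$bins$bin_index == 51], 1)
  expect_equal(sum(s$bins$n_recordings), 300)
})

test_that("uniform positives give flat probabilities across sampled weeks", {
  times <- rep(as.POSIXct("2021-03-01 08:00:00", tz = "UTC") +
                 (0:9) * 7 * 86400, each = 300)
  det <- det_table(times, rep(c(1, 0), 1500))
  s <- seasonal_distribution(det, min_recordings = 250)
  p <- s$bins$probability[!is.na(s$bins$probability)]
  expect_true(all(abs(p - 0.5) < 1e-9))
})

test_that("fold aggregation reports per-bin mean/sd and exclusion provenance", {
  mk <- function(p, excl_week = NULL) {
    n <- rep(300, 2)
    t1 <- rep(as.POSIXct("2021-01-03 06:00:00", tz = "UTC"), 300)
    t2 <- rep(as.POSIXct("2021-01-10 06:00:00", tz = "UTC"),
              if (is.null(excl_week)) 300 else 100)
    seasonal_distribution(det_table(c(t1, t2), c(as.integer(stats::runif(300) < p),
                                                 rep(1, length(t2)))),
                          min_recordings = 250)
  }
  d1 <- mk(0.2); d2 <- mk(0.4, excl_week = 1)
  # identical distributions: sd 0, mean = input
  agg_same <- aggregate_folds(list(d1, d1, d1))
  w0 <- agg_same$bins[agg_same$bins$bin_index == 0, ]
  expect_equal(w0$fold_sd, 0)
  expect_equal(w0$fold_mean, d1$bins$probability[1])
  # forced arithmetic: probabilities 0.2 and 0.4 -> mean 0.3, sample sd 0.1414
  da <- d1; db <- d1
  da$bins$probability[1] <- 0.2; db$bins$probability[1] <- 0.4
  agg <- aggregate_folds(list(da, db))
  expect_equal(agg$bins$fold_mean[1], 0.3)
  expect_equal(agg$bins$fold_sd[1], sqrt(0.02), tolerance = 1e-6)
  # a bin excluded in any fold is flagged, with contributing fold count
  agg2 <- aggregate_folds(list(d1, d2))
  w1 <- agg2$bins[agg2$bins$bin_index == 1, ]
  expect_true(w1$excluded)
  expect_identical(w1$n_folds, 1)
  dd <- diel_distribution(det_table(rep("2021-01-03 06:00:00", 3), c(1, 0, 1)))
  expect_error(aggregate_folds(list(d1, dd)), "mixed axes")
})

test_that("a simulated year recovers the configured activity profiles", {
  cfg <- sim_config(seed = 99)
  ds <- generate_dataset(cfg, n_days = 365, sites = "A", mode = "labels",
                         start_date = as.Date("2021-01-01"))
  det <- data.frame(file_id = ds$labels$file_id,
                    start_datetime = ds$labels$start_datetime,
                    label = ds$labels$label)
  d <- diel_distribution(det)
  s <- seasonal_distribution(det, min_recordings = 250)
  expect_gt(stats::cor(d$bins$probability, cfg$diel_profile), 0.9)
  samp <- !s$bins$excluded
  expect_gt(stats::cor(s$bins$probability[samp], cfg$seasonal_profile[samp]),
            0.9)
  # every week of a full year is sampled at 48 recordings/day
  expect_true(all(!s$bins$excluded))
})
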