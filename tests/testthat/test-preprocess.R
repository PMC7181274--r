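make_rec <- function(values, labels = rep(0L, nrow(values)), rate = 30) {
  values <- as.matrix(values)
  marginhar:::new_sensor_recording(values, is.na(values), labels, rate,
                                   sprintf("ch%d", seq_len(ncol(values))))
}

test_that("fill_missing forward-fills from the last observation", {
  rec <- make_rec(cbind(c(NA, 1, NA, 2)))
  filled <- fill_missing(rec)
  expect_equal(as.vector(filled$values), c(0, 1, 1, 2))
  expect_false(any(filled$missing_mask))

  # identity on complete data
  rec2 <- make_rec(cbind(1:4, 4:1))
  expect_equal(fill_missing(rec2)$values, rec2$values)

  # an all-missing channel becomes zeros
  rec3 <- make_rec(cbind(c(NA, NA, NA), c(1, NA, 3)))
  expect_equal(fill_missing(rec3)$values, cbind(c(0, 0, 0), c(1, 1, 3)))

  # idempotent
  expect_equal(fill_missing(filled), filled)
})

test_that("downsample averages groups and majority-labels them", {
  rec <- make_rec(cbind(c(1, 1, 4, 4)), labels = c(0L, 0L, 1L, 1L))
  ds <- downsample(rec, 2)
  expect_equal(as.vector(ds$values), c(1, 4))
  expect_equal(ds$labels, c(0L, 1L))
  expect_equal(ds$sampling_rate, 15)

  expect_equal(downsample(rec, 1), rec)

  # trailing partial group dropped: floor(10/3) = 3 groups
  rec10 <- make_rec(cbind(1:10), labels = rep(0L, 10))
  expect_equal(nrow(downsample(rec10, 3)$values), 3)

  # label ties break to the last sample of the group
  rec_tie <- make_rec(cbind(1:4), labels = c(0L, 0L, 1L, 1L))
  expect_equal(downsample(rec_tie, 4)$labels, 1L)

  expect_error(downsample(rec, 0), "positive")
})

test_that("slide_windows matches the stated coordinates", {
  rec <- make_rec(cbind(1:10, 101:110), labels = rep(0L, 10))
  ws <- slide_windows(rec, 4, 3)
  expect_equal(dim(ws$data), c(3, 4, 2))
  # starts 0, 3, 6 (0-based, half-open)
  expect_equal(ws$data[1, , 1], 1:4)
  expect_equal(ws$data[2, , 1], 4:7)
  expect_equal(ws$data[3, , 2], 107:110)

  # L = T gives exactly one window
  expect_equal(dim(slide_windows(make_rec(cbind(1:4)), 4, 1)$data)[1], 1)

  # window label: tie between 0 and 1 -> last sample's label
  rec_tie <- make_rec(cbind(1:4), labels = c(0L, 0L, 1L, 1L))
  expect_equal(slide_windows(rec_tie, 4, 1)$labels, 1L)

  # L < T: empty set plus warning
  expect_warning(ws0 <- slide_windows(make_rec(cbind(1:3)), 5, 1), "empty")
  expect_equal(dim(ws0$data)[1], 0)
})

test_that("slide_windows agrees with exhaustive enumeration", {
  set.seed(7)
  for (i in 1:200) {
    L <- sample(1:60, 1); T <- sample(1:20, 1); stride <- sample(1:10, 1)
    values <- matrix(rnorm(L * 2), L, 2)
    labels <- sample(0:2, L, replace = TRUE)
    rec <- make_rec(values, labels)
    oracle <- enumerate_windows(values, labels, T, stride)
    ws <- suppressWarnings(slide_windows(rec, T, stride))
    expect_equal(dim(ws$data)[1], length(oracle))
    if (length(oracle) > 0) {
      expect_equal(ws$labels, vapply(oracle, `[[`, integer(1), "label"))
      j <- sample(length(oracle), 1)
      w <- ws$data[j, , , drop = FALSE]
      dim(w) <- dim(w)[2:3]
      expect_equal(w, unname(oracle[[j]]$data))
    }
  }
})

test_that("channels rank by descending variance with index tie-break", {
  base <- scale(rnorm(40))[, 1]  # exactly unit variance
  # planted variances 4, 1, 9, 0, 1 -> ranking (3, 1, 2, 5, 4) in 1-based ids
  vals <- cbind(2 * base, 1 * base, 3 * base, 0 * base, 1 * base)
  ws <- marginhar:::new_window_set(array(vals, c(4, 10, 5)), rep(0L, 4),
                                   NA_integer_, 30, sprintf("ch%d", 1:5))
  # rebuild so each channel of the tensor holds the planted series
  arr <- array(0, c(4, 10, 5))
  for (c in 1:5) arr[, , c] <- matrix(vals[, c], 4, 10)
  ws <- marginhar:::new_window_set(arr, rep(0L, 4), NA_integer_, 30,
                                   sprintf("ch%d", 1:5))
  expect_equal(rank_channels_by_variance(ws), c(3, 1, 2, 5, 4))

  # constant vs noisy
  arr2 <- array(c(rep(1, 20), rnorm(20)), c(2, 10, 2))
  ws2 <- marginhar:::new_window_set(arr2, c(0L, 1L), NA_integer_, 30,
                                    c("a", "b"))
  expect_equal(rank_channels_by_variance(ws2)[1], 2)

  # identical channels preserve index order
  arr3 <- array(rep(rnorm(20), 2), c(2, 10, 2))
  ws3 <- marginhar:::new_window_set(arr3, c(0L, 1L), NA_integer_, 30,
                                    c("a", "b"))
  expect_equal(rank_channels_by_variance(ws3), c(1, 2))
})

test_that("select_top_channels keeps ranked channels in original order", {
  arr <- array(rnorm(2 * 10 * 5), c(2, 10, 5))
  for (c in 1:5) arr[, , c] <- arr[, , c] * c(2, 1, 3, 0.1, 1)[c]
  ws <- marginhar:::new_window_set(arr, c(0L, 1L), NA_integer_, 30,
                                   sprintf("ch%d", 1:5))
  rk <- rank_channels_by_variance(ws)
  top3 <- select_top_channels(ws, rk, 3)
  expect_equal(top3$channel_names, sprintf("ch%d", sort(rk[1:3])))
  expect_equal(dim(top3$data)[3], 3)

  all5 <- select_top_channels(ws, rk, 5)
  expect_equal(all5$data, ws$data)     # identity up to order preservation
  expect_equal(dim(select_top_channels(ws, rk, 1)$data)[3], 1)
  expect_error(select_top_channels(ws, rk, 6), "n must be")
  expect_error(select_top_channels(ws, rk, 0), "n must be")
})

test_that("fill -> downsample -> slide never yields missing values", {
  cfg <- synthetic_config(n_classes = 3, n_windows_per_class = 10,
                          missing_rate = 0.3, rng_seed = 5)
  rec <- generate_recording(cfg)
  ws <- slide_windows(downsample(fill_missing(rec), 2), 8, 3)
  expect_false(anyNA(ws$data))
  expect_gt(dim(ws$data)[1], 0)
})
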