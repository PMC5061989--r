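test_that("window segmentation matches the count formula and a naive oracle", {
  # 10 s at 128 Hz, 2 s windows, 50% overlap: 9 windows at starts 0,128,...,1024
  rec <- recording(matrix(rnorm(1280 * 2), 1280, 2), sample_rate = 128)
  wins <- segment_windows(rec)
  expect_length(wins, 9L)
  expect_identical(vapply(wins, `[[`, integer(1), "start_index"),
                   seq.int(0L, 1024L, by = 128L))
  expect_true(all(vapply(wins, function(w) nrow(w$data), integer(1)) == 256L))

  # property: count = floor((N - W)/H) + 1 against a naive sliding loop
  set.seed(3)
  for (case in 1:25) {
    N <- sample(20:400, 1); W <- sample(5:20, 1) * 2L
    if (N < W) next
    ov <- sample(c(0, 0.25, 0.5, 0.75), 1)
    rec <- recording(matrix(0, N, 1), sample_rate = 2)
    wins <- segment_windows(rec, window_s = W / 2, overlap = ov)
    H <- max(1L, as.integer(round(W * (1 - ov))))
    expect_length(wins, floor((N - W) / H) + 1)
    expect_identical(vapply(wins, `[[`, integer(1), "start_index"),
                     naive_window_starts(N, W, H))
  }
})

test_that("segmentation edge cases: exact fit and too-short recordings", {
  rec <- recording(matrix(0, 256, 1), sample_rate = 128)
  expect_length(segment_windows(rec), 1L)
  short <- recording(matrix(0, 255, 1), sample_rate = 128)
  expect_error(segment_windows(short), class = "fnnbci_short_recording")
  expect_match(tryCatch(segment_windows(short), error = conditionMessage),
               "shorter than window")
})

test_that("windows inherit the recording label", {
  rec <- recording(matrix(0, 512, 1), sample_rate = 128, label = "left")
  expect_true(all(vapply(segment_windows(rec), `[[`, "", "label") == "left"))
})

test_that("channel centring zeroes means and leaves shape unchanged", {
  win <- eeg_window(cbind(rep(5, 8), 1:8, c(-1, 1, -1, 1, -1, 1, -1, 1)))
  cen <- center_channels(win)
  expect_equal(dim(cen$data), dim(win$data))
  expect_lt(max(abs(colMeans(cen$data))), 1e-12)
  expect_equal(cen$data[, 1], rep(0, 8))
  expect_equal(cen$data[, 2], (1:8) - 4.5)
  expect_equal(cen$data[, 3], win$data[, 3])   # already zero-mean
})

test_that("Hamming taper has the printed endpoint, peak and symmetry", {
  h <- hamming_coefficients(256L)
  expect_equal(h[1], 0.08)
  expect_equal(h, rev(h))
  h9 <- hamming_coefficients(9L)
  expect_equal(h9[5], 1.0)                     # midpoint of odd length
  win <- eeg_window(matrix(1, 16, 2))
  expect_equal(apply_hamming(win)$data[, 1], hamming_coefficients(16L))
})

test_that("spectral features match a brute-force DFT oracle", {
  # zero signal -> all-zero features
  z <- spectral_features(eeg_window(matrix(0, 256, 3)))
  expect_length(z, 3 * 64)
  expect_true(all(z == 0))

  # unit 8 Hz sinusoid at 128 Hz: peak at bin 16 (= 8 / 0.5 Hz)
  t <- (0:255) / 128
  x <- sin(2 * pi * 8 * t)
  win <- apply_hamming(center_channels(eeg_window(matrix(x, 256, 1))))
  feats <- spectral_features(win)
  expect_identical(unname(which.max(feats)), 17L)   # bin 16, 0-based
  oracle <- vapply(0:63, function(k) dft_magnitude(win$data[, 1], k),
                   numeric(1))
  expect_equal(unname(feats), oracle, tolerance = 1e-10)

  # energy of an in-bin tone concentrates >= 90% in its bin +/- 1
  full <- vapply(0:128, function(k) dft_magnitude(win$data[, 1], k),
                 numeric(1))
  expect_gte(sum(full[16:18]^2) / sum(full^2), 0.9)
})

test_that("14 channels x 64 bins gives 896 named features", {
  win <- eeg_window(matrix(rnorm(256 * 14), 256,
                           dimnames = list(NULL, emotiv_channels)))
  feats <- spectral_features(apply_hamming(center_channels(win)))
  expect_length(feats, 896L)
  expect_false(anyDuplicated(names(feats)) > 0)
  expect_identical(names(feats)[1:2], c("AF3_0Hz", "AF3_0.5Hz"))
  expect_error(spectral_features(win, n_bins = 200),
               class = "fnnbci_too_many_bins")
})

test_that("information gain reproduces hand-computed entropies", {
  # feature equal to a balanced binary label: exactly 1 bit
  y <- rep(c("a", "b"), each = 20)
  fm <- feature_matrix(cbind(f1 = rep(c(0, 1), each = 20),
                             f2 = rep(3, 40)), labels = y)
  rk <- info_gain_rank(fm)
  expect_equal(rk$scores[1], 1.0)
  expect_equal(rk$scores[2], 0.0)              # constant feature
  expect_identical(rk$order, c(1L, 2L))

  # perfect separation of 6 balanced classes: log2(6) bits
  y6 <- rep(letters[1:6], each = 10)
  fm6 <- feature_matrix(cbind(sep = rep(1:6, each = 10)), labels = y6)
  expect_equal(info_gain_rank(fm6)$scores[1], log2(6))

  expect_error(info_gain_rank(feature_matrix(cbind(1:4), labels = rep("a", 4))),
               class = "fnnbci_single_class")
})

test_that("information gain is invariant under strictly monotone transforms", {
  set.seed(8)
  x <- rnorm(120)
  y <- rep(c("a", "b", "c"), 40)
  base <- info_gain_rank(feature_matrix(cbind(f = x), labels = y))$scores
  for (f in list(function(v) v^3, exp, function(v) 5 * v - 2)) {
    tr <- info_gain_rank(feature_matrix(cbind(f = f(x)), labels = y))$scores
    expect_equal(tr, base)
  }
})

test_that("top-k selection keeps ranked order and validates k", {
  set.seed(5)
  fm <- feature_matrix(matrix(rnorm(40 * 6), 40, 6),
                       paste0("f", 1:6), rep(c("a", "b"), 20))
  rk <- info_gain_rank(fm)
  all6 <- select_top_k(fm, rk, 6)
  expect_setequal(all6$feature_names, fm$feature_names)
  expect_identical(all6$feature_names, fm$feature_names[rk$order])
  top1 <- select_top_k(fm, rk, 1)
  expect_identical(top1$feature_names, fm$feature_names[rk$order[1]])
  expect_error(select_top_k(fm, rk, 7), class = "fnnbci_bad_k")
  # determinism of ranking + selection
  expect_identical(select_top_k(fm, info_gain_rank(fm), 3)$feature_names,
                   select_top_k(fm, info_gain_rank(fm), 3)$feature_names)
})

test_that("min-max scaling maps train to [0,1] and clips apply data", {
  train <- feature_matrix(cbind(a = c(1, 3, 5), b = c(2, 2, 2)))
  sc <- scale_features(train)
  expect_equal(sc$values[, "a"], c(0, 0.5, 1))
  expect_equal(sc$values[, "b"], c(0, 0, 0))   # constant column -> zeros
  app <- feature_matrix(cbind(a = c(0, 6), b = c(1, 9)))
  sca <- scale_features(train, app)
  expect_equal(unname(sca$values[, "a"]), c(0, 1))   # clipped both sides
  expect_true(all(sca$values >= 0 & sca$values <= 1))
})

test_that("feature matrices round trip through CSV", {
  fm <- feature_matrix(matrix(rnorm(12), 4, 3), c("x_1Hz", "y_2Hz", "z_3Hz"),
                       labels = c("a", "b", "a", "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_identical(back$feature_names, fm$feature_names)
  expect_equal(back$values, fm$values, tolerance = 1e-12)
  expect_identical(as.character(back$labels), as.character(fm$labels))
})
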