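# Shared fixtures and independent oracles for the test suite.

# Small random network with well-conditioned widths.
random_model <- function(m, r, n, seed = 1L, class_names = NULL) {
  set.seed(seed)
  fnn_model(centers = matrix(stats::rnorm(m * r), m, r),
            widths = matrix(stats::runif(m * r, 0.3, 1.5), m, r),
            a = matrix(stats::runif(m * r, -1, 1), m, r),
            b = stats::runif(r, -1, 1),
            w = matrix(stats::runif(r * n, -1, 1), r, n),
            class_names = class_names)
}

# Central-difference numerical gradient of scalar f at x.
numerical_gradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# Flatten all model parameters; inverse of unpack_model.
pack_model <- function(model)
  c(model$centers, model$widths, model$a, model$b, model$w)

unpack_model <- function(model, p) {
  m <- model$m; r <- model$r; n <- model$n
  i <- 0L
  model$centers[] <- p[i + seq_len(m * r)]; i <- i + m * r
  model$widths[] <- p[i + seq_len(m * r)]; i <- i + m * r
  model$a[] <- p[i + seq_len(m * r)]; i <- i + m * r
  model$b <- p[i + seq_len(r)]; i <- i + r
  model$w[] <- p[i + seq_len(r * n)]
  model
}

# Brute-force single-channel DFT magnitude at bin k (independent of
# stats::fft), used as the spectral oracle.
dft_magnitude <- function(x, k) {
  W <- length(x)
  t <- seq_len(W) - 1L
  Mod(sum(x * exp(-2i * pi * k * t / W)))
}

# Naive sliding-window counter used as the windowing oracle.
naive_window_starts <- function(N, W, H) {
  starts <- integer(0)
  s <- 0L
  while (s + W <= N) {
    starts <- c(starts, s)
    s <- s + H
  }
  starts
}

# Cluster-structured teacher-student regression problem: inputs are r
# Gaussian blobs (the structure the FCM-based width heuristic assumes),
# targets are the noise-free outputs of a random teacher network whose
# rule centres sit on the blob centres.
make_teacher_student <- function(N = 200L, m = 5L, r = 3L, n = 2L,
                                 seed = 99L) {
  set.seed(seed)
  blob_centers <- matrix(stats::runif(m * r, 0.1, 0.9), r, m)
  per <- N %/% r
  X <- do.call(rbind, lapply(seq_len(r), function(j)
    sapply(seq_len(m), function(d)
      stats::rnorm(per, blob_centers[j, d], 0.08))))
  teacher <- fnn_model(t(blob_centers), matrix(0.4, m, r),
                       matrix(stats::runif(m * r, -1, 1), m, r),
                       stats::runif(r, -1, 1),
                       matrix(stats::runif(r * n, -1, 1), r, n))
  list(X = X, U = fnn_forward(X, teacher), teacher = teacher,
       m = m, r = r, n = n)
}

# Selected, unscaled feature matrix for a small synthetic dataset.
small_feature_set <- function(duration_s = 10, seed = 42, k = 100,
                              noise_sd = 0.05) {
  recs <- generate_dataset(1, default_class_specs(noise_sd),
                           duration_s = duration_s, seed = seed)
  fm <- extract_features(recs)
  select_top_k(fm, info_gain_rank(fm), k)
}
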