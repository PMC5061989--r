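# Parameter estimation for the TSK network: fuzzy c-means for the
# antecedents, seeded random init of the consequents, per-sample gradient
# descent with momentum and a bold-driver adaptive learning rate, and
# stratified 10-fold cross-validated evaluation.

# Labelled sub-seed fan-out: one user seed reproducibly drives data
# generation, clustering, init, shuffling and fold assignment without the
# streams colliding.
sub_seed <- function(seed, what) {
  offs <- c(generate = 11L, fcm = 23L, init = 37L, shuffle = 53L,
            folds = 71L, eval = 89L)
  off <- offs[[what]]
  as.integer((as.double(seed) * 1009 + off) %% 2147483647)
}

#' Fuzzy c-means clustering
#'
#' Standard alternating-optimisation fuzzy c-means: memberships
#' `u_ij = 1 / sum_l (d_ij / d_il)^(2/(f-1))`, centres as the
#' `u^f`-weighted means, iterated until the largest centre shift falls
#' below `tol` or `max_iter` passes. Each membership row sums to 1. A
#' point coincident with a centre gets full membership in that cluster.
#'
#' @param X N-by-m data matrix.
#' @param r number of clusters (`N >= r >= 1`).
#' @param fuzzifier membership exponent `f > 1` (default 2).
#' @param tol convergence tolerance on the centre shift (default 1e-6).
#' @param max_iter iteration cap (default 300).
#' @param seed RNG seed for the initial centres (distinct data points).
#' @return list of class `fcm_result`: `centers` (r-by-m),
#'   `memberships` (N-by-r, rows summing to 1), `iterations`,
#'   `objective` (final value of `sum u^f d^2`), `objective_trace`
#'   (per-iteration), `data_sd` (per-dimension standard deviation of X,
#'   kept for the single-rule width rule).
#' @export
fcm_cluster <- function(X, r, fuzzifier = 2.0, tol = 1e-6, max_iter = 300L,
                        seed = NULL) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (r < 1L) abort("need at least one cluster", "fnnbci_bad_r")
  if (N < r)
    abort(sprintf("fewer points (%d) than clusters (%d)", N, r),
          "fnnbci_too_few_points")
  if (fuzzifier <= 1) abort("fuzzifier must exceed 1", "fnnbci_bad_fuzzifier")
  if (!is.null(seed)) set.seed(seed)
  centers <- X[sample.int(N, r), , drop = FALSE]
  expo <- 2 / (fuzzifier - 1)
  trace <- numeric(0)
  U <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(X^2), rep(1, r)) - 2 * X %*% t(centers) +
      outer(rep(1, N), rowSums(centers^2))
    d2 <- pmax(d2, 0)
    U <- matrix(0, N, r)
    zero <- d2 < 1e-300
    any_zero <- rowSums(zero) > 0
    if (any(any_zero))                       # coincident point: full membership
      U[any_zero, ] <- zero[any_zero, , drop = FALSE] /
        rowSums(zero[any_zero, , drop = FALSE])
    if (any(!any_zero)) {
      inv <- d2[!any_zero, , drop = FALSE]^(-expo / 2)
      U[!any_zero, ] <- inv / rowSums(inv)
    }
    Uf <- U^fuzzifier
    trace <- c(trace, sum(Uf * d2))
    new_centers <- (t(Uf) %*% X) / colSums(Uf)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  structure(list(centers = centers, memberships = U, iterations = it,
                 objective = trace[length(trace)], objective_trace = trace,
                 data_sd = apply(X, 2L, stats::sd)),
            class = "fcm_result")
}

#' Antecedent parameters from a clustering
#'
#' Membership centres are the FCM cluster centres; each rule's width is
#' `alpha` times the Euclidean distance from its centre to the nearest
#' *distinct* centre, shared across inputs and floored at `floor`.
#'
#' When the requested rule count exceeds the number of natural clusters,
#' FCM converges with several centres (near-)coincident on one cluster.
#' Such duplicates carry no scale information — taking the raw nearest
#' distance would give those rules vanishing widths, and rules far
#' narrower than their neighbours are silenced by the normalised mixing
#' layer and never recover during training. Centres closer than
#' `coincident_tol` are therefore treated as the same centre; a rule with
#' no distinct neighbour (including the single-rule case) falls back to
#' the per-dimension data standard deviation.
#'
#' @param fcm an `fcm_result`.
#' @param alpha width scale (default 0.5).
#' @param floor minimum width (default 0.05, in scaled feature units).
#' @param coincident_tol centre separation below which two centres count
#'   as duplicates (default 0.01 in scaled feature units).
#' @return list with `centers` and `widths`, both m-by-r.
#' @export
init_antecedents <- function(fcm, alpha = 0.5, floor = 0.05,
                             coincident_tol = 0.01) {
  centers <- t(fcm$centers)                  # m x r
  r <- ncol(centers); m <- nrow(centers)
  sd_width <- pmax(fcm$data_sd, floor)
  widths <- matrix(0, m, r)
  D <- if (r > 1L) as.matrix(stats::dist(fcm$centers)) else NULL
  for (j in seq_len(r)) {
    distinct <- if (r > 1L) D[j, -j][D[j, -j] > coincident_tol] else numeric(0)
    widths[, j] <- if (length(distinct) == 0L) sd_width
                   else max(alpha * min(distinct), floor)
  }
  list(centers = centers, widths = widths)
}

#' Random initial consequent and mixing parameters
#'
#' All consequent coefficients, intercepts and mixing weights drawn
#' i.i.d. uniform on `[-1, 1]`, reproducibly for a given seed.
#' @param m,r,n input, rule and output counts.
#' @param seed RNG seed.
#' @return list with `a` (m-by-r), `b` (length r), `w` (r-by-n).
#' @export
init_consequents <- function(m, r, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(a = matrix(stats::runif(m * r, -1, 1), m, r),
       b = stats::runif(r, -1, 1),
       w = matrix(stats::runif(r * n, -1, 1), r, n))
}

#' Half squared error of one sample
#'
#' `E = 1/2 sum_k (u_k^d - u_k)^2`, the per-sample training criterion.
#' @param u network outputs.
#' @param u_d desired (one-hot) outputs.
#' @return scalar `E >= 0`.
#' @export
sample_error <- function(u, u_d) {
  if (length(u) != length(u_d))
    abort("output and target lengths differ", "fnnbci_bad_shape")
  0.5 * sum((u_d - u)^2)
}

#' Analytic gradients of the per-sample error
#'
#' Exact partial derivatives of [sample_error()] with respect to every
#' parameter group of the network (mixing weights, consequent
#' coefficients and intercepts, membership centres and widths), under
#' the product t-norm. These are the gradients the training loop uses.
#'
#' @param x length-m input vector.
#' @param u_d length-n target vector.
#' @param model an `fnn_model` (product t-norm).
#' @return list of gradients `w` (r-by-n), `a` (m-by-r), `b` (length r),
#'   `centers`, `widths` (m-by-r), plus the forward output `u`.
#' @export
fnn_gradients <- function(x, u_d, model) {
  if (model$tnorm != "product")
    abort("gradients are defined for the product t-norm only",
          "fnnbci_min_tnorm")
  fnn_gradients_cpp(as.numeric(x), as.numeric(u_d), model$centers,
                    model$widths, model$a, model$b, model$w)
}

#' Training configuration
#'
#' @param epochs passes over the training set (default 1000).
#' @param gamma initial learning rate (default 0.01). With momentum
#'   `lambda` the steady-state effective step of the heavy-ball update
#'   is `gamma / (1 - lambda)`; 0.01 at the default momentum gives an
#'   effective step of 0.1 and converges on scaled `[0, 1]` features,
#'   where hotter rates destabilise the per-sample updates.
#' @param lambda momentum coefficient in `[0, 1)` (default 0.9).
#' @param lr_up bold-driver factor applied after an epoch whose training
#'   RMSE improved (default 1.05).
#' @param lr_down factor applied after a worsening epoch (default 0.7).
#' @param r number of fuzzy rules (default 6).
#' @param width_scale scale `alpha` of [init_antecedents()].
#' @param width_floor minimum membership width.
#' @param fuzzifier,fcm_tol,fcm_max_iter fuzzy c-means settings.
#' @param batch if `TRUE`, one mean-gradient update per epoch instead of
#'   per-sample updates.
#' @param n_starts random restarts of the whole initialisation +
#'   training procedure (default 5). The fit is non-convex and an
#'   unlucky initial draw can strand on a plateau; each start is piloted
#'   for `pilot_epochs` and the start with the lowest pilot *training*
#'   RMSE is rerun for the full epoch budget. Deterministic given
#'   `seed`.
#' @param pilot_epochs pilot length used to compare starts
#'   (default 100).
#' @param seed RNG seed fanned out to clustering, init and shuffling.
#' @return a `training_config` list.
#' @export
training_config <- function(epochs = 1000L, gamma = 0.01, lambda = 0.9,
                            lr_up = 1.05, lr_down = 0.7, r = 6L,
                            width_scale = 0.5, width_floor = 0.05,
                            fuzzifier = 2.0, fcm_tol = 1e-6,
                            fcm_max_iter = 300L, batch = FALSE,
                            n_starts = 5L, pilot_epochs = 100L,
                            seed = 1L) {
  if (epochs < 0L) abort("epochs must be >= 0", "fnnbci_bad_config")
  if (lambda < 0 || lambda >= 1)
    abort("momentum must be in [0, 1)", "fnnbci_bad_config")
  if (gamma <= 0) abort("learning rate must be positive", "fnnbci_bad_config")
  structure(list(epochs = as.integer(epochs), gamma = gamma, lambda = lambda,
                 lr_up = lr_up, lr_down = lr_down, r = as.integer(r),
                 width_scale = width_scale, width_floor = width_floor,
                 fuzzifier = fuzzifier, fcm_tol = fcm_tol,
                 fcm_max_iter = as.integer(fcm_max_iter), batch = batch,
                 n_starts = as.integer(n_starts),
                 pilot_epochs = as.integer(pilot_epochs),
                 seed = as.integer(seed)),
            class = "training_config")
}

one_hot <- function(labels, class_names) {
  T <- matrix(0, length(labels), length(class_names))
  T[cbind(seq_along(labels), match(as.character(labels), class_names))] <- 1
  T
}

#' Train the fuzzy neural network
#'
#' Antecedents are initialised by fuzzy c-means on the training inputs
#' (one joint clustering with `r` clusters; the rule count equals the
#' cluster count), consequents and mixing weights uniformly on
#' `[-1, 1]`. All five parameter groups are then updated by per-sample
#' gradient descent with momentum, in a freshly shuffled order each
#' epoch, under a bold-driver adaptive learning rate: an epoch whose
#' training RMSE improves is accepted and the rate grown by `lr_up`; a
#' worsening (or numerically overflowing) epoch is rejected — the
#' parameters are restored, the momentum reset and the rate shrunk by
#' `lr_down` — so the recorded training RMSE never increases and the
#' adaptive rate safeguards convergence. Targets are one-hot: 1 for the
#' true class, 0 elsewhere.
#'
#' @param fm a labelled, min-max scaled `feature_matrix`.
#' @param cfg a [training_config()].
#' @param eval_fm optional held-out `feature_matrix` monitored per epoch
#'   (never used for updates).
#' @param class_names output order; defaults to the label levels.
#' @return list with `model` (an `fnn_model`) and `history` (data frame
#'   with one row per epoch: `epoch`, `train_rmse`, `eval_rmse`, `lr`).
#' @export
fnn_train <- function(fm, cfg = training_config(), eval_fm = NULL,
                      class_names = NULL) {
  if (is.null(fm$labels)) abort("training needs labels", "fnnbci_no_labels")
  X <- fm$values
  if (is.null(class_names)) class_names <- levels(fm$labels)
  T <- one_hot(fm$labels, class_names)
  N <- nrow(X); m <- ncol(X); n <- length(class_names)
  if (N < cfg$r)
    abort("fewer training samples than rules", "fnnbci_too_few_points")

  if (cfg$epochs == 0L) {
    fcm <- fcm_cluster(X, cfg$r, cfg$fuzzifier, cfg$fcm_tol,
                       cfg$fcm_max_iter, seed = sub_seed(cfg$seed, "fcm"))
    ants <- init_antecedents(fcm, cfg$width_scale, cfg$width_floor)
    cons <- init_consequents(m, cfg$r, n, seed = sub_seed(cfg$seed, "init"))
    model <- fnn_model(ants$centers, ants$widths, cons$a, cons$b, cons$w,
                       class_names, bounds = attr(fm, "bounds"))
    history <- data.frame(epoch = integer(0), train_rmse = numeric(0),
                          eval_rmse = numeric(0), lr = numeric(0))
    return(list(model = model, history = history, fcm = fcm))
  }

  has_eval <- !is.null(eval_fm)
  Xev <- if (has_eval) eval_fm$values else matrix(0, 0L, m)
  Tev <- if (has_eval) one_hot(eval_fm$labels, class_names)
         else matrix(0, 0L, n)

  # the fit is non-convex: pilot each seeded start briefly and rerun
  # the one with the lowest pilot training RMSE for the full budget
  start_seeds <- cfg$seed + 101L * (seq_len(cfg$n_starts) - 1L)
  best_seed <- start_seeds[1]
  if (cfg$n_starts > 1L && cfg$epochs > cfg$pilot_epochs) {
    pilot_rmse <- vapply(start_seeds, function(s)
      utils::tail(gd_run(X, T, matrix(0, 0L, m), matrix(0, 0L, n), cfg, s,
                         cfg$pilot_epochs)$fit$train_rmse, 1),
      numeric(1))
    best_seed <- start_seeds[which.min(pilot_rmse)]
  }
  run <- gd_run(X, T, Xev, Tev, cfg, best_seed, cfg$epochs)
  fit <- run$fit
  model <- fnn_model(fit$centers, fit$widths, fit$a, as.numeric(fit$b),
                     fit$w, class_names, bounds = attr(fm, "bounds"))
  history <- data.frame(epoch = seq_len(cfg$epochs),
                        train_rmse = as.numeric(fit$train_rmse),
                        eval_rmse = as.numeric(fit$eval_rmse),
                        lr = as.numeric(fit$lr))
  list(model = model, history = history, fcm = run$fcm,
       start_seed = best_seed)
}

# One complete seeded initialisation + gradient-descent run.
gd_run <- function(X, T, Xev, Tev, cfg, seed, epochs) {
  N <- nrow(X); m <- ncol(X); n <- ncol(T)
  fcm <- fcm_cluster(X, cfg$r, cfg$fuzzifier, cfg$fcm_tol, cfg$fcm_max_iter,
                     seed = sub_seed(seed, "fcm"))
  ants <- init_antecedents(fcm, cfg$width_scale, cfg$width_floor)
  cons <- init_consequents(m, cfg$r, n, seed = sub_seed(seed, "init"))
  set.seed(sub_seed(seed, "shuffle"))
  order_mat <- t(vapply(seq_len(epochs), function(e) sample.int(N),
                        integer(N)))
  fit <- fnn_train_cpp(X, T, Xev, Tev, ants$centers, ants$widths,
                       cons$a, cons$b, cons$w, order_mat,
                       cfg$gamma, cfg$lambda, cfg$lr_up, cfg$lr_down,
                       cfg$width_floor, cfg$batch)
  list(fit = fit, fcm = fcm)
}

#' Root-mean-square error over all samples and outputs
#'
#' `sqrt(mean((U_d - U)^2))` over every sample and output neuron, the
#' performance criterion reported during and after training.
#' @param u N-by-n predictions (or a vector).
#' @param u_d matching targets.
#' @return scalar RMSE.
#' @export
rmse <- function(u, u_d) {
  if (length(u) == 0L) abort("empty predictions", "fnnbci_bad_shape")
  sqrt(mean((as.matrix(u_d) - as.matrix(u))^2))
}

# Seeded per-class sampler for the evaluation split: picks ~fraction of
# each class, never the whole class.
stratified_sample <- function(labels, fraction, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pick <- logical(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) next
    n_pick <- min(max(1L, round(length(idx) * fraction)), length(idx) - 1L)
    pick[sample(idx, n_pick)] <- TRUE
  }
  pick
}

stratified_folds <- function(labels, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold_of <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    if (length(idx) < folds)
      warning(sprintf(
        "class '%s' has %d members, fewer than %d folds; some folds lack it",
        cl, length(idx), folds), call. = FALSE)
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

subset_fm <- function(fm, idx) {
  feature_matrix(fm$values[idx, , drop = FALSE], fm$feature_names,
                 if (is.null(fm$labels)) NULL else fm$labels[idx])
}

#' Stratified k-fold cross-validation of the full classifier
#'
#' Splits windows into stratified folds (per-class counts differing by
#' at most one), trains on the remainder of each fold and tests on the
#' held-out fold, so every window is tested exactly once. Within each
#' training portion a stratified 10% evaluation split is monitored
#' during the epochs but never used for updates. Feature scaling bounds
#' are computed from each fold's training portion only.
#'
#' @param fm a labelled, *unscaled* `feature_matrix` (already
#'   feature-selected).
#' @param cfg a [training_config()].
#' @param folds number of folds (default 10).
#' @param seed seed for fold assignment and the evaluation split;
#'   defaults to `cfg$seed`.
#' @param eval_fraction fraction of the training portion held out for
#'   epoch monitoring (default 0.1).
#' @return list of class `cv_result`: `per_fold` data frame (fold,
#'   train/eval/test RMSE, test error count), `confusion` (n-by-n matrix,
#'   rows = truth), `accuracy` (fraction), `correct`, `incorrect`,
#'   `predictions` data frame.
#' @export
cross_validate <- function(fm, cfg = training_config(), folds = 10L,
                           seed = NULL, eval_fraction = 0.1) {
  if (is.null(fm$labels)) abort("labels required", "fnnbci_no_labels")
  N <- nrow(fm$values)
  if (N < folds) abort("fewer windows than folds", "fnnbci_too_few_points")
  if (is.null(seed)) seed <- cfg$seed
  labels <- droplevels(fm$labels)
  class_names <- levels(labels)
  fold_of <- stratified_folds(labels, folds, seed = sub_seed(seed, "folds"))
  pred <- character(N); truth <- as.character(labels)
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    train_lab <- labels[train_idx]
    ev_pick <- stratified_sample(droplevels(train_lab), eval_fraction,
                                 seed = sub_seed(seed + f, "eval"))
    upd_idx <- train_idx[!ev_pick]
    ev_idx <- train_idx[ev_pick]
    upd_fm <- subset_fm(fm, upd_idx)
    sc_upd <- scale_features(upd_fm)
    bounds <- attr(sc_upd, "bounds")
    sc_ev <- scale_features(bounds, subset_fm(fm, ev_idx))
    fit <- fnn_train(sc_upd, cfg, eval_fm = sc_ev,
                     class_names = class_names)
    sc_test <- scale_features(bounds, subset_fm(fm, test_idx))
    U <- fnn_forward(sc_test$values, fit$model)
    pred[test_idx] <- fnn_classify(U, class_names)
    last <- nrow(fit$history)
    per_fold[[f]] <- data.frame(
      fold = f,
      train_rmse = if (last) fit$history$train_rmse[last] else NA_real_,
      eval_rmse = if (last) fit$history$eval_rmse[last] else NA_real_,
      test_rmse = rmse(U, one_hot(labels[test_idx], class_names)),
      test_errors = sum(pred[test_idx] != truth[test_idx]))
  }
  per_fold <- do.call(rbind, per_fold)
  confusion <- table(factor(truth, class_names), factor(pred, class_names))
  confusion <- unclass(as.matrix(confusion))
  names(dimnames(confusion)) <- c("truth", "predicted")
  correct <- sum(diag(confusion))
  structure(list(per_fold = per_fold, confusion = confusion,
                 accuracy = correct / N, correct = correct,
                 incorrect = N - correct,
                 predictions = data.frame(truth = truth, predicted = pred,
                                          fold = fold_of)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d folds | accuracy %.1f%% (%d/%d correct)\n",
    nrow(x$per_fold), 100 * x$accuracy, x$correct,
    x$correct + x$incorrect))
  cat(sprintf("mean RMSE: train %.4f, eval %.4f, test %.4f\n",
              mean(x$per_fold$train_rmse), mean(x$per_fold$eval_rmse),
              mean(x$per_fold$test_rmse)))
  invisible(x)
}
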