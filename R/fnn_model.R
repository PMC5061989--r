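#' Construct a TSK fuzzy neural network model
#'
#' The network has six layers: input distribution, Gaussian membership
#' functions, rule firing (t-norm), linear TSK consequents, rule-output
#' weighting, and a firing-strength-normalised mixing layer producing one
#' output per class.
#'
#' @param centers m-by-r matrix of Gaussian membership centres `c_ij`.
#' @param widths m-by-r matrix of Gaussian widths `sigma_ij` (all > 0).
#' @param a m-by-r matrix of consequent coefficients `a_ij`.
#' @param b length-r vector of consequent intercepts `b_j`.
#' @param w r-by-n matrix of output mixing weights `w_jk`.
#' @param class_names length-n character vector naming the outputs.
#' @param tnorm `"product"` (default; differentiable, used for training)
#'   or `"min"` (forward pass only).
#' @param bounds optional feature-scaling bounds ([feature_bounds()]) so
#'   a saved model is self-contained.
#' @return an object of class `fnn_model` with dimensions `m`, `r`, `n`.
#' @export
fnn_model <- function(centers, widths, a, b, w, class_names = NULL,
                      tnorm = c("product", "min"), bounds = NULL) {
  tnorm <- match.arg(tnorm)
  centers <- as.matrix(centers); widths <- as.matrix(widths)
  a <- as.matrix(a); b <- as.numeric(b); w <- as.matrix(w)
  m <- nrow(centers); r <- ncol(centers); n <- ncol(w)
  if (m < 1L || r < 1L || n < 1L)
    abort("model dimensions must all be at least 1", "fnnbci_bad_shape")
  if (!all(dim(widths) == c(m, r)) || !all(dim(a) == c(m, r)) ||
      length(b) != r || nrow(w) != r)
    abort("parameter shapes are inconsistent", "fnnbci_bad_shape")
  if (any(widths <= 0))
    abort("all membership widths must be positive", "fnnbci_bad_width")
  if (any(!is.finite(centers)) || any(!is.finite(widths)) ||
      any(!is.finite(a)) || any(!is.finite(b)) || any(!is.finite(w)))
    abort("model parameters must be finite", "fnnbci_nonfinite")
  if (is.null(class_names)) class_names <- paste0("class", seq_len(n))
  if (length(class_names) != n)
    abort("class_names length must equal the output count",
          "fnnbci_bad_shape")
  structure(list(centers = centers, widths = widths, a = a, b = b, w = w,
                 m = m, r = r, n = n,
                 class_names = as.character(class_names),
                 tnorm = tnorm, bounds = bounds),
            class = "fnn_model")
}

#' @export
print.fnn_model <- function(x, ...) {
  cat(sprintf(
    "<fnn_model> %d inputs, %d rules, %d outputs (%s t-norm)\nclasses: %s\n",
    x$m, x$r, x$n, x$tnorm, paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Gaussian membership degree
#'
#' `mu(x) = exp(-(x - c)^2 / sigma^2)` — note there is no factor 2 in the
#' denominator; the fitted widths absorb the convention.
#'
#' @param x input value(s).
#' @param c membership centre.
#' @param sigma membership width (> 0).
#' @return degree(s) in `(0, 1]`.
#' @export
membership <- function(x, c, sigma) {
  if (any(sigma <= 0))
    abort("membership width must be positive", "fnnbci_bad_width")
  exp(-(x - c)^2 / sigma^2)
}

#' Rule firing strengths
#'
#' Conjunction of the per-input membership degrees of each rule: the
#' product (default) or minimum over inputs.
#'
#' @param x length-m input vector.
#' @param model an `fnn_model`, or any list with `centers` and `widths`.
#' @param tnorm overrides the model's t-norm if given.
#' @return length-r vector of firing strengths in `(0, 1]`. Raw products
#'   can underflow to 0 in high dimension; [fnn_forward()] normalises in
#'   log space and is immune to this.
#' @export
firing_strengths <- function(x, model, tnorm = NULL) {
  tnorm <- tnorm %||% model$tnorm %||% "product"
  mem <- membership(matrix(x, nrow = length(x), ncol = ncol(model$centers)),
                    model$centers, model$widths)
  if (tnorm == "min") apply(mem, 2L, min) else apply(mem, 2L, prod)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' TSK consequent outputs
#'
#' The crisp linear consequent of each rule, `y_j = sum_i a_ij x_i + b_j`.
#' @param x length-m input vector.
#' @param model an `fnn_model`, or any list with `a` and `b`.
#' @return length-r vector.
#' @export
consequent_outputs <- function(x, model) {
  as.numeric(crossprod(model$a, x)) + model$b
}

#' Forward pass of the network
#'
#' `u_k = sum_j w_jk mu_j y_j / sum_j mu_j`: rule outputs weighted by
#' firing strength, mixed per class and normalised by the total firing
#' strength. Computed in log space (softmax normalisation), so the
#' denominator never underflows for finite inputs.
#'
#' @param x length-m numeric vector, or an N-by-m matrix of inputs.
#' @param model an `fnn_model`.
#' @return length-n output vector `u` (or N-by-n matrix), columns named
#'   by class.
#' @export
fnn_forward <- function(x, model) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != model$m)
    abort(sprintf("input has %d columns, model expects %d",
                  ncol(X), model$m), "fnnbci_bad_shape")
  U <- fnn_forward_cpp(X, model$centers, model$widths, model$a, model$b,
                       model$w, as.integer(model$tnorm == "min"))
  colnames(U) <- model$class_names
  if (is.matrix(x)) U else U[1L, ]
}

#' Decide the class from the network outputs
#'
#' Returns the class with the maximal output; ties break to the lowest
#' index.
#' @param u length-n output vector (or N-by-n matrix).
#' @param class_names length-n character vector.
#' @return class name(s) as a character vector.
#' @export
fnn_classify <- function(u, class_names) {
  if (is.matrix(u)) class_names[max.col(u, ties.method = "first")]
  else class_names[which.max(u)]
}

#' Classify all rows of a feature matrix
#'
#' Applies the model's stored scaling bounds (if present), runs the
#' forward pass and the argmax decision.
#' @param model an `fnn_model`.
#' @param fm a `feature_matrix` on the model's feature set (unscaled if
#'   the model carries bounds, scaled otherwise).
#' @param scaled set `TRUE` if `fm` is already min-max scaled.
#' @return list with `class` (character vector) and `outputs`
#'   (N-by-n matrix).
#' @export
fnn_predict <- function(model, fm, scaled = is.null(model$bounds)) {
  if (!scaled) fm <- scale_features(model$bounds, fm)
  U <- fnn_forward(fm$values, model)
  list(class = fnn_classify(U, model$class_names), outputs = U)
}

#' Rule count of a grid-partitioned fuzzy system
#'
#' A classical neuro-fuzzy design builds one rule per combination of
#' per-input clusters, i.e. `clusters^m` rules — `2^100` for 100 inputs
#' with 2 clusters each, which is why this package instead sets the rule
#' count equal to the number of joint fuzzy c-means clusters.
#' @param m number of inputs.
#' @param clusters clusters per input.
#' @return `clusters^m` as a double.
#' @export
grid_rule_count <- function(m, clusters) as.numeric(clusters)^m

#' Save a model as a self-contained JSON document
#' @param model an `fnn_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_fnn <- function(model, path) {
  obj <- list(m = model$m, r = model$r, n = model$n,
              centers = as.numeric(model$centers),   # column-major flat
              widths = as.numeric(model$widths),
              a = as.numeric(model$a), b = model$b,
              w = as.numeric(model$w),
              class_names = model$class_names, tnorm = model$tnorm)
  if (!is.null(model$bounds))
    obj$bounds <- list(min = unname(model$bounds$min),
                       max = unname(model$bounds$max),
                       feature_names = model$bounds$feature_names)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model saved by [save_fnn()]
#' @param path JSON path.
#' @return an `fnn_model`.
#' @export
load_fnn <- function(path) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "fnnbci_missing_file")
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, nr) matrix(as.numeric(unlist(x)), nrow = nr)
  bounds <- NULL
  if (!is.null(o$bounds))
    bounds <- list(min = as.numeric(o$bounds$min),
                   max = as.numeric(o$bounds$max),
                   feature_names = as.character(o$bounds$feature_names))
  fnn_model(as_mat(o$centers, o$m), as_mat(o$widths, o$m),
            as_mat(o$a, o$m), as.numeric(o$b), as_mat(o$w, o$r),
            class_names = as.character(o$class_names), tnorm = o$tnorm,
            bounds = bounds)
}
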