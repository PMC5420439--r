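#' Between- and within-class scatter matrices
#'
#' `S_b = sum_k n_k (mu_k - mu)(mu_k - mu)^T` with `mu` the overall mean;
#' `S_w = sum_k sum_{x in C_k} (x - mu_k)(x - mu_k)^T`.
#'
#' @param x1 `n1 x d` matrix, class 1 (red lesion).
#' @param x2 `n2 x d` matrix, class 2 (non-lesion).
#' @return list `S_b`, `S_w`, `mu1`, `mu2` (and `mu`, the pooled mean).
#' @export
scatter_matrices <- function(x1, x2) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (nrow(x1) < 2L || nrow(x2) < 2L)
    stop("scatter_matrices: each class needs at least 2 samples")
  n1 <- nrow(x1); n2 <- nrow(x2)
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  mu <- (n1 * mu1 + n2 * mu2) / (n1 + n2)
  S_b <- n1 * tcrossprod(mu1 - mu) + n2 * tcrossprod(mu2 - mu)
  c1 <- sweep(x1, 2, mu1); c2 <- sweep(x2, 2, mu2)
  S_w <- crossprod(c1) + crossprod(c2)
  list(S_b = S_b, S_w = S_w, mu1 = mu1, mu2 = mu2, mu = mu)
}

#' Fit a Fisher discriminant model
#'
#' Solves the generalized eigenproblem `S_b phi = lambda (S_w + eps I) phi`
#' for the leading direction `w`, verifies it against the two-class closed
#' form `w \propto (S_w + eps I)^{-1}(mu1 - mu2)`, orients it so the red
#' class (class 1) projects higher, and sets the threshold at the midpoint
#' of the projected class means, `c = w^T (mu1 + mu2) / 2`.
#'
#' @param x1,x2 training matrices (normalized features), class 1 = red.
#' @param epsilon ridge added to `S_w`; default `1e-6 * tr(S_w) / d`.
#'   Pass 0 to disable (errors if `S_w` is singular).
#' @param norm_stats optional normalization stats to store with the model.
#' @return an object of class `fda_model`: `w`, `c`, `mu1`, `mu2`,
#'   `epsilon`, `norm_stats`, `sign_flipped`.
#' @export
fit_fda <- function(x1, x2, epsilon = NULL, norm_stats = NULL) {
  sc <- scatter_matrices(x1, x2)
  d <- ncol(as.matrix(x1))
  if (is.null(epsilon)) epsilon <- 1e-6 * sum(diag(sc$S_w)) / d
  Sw <- sc$S_w + diag(epsilon, d)
  w_cf <- tryCatch(solve(Sw, sc$mu1 - sc$mu2), error = function(e)
    stop("fit_fda: within-class scatter is singular; use epsilon > 0 ",
         "(got epsilon = ", epsilon, ")"))
  # leading generalized eigenvector of (S_b, S_w + eps I)
  M <- solve(Sw, sc$S_b)
  ev <- eigen(M)
  w <- Re(ev$vectors[, which.max(Re(ev$values))])
  w <- w / sqrt(sum(w^2))
  w_cf_n <- w_cf / sqrt(sum(w_cf^2))
  cosine <- abs(sum(w * w_cf_n))
  if (cosine < 1 - 1e-6)
    warning(sprintf(
      "fit_fda: eigen direction deviates from closed form (cosine %.8f)",
      cosine))
  sign_flipped <- FALSE
  if (sum(w * sc$mu1) < sum(w * sc$mu2)) { w <- -w; sign_flipped <- TRUE }
  cthr <- sum(w * (sc$mu1 + sc$mu2)) / 2
  structure(list(w = w, c = cthr, mu1 = sc$mu1, mu2 = sc$mu2,
                 epsilon = epsilon, norm_stats = norm_stats,
                 sign_flipped = sign_flipped,
                 feature_names = colnames(as.matrix(x1))),
            class = "fda_model")
}

#' @export
print.fda_model <- function(x, ...) {
  cat(sprintf("<fda_model: %d features, threshold c = %.6g>\n",
              length(x$w), x$c))
  invisible(x)
}

#' Project samples on the discriminant direction
#'
#' Returns `w^T x`; higher scores mean more lesion-like under the stored
#' sign convention.
#'
#' @param model an `fda_model`.
#' @param x a feature vector or `n x d` matrix (already normalized).
#' @return numeric score(s).
#' @export
fda_score <- function(model, x) {
  stopifnot(inherits(model, "fda_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$w))
    stop("fda_score: feature dimension mismatch")
  drop(as.matrix(x) %*% model$w)
}

#' Thresholded classification
#'
#' A sample is labelled red iff its score strictly exceeds the threshold
#' (the stored projected-means midpoint, or `c_override`, e.g. 0.01, the
#' operating point used in the source experiments).
#'
#' @inheritParams fda_score
#' @param c_override optional threshold replacing `model$c`.
#' @return logical vector, `TRUE` = red lesion.
#' @export
fda_classify <- function(model, x, c_override = NULL) {
  thr <- if (is.null(c_override)) model$c else c_override
  fda_score(model, x) > thr
}

#' Serialize / restore an FDA model as JSON
#'
#' @param model an `fda_model`.
#' @param path JSON path.
#' @return (`write`) the path invisibly; (`read`) an `fda_model`.
#' @export
write_fda_model <- function(model, path) {
  stopifnot(inherits(model, "fda_model"))
  obj <- unclass(model)
  obj$version <- "1"
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_fda_model
#' @export
read_fda_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$version <- NULL
  if (!is.null(obj$norm_stats))
    obj$norm_stats <- list(mu = as.numeric(obj$norm_stats$mu),
                           sigma = as.numeric(obj$norm_stats$sigma))
  obj$w <- as.numeric(obj$w)
  obj$mu1 <- as.numeric(obj$mu1); obj$mu2 <- as.numeric(obj$mu2)
  structure(obj, class = "fda_model")
}
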