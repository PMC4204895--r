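#' Covariance-based PLS direction vector
#'
#' The direction vector for a single-output partial least-squares component
#' has entries proportional to cov(x_i, y) and unit Euclidean norm.  When
#' every input is uncorrelated with the output the direction is undefined
#' and the zero vector is returned with `degenerate = TRUE`.
#'
#' @param X numeric matrix, features in rows, samples in columns.
#' @param y numeric output vector, one value per sample.
#' @param tol covariances with norm below `tol` count as zero.
#' @return list with `p` (unit vector over features) and `degenerate`.
#' @export
direction_vector <- function(X, y, tol = 1e-12) {
  X <- as.matrix(X)
  if (ncol(X) < 2L)
    stop("InsufficientData: need >= 2 samples")
  if (ncol(X) != length(y))
    stop("X and y disagree on sample count")
  cv <- apply(X, 1L, function(x) stats::cov(x, y))
  nrm <- sqrt(sum(cv^2))
  if (!is.finite(nrm) || nrm < tol)
    return(list(p = numeric(nrow(X)), degenerate = TRUE))
  list(p = cv / nrm, degenerate = FALSE)
}

#' Deflate inputs and output against one PLS component
#'
#' Forms the score vector t = p'X, regresses every input row and the output
#' on t (no intercept), and returns the loadings and residuals.  Residuals
#' are orthogonal to the scores by construction.
#'
#' @param X feature x sample matrix.
#' @param y output vector.
#' @param p unit-norm direction vector over features.
#' @return list with `rx` (input residual matrix), `ry` (output residual),
#'   `ax` (input loadings), `ay` (output loading) and `scores`.
#' @export
deflate <- function(X, y, p) {
  X <- as.matrix(X)
  scores <- drop(crossprod(X, p))          # t = p'X, one score per sample
  tt <- sum(scores^2)
  if (!is.finite(tt) || tt < 1e-24)
    stop("DegenerateDirection: zero score vector")
  ax <- drop(X %*% scores) / tt
  rx <- X - outer(ax, scores)
  ay <- sum(y * scores) / tt
  ry <- y - ay * scores
  list(rx = rx, ry = ry, ax = ax, ay = ay, scores = scores)
}

#' Fit a single-output PLS regression
#'
#' Iterates [direction_vector()] and [deflate()] on the running residuals
#' until the output residual is small, the next direction is degenerate, or
#' the component count reaches its cap (at most `n_samples - 1`, since
#' further directions carry no information at small sample size).  The
#' coefficients over the original inputs are recovered by mapping each
#' direction back through the accumulated deflations: with r_1 = p_1 and
#' r_k = p_k - sum_{j<k} (ax_j' p_k) r_j, the prediction is
#' y_hat = X' (sum_k ay_k r_k).
#'
#' @param X feature x sample matrix.
#' @param y output vector.
#' @param max_components cap on the number of components; defaults to
#'   `min(nrow(X), ncol(X) - 1)`.
#' @param residual_tol stop when the output residual norm falls below this.
#' @return object of class `pls_model`: components (list of p, ax, ay,
#'   scores), `n_components`, `coefficients` (over original inputs, all
#'   components), `basis` (columns r_k), `ay`, `rss` (residual sum of
#'   squares after 1..m components), `residual` (final output residual),
#'   `y_var` (sample variance of y, the default penalty weight).
#' @export
fit_pls <- function(X, y, max_components = NULL, residual_tol = 1e-8) {
  X <- as.matrix(X)
  n_feat <- nrow(X); n_samp <- ncol(X)
  if (n_samp != length(y)) stop("X and y disagree on sample count")
  cap <- n_samp - 1L
  if (is.null(max_components)) max_components <- min(n_feat, cap)
  if (max_components > cap)
    stop("max_components must be <= samples - 1")
  comps <- list(); basis <- NULL; ay <- numeric(); rss <- numeric()
  Xc <- X; yc <- y
  while (length(comps) < max_components) {
    dv <- direction_vector(Xc, yc)
    if (dv$degenerate) break
    # a direction orthogonal to the remaining input variation ends the fit
    # the same way a zero-covariance direction does
    df <- tryCatch(deflate(Xc, yc, dv$p), error = function(e) NULL)
    if (is.null(df)) break
    # map the direction back to the original input space
    r <- dv$p
    if (!is.null(basis)) {
      for (j in seq_len(ncol(basis)))
        r <- r - sum(comps[[j]]$ax * dv$p) * basis[, j]
    }
    basis <- cbind(basis, r)
    ay <- c(ay, df$ay)
    comps[[length(comps) + 1L]] <- list(p = dv$p, ax = df$ax, ay = df$ay,
                                        scores = df$scores)
    Xc <- df$rx; yc <- df$ry
    rss <- c(rss, sum(yc^2))
    if (sqrt(sum(yc^2)) < residual_tol) break
  }
  coef <- if (length(ay)) drop(basis %*% ay) else numeric(n_feat)
  structure(list(components = comps, n_components = length(comps),
                 coefficients = coef, basis = basis, ay = ay, rss = rss,
                 residual = yc, y_var = stats::var(y),
                 features = rownames(X)),
            class = "pls_model")
}

#' Recovered coefficients using the first m components
#' @param object a `pls_model`.
#' @param ncomp number of components to use (default all fitted).
#' @param ... unused.
#' @return coefficient vector over the original inputs.
#' @export
coef.pls_model <- function(object, ncomp = NULL, ...) {
  m <- if (is.null(ncomp)) object$n_components else ncomp
  if (m == 0L || object$n_components == 0L)
    return(numeric(length(object$coefficients)))
  m <- min(m, object$n_components)
  drop(object$basis[, seq_len(m), drop = FALSE] %*% object$ay[seq_len(m)])
}

#' @export
predict.pls_model <- function(object, X, ncomp = NULL, ...) {
  drop(crossprod(as.matrix(X), coef(object, ncomp)))
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d component(s), final residual norm %.3g\n",
              x$n_components,
              if (length(x$rss)) sqrt(x$rss[x$n_components]) else sqrt(sum(x$residual^2))))
  invisible(x)
}

#' Log-penalized choice of the PLS component count
#'
#' Picks the component count m minimising RSS(m) + lambda * ln(1 + m), the
#' log-penalized criterion that trades fit against model complexity so the
#' regression generalises beyond the handful of training samples.  Ties go
#' to the smaller m.
#'
#' @param pls a fitted `pls_model`.
#' @param lambda penalty weight; defaults to the sample variance of y.
#' @return integer in 1..n_components (0 if no component was fitted).
#' @export
penalized_component_count <- function(pls, lambda = NULL) {
  if (pls$n_components == 0L) return(0L)
  if (is.null(lambda)) lambda <- pls$y_var
  m <- seq_len(pls$n_components)
  crit <- pls$rss + lambda * log(1 + m)
  which.min(crit)
}

#' Enforce declared regulation signs on coefficients
#'
#' A coefficient whose sign contradicts the declared sign of its regulation
#' is replaced by sign * epsilon, a small value of the correct sign;
#' conforming coefficients (and exact zeros) are untouched.  Idempotent.
#'
#' @param coefficients numeric vector.
#' @param signs vector of +/-1, one per coefficient.
#' @param epsilon magnitude of the replacement value (> 0, default 1e-3).
#' @return corrected coefficient vector.
#' @export
enforce_sign_constraints <- function(coefficients, signs, epsilon = 1e-3) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (length(signs) != length(coefficients))
    stop("KeyMismatch: one sign per coefficient required")
  bad <- coefficients * signs < 0
  coefficients[bad] <- signs[bad] * epsilon
  coefficients
}
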