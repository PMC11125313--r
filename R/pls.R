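#' Column standardization with stored parameters
#'
#' Centers and scales each feature column to mean 0, SD 1 (denominator
#' n - 1). Columns with zero variance carry no calibration information and
#' cannot be scaled; they are dropped and recorded in the returned
#' parameters so the same treatment is applied at prediction time.
#'
#' @param X Numeric matrix or data.frame of features (rows = samples).
#' @return List with \code{Xs} (standardized matrix over the retained
#'   columns) and \code{params}: \code{center}, \code{scale} (named, retained
#'   columns only), \code{kept}, \code{dropped}.
#' @export
standardize_features <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) .fail("standardization needs at least 2 rows")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(!is.finite(X))) .fail("feature matrix contains missing values")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  kept <- names(scl)[scl > 0]
  if (length(kept) == 0) .fail("all feature columns are constant")
  params <- list(center = ctr[kept], scale = scl[kept], kept = kept,
                 dropped = setdiff(colnames(X), kept))
  list(Xs = apply_standardization(params, X), params = params)
}

#' @rdname standardize_features
#' @param params Parameters returned by \code{standardize_features()}.
#' @export
apply_standardization <- function(params, X) {
  X <- as.matrix(X)
  miss <- setdiff(params$kept, colnames(X))
  if (length(miss))
    .fail("new data is missing feature column(s): ",
          paste(miss, collapse = ", "))
  scale(X[, params$kept, drop = FALSE], center = params$center,
        scale = params$scale)
}

# sign convention: first element of w larger than tol in magnitude is positive
.fix_sign <- function(w, tol = 1e-12) {
  i <- which(abs(w) > tol)
  if (length(i) && w[i[1]] < 0) -w else w
}

#' NIPALS partial least squares for a single response
#'
#' The classical one-component-at-a-time algorithm on already standardized
#' data. Per component: weight \eqn{w \propto X^T y} (unit norm, sign fixed
#' so the first nonzero element is positive), score \eqn{t = X w}, X-loading
#' \eqn{p = X^T t / t^T t}, y-loading \eqn{q = y^T t / t^T t}, then X and y
#' are deflated by the rank-one fits. The regression coefficients on the
#' standardized scale are \eqn{B = W (P^T W)^{-1} q}. Successive scores are
#' mutually orthogonal.
#'
#' @param X Standardized predictor matrix.
#' @param y Standardized response vector.
#' @param n_components Number of latent components (>= 1, <= rank of X).
#' @return List with \code{weights} (W), \code{x_loadings} (P),
#'   \code{y_loadings} (q), \code{scores} (T), \code{coef} (B),
#'   \code{n_components}.
#' @export
pls_fit <- function(X, y, n_components) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) != length(y)) .fail("X and y sizes disagree")
  if (stats::sd(y) == 0) .fail("response has zero variance")
  if (n_components < 1) .fail("`n_components` must be >= 1")
  rk <- qr(X)$rank
  if (n_components > rk)
    .fail(sprintf("n_components (%d) exceeds the rank of X (%d)",
                  n_components, rk))
  n <- nrow(X); p <- ncol(X); A <- as.integer(n_components)
  W <- P <- matrix(0, p, A, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  Xa <- X; ya <- y
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) .fail("X carries no remaining covariance with y at ",
                          "component ", a)
    w <- .fix_sign(w / nw)
    t_a <- drop(Xa %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xa, t_a)) / tt
    q_a <- sum(ya * t_a) / tt
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - q_a * t_a
  }
  coef <- drop(W %*% solve(crossprod(P, W), q))
  names(coef) <- colnames(X)
  list(weights = W, x_loadings = P, y_loadings = q, scores = Tm,
       coef = coef, n_components = A)
}

#' Fit a PLS calibration model on a feature table
#'
#' Standardizes the 10 color channels and the concentration, runs the NIPALS
#' decomposition, and packages everything needed for prediction. Four latent
#' components are used by default, the dimensionality found adequate for
#' 10-channel color data; an error is raised if the request exceeds the rank
#' of the standardized features (nothing is reduced silently).
#'
#' @param table Feature table with column \code{conc_mg_per_L} and the 10
#'   channels of [feature_channels()] (extra columns are ignored).
#' @param n_components Number of latent components (default 4).
#' @param channels Feature columns to use (default the 10-channel set).
#' @return Object of class \code{pls_model} with the decomposition,
#'   standardization parameters and training fitted values.
#' @export
pls_calibration <- function(table, n_components = 4,
                            channels = feature_channels()) {
  miss <- setdiff(c("conc_mg_per_L", channels), names(table))
  if (length(miss))
    .fail("feature table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(table) < n_components + 2)
    .fail("need at least n_components + 2 samples")
  y <- table$conc_mg_per_L
  st <- standardize_features(table[, channels, drop = FALSE])
  y_mean <- mean(y); y_sd <- stats::sd(y)
  if (y_sd == 0) .fail("all calibration concentrations are identical")
  fit <- pls_fit(st$Xs, (y - y_mean) / y_sd, n_components)
  fitted <- drop(st$Xs %*% fit$coef) * y_sd + y_mean
  structure(list(fit = fit, std = st$params, y_mean = y_mean, y_sd = y_sd,
                 n_components = fit$n_components, channels = st$params$kept,
                 fitted = fitted, training_conc = y,
                 schema_version = "1.0"),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS calibration (NIPALS, %d components, %d channels, n = %d)\n",
              x$n_components, length(x$channels), length(x$training_conc)))
  cat(sprintf("  concentration range: %g to %g mg/L\n",
              min(x$training_conc), max(x$training_conc)))
  if (length(x$std$dropped))
    cat("  dropped constant channels:", paste(x$std$dropped, collapse = ", "),
        "\n")
  invisible(x)
}

#' Predict concentrations from color features
#'
#' Standardizes the new features with the model's stored parameters, applies
#' the PLS coefficients and back-transforms to mg/L. Predictions are never
#' clipped; values below zero are reported as-is and flagged in the
#' \code{"negative"} attribute.
#'
#' @param model A [pls_calibration()] model.
#' @param features Feature table or matrix containing the model's channels.
#' @return Numeric vector of predicted concentrations (mg/L) with attribute
#'   \code{negative} (logical vector).
#' @export
pls_predict <- function(model, features) {
  if (!inherits(model, "pls_model")) .fail("`model` is not a fitted pls_model")
  if (is.data.frame(features))
    features <- as.matrix(features[, intersect(names(features),
                                               model$std$kept), drop = FALSE])
  Xs <- apply_standardization(model$std, features)
  pred <- drop(Xs %*% model$fit$coef) * model$y_sd + model$y_mean
  attr(pred, "negative") <- pred < 0
  pred
}

#' Leave-one-out cross-validation of the PLS calibration
#'
#' Each sample is predicted by a model fitted on the remaining n - 1, with
#' the standardization re-estimated inside every fold so no information
#' leaks from the held-out sample.
#'
#' @inheritParams pls_calibration
#' @return List with \code{predictions} (out-of-fold, in input order),
#'   \code{measured}, \code{rmsecv}, \code{residual_sd} (SD of out-of-fold
#'   residuals, n - 1 denominator), and \code{r2} / \code{slope} /
#'   \code{intercept} of the predicted-vs-measured line.
#' @export
pls_cross_validate <- function(table, n_components = 4,
                               channels = feature_channels()) {
  n <- nrow(table)
  if (n < n_components + 2) .fail("too few samples for leave-one-out CV")
  preds <- vapply(seq_len(n), function(i) {
    m <- pls_calibration(table[-i, , drop = FALSE], n_components, channels)
    unname(pls_predict(m, table[i, , drop = FALSE]))
  }, numeric(1))
  measured <- table$conc_mg_per_L
  resid <- preds - measured
  line <- calibration_metrics(measured, preds)
  list(predictions = preds, measured = measured,
       rmsecv = sqrt(mean(resid^2)),
       residual_sd = stats::sd(resid),
       r2 = line$r2, slope = line$slope, intercept = line$intercept)
}

#' Calibration line metrics: R-squared, slope, intercept, RMSE
#'
#' Least-squares line of predicted on measured; RMSE is the root mean square
#' of the raw prediction errors (predicted - measured), not of the line's
#' residuals.
#'
#' @param measured,predicted Equal-length numeric vectors (n >= 3).
#' @return List \code{r2, slope, intercept, rmse, n}.
#' @export
calibration_metrics <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 3)
    .fail("need equal-length vectors of at least 3 values")
  if (stats::sd(measured) == 0) .fail("`measured` has zero variance")
  fit <- stats::lsfit(measured, predicted)
  r2 <- if (stats::sd(predicted) == 0) 0 else
    stats::cor(measured, predicted)^2
  list(r2 = r2,
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       rmse = sqrt(mean((predicted - measured)^2)),
       n = length(measured))
}
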