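#' Scan candidate upper concentration bounds for the working range
#'
#' The full 0–20 mg/L color response saturates at high loading, so the
#' calibration improves when restricted to the quasi-linear low range. For
#' every candidate upper bound the table is truncated, refitted and
#' cross-validated (leave-one-out), and its predicted-vs-measured R-squared,
#' slope and RMSECV recorded. The chosen range maximizes a deterministic
#' lexicographic score: slope closest to 1 first, then highest R-squared,
#' then lowest RMSECV (eyeballing metric plots is not reproducible; this
#' rule is).
#'
#' @inheritParams pls_calibration
#' @param candidate_uppers Numeric vector of at least 2 candidate upper
#'   bounds (mg/L); each must retain at least \code{n_components + 2}
#'   samples. A single candidate is allowed and returned unconditionally.
#' @return Object of class \code{range_scan}: list with \code{metrics} (one
#'   row per candidate: upper, n, r2, slope, rmsecv), \code{chosen_upper},
#'   \code{chosen_range} \code{c(low, high)} over the retained standards,
#'   and \code{n_components}.
#' @export
select_working_range <- function(table, n_components = 4, candidate_uppers,
                                 channels = feature_channels()) {
  if (length(candidate_uppers) < 1) .fail("no candidate upper bounds given")
  candidate_uppers <- sort(unique(candidate_uppers))
  rows <- lapply(candidate_uppers, function(up) {
    sub <- table[table$conc_mg_per_L <= up + 1e-9, , drop = FALSE]
    if (nrow(sub) < n_components + 2)
      .fail(sprintf("candidate upper %g retains only %d samples (need %d)",
                    up, nrow(sub), n_components + 2))
    cv <- pls_cross_validate(sub, n_components, channels)
    data.frame(upper = up, n = nrow(sub), r2 = cv$r2, slope = cv$slope,
               rmsecv = cv$rmsecv)
  })
  metrics <- do.call(rbind, rows)
  best <- order(abs(metrics$slope - 1), -metrics$r2, metrics$rmsecv)[1]
  chosen <- metrics$upper[best]
  kept <- table$conc_mg_per_L[table$conc_mg_per_L <= chosen + 1e-9]
  structure(list(metrics = metrics, chosen_upper = chosen,
                 chosen_range = c(low = min(kept), high = max(kept)),
                 n_components = n_components),
            class = "range_scan")
}

#' @export
print.range_scan <- function(x, ...) {
  cat(sprintf("Working-range scan (%d components)\n", x$n_components))
  print(x$metrics, row.names = FALSE, digits = 4)
  cat(sprintf("chosen: 0 to %g mg/L (scanned range %g to %g)\n",
              x$chosen_upper, x$chosen_range["low"], x$chosen_range["high"]))
  invisible(x)
}

#' Limit of detection and quantification from cross-validated residuals
#'
#' The usual residual-SD rule: \eqn{LOD = 3.3 s / |m|} and
#' \eqn{LOQ = 10 s / |m|}, with \eqn{s} the SD of the out-of-fold residuals
#' inside the working range and \eqn{m} the predicted-vs-measured slope. The
#' LOQ is additionally floored at the lowest non-zero calibration standard —
#' a method cannot claim quantification below the lowest level it was ever
#' shown — and the flooring is flagged. With \eqn{s = 0} both limits
#' degenerate to 0 and are flagged.
#'
#' @param residual_sd SD of cross-validated residuals (mg/L), or a result of
#'   [pls_cross_validate()] from which \code{residual_sd} and \code{slope}
#'   are taken.
#' @param slope Calibration slope (ignored when a CV result is supplied).
#' @param lowest_standard Lowest non-zero calibration concentration (mg/L),
#'   or NULL to disable the floor.
#' @return List \code{lod, loq, loq_unfloored, floored, degenerate}.
#' @export
lod_loq <- function(residual_sd, slope = NULL, lowest_standard = NULL) {
  if (is.list(residual_sd)) {
    slope <- residual_sd$slope
    residual_sd <- residual_sd$residual_sd
  }
  .check_number(residual_sd, "residual_sd", min = 0)
  if (is.null(slope) || !is.finite(slope) || slope == 0)
    .fail("`slope` must be a nonzero number")
  if (residual_sd == 0)
    return(list(lod = 0, loq = 0, loq_unfloored = 0, floored = FALSE,
                degenerate = TRUE))
  lod <- 3.3 * residual_sd / abs(slope)
  loq_raw <- 10 * residual_sd / abs(slope)
  floored <- !is.null(lowest_standard) && loq_raw < lowest_standard
  list(lod = lod, loq = if (floored) lowest_standard else loq_raw,
       loq_unfloored = loq_raw, floored = floored, degenerate = FALSE)
}

#' Biplot coordinates and channel-concentration correlations
#'
#' Scores and variable loadings of the first two latent components of the
#' standardized feature matrix (taken from the PLS decomposition against
#' concentration, the same axes the calibration uses), plus the signed
#' Pearson correlation of each raw channel with concentration. For a plate
#' that yellows with loading, concentration correlates positively with H, S
#' and Y and negatively with V, R and G.
#'
#' @inheritParams pls_calibration
#' @return List with \code{scores} (n x 2), \code{loadings} (channels x 2),
#'   \code{correlations} (named, signed), \code{y_loadings}.
#' @export
pca_biplot <- function(table, channels = feature_channels()) {
  if (nrow(table) < 3) .fail("need at least 3 samples")
  y <- table$conc_mg_per_L
  st <- standardize_features(table[, channels, drop = FALSE])
  fit <- pls_fit(st$Xs, (y - mean(y)) / stats::sd(y), 2)
  cors <- vapply(st$params$kept,
                 function(ch) stats::cor(table[[ch]], y), numeric(1))
  list(scores = fit$scores, loadings = fit$x_loadings,
       correlations = cors, y_loadings = fit$y_loadings)
}

#' Repeatability and accuracy summary
#'
#' For n replicate determinations at a nominal level: mean, sample SD
#' (n - 1), relative standard deviation \eqn{RSD = 100 \cdot SD / mean}, and
#' accuracy \eqn{= 100 \cdot mean / nominal}.
#'
#' @param values Numeric vector of replicate determinations (n >= 2).
#' @param nominal The true/nominal level (> 0).
#' @return List \code{n, mean, sd, rsd_percent, accuracy_percent, nominal}.
#' @examples
#' repeatability_summary(c(4.9, 5.1, 5.0), nominal = 5)
#' @export
repeatability_summary <- function(values, nominal) {
  if (length(values) < 2) .fail("need at least 2 replicate values")
  .check_number(nominal, "nominal", min = 0, allow_zero = FALSE)
  m <- mean(values); s <- stats::sd(values)
  list(n = length(values), mean = m, sd = s,
       rsd_percent = 100 * s / m,
       accuracy_percent = 100 * m / nominal,
       nominal = nominal)
}

#' Standard-addition estimate of an unknown concentration
#'
#' Fits the least-squares line response = a + b * added over at least three
#' addition levels including zero, and extrapolates to zero response: the
#' unknown is the magnitude of the x-intercept, \eqn{a / b}.
#'
#' @param added_concs Added analyte levels (same units as the answer); must
#'   include 0.
#' @param responses Instrument responses, linear in the added amount.
#' @return The estimated concentration (single number).
#' @export
standard_addition_estimate <- function(added_concs, responses) {
  if (length(added_concs) != length(responses) || length(added_concs) < 3)
    .fail("need at least 3 matched addition levels")
  if (!any(added_concs == 0))
    .fail("the addition design must include a zero-addition level")
  fit <- stats::lm(responses ~ added_concs)
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  if (!is.finite(b) || b <= 0)
    .fail("standard-addition slope must be positive (got ", signif(b, 4), ")")
  abs(a / b)
}
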