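#' Removal percentage of a batch adsorption test
#'
#' Fraction of the analyte removed from solution between the initial
#' concentration Co and the equilibrium concentration Ce. Two conventions
#' are offered:
#' \describe{
#'   \item{standard (default)}{\eqn{100 (C_o - C_e)/C_o} — bounded by 100
#'     whenever \eqn{C_e \le C_o}; this is what batch-adsorption removal
#'     percentages conventionally mean.}
#'   \item{as_printed}{\eqn{100 (C_o - C_e)/C_e} — the equilibrium
#'     concentration in the denominator, provided for fidelity with sources
#'     that print the formula this way; it exceeds 100\% for removals above
#'     one half.}
#' }
#' Reports built on this function always name the convention used.
#'
#' @param Co,Ce Initial and equilibrium concentrations (mg/L); vectorized.
#' @param convention \code{"standard"} or \code{"as_printed"}.
#' @return Removal percentage(s), with attribute \code{convention}.
#' @examples
#' removal_percent(10, 5)                       # 50
#' removal_percent(10, 5, "as_printed")         # 100
#' @export
removal_percent <- function(Co, Ce, convention = c("standard", "as_printed")) {
  convention <- match.arg(convention)
  if (length(Co) != length(Ce)) .fail("Co and Ce must have equal length")
  denom <- if (convention == "standard") Co else Ce
  if (any(denom <= 0))
    .fail("zero/negative denominator (", convention, " convention)")
  out <- 100 * (Co - Ce) / denom
  attr(out, "convention") <- convention
  out
}

#' Areal adsorption capacity Q
#'
#' Analyte mass captured per unit plate area:
#' \eqn{Q = (C_o - C_e) V / A} (mg cm\eqn{^{-2}}). For the canonical
#' 1 cm x 1 cm plate (A = 1) this reduces to \eqn{(C_o - C_e) V}.
#'
#' @param Co,Ce Initial and equilibrium concentrations (mg/L); vectorized.
#' @param V_L Solution volume in liters (> 0).
#' @param A_cm2 Plate area in cm^2 (> 0, default 1).
#' @return Q in mg cm^-2. A warning (not an error) is raised when Ce > Co,
#'   which would mean the plate released analyte.
#' @examples
#' adsorption_capacity(10, 4.3, V_L = 0.010)    # 0.057 mg cm^-2
#' @export
adsorption_capacity <- function(Co, Ce, V_L, A_cm2 = 1) {
  .check_number(V_L, "V_L", min = 0, allow_zero = FALSE)
  .check_number(A_cm2, "A_cm2", min = 0, allow_zero = FALSE)
  if (any(Co < 0) || any(Ce < 0)) .fail("concentrations must be non-negative")
  if (any(Ce > Co))
    warning("Ce > Co for some record(s): negative capacity", call. = FALSE)
  (Co - Ce) * V_L / A_cm2
}

#' Spectrophotometric calibration line (absorbance at 427 nm)
#'
#' @param slope Absorbance per (mg/L); must be positive.
#' @param intercept Blank absorbance (default 0).
#' @param range Absorbance validity range \code{c(lo, hi)}; values outside
#'   are still converted but flagged.
#' @return Object of class \code{beer_lambert_calibration}.
#' @export
beer_lambert_calibration <- function(slope, intercept = 0,
                                     range = c(-Inf, Inf)) {
  .check_number(slope, "slope", min = 0, allow_zero = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 range = sort(as.numeric(range))),
            class = "beer_lambert_calibration")
}

#' Convert absorbances to concentrations through a calibration line
#'
#' @param absorbances Numeric vector of absorbances.
#' @param cal A [beer_lambert_calibration()].
#' @return Concentrations (mg/L) with attribute \code{out_of_range}
#'   (logical): out-of-range absorbances are flagged but still converted.
#' @export
absorbance_to_concentration <- function(absorbances, cal) {
  stopifnot(inherits(cal, "beer_lambert_calibration"))
  conc <- (absorbances - cal$intercept) / cal$slope
  attr(conc, "out_of_range") <-
    absorbances < cal$range[1] | absorbances > cal$range[2]
  conc
}

# linear least squares returning slope/intercept/R^2 on the given axes
.linfit <- function(x, y) {
  fit <- stats::lsfit(x, y)
  r2 <- stats::cor(x, y)^2
  list(intercept = unname(fit$coefficients[1]),
       slope = unname(fit$coefficients[2]), r2 = r2)
}

#' Fit adsorption kinetic models by their linearized forms
#'
#' Exactly the classical linearizations:
#' \describe{
#'   \item{PFO}{\eqn{\log_{10}(Q_e - Q_t) = \log_{10} Q_e - k_1 t / 2.303};
#'     regress \eqn{\log_{10}(Q_e - Q_t)} on t with \eqn{Q_e} fixed at
#'     \code{Qe_exp}; \eqn{k_1 = -2.303 \cdot} slope,
#'     \eqn{Q_{cal} = 10^{intercept}}.}
#'   \item{PSO}{\eqn{t/Q_t = 1/(k_2 Q_e^2) + t/Q_e}; regress \eqn{t/Q_t} on
#'     t; \eqn{Q_e = 1/}slope, \eqn{k_2 = } slope\eqn{^2}/intercept
#'     (cm^2 mg^-1 min^-1).}
#'   \item{IPD}{\eqn{Q_t = k_{id} \sqrt{t} + C}; regress \eqn{Q_t} on
#'     \eqn{\sqrt{t}} over the diffusion-controlled window (default
#'     10–60 min, the stage before surface phenomena take over).}
#' }
#' R-squared is computed on the linearized axes (that is what tabulated
#' kinetic R-squared values describe); an optional nonlinear least-squares
#' refit of the closed form is reported alongside, with its own
#' nonlinear-space R-squared, as a secondary diagnostic.
#'
#' For the PFO model \code{Qe_exp} defaults to the last (plateau)
#' observation; points with \eqn{Q_e - Q_t \le 0} (at least the plateau
#' point itself) cannot enter the log and are dropped with a message. An
#' error is raised if fewer than 3 usable points remain.
#'
#' @param data \code{data.frame(t_min, Qt_mg_per_cm2)} (or any two-column
#'   table in that order).
#' @param model \code{"PFO"}, \code{"PSO"} or \code{"IPD"}.
#' @param window Optional \code{c(t_lo, t_hi)} restricting the fit (minutes);
#'   default \code{c(10, 60)} for IPD, the full data otherwise.
#' @param Qe_exp Experimental equilibrium capacity for the PFO log argument;
#'   default: last observation in the window.
#' @param nonlinear Also refit the closed form with [minpack.lm::nlsLM()]?
#' @return Object of class \code{kinetic_fit}: model name, parameters
#'   (\code{k1, Q_cal} / \code{k2, Qe} / \code{kid, C}), \code{Q_exp},
#'   \code{r2}, \code{window}, \code{n}, and \code{nonlinear} (parameters +
#'   r2 in the original axes) when requested.
#' @export
fit_kinetics <- function(data, model = c("PFO", "PSO", "IPD"), window = NULL,
                         Qe_exp = NULL, nonlinear = TRUE) {
  model <- match.arg(model)
  data <- stats::setNames(as.data.frame(data)[, 1:2],
                          c("t_min", "Qt_mg_per_cm2"))
  if (is.null(window)) window <- if (model == "IPD") c(10, 60) else
    range(data$t_min)
  keep <- data$t_min >= window[1] & data$t_min <= window[2]
  d <- data[keep, , drop = FALSE]
  if (nrow(d) < 3) .fail("fewer than 3 points in the fit window")
  t <- d$t_min; Qt <- d$Qt_mg_per_cm2
  if (is.null(Qe_exp)) Qe_exp <- Qt[length(Qt)]

  res <- switch(model,
    PFO = {
      usable <- (Qe_exp - Qt) > 0
      if (!all(usable))
        message(sum(!usable), " point(s) with Qe - Qt <= 0 dropped from the ",
                "PFO log-linearization")
      if (sum(usable) < 3)
        .fail("PFO linearization: fewer than 3 points with Qe - Qt > 0 ",
              "(is Qe_exp too small?)")
      lf <- .linfit(t[usable], log10(Qe_exp - Qt[usable]))
      list(parameters = c(k1 = -2.303 * lf$slope,
                          Q_cal = 10^lf$intercept), r2 = lf$r2)
    },
    PSO = {
      if (any(Qt <= 0)) .fail("PSO linearization needs strictly positive Qt")
      lf <- .linfit(t, t / Qt)
      if (lf$intercept == 0) .fail("PSO linearization has zero intercept")
      list(parameters = c(k2 = lf$slope^2 / lf$intercept,
                          Qe = 1 / lf$slope, Q_cal = 1 / lf$slope),
           r2 = lf$r2)
    },
    IPD = {
      lf <- .linfit(sqrt(t), Qt)
      list(parameters = c(kid = lf$slope, C = lf$intercept), r2 = lf$r2)
    })

  nl <- NULL
  if (nonlinear) nl <- tryCatch({
    start <- switch(model,
      PFO = list(Qe = max(Qe_exp, max(Qt)), k1 = max(res$parameters["k1"],
                                                     1e-4)),
      PSO = list(Qe = res$parameters[["Qe"]],
                 k2 = max(res$parameters[["k2"]], 1e-6)),
      IPD = list(kid = res$parameters[["kid"]], C = res$parameters[["C"]]))
    form <- switch(model,
      PFO = Qt ~ Qe * (1 - exp(-k1 * t)),
      PSO = Qt ~ k2 * Qe^2 * t / (1 + k2 * Qe * t),
      IPD = Qt ~ kid * sqrt(t) + C)
    fit <- minpack.lm::nlsLM(form, data = data.frame(t = t, Qt = Qt),
                             start = start)
    pred <- stats::predict(fit)
    list(parameters = stats::coef(fit),
         r2 = 1 - sum((Qt - pred)^2) / sum((Qt - mean(Qt))^2))
  }, error = function(e) NULL)

  structure(list(model = model, parameters = res$parameters,
                 Q_exp = Qe_exp, r2 = res$r2, window = window,
                 n = length(t), nonlinear = nl),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%s kinetic fit (linearized, %d points, window %g-%g min)\n",
              x$model, x$n, x$window[1], x$window[2]))
  cat("  ", paste(sprintf("%s = %.4g", names(x$parameters), x$parameters),
                  collapse = ", "), "\n")
  cat(sprintf("  R^2 (linear axes) = %.4f; Q_exp = %.4g\n", x$r2, x$Q_exp))
  if (!is.null(x$nonlinear))
    cat("  nonlinear refit: ",
        paste(sprintf("%s = %.4g", names(x$nonlinear$parameters),
                      x$nonlinear$parameters), collapse = ", "),
        sprintf(" (R^2 = %.4f)\n", x$nonlinear$r2))
  invisible(x)
}

#' Fit equilibrium isotherm models by their linearized forms
#'
#' \describe{
#'   \item{Langmuir}{\eqn{C_e/Q_e = C_e/Q_m + 1/(b Q_m)}; regress
#'     \eqn{C_e/Q_e} on \eqn{C_e}; \eqn{Q_m = 1/}slope, \eqn{b = }
#'     slope/intercept.}
#'   \item{Freundlich}{\eqn{\log_{10} Q_e = (1/n)\log_{10} C_e +
#'     \log_{10} K_f}; regress \eqn{\log_{10} Q_e} on \eqn{\log_{10} C_e};
#'     \eqn{n = 1/}slope, \eqn{K_f = 10^{intercept}}. A heterogeneity
#'     exponent \eqn{1/n} in (0, 1) is flagged as a favorable isotherm.}
#' }
#' R-squared is reported on the linearized axes, with an optional nonlinear
#' refit alongside.
#'
#' @param data \code{data.frame(Ce_mg_per_L, Qe_mg_per_cm2)}.
#' @param model \code{"Langmuir"} or \code{"Freundlich"}.
#' @param nonlinear Also refit the closed form?
#' @return Object of class \code{isotherm_fit}: model name, parameters
#'   (\code{Qm, b} / \code{Kf, n}), \code{r2}, \code{favorable} (Freundlich
#'   only), \code{nonlinear}.
#' @export
fit_isotherm <- function(data, model = c("Langmuir", "Freundlich"),
                         nonlinear = TRUE) {
  model <- match.arg(model)
  data <- stats::setNames(as.data.frame(data)[, 1:2],
                          c("Ce_mg_per_L", "Qe_mg_per_cm2"))
  if (nrow(data) < 3) .fail("need at least 3 isotherm points")
  Ce <- data$Ce_mg_per_L; Qe <- data$Qe_mg_per_cm2
  if (any(Ce <= 0) || any(Qe <= 0))
    .fail(model, " linearization needs strictly positive Ce and Qe")
  res <- switch(model,
    Langmuir = {
      lf <- .linfit(Ce, Ce / Qe)
      if (lf$intercept == 0) .fail("Langmuir linearization has zero intercept")
      list(parameters = c(Qm = 1 / lf$slope, b = lf$slope / lf$intercept),
           r2 = lf$r2, favorable = NA)
    },
    Freundlich = {
      lf <- .linfit(log10(Ce), log10(Qe))
      list(parameters = c(Kf = 10^lf$intercept, n = 1 / lf$slope),
           r2 = lf$r2, favorable = lf$slope > 0 && lf$slope < 1)
    })
  nl <- NULL
  if (nonlinear) nl <- tryCatch({
    start <- as.list(res$parameters)
    form <- switch(model,
      Langmuir = Qe ~ Qm * b * Ce / (1 + b * Ce),
      Freundlich = Qe ~ Kf * Ce^(1 / n))
    fit <- minpack.lm::nlsLM(form, data = data.frame(Ce = Ce, Qe = Qe),
                             start = start)
    pred <- stats::predict(fit)
    list(parameters = stats::coef(fit),
         r2 = 1 - sum((Qe - pred)^2) / sum((Qe - mean(Qe))^2))
  }, error = function(e) NULL)
  structure(list(model = model, parameters = res$parameters, r2 = res$r2,
                 favorable = res$favorable, n = nrow(data), nonlinear = nl),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("%s isotherm fit (linearized, %d points)\n", x$model, x$n))
  cat("  ", paste(sprintf("%s = %.4g", names(x$parameters), x$parameters),
                  collapse = ", "), "\n")
  cat(sprintf("  R^2 (linear axes) = %.4f\n", x$r2))
  if (isTRUE(x$favorable)) cat("  1/n in (0, 1): favorable isotherm\n")
  invisible(x)
}

#' Imprinting factor of a molecularly imprinted polymer
#'
#' Ratio of the removal achieved by the imprinted polymer to that of the
#' non-imprinted control under identical conditions:
#' \eqn{\alpha = removal_{MIP} / removal_{NIP}}. Values above 1 indicate
#' that the template-shaped cavities contribute to uptake.
#'
#' @param removal_mip,removal_nip Removal percentages (vectorized).
#' @return \eqn{\alpha} (dimensionless).
#' @export
imprinting_factor <- function(removal_mip, removal_nip) {
  if (any(removal_nip <= 0)) .fail("NIP removal must be positive")
  removal_mip / removal_nip
}

#' Selectivity factor relative to the template dye
#'
#' \eqn{\beta = \alpha_{template} / \alpha_{interferent}}: how much more the
#' imprinting favors the template than a competing dye. By construction
#' \eqn{\beta = 1} for the template itself.
#'
#' @param alpha_template Imprinting factor of the template.
#' @param alpha_interferent Imprinting factor(s) of the interferent(s).
#' @return \eqn{\beta} (dimensionless, vectorized over interferents).
#' @export
selectivity_factor <- function(alpha_template, alpha_interferent) {
  if (any(alpha_interferent <= 0)) .fail("interferent alpha must be positive")
  alpha_template / alpha_interferent
}

#' Full selectivity analysis from batch records
#'
#' Computes per-dye removals for MIP and NIP, imprinting factors and
#' selectivity factors relative to a template dye.
#'
#' @param records \code{data.frame(label, sorbent, Co, Ce, ...)} with
#'   sorbent values \code{"MIP"} and \code{"NIP"} for every dye.
#' @param template Label of the template dye.
#' @param convention Removal convention, see [removal_percent()].
#' @return \code{data.frame(label, removal_mip, removal_nip, alpha, beta)};
#'   beta is 1 for the template row.
#' @export
selectivity_analysis <- function(records, template,
                                 convention = c("standard", "as_printed")) {
  convention <- match.arg(convention)
  need <- c("label", "sorbent", "Co", "Ce")
  miss <- setdiff(need, names(records))
  if (length(miss)) .fail("records missing column(s): ",
                          paste(miss, collapse = ", "))
  dyes <- unique(records$label)
  if (!template %in% dyes) .fail("template dye '", template,
                                 "' not found in records")
  one <- function(dye, sorb) {
    r <- records[records$label == dye & records$sorbent == sorb, ]
    if (nrow(r) == 0) .fail("no ", sorb, " record for dye '", dye, "'")
    mean(removal_percent(r$Co, r$Ce, convention))
  }
  rm_mip <- vapply(dyes, one, numeric(1), sorb = "MIP")
  rm_nip <- vapply(dyes, one, numeric(1), sorb = "NIP")
  alpha <- imprinting_factor(rm_mip, rm_nip)
  beta <- selectivity_factor(alpha[[template]], alpha)
  data.frame(label = dyes, removal_mip = rm_mip, removal_nip = rm_nip,
             alpha = alpha, beta = beta, row.names = NULL)
}

#' Reusability profile across regeneration cycles
#'
#' Removal percentage per cycle, and the first cycle whose removal drops
#' below \eqn{(1 - \delta)} times the first-cycle removal (default
#' \eqn{\delta = 0.10}, i.e. a 10\% relative loss counts as degradation).
#'
#' @param records \code{data.frame} ordered by cycle with columns \code{Co},
#'   \code{Ce} (and optionally \code{cycle}; defaults to row order).
#' @param delta Relative drop tolerance in [0, 1).
#' @param convention Removal convention, see [removal_percent()].
#' @return List with \code{removals} (per cycle), \code{drop_cycle} (integer
#'   or NA when no cycle drops), \code{delta}.
#' @export
reusability_profile <- function(records, delta = 0.10,
                                convention = c("standard", "as_printed")) {
  convention <- match.arg(convention)
  if (NROW(records) < 2) .fail("need at least 2 cycles")
  if (delta < 0 || delta >= 1) .fail("`delta` must lie in [0, 1)")
  cyc <- if ("cycle" %in% names(records)) records$cycle
         else seq_len(nrow(records))
  rem <- as.numeric(removal_percent(records$Co, records$Ce, convention))
  thr <- (1 - delta) * rem[1]
  below <- which(rem < thr)
  list(removals = stats::setNames(rem, cyc),
       drop_cycle = if (length(below)) cyc[below[1]] else NA_integer_,
       delta = delta)
}
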