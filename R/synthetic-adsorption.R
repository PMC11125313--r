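#' Design of a simulated batch-adsorption experiment
#'
#' Bundles the experimental design (concentrations, volume, plate area,
#' sampling times) with the generating model and its parameters. The model
#' names mirror the fitters in [fit_kinetics()] and [fit_isotherm()]:
#' \describe{
#'   \item{PFO}{pseudo-first order, \eqn{Q_t = Q_e (1 - e^{-k_1 t})};
#'     params \code{Qe}, \code{k1}.}
#'   \item{PSO}{pseudo-second order, \eqn{Q_t = k_2 Q_e^2 t / (1 + k_2 Q_e t)};
#'     params \code{Qe}, \code{k2}.}
#'   \item{IPD}{intraparticle diffusion, \eqn{Q_t = k_{id} \sqrt{t} + C};
#'     params \code{kid}, \code{C}.}
#'   \item{Langmuir}{\eqn{Q_e = Q_m b C_e / (1 + b C_e)}; params \code{Qm},
#'     \code{b}.}
#'   \item{Freundlich}{\eqn{Q_e = K_f C_e^{1/n}}; params \code{Kf}, \code{n}.}
#' }
#'
#' @param Co_list Initial (kinetics) or equilibrium (isotherm) concentrations,
#'   mg/L, all non-negative.
#' @param V Solution volume, L.
#' @param A Plate area, cm^2.
#' @param times Sampling times in minutes, strictly increasing, non-negative.
#' @param model_name One of \code{"PFO"}, \code{"PSO"}, \code{"IPD"},
#'   \code{"Langmuir"}, \code{"Freundlich"}.
#' @param model_params Named list/vector of the parameters listed above.
#' @param noise_sd Relative (multiplicative) Gaussian noise SD on Q.
#' @param seed Integer RNG seed (mandatory).
#' @return Object of class \code{batch_design}.
#' @export
batch_design <- function(Co_list = numeric(), V = 0.01, A = 1,
                         times = numeric(), model_name, model_params,
                         noise_sd = 0, seed) {
  if (missing(seed)) .fail("`seed` is mandatory for batch_design()")
  allowed <- c("PFO", "PSO", "IPD", "Langmuir", "Freundlich")
  if (!model_name %in% allowed)
    .fail("`model_name` must be one of: ", paste(allowed, collapse = ", "))
  if (any(Co_list < 0) || V < 0 || A < 0 || any(times < 0))
    .fail("concentrations, V, A and times must all be non-negative")
  if (length(times) > 1 && any(diff(times) <= 0))
    .fail("`times` must be strictly increasing")
  .check_number(noise_sd, "noise_sd", min = 0)
  params <- as.list(model_params)
  required <- switch(model_name,
    PFO = c("Qe", "k1"), PSO = c("Qe", "k2"), IPD = c("kid", "C"),
    Langmuir = c("Qm", "b"), Freundlich = c("Kf", "n"))
  missing_p <- setdiff(required, names(params))
  if (length(missing_p))
    .fail(model_name, " requires parameter(s): ",
          paste(missing_p, collapse = ", "))
  neg <- names(params)[vapply(params, function(p) is.numeric(p) && p < 0,
                              logical(1))]
  neg <- setdiff(neg, "C")  # the IPD boundary-layer intercept may be any sign
  if (length(neg))
    .fail("negative model parameter(s): ", paste(neg, collapse = ", "))
  structure(list(Co_list = as.numeric(Co_list), V = V, A = A,
                 times = as.numeric(times), model_name = model_name,
                 model_params = params, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "batch_design")
}

# closed-form uptake curves; shared by the generator and the nonlinear refits
.kinetic_curve <- function(model_name, params, t) {
  p <- params
  switch(model_name,
    PFO = p$Qe * (1 - exp(-p$k1 * t)),
    PSO = p$k2 * p$Qe^2 * t / (1 + p$k2 * p$Qe * t),
    IPD = p$kid * sqrt(t) + p$C,
    .fail("not a kinetic model: ", model_name))
}

.isotherm_curve <- function(model_name, params, Ce) {
  p <- params
  switch(model_name,
    Langmuir = p$Qm * p$b * Ce / (1 + p$b * Ce),
    Freundlich = p$Kf * Ce^(1 / p$n),
    .fail("not an isotherm model: ", model_name))
}

#' Simulate an adsorption kinetics experiment
#'
#' Evaluates the design's closed-form uptake curve at the design times and
#' applies multiplicative Gaussian noise if requested.
#'
#' @param design A [batch_design()] with \code{model_name} PFO, PSO or IPD.
#' @return \code{data.frame(t_min, Qt_mg_per_cm2)}.
#' @examples
#' d <- batch_design(times = seq(10, 120, 10), model_name = "PFO",
#'                   model_params = list(Qe = 0.059, k1 = 0.023), seed = 1)
#' generate_kinetics(d)
#' @export
generate_kinetics <- function(design) {
  stopifnot(inherits(design, "batch_design"))
  if (!design$model_name %in% c("PFO", "PSO", "IPD"))
    .fail("generate_kinetics() needs model_name PFO, PSO or IPD")
  if (length(design$times) == 0) .fail("design has no sampling times")
  Qt <- .kinetic_curve(design$model_name, design$model_params, design$times)
  if (design$noise_sd > 0)
    Qt <- withr::with_seed(design$seed,
      Qt * (1 + stats::rnorm(length(Qt), 0, design$noise_sd)))
  data.frame(t_min = design$times, Qt_mg_per_cm2 = Qt)
}

#' Simulate an adsorption isotherm experiment
#'
#' Evaluates the design's equilibrium curve at the design concentrations
#' (taken as equilibrium concentrations Ce).
#'
#' @param design A [batch_design()] with \code{model_name} Langmuir or
#'   Freundlich.
#' @return \code{data.frame(Ce_mg_per_L, Qe_mg_per_cm2)}.
#' @export
generate_isotherm <- function(design) {
  stopifnot(inherits(design, "batch_design"))
  if (!design$model_name %in% c("Langmuir", "Freundlich"))
    .fail("generate_isotherm() needs model_name Langmuir or Freundlich")
  if (length(design$Co_list) == 0) .fail("design has no concentrations")
  Ce <- design$Co_list
  Qe <- .isotherm_curve(design$model_name, design$model_params, Ce)
  if (design$noise_sd > 0)
    Qe <- withr::with_seed(design$seed,
      Qe * (1 + stats::rnorm(length(Qe), 0, design$noise_sd)))
  data.frame(Ce_mg_per_L = Ce, Qe_mg_per_cm2 = Qe)
}

#' Simulate a MIP/NIP selectivity experiment
#'
#' Emits batch records whose equilibrium concentrations are consistent with
#' requested removal percentages for an imprinted (MIP) and a non-imprinted
#' (NIP) plate exposed to a panel of dyes: \eqn{C_e = C_o (1 - removal/100)},
#' plus optional multiplicative noise on Ce.
#'
#' @param removal_mip,removal_nip Named vectors of removal percentages in
#'   [0, 100]; names are dye labels and must match between the two.
#' @param noise_sd Relative Gaussian noise SD on Ce.
#' @param seed Integer RNG seed.
#' @param Co Common initial concentration, mg/L (default 100, the
#'   concentration at which imprinting dominates).
#' @param V Volume (L), carried into the records.
#' @param A Plate area (cm^2), carried into the records.
#' @return \code{data.frame(label, sorbent, Co, Ce, V_L, A_cm2)} with one
#'   MIP and one NIP row per dye.
#' @export
generate_selectivity_experiment <- function(removal_mip, removal_nip,
                                            noise_sd = 0, seed,
                                            Co = 100, V = 0.01, A = 1) {
  if (missing(seed)) .fail("`seed` is mandatory")
  if (is.null(names(removal_mip)) || is.null(names(removal_nip)) ||
      !setequal(names(removal_mip), names(removal_nip)))
    .fail("`removal_mip` and `removal_nip` must be named and share dye names")
  removal_nip <- removal_nip[names(removal_mip)]
  for (v in list(removal_mip, removal_nip))
    if (any(v < 0 | v > 100)) .fail("removal percentages must lie in [0, 100]")
  dyes <- names(removal_mip)
  rec <- data.frame(
    label = rep(dyes, 2L),
    sorbent = rep(c("MIP", "NIP"), each = length(dyes)),
    Co = Co,
    Ce = Co * (1 - c(removal_mip, removal_nip) / 100),
    V_L = V, A_cm2 = A,
    stringsAsFactors = FALSE)
  if (noise_sd > 0)
    rec$Ce <- withr::with_seed(as.integer(seed),
      rec$Ce * (1 + stats::rnorm(nrow(rec), 0, noise_sd)))
  rec
}
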