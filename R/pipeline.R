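SCHEMA_VERSION <- "1.0"

.default_config <- function() {
  list(
    seed = NULL,
    out_dir = "mipsense-run",
    concs = 0:20,                 # calibration standards, mg/L
    replicates = 2L,
    volume_L = 0.003,
    area_cm2 = 1,
    width_px = 64L, height_px = 64L,
    n_components = 4L,
    candidate_uppers = c(5, 6, 7, 8, 10, 12, 15, 20),
    delta = 0.10,
    removal_convention = "standard",
    ipd_window = c(10, 60),
    schema_version = SCHEMA_VERSION)
}

#' Assemble a run configuration
#'
#' Starts from the package defaults, overlays an optional YAML config file,
#' then overlays explicit arguments. Unknown keys are rejected rather than
#' silently ignored, and a seed is mandatory — no run may be
#' nondeterministic by accident.
#'
#' @param config_file Optional YAML file of overrides.
#' @param ... Named overrides applied last (highest precedence).
#' @return Named list of class \code{run_config}.
#' @export
run_config <- function(config_file = NULL, ...) {
  cfg <- .default_config()
  overlay <- function(cfg, new, src) {
    unknown <- setdiff(names(new), names(cfg))
    if (length(unknown))
      .fail("unknown configuration key(s) from ", src, ": ",
            paste(unknown, collapse = ", "))
    utils::modifyList(cfg, new)
  }
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) .fail("config file not found: ",
                                         config_file)
    cfg <- overlay(cfg, yaml::read_yaml(config_file), config_file)
  }
  dots <- list(...)
  if (length(dots)) cfg <- overlay(cfg, dots, "arguments")
  if (is.null(cfg$seed))
    .fail("a `seed` is required (set it in the config or as an argument)")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

.log_msg <- function(...) message("[mipsense] ", ...)

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate the full synthetic fixture set
#'
#' Writes calibration plate PNGs with their ROI manifest, plus kinetics,
#' isotherm and selectivity CSVs, all derived deterministically from the
#' config seed. A JSON run manifest records every file and the parameters
#' used.
#'
#' @param config A [run_config()].
#' @return Invisibly, the run manifest (list).
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(file.path(out, "plates"), recursive = TRUE, showWarnings = FALSE)
  resp <- plate_response_model(seed = config$seed)
  series <- generate_calibration_series(
    config$concs, resp, config$replicates, config$volume_L, config$area_cm2,
    config$width_px, config$height_px)
  rois <- default_rois(config$width_px, config$height_px)
  man <- do.call(rbind, lapply(seq_along(series), function(i) {
    s <- series[[i]]
    p <- file.path("plates", sprintf("plate_%03d.png", i))
    write_plate_png(s$image, file.path(out, p))
    data.frame(image_path = p, conc_mg_per_L = s$conc_mg_per_L,
               roi_row = vapply(rois, `[[`, integer(1), "row"),
               roi_col = vapply(rois, `[[`, integer(1), "col"))
  }))
  utils::write.csv(man, file.path(out, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)

  # sampled through the slow approach to equilibrium and beyond, so the
  # plateau default of the PFO linearization is well conditioned
  kin <- generate_kinetics(batch_design(
    times = c(seq(10, 120, by = 10), 180, 240), model_name = "PFO",
    model_params = list(Qe = 0.059, k1 = 0.023), noise_sd = 0.002,
    seed = .child_seed(config$seed, 1001)))
  utils::write.csv(kin, file.path(out, "kinetics.csv"), row.names = FALSE,
                   quote = FALSE)
  iso <- generate_isotherm(batch_design(
    Co_list = seq(10, 100, by = 10), model_name = "Freundlich",
    model_params = list(Kf = 0.0375, n = 3.66), noise_sd = 0.01,
    seed = .child_seed(config$seed, 1002)))
  utils::write.csv(iso, file.path(out, "isotherm.csv"), row.names = FALSE,
                   quote = FALSE)
  sel <- generate_selectivity_experiment(
    removal_mip = c(tartrazine = 54, sunset_yellow = 30, basic_red = 26.4,
                    methyl_green = 24, yellow_he3g = 12),
    removal_nip = c(tartrazine = 20, sunset_yellow = 25, basic_red = 30,
                    methyl_green = 30, yellow_he3g = 30),
    noise_sd = 0, seed = .child_seed(config$seed, 1003))
  utils::write.csv(sel, file.path(out, "selectivity.csv"), row.names = FALSE,
                   quote = FALSE)

  manifest <- list(schema_version = SCHEMA_VERSION, seed = config$seed,
                   n_images = length(series),
                   files = c("manifest.csv", "kinetics.csv", "isotherm.csv",
                             "selectivity.csv",
                             file.path("plates", sprintf("plate_%03d.png",
                                                         seq_along(series)))),
                   parameters = list(concs = config$concs,
                                     replicates = config$replicates,
                                     volume_L = config$volume_L,
                                     area_cm2 = config$area_cm2))
  .write_json(manifest, file.path(out, "run_manifest.json"))
  .log_msg("simulated ", length(series), " plates + adsorption CSVs in ", out)
  invisible(manifest)
}

#' Serialize / restore a PLS model as JSON
#'
#' The JSON carries the standardization parameters, NIPALS weights and
#' loadings, coefficients and metadata plus a schema version; readers reject
#' files written by a newer major version.
#'
#' @param model A [pls_calibration()] model.
#' @param path JSON file path.
#' @return \code{write_pls_model()} the path, invisibly;
#'   \code{read_pls_model()} the restored \code{pls_model}.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  payload <- list(
    schema_version = model$schema_version,
    n_components = model$n_components,
    channels = model$channels,
    std = list(center = as.list(model$std$center),
               scale = as.list(model$std$scale),
               kept = model$std$kept, dropped = model$std$dropped),
    y_mean = model$y_mean, y_sd = model$y_sd,
    coef = as.list(model$fit$coef),
    weights = apply(model$fit$weights, 2, identity, simplify = FALSE),
    x_loadings = apply(model$fit$x_loadings, 2, identity, simplify = FALSE),
    y_loadings = model$fit$y_loadings,
    training_conc = model$training_conc,
    fitted = model$fitted)
  .write_json(payload, path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  if (!file.exists(path)) .fail("model file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  major <- function(v) as.integer(strsplit(v, ".", fixed = TRUE)[[1]][1])
  if (major(p$schema_version) > major(SCHEMA_VERSION))
    .fail("model schema version ", p$schema_version,
          " is newer than supported (", SCHEMA_VERSION, ")")
  chans <- as.character(unlist(p$channels))
  as_named <- function(l) stats::setNames(as.numeric(unlist(l)), chans)
  W <- do.call(cbind, lapply(p$weights, function(v) as.numeric(unlist(v))))
  P <- do.call(cbind, lapply(p$x_loadings,
                             function(v) as.numeric(unlist(v))))
  rownames(W) <- rownames(P) <- chans
  structure(list(
    fit = list(weights = W, x_loadings = P,
               y_loadings = as.numeric(p$y_loadings),
               coef = as_named(p$coef), n_components = p$n_components),
    std = list(center = as_named(p$std$center), scale = as_named(p$std$scale),
               kept = as.character(unlist(p$std$kept)),
               dropped = as.character(unlist(p$std$dropped))),
    y_mean = p$y_mean, y_sd = p$y_sd, n_components = p$n_components,
    channels = chans, fitted = as.numeric(p$fitted),
    training_conc = as.numeric(p$training_conc),
    schema_version = p$schema_version), class = "pls_model")
}

#' Calibrate end-to-end from a plate manifest
#'
#' Extract features from the manifest images, scan the candidate working
#' ranges, fit the final PLS model on the chosen range, cross-validate, and
#' compute LOD/LOQ and the biplot channel correlations. Writes
#' \code{features.csv}, \code{model.json} and \code{metrics.json} into the
#' config output directory and logs every decision taken (chosen range,
#' components, dropped channels, LOQ flooring).
#'
#' @param config A [run_config()].
#' @param manifest Manifest CSV path (default
#'   \code{file.path(config$out_dir, "manifest.csv")}).
#' @return Invisibly, a list with \code{model}, \code{scan}, \code{cv},
#'   \code{metrics}.
#' @export
run_calibrate <- function(config,
                          manifest = file.path(config$out_dir,
                                               "manifest.csv")) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  tab <- tryCatch(feature_table_from_manifest(manifest),
                  error = function(e) .fail("[features] ", conditionMessage(e)))
  write_feature_table(tab, file.path(out, "features.csv"))
  scan <- tryCatch(
    select_working_range(tab, config$n_components, config$candidate_uppers),
    error = function(e) .fail("[range-scan] ", conditionMessage(e)))
  .log_msg("working range chosen: 0 to ", scan$chosen_upper, " mg/L")
  sub <- tab[tab$conc_mg_per_L <= scan$chosen_upper + 1e-9, , drop = FALSE]
  model <- pls_calibration(sub, config$n_components)
  if (length(model$std$dropped))
    .log_msg("dropped constant channels: ",
             paste(model$std$dropped, collapse = ", "))
  cv <- pls_cross_validate(sub, config$n_components)
  lowest <- min(sub$conc_mg_per_L[sub$conc_mg_per_L > 0])
  lim <- lod_loq(cv, lowest_standard = lowest)
  if (lim$floored)
    .log_msg("LOQ floored at the lowest non-zero standard (", lowest,
             " mg/L)")
  bip <- pca_biplot(tab)
  cal <- calibration_metrics(sub$conc_mg_per_L, model$fitted)
  metrics <- list(
    schema_version = SCHEMA_VERSION,
    n_components = config$n_components,
    chosen_upper = scan$chosen_upper,
    working_range = as.list(scan$chosen_range),
    loq_floored_range = c(lim$loq, scan$chosen_range[["high"]]),
    scan = scan$metrics,
    r2_calibration = cal$r2, rmse_calibration = cal$rmse,
    r2_cv = cv$r2, slope_cv = cv$slope, rmsecv = cv$rmsecv,
    lod = lim$lod, loq = lim$loq, loq_unfloored = lim$loq_unfloored,
    loq_floored = lim$floored,
    correlations = as.list(bip$correlations),
    decisions = list(cv_scheme = "leave-one-out",
                     lod_rule = "3.3*s/|slope|, LOQ 10*s/|slope| floored at lowest standard",
                     removal_convention = config$removal_convention))
  write_pls_model(model, file.path(out, "model.json"))
  .write_json(metrics, file.path(out, "metrics.json"))
  utils::write.csv(scan$metrics, file.path(out, "range_scan.csv"),
                   row.names = FALSE, quote = FALSE)
  .log_msg(sprintf("calibrated: R2(CV) %.4f, slope %.3f, RMSECV %.3f, LOD %.3g, LOQ %.3g",
                   cv$r2, cv$slope, cv$rmsecv, lim$lod, lim$loq))
  invisible(list(model = model, scan = scan, cv = cv, metrics = metrics))
}

#' Quantify unknowns with a stored calibration
#'
#' Predicts concentrations for new feature rows (or plate images listed in a
#' manifest), flags predictions below the model's LOD when one is supplied,
#' and, when the replicates share a nominal level, emits the repeatability
#' summary.
#'
#' @param model A \code{pls_model} or the path of a model JSON.
#' @param features Feature table (data.frame/CSV path) with the model's
#'   channels.
#' @param nominal Optional nominal concentration shared by the replicates.
#' @param lod Optional LOD (mg/L) used to flag predictions.
#' @return List with \code{predictions} (data.frame: sample, predicted,
#'   negative, below_lod) and \code{repeatability} (or NULL).
#' @export
run_quantify <- function(model, features, nominal = NULL, lod = NULL) {
  if (is.character(model)) model <- read_pls_model(model)
  if (is.character(features)) features <- utils::read.csv(features)
  if (NROW(features) == 0) .fail("no samples to quantify")
  pred <- pls_predict(model, features)
  res <- data.frame(sample = seq_along(pred), predicted_mg_per_L = pred,
                    negative = attr(pred, "negative"),
                    below_lod = if (is.null(lod)) NA else pred < lod)
  rep_sum <- NULL
  if (!is.null(nominal) && length(pred) >= 2)
    rep_sum <- repeatability_summary(as.numeric(pred), nominal)
  list(predictions = res, repeatability = rep_sum)
}

#' Run an adsorption analysis suite
#'
#' Dispatches to the kinetic, isotherm, selectivity or reusability analysis
#' on CSVs conforming to the module schemas, and writes one JSON report per
#' analysis into the config output directory.
#'
#' @param config A [run_config()].
#' @param what One of \code{"kinetics"}, \code{"isotherm"},
#'   \code{"selectivity"}, \code{"reusability"}.
#' @param file Input CSV (defaults to the file [run_simulate()] writes for
#'   that analysis).
#' @param template Template dye label for the selectivity analysis.
#' @return Invisibly, the report list.
#' @export
run_adsorption <- function(config, what = c("kinetics", "isotherm",
                                            "selectivity", "reusability"),
                           file = NULL, template = "tartrazine") {
  stopifnot(inherits(config, "run_config"))
  what <- match.arg(what)
  out <- config$out_dir
  if (is.null(file)) file <- file.path(out, paste0(what, ".csv"))
  if (!file.exists(file)) .fail("[", what, "] input CSV not found: ", file)
  dat <- utils::read.csv(file)
  report <- switch(what,
    kinetics = {
      fits <- lapply(c("PFO", "PSO", "IPD"), function(m)
        tryCatch(fit_kinetics(dat, m, window = if (m == "IPD")
                                config$ipd_window else NULL),
                 error = function(e) .fail("[kinetics:", m, "] ",
                                           conditionMessage(e))))
      names(fits) <- c("PFO", "PSO", "IPD")
      # model comparison on a common footing: every model fitted over the
      # full time window (the windowed IPD fit above stays the mechanistic
      # diffusion analysis)
      cmp <- c(PFO = fits$PFO$r2, PSO = fits$PSO$r2,
               IPD = fit_kinetics(dat, "IPD", window = range(dat[[1]]),
                                  nonlinear = FALSE)$r2)
      best <- names(cmp)[which.max(cmp)]
      list(analysis = "kinetics", best_model = best,
           comparison_r2_full_window = as.list(cmp),
           fits = lapply(fits, function(f)
             list(model = f$model, parameters = as.list(f$parameters),
                  r2 = f$r2, window = f$window,
                  nonlinear = if (is.null(f$nonlinear)) NULL else
                    list(parameters = as.list(f$nonlinear$parameters),
                         r2 = f$nonlinear$r2))))
    },
    isotherm = {
      fits <- lapply(c("Langmuir", "Freundlich"), function(m)
        fit_isotherm(dat, m))
      names(fits) <- c("Langmuir", "Freundlich")
      best <- names(fits)[which.max(vapply(fits, `[[`, numeric(1), "r2"))]
      list(analysis = "isotherm", best_model = best,
           fits = lapply(fits, function(f)
             list(model = f$model, parameters = as.list(f$parameters),
                  r2 = f$r2, favorable = f$favorable)))
    },
    selectivity = {
      res <- selectivity_analysis(dat, template, config$removal_convention)
      list(analysis = "selectivity", template = template,
           convention = config$removal_convention, table = res)
    },
    reusability = {
      prof <- reusability_profile(dat, config$delta,
                                  config$removal_convention)
      list(analysis = "reusability", delta = config$delta,
           convention = config$removal_convention,
           removals = as.list(prof$removals), drop_cycle = prof$drop_cycle)
    })
  report$schema_version <- SCHEMA_VERSION
  .write_json(report, file.path(out, paste0(what, "_report.json")))
  .log_msg(what, " report written")
  invisible(report)
}
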