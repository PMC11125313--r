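#' Optical response model of a dye-loaded MIP plate
#'
#' Describes how the mean color of a blank MIP-PET plate changes as tartrazine
#' accumulates on it. Each 8-bit channel attenuates decadically with the areal
#' loading \eqn{q} (mg cm\eqn{^{-2}}):
#' \deqn{ch(q) = ch_0 \cdot 10^{-a_{ch} q},}
#' a reflectance analogue of the Beer–Lambert law. A yellow dye absorbs blue
#' light most strongly and red/green only through weak absorption tails, so
#' the attenuation coefficients must satisfy
#' \code{blue_attenuation > green_attenuation >= red_attenuation >= 0}; this
#' is what makes the plate turn yellow as it loads. The decadic form keeps
#' every channel inside [0, 255] at any loading and produces the curvature at
#' high concentration that motivates restricting the calibration to a working
#' range.
#'
#' The defaults are frozen fixture constants chosen so that a 0–20 mg/L
#' calibration series (3 mL on 1 cm\eqn{^2}) is close to linear in the low
#' milligram-per-liter range and visibly saturated toward 20 mg/L, with the
#' equal red and green tails keeping the hue's march toward yellow monotone;
#' they are conventions of the generator, not measured properties of any
#' real plate.
#'
#' @param base_rgb Numeric length-3, mean R, G, B of a blank plate on the
#'   0–255 scale. Default \code{c(235, 230, 225)} (near-white, slightly warm).
#' @param blue_attenuation,green_attenuation,red_attenuation Decadic
#'   attenuation coefficients per (mg cm\eqn{^{-2}}) of loading.
#' @param pixel_noise_sd Per-channel Gaussian pixel noise SD in 8-bit counts.
#' @param illumination_gradient Maximum fractional brightness change across
#'   the plate (a linear field whose orientation is drawn per image).
#' @param seed Integer RNG seed; mandatory so every image is reproducible.
#' @return An object of class \code{plate_response_model}.
#' @examples
#' resp <- plate_response_model(seed = 1)
#' img <- generate_plate_image(5, response = resp)
#' @export
plate_response_model <- function(base_rgb = c(235, 230, 225),
                                 blue_attenuation = 25,
                                 green_attenuation = 8,
                                 red_attenuation = 8,
                                 pixel_noise_sd = 8,
                                 illumination_gradient = 0.02,
                                 seed) {
  if (missing(seed)) .fail("`seed` is mandatory for plate_response_model()")
  if (length(base_rgb) != 3L || any(!is.finite(base_rgb)) ||
      any(base_rgb < 0) || any(base_rgb > 255))
    .fail("`base_rgb` must be three values in [0, 255]")
  for (nm in c("blue_attenuation", "green_attenuation", "red_attenuation",
               "pixel_noise_sd", "illumination_gradient"))
    .check_number(get(nm), nm, min = 0)
  if (!(blue_attenuation > green_attenuation &&
        green_attenuation >= red_attenuation))
    .fail("attenuation coefficients must satisfy blue > green >= red >= 0")
  structure(
    list(base_rgb = as.numeric(base_rgb),
         attenuation = c(red = red_attenuation, green = green_attenuation,
                         blue = blue_attenuation),
         pixel_noise_sd = pixel_noise_sd,
         illumination_gradient = illumination_gradient,
         seed = as.integer(seed)),
    class = "plate_response_model")
}

#' @export
print.plate_response_model <- function(x, ...) {
  cat("Plate response model (decadic channel attenuation)\n")
  cat(sprintf("  blank RGB      : (%g, %g, %g)\n", x$base_rgb[1],
              x$base_rgb[2], x$base_rgb[3]))
  cat(sprintf("  attenuation/q  : R %g, G %g, B %g (per mg cm^-2)\n",
              x$attenuation["red"], x$attenuation["green"],
              x$attenuation["blue"]))
  cat(sprintf("  pixel noise SD : %g counts; illumination gradient %g%%\n",
              x$pixel_noise_sd, 100 * x$illumination_gradient))
  cat(sprintf("  seed           : %d\n", x$seed))
  invisible(x)
}

# Expected (noise-free, unit-illumination) channel means for a loading q.
.expected_channels <- function(response, q) {
  response$base_rgb * 10^(-response$attenuation * q)
}

#' Simulate a photographed MIP plate after dye uptake
#'
#' Renders an 8-bit RGB image of a plate exposed to a tartrazine solution
#' under the complete-uptake assumption: all analyte in the aliquot adsorbs,
#' so the areal loading is \eqn{q = C \cdot V / A} (mg cm\eqn{^{-2}}). Every
#' pixel's expected value is the response model's channel mean at that
#' loading, multiplied by a linear illumination field (random orientation,
#' fixed magnitude), plus i.i.d. Gaussian noise, then clipped to [0, 255] and
#' rounded. The same seed and arguments always give a bit-identical image.
#'
#' @param conc_mg_per_L Solution concentration, mg/L (non-negative).
#' @param volume_L Aliquot volume in liters (default 0.003, i.e. 3 mL).
#' @param area_cm2 Plate area in cm^2 (default 1).
#' @param response A [plate_response_model()].
#' @param width_px,height_px Image dimensions in pixels (at least 16 so a
#'   16x16 ROI fits).
#' @return Integer array \code{height_px x width_px x 3} with values 0–255.
#' @examples
#' img <- generate_plate_image(10, response = plate_response_model(seed = 7))
#' dim(img)
#' @export
generate_plate_image <- function(conc_mg_per_L, volume_L = 0.003,
                                 area_cm2 = 1, response,
                                 width_px = 64, height_px = 64) {
  stopifnot(inherits(response, "plate_response_model"))
  .check_number(conc_mg_per_L, "conc_mg_per_L", min = 0)
  .check_number(volume_L, "volume_L", min = 0)
  .check_number(area_cm2, "area_cm2", min = 0, allow_zero = FALSE)
  if (width_px < 16 || height_px < 16)
    .fail("image dimensions must be at least 16x16 pixels")
  q <- conc_mg_per_L * volume_L / area_cm2
  mu <- .expected_channels(response, q)
  h <- as.integer(height_px); w <- as.integer(width_px)
  withr::with_seed(response$seed, {
    g <- response$illumination_gradient
    if (g > 0) {
      theta <- stats::runif(1, 0, 2 * pi)
      cx <- (col(matrix(0, h, w)) - 1) / (w - 1) - 0.5
      cy <- (row(matrix(0, h, w)) - 1) / (h - 1) - 0.5
      proj <- (cx * cos(theta) + cy * sin(theta)) /
        (abs(cos(theta)) + abs(sin(theta)))
      field <- 1 + g * proj     # spans exactly [1 - g/2, 1 + g/2]
    } else {
      field <- matrix(1, h, w)
    }
    img <- array(0L, dim = c(h, w, 3L))
    for (ch in 1:3) {
      px <- mu[ch] * field
      if (response$pixel_noise_sd > 0)
        px <- px + stats::rnorm(h * w, 0, response$pixel_noise_sd)
      img[, , ch] <- as.integer(round(pmin(255, pmax(0, px))))
    }
    img
  })
}

# deterministic child seed for the i-th sample of a series (kept < 2^31)
.child_seed <- function(master, i) {
  as.integer((as.double(master) + 99991 * as.double(i)) %% 2147483647L)
}

#' Simulate a full calibration plate series
#'
#' One image per concentration and replicate, emulating a calibration set of
#' plates equilibrated in standards (default conditions: 3 mL aliquots on
#' 1 cm^2 plates). Each image gets its own response model whose seed is
#' derived deterministically from the master seed and the sample index, so
#' the whole series is reproducible while replicates still differ.
#'
#' @param concs Non-empty vector of non-negative concentrations (mg/L).
#' @param response Master [plate_response_model()]; its seed drives the series.
#' @param replicates Images per concentration (>= 1).
#' @inheritParams generate_plate_image
#' @return A list with one element per image: \code{list(image, conc_mg_per_L,
#'   replicate, seed)}, ordered concentration-major.
#' @export
generate_calibration_series <- function(concs, response, replicates = 2,
                                        volume_L = 0.003, area_cm2 = 1,
                                        width_px = 64, height_px = 64) {
  if (length(concs) == 0) .fail("`concs` must be non-empty")
  if (any(!is.finite(concs)) || any(concs < 0))
    .fail("`concs` must all be finite and non-negative")
  if (replicates < 1) .fail("`replicates` must be >= 1")
  stopifnot(inherits(response, "plate_response_model"))
  out <- vector("list", length(concs) * replicates)
  k <- 0L
  for (i in seq_along(concs)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      resp_k <- response
      resp_k$seed <- .child_seed(response$seed, k)
      out[[k]] <- list(
        image = generate_plate_image(concs[i], volume_L, area_cm2, resp_k,
                                     width_px, height_px),
        conc_mg_per_L = concs[i], replicate = r, seed = resp_k$seed)
    }
  }
  out
}

#' Write / read plate images
#'
#' Images are stored as lossless 8-bit RGB PNG. JPEG is accepted on read only
#' (smartphone cameras save JPG), never written.
#'
#' @param image Integer array h x w x 3, values 0–255.
#' @param path File path (.png to write; .png/.jpg/.jpeg to read).
#' @return \code{write_plate_png()} returns the path invisibly;
#'   \code{read_plate_image()} returns the 0–255 integer array.
#' @export
write_plate_png <- function(image, path) {
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' @rdname write_plate_png
#' @export
read_plate_image <- function(path) {
  if (!file.exists(path)) .fail("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    .fail("unsupported image format: .", ext, " (use PNG or JPG)"))
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3), c(dim(raw), 3L))
  arr <- raw[, , 1:3, drop = FALSE] * 255
  array(as.integer(round(arr)), dim = dim(arr))
}
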