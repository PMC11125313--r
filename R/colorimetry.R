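#' Region-of-interest specification
#'
#' Pixel coordinates are 0-based, row-major, origin at the top-left corner;
#' the ROI covers the half-open block
#' \code{[row, row + height) x [col, col + width)}. The default 16 x 16 block
#' matches the sampling window used when reading plate photographs.
#'
#' @param row,col 0-based indices of the top-left pixel.
#' @param height,width ROI size in pixels (default 16).
#' @return Object of class \code{roi_spec}.
#' @export
roi_spec <- function(row, col, height = 16, width = 16) {
  for (nm in c("row", "col")) .check_number(get(nm), nm, min = 0)
  for (nm in c("height", "width"))
    .check_number(get(nm), nm, min = 1)
  structure(list(row = as.integer(row), col = as.integer(col),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_spec")
}

#' Mean RGB over a region of interest
#'
#' Arithmetic mean of each channel over the ROI pixels; means are real-valued
#' even though pixels are 8-bit.
#'
#' @param image Integer/numeric array \code{h x w x 3} on the 0–255 scale.
#' @param roi A [roi_spec()]; must lie fully inside the image.
#' @return Named numeric \code{c(R=, G=, B=)}.
#' @export
extract_roi_mean <- function(image, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  d <- dim(image)
  if (length(d) != 3L || d[3] < 3L) .fail("`image` must be an h x w x 3 array")
  if (roi$row + roi$height > d[1])
    .fail(sprintf("ROI exceeds image height: rows [%d, %d) but image has %d",
                  roi$row, roi$row + roi$height, d[1]))
  if (roi$col + roi$width > d[2])
    .fail(sprintf("ROI exceeds image width: cols [%d, %d) but image has %d",
                  roi$col, roi$col + roi$width, d[2]))
  rows <- (roi$row + 1L):(roi$row + roi$height)
  cols <- (roi$col + 1L):(roi$col + roi$width)
  c(R = mean(image[rows, cols, 1]),
    G = mean(image[rows, cols, 2]),
    B = mean(image[rows, cols, 3]))
}

.check_rgb <- function(rgb) {
  rgb <- as.numeric(rgb)
  if (length(rgb) != 3L || any(!is.finite(rgb)))
    .fail("an RGB triplet must be three finite numbers")
  if (any(rgb < 0) || any(rgb > 255))
    .fail("RGB channels must lie in [0, 255] (got ",
          paste(signif(rgb, 6), collapse = ", "), ")")
  rgb
}

#' RGB to CMYK, as used in digital image colorimetry
#'
#' The plain subtractive conversion on the 0–255 scale:
#' \deqn{C = 1 - R/255,\quad M = 1 - G/255,\quad Y = 1 - B/255,\quad
#'       K = \min(C, M, Y).}
#' Note that C, M, Y are \emph{not} rescaled by \eqn{(1-K)} — the four
#' channels are kept exactly as the printed formulas define them, so K always
#' equals the minimum of the other three.
#'
#' @param rgb Numeric length-3 (R, G, B) on the 0–255 scale.
#' @return Named numeric \code{c(C=, M=, Y=, K=)}, each in [0, 1].
#' @examples
#' rgb_to_cmyk(c(255, 255, 0))  # pure yellow: C=M=K=0, Y=1
#' @export
rgb_to_cmyk <- function(rgb) {
  rgb <- .check_rgb(rgb)
  C <- 1 - rgb[1] / 255
  M <- 1 - rgb[2] / 255
  Y <- 1 - rgb[3] / 255
  c(C = C, M = M, Y = Y, K = min(C, M, Y))
}

#' RGB to HSV with the piecewise hue formula
#'
#' Mixed-scale HSV as conventionally tabulated in colorimetric sensing work:
#' \itemize{
#'   \item \eqn{V = \max(R, G, B)} — kept on the 0–255 count scale;
#'   \item \eqn{S = 0} if \eqn{V = 0}, else \eqn{1 - \min(R,G,B)/V} (a ratio);
#'   \item \eqn{H} in degrees by the six-case formula: with
#'     \eqn{\Delta = MAX - MIN},
#'     \eqn{H = 60 (G-B)/\Delta} when MAX = R and \eqn{G \ge B};
#'     \eqn{60 (G-B)/\Delta + 360} when MAX = R and \eqn{G < B};
#'     \eqn{60 (B-R)/\Delta + 120} when MAX = G;
#'     \eqn{60 (R-G)/\Delta + 240} when MAX = B.
#' }
#' When MAX = MIN the hue is mathematically undefined; the package fixes
#' \eqn{H = 0} so that blank (gray/white) plates still yield a complete
#' feature vector. Ties in MAX are resolved in the printed case order: the R
#' branch takes precedence, then G, then B. Note V is in counts while S is a
#' ratio — the two scales are deliberately not harmonized, matching the
#' convention used with these features.
#'
#' @param rgb Numeric length-3 (R, G, B) on the 0–255 scale.
#' @return Named numeric \code{c(H=, S=, V=)}; H in [0, 360) degrees, S in
#'   [0, 1], V in [0, 255].
#' @examples
#' rgb_to_hsv_channels(c(255, 255, 0))  # yellow: H=60, S=1, V=255
#' @export
rgb_to_hsv_channels <- function(rgb) {
  rgb <- .check_rgb(rgb)
  R <- rgb[1]; G <- rgb[2]; B <- rgb[3]
  V <- max(R, G, B)
  MIN <- min(R, G, B)
  S <- if (V == 0) 0 else 1 - MIN / V
  d <- V - MIN
  H <- if (d == 0) {
    0                                   # undefined hue -> 0 by convention
  } else if (V == R && G >= B) {
    60 * (G - B) / d
  } else if (V == R) {
    60 * (G - B) / d + 360
  } else if (V == G) {
    60 * (B - R) / d + 120
  } else {
    60 * (R - G) / d + 240
  }
  if (H >= 360) H <- H - 360            # keep the half-open [0, 360) range
  c(H = H, S = S, V = V)
}

#' Expand a mean RGB triplet into the 10-channel color feature vector
#'
#' @param rgb Numeric length-3 (R, G, B), 0–255.
#' @return Named numeric of length 10 in the fixed order
#'   \code{(R, G, B, C, M, Y, K, H, S, V)}.
#' @export
color_features <- function(rgb) {
  rgb <- .check_rgb(rgb)
  c(R = rgb[1], G = rgb[2], B = rgb[3], rgb_to_cmyk(rgb),
    rgb_to_hsv_channels(rgb))
}

#' Names of the 10 color feature channels, in schema order
#' @export
feature_channels <- function() c("R", "G", "B", "C", "M", "Y", "K", "H", "S", "V")

#' Default pair of ROIs for the simulated 64 x 64 plates
#'
#' Two 16 x 16 blocks placed symmetrically about the image center, so that
#' averaging them cancels any linear illumination gradient.
#'
#' @param width_px,height_px Image dimensions the ROIs are placed in.
#' @return List of two [roi_spec()] objects.
#' @export
default_rois <- function(width_px = 64, height_px = 64) {
  r <- as.integer(height_px / 2 - 8)
  off <- as.integer(width_px / 4)
  list(roi_spec(r, as.integer(width_px / 2) - off - 8L),
       roi_spec(r, as.integer(width_px / 2) + off - 8L))
}

#' Build the calibration feature table from labelled plate images
#'
#' For each sample the mean RGB of its one or two ROIs is averaged into a
#' single triplet (the two sampling windows describe the same plate, so they
#' are pooled rather than treated as replicates) and expanded into the
#' 10-channel feature vector.
#'
#' @param samples List of samples, each a list with elements \code{image}
#'   (0–255 array) or \code{path} (PNG/JPG file), \code{conc_mg_per_L}, and
#'   optionally \code{rois} (list of 1–2 [roi_spec()]; default
#'   [default_rois()] for the image's size).
#' @return \code{data.frame} with columns \code{sample_id, conc_mg_per_L}
#'   and the 10 channels \code{R, G, B, C, M, Y, K, H, S, V}.
#' @export
build_feature_table <- function(samples) {
  if (length(samples) == 0) .fail("`samples` must contain at least one sample")
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    img <- if (!is.null(s$image)) s$image
           else if (!is.null(s$path)) read_plate_image(s$path)
           else .fail("sample ", i, " has neither `image` nor `path`")
    if (is.null(s$conc_mg_per_L))
      .fail("sample ", i, " is missing `conc_mg_per_L`")
    rois <- s$rois
    if (is.null(rois)) rois <- default_rois(dim(img)[2], dim(img)[1])
    if (length(rois) < 1 || length(rois) > 2)
      .fail("sample ", i, " must have 1 or 2 ROIs")
    means <- vapply(rois, function(r) extract_roi_mean(img, r), numeric(3))
    feats <- color_features(rowMeans(means))
    cbind(data.frame(sample_id = i, conc_mg_per_L = s$conc_mg_per_L),
          as.data.frame(as.list(feats)))
  })
  do.call(rbind, rows)
}

#' Build the feature table from a manifest file
#'
#' The manifest is a CSV with columns
#' \code{image_path, conc_mg_per_L, roi_row, roi_col} (0-based top-left ROI
#' corners; 16 x 16 ROIs; one row per ROI, so each image appears once or
#' twice).
#'
#' @param manifest Path to the manifest CSV, or an equivalent data.frame.
#' @param base_dir Directory that relative \code{image_path}s resolve
#'   against (default: the manifest's directory, or \code{"."}).
#' @return Feature table as in [build_feature_table()].
#' @export
feature_table_from_manifest <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(base_dir)) base_dir <- "."
  need <- c("image_path", "conc_mg_per_L", "roi_row", "roi_col")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    .fail("manifest is missing column(s): ", paste(miss, collapse = ", "))
  samples <- lapply(split(manifest, manifest$image_path)[
                      unique(manifest$image_path)], function(g) {
    p <- g$image_path[1]
    if (!file.exists(p)) p <- file.path(base_dir, g$image_path[1])
    list(path = p, conc_mg_per_L = g$conc_mg_per_L[1],
         rois = mapply(roi_spec, g$roi_row, g$roi_col, SIMPLIFY = FALSE))
  })
  tab <- build_feature_table(samples)
  tab$sample_id <- seq_len(nrow(tab))
  tab
}

#' Write a feature table to CSV with the fixed 12-column schema
#'
#' @param table Feature table from [build_feature_table()].
#' @param path Output CSV path.
#' @export
write_feature_table <- function(table, path) {
  cols <- c("sample_id", "conc_mg_per_L", feature_channels())
  miss <- setdiff(cols, names(table))
  if (length(miss))
    .fail("feature table missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(table[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
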