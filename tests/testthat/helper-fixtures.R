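# Shared fixtures, all generated in code under fixed seeds.

# independent brute-force HSV per the piecewise hue definition, written
# directly from the case table (kept separate from the package's vectorized
# route on purpose)
oracle_hsv <- function(R, G, B) {
  V <- max(c(R, G, B))
  MIN <- min(c(R, G, B))
  S <- if (V == 0) 0 else 1 - MIN / V
  if (V == MIN) return(c(H = 0, S = S, V = V))
  H <- if (V == R && G >= B) 60 * (G - B) / (V - MIN)
  else if (V == R && G < B)  60 * (G - B) / (V - MIN) + 360
  else if (V == G)           60 * (B - R) / (V - MIN) + 120
  else                       60 * (R - G) / (V - MIN) + 240
  c(H = H %% 360, S = S, V = V)
}

# RGB triplets covering all six hue branches plus degenerate cases
hue_branch_triplets <- function() {
  rbind(
    c(200, 150, 100),  # MAX=R, G>B
    c(200, 100, 100),  # MAX=R, G=B (R branch, H=0)
    c(200, 100, 150),  # MAX=R, G<B (+360 branch)
    c(100, 200, 150),  # MAX=G
    c(150, 100, 200),  # MAX=B
    c(255, 255, 0),    # tie R=G>B (R branch precedence)
    c(0, 255, 255),    # tie G=B>R (G branch precedence)
    c(128, 128, 128),  # gray: MAX=MIN
    c(0, 0, 0),        # black
    c(255, 255, 255))  # white
}

# small noise-free calibration table with y exactly linear in the channels
linear_feature_table <- function(n = 12) {
  conc <- seq(0, 11, length.out = n)
  tab <- data.frame(sample_id = seq_len(n), conc_mg_per_L = conc)
  set.seed(99)
  basis <- matrix(stats::rnorm(10 * 3), 3, 10)
  Z <- cbind(conc, conc^0.5, stats::rnorm(n))
  feats <- Z %*% basis
  colnames(feats) <- feature_channels()
  cbind(tab, as.data.frame(feats))
}

# the default frozen synthetic calibration fixture (42 plates, 0-20 mg/L)
frozen_calibration_table <- local({
  cache <- NULL
  function(seed = 42) {
    if (!is.null(cache)) return(cache)
    resp <- plate_response_model(seed = seed)
    ser <- generate_calibration_series(0:20, resp, replicates = 2)
    tab <- build_feature_table(lapply(ser, function(s)
      list(image = s$image, conc_mg_per_L = s$conc_mg_per_L)))
    cache <<- tab
    tab
  }
})

extdata <- function(file) {
  system.file("extdata", file, package = "mipsense", mustWork = TRUE)
}
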