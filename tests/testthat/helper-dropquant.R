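# Shared fixtures: a rain-free amplitude model for calibration checks, and
# the midpoint thresholds of the default synthetic clusters.
rainless_model <- function(...) amplitude_model(rain_fraction = 0, ...)

MID_THRESHOLDS <- c(5000, 5000)

# Fit a duplex well with fixed midpoint thresholds (skips auto-thresholding
# where the test is not about thresholding).
fit_mid <- function(well, ...) ddpcr_fit(well, thresholds = MID_THRESHOLDS, ...)
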