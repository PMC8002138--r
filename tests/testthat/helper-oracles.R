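# Independent oracles used across the suite.

# Definitional two-way ANOVA ICC oracle: sums of squares written out as
# explicit loops over deviations, independent of the package's closed-form
# mean-square computation.
oracle_icc <- function(x, form) {
  n <- nrow(x); k <- ncol(x)
  grand <- sum(x) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - grand)^2
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (x[i, j] - grand)^2
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  if (form == "single") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
}

# Standard control-like phantom used by several densitometry tests.
control_phantom <- function(psf = 4, noise = 3, ...) {
  vessel_phantom_spec(130.71, 97.21, psf_sigma_um = psf, noise_sd = noise, ...)
}
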