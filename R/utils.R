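# Internal numeric helpers shared across modules.

# Lognormal parameters whose arithmetic mean and SD equal `mean` and `sd`
# (moment matching): sdlog^2 = log(1 + (sd/mean)^2), meanlog = log(mean) -
# sdlog^2 / 2.
lnorm_params <- function(mean, sd) {
  if (any(!is.finite(mean)) || any(!is.finite(sd)) ||
      any(mean <= 0) || any(sd <= 0)) {
    abort("lognormal targets require strictly positive mean and sd",
          class = "cytomesf_parameterization_error")
  }
  sdlog <- sqrt(log1p((sd / mean)^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Unit-mean multiplicative lognormal noise with coefficient of variation `cv`.
mult_noise <- function(n, cv) {
  if (cv < 0) abort("noise CV must be >= 0",
                    class = "cytomesf_parameterization_error")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Instrument response in linear fluorescence: MFI = 10^(offset + gain *
# log10(x)). gain/offset act in the log10 domain, matching photomultiplier
# voltage behaviour.
protocol_transform <- function(x, gain, offset) {
  10^(offset + gain * log10(x))
}

assert_cols <- function(df, cols, what = "data") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "cytomesf_input_error")
  }
  invisible(df)
}

# Derive a stream-specific child seed from a user seed; kept below 2^31.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
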