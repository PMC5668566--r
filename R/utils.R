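# shared internal helpers

# lognormal parameterised by arithmetic mean and coefficient of variation
lnorm_params <- function(mean, cv) {
  stopifnot(mean > 0, cv >= 0)
  sdlog <- sqrt(log1p(cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  p <- lnorm_params(mean, cv)
  rlnorm(n, p$meanlog, p$sdlog)
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# canonical gradient region order, light to heavy
REGIONS <- c("RNP", "40S", "60S", "80S", "POLYSOMES")
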