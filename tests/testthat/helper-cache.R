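# Shared memoized computations. Test files run in one session, so expensive
# network scans are computed once and reused across files.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# standard pulse protocol used throughout: width 5 min, 1e-7 M
std_protocol <- function(period, horizon = 960, amplitude = 1e-7, width = 5) {
  pulse_protocol(amplitude, width = width, period = period, horizon = horizon)
}

# network timecourse at given int_mult and period (960 min, defaults)
cached_network_tc <- function(int_mult, period, horizon = 960) {
  key <- sprintf("tc_%g_%g_%g", int_mult, period, horizon)
  memo(key, {
    p <- network_params(int_mult = int_mult)
    simulate_network(p, std_protocol(period, horizon),
                     y0 = cached_rest(int_mult))
  })
}

cached_rest <- function(int_mult = 1) {
  key <- sprintf("rest_%g", int_mult)
  memo(key, resting_steady_state(network_params(int_mult = int_mult)))
}

# constant-stimulation dose timecourse
cached_dose_tc <- function(int_mult, conc, horizon = 960) {
  key <- sprintf("dose_%g_%g", int_mult, conc)
  memo(key, {
    p <- network_params(int_mult = int_mult)
    simulate_network(p, pulse_protocol(conc, horizon, horizon, horizon),
                     y0 = cached_rest(int_mult))
  })
}

# full-period-grid frequency scan used by the acceptance ladder
gate_periods <- c(5, 15, 30, 60, 120, 240, 480)

cached_freq_scan <- function(int_mult, periods = gate_periods) {
  key <- sprintf("scan_%g_%s", int_mult, paste(periods, collapse = "_"))
  memo(key, frequency_scan(network_params(int_mult = int_mult),
                           periods = periods))
}

# reporter AUCs over the period grid for one gate mode at one int_mult,
# reusing the cached network timecourses
gate_freq_aucs <- function(int_mult, mode) {
  vapply(gate_periods, function(T) {
    attr(simulate_reporter(cached_network_tc(int_mult, T), gate_spec(mode)),
         "auc")
  }, numeric(1))
}

# minimal-model scans
cached_minimal_noncomp <- function() {
  memo("min_noncomp", minimal_frequency_scan(
    minimal_params(), periods = c(4, 8, 16, 32, 64, 128, 256), width = 4,
    horizon = 1024))
}

cached_minimal_comp <- function() {
  memo("min_comp", minimal_frequency_scan(
    minimal_params(), periods = c(12, 24, 48, 96, 192, 384),
    duty_fraction = 1 / 12, compensated = TRUE, horizon = 768))
}

# additive-Gaussian-noise channel with equally spaced means: synthetic
# samples plus the exact MI by numerical integration of the mixture densities
gauss_means <- c(0, 2, 4, 6)
gauss_sd <- 1

gauss_channel_samples <- function(n_per_level = 2000, seed = 11) {
  memo(sprintf("gauss_%d_%d", n_per_level, seed), {
    set.seed(seed)
    tibble::tibble(
      stimulus_index = rep(seq_along(gauss_means), each = n_per_level),
      response = rnorm(length(gauss_means) * n_per_level,
                       mean = rep(gauss_means, each = n_per_level),
                       sd = gauss_sd))
  })
}

gauss_channel_mi_oracle <- function() {
  memo("gauss_oracle", {
    m <- length(gauss_means)
    dens <- function(x, mu) dnorm(x, mu, gauss_sd)
    mix <- function(x) Reduce(`+`, lapply(gauss_means, dens, x = x)) / m
    terms <- vapply(gauss_means, function(mu) {
      integrand <- function(x) {
        f <- dens(x, mu)
        ifelse(f > 0, f * log2(f / mix(x)), 0)
      }
      integrate(integrand, mu - 10 * gauss_sd, mu + 10 * gauss_sd,
                rel.tol = 1e-10)$value
    }, numeric(1))
    mean(terms)
  })
}

# straight-line-through-origin R^2
r2_origin <- function(f, y) {
  b <- sum(f * y) / sum(f * f)
  1 - sum((y - b * f)^2) / sum((y - mean(y))^2)
}
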