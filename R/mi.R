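# Single-cell population simulation and mutual-information estimation.

#' Shannon entropy of the stimulus distribution
#'
#' @param n_levels Number of stimulus levels (>= 1).
#' @param probabilities Optional probability vector of length `n_levels`
#'   (must sum to 1); uniform by default.
#' @return Entropy in bits.
#' @examples
#' input_entropy(8)  # 3 bits
#' @export
input_entropy <- function(n_levels, probabilities = NULL) {
  stop_if_not(is.numeric(n_levels), length(n_levels) == 1, n_levels >= 1,
              n_levels == round(n_levels),
              msg = "`n_levels` must be a single positive integer")
  if (is.null(probabilities)) {
    probabilities <- rep(1 / n_levels, n_levels)
  }
  stop_if_not(length(probabilities) == n_levels, all(probabilities >= 0),
              abs(sum(probabilities) - 1) < 1e-9,
              msg = "`probabilities` must be a valid probability vector of length n_levels")
  p <- probabilities[probabilities > 0]
  -sum(p * log2(p))
}

#' Specify a synthetic single-cell population
#'
#' Cell-to-cell variability is modelled as per-cell log-normal scaling of
#' designated model parameters (median 1, coefficient of variation `cv`),
#' plus additive Gaussian measurement noise on the response.
#'
#' @param stimulus_levels Stimulus concentrations (M), one per level.
#' @param n_cells Cells per stimulus level (>= 1).
#' @param cv Coefficient of variation of the log-normal per-cell parameter
#'   scaling (default 0.3).
#' @param heterogeneous_params Character vector of [network_params()] names
#'   scaled per cell (default receptor and ERK totals).
#' @param noise_sd Additive Gaussian measurement noise sd (response units).
#' @param seed Integer seed fixing the full sample.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(stimulus_levels, n_cells = 50, cv = 0.3,
                            heterogeneous_params = c("Rtot", "erk_tot"),
                            noise_sd = 0, seed = 1) {
  stop_if_not(length(stimulus_levels) >= 1, all(stimulus_levels >= 0),
              msg = "`stimulus_levels` must be non-negative")
  stop_if_not(n_cells >= 1, msg = "`n_cells` must be >= 1")
  stop_if_not(cv >= 0, noise_sd >= 0, msg = "`cv` and `noise_sd` must be >= 0")
  structure(list(stimulus_levels = stimulus_levels, n_cells = n_cells,
                 cv = cv, heterogeneous_params = heterogeneous_params,
                 noise_sd = noise_sd, seed = seed),
            class = "population_spec")
}

#' Simulate single-cell responses across stimulus levels
#'
#' For each stimulus level and cell, draws per-cell parameter scalings, runs
#' the response model under constant stimulation and records the chosen
#' channel at `readout_time` plus measurement noise. All randomness is drawn
#' up front from `spec$seed` in a fixed order, so the sample is fully
#' reproducible. Cells whose simulation fails are excluded with a warning.
#'
#' @param params A [network_params()] (ignored when `response_fn` is given).
#' @param spec A [population_spec()].
#' @param channel Network output channel (default `"ppERK_nuc_uM"`).
#' @param readout_time Readout time (min), default 60.
#' @param response_fn Optional deterministic response function
#'   `function(params, stimulus, readout_time) -> numeric(1)` replacing the
#'   network simulation (e.g. a dose-response curve for conceptual
#'   scenarios); it receives the per-cell scaled `params`.
#' @param dt Solver output step for network readouts.
#' @return A tibble of class `cell_samples` with columns `stimulus_index`,
#'   `stimulus_M`, `cell_id`, `response`.
#' @export
simulate_population <- function(params = network_params(), spec, channel = "ppERK_nuc_uM",
                                readout_time = 60, response_fn = NULL, dt = 0.1) {
  stopifnot(inherits(spec, "population_spec"))
  levels <- spec$stimulus_levels
  n <- spec$n_cells
  n_par <- length(spec$heterogeneous_params)
  # draw all randomness up front: per (level, cell) parameter scalings, then noise
  set.seed(spec$seed)
  sdlog <- sqrt(log(1 + spec$cv^2))
  scal <- array(rlnorm(length(levels) * n * n_par, meanlog = 0, sdlog = sdlog),
                dim = c(length(levels), n, n_par))
  noise <- matrix(rnorm(length(levels) * n, sd = spec$noise_sd),
                  nrow = length(levels))
  if (spec$cv == 0) scal[] <- 1
  base_fn <- response_fn
  if (is.null(base_fn)) {
    base_fn <- function(p, stimulus, readout_time) {
      prot <- pulse_protocol(max(stimulus, 1e-300), width = readout_time,
                             period = readout_time, horizon = readout_time)
      tc <- simulate_network(p, prot, dt = dt)
      tc[[channel]][nrow(tc)]
    }
  }
  rows <- vector("list", length(levels) * n)
  failures <- 0L
  idx <- 0L
  for (li in seq_along(levels)) {
    for (ci in seq_len(n)) {
      idx <- idx + 1L
      p <- params
      for (k in seq_len(n_par)) {
        nm <- spec$heterogeneous_params[k]
        p[[nm]] <- p[[nm]] * scal[li, ci, k]
      }
      resp <- tryCatch(base_fn(p, levels[li], readout_time),
                       error = function(e) NA_real_)
      if (is.na(resp) || !is.finite(resp)) {
        failures <- failures + 1L
        next
      }
      rows[[idx]] <- tibble::tibble(stimulus_index = li,
                                    stimulus_M = levels[li],
                                    cell_id = ci,
                                    response = resp + noise[li, ci])
    }
  }
  if (failures > 0) {
    warning(sprintf("%d cell simulation(s) failed and were excluded", failures))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "spec") <- spec
  class(out) <- c("cell_samples", class(out))
  out
}

# internal: plug-in MI (bits) from a stimulus-index vector and a response-bin
# index vector
.mi_plugin <- function(s, b) {
  tab <- table(s, b)
  n <- sum(tab)
  pj <- tab / n
  ps <- rowSums(pj)
  pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / (ps[row(pj)[nz]] * pb[col(pj)[nz]])))
}

# internal: jackknife bias-corrected MI; leave-one-out values are identical
# within each (stimulus, bin) cell, so only distinct cells are recomputed
.mi_jackknife <- function(s, b) {
  mi <- .mi_plugin(s, b)
  n <- length(s)
  cells <- unique(data.frame(s = s, b = b))
  loo_sum <- 0
  for (i in seq_len(nrow(cells))) {
    sel <- which(s == cells$s[i] & b == cells$b[i])[1]
    w <- sum(s == cells$s[i] & b == cells$b[i])
    loo_sum <- loo_sum + w * .mi_plugin(s[-sel], b[-sel])
  }
  list(mi = mi, mi_bc = n * mi - (n - 1) * loo_sum / n)
}

# internal: quantile binning of a response vector
.quantile_bins <- function(x, bins) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 8))
  if (length(br) < 2) return(rep(1L, length(x)))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

# internal: Ross (2014)-style kNN MI for a discrete stimulus and a
# one-dimensional continuous response
.mi_knn <- function(s, x, k = 3) {
  n <- length(x)
  lev <- unique(s)
  # tiny jitter breaks ties deterministically
  x <- x + seq_along(x) * 1e-12 * (max(abs(x)) + 1)
  psi_terms <- numeric(n)
  nx <- numeric(n)
  for (l in lev) {
    sel <- which(s == l)
    nl <- length(sel)
    kk <- min(k, nl - 1)
    if (kk < 1) next
    for (i in sel) {
      d <- sort(abs(x[sel] - x[i]))[kk + 1]  # kth neighbour within level
      m <- sum(abs(x - x[i]) <= d) - 1
      psi_terms[i] <- digamma(m)
      nx[i] <- nl
    }
  }
  mi_nats <- digamma(n) - mean(digamma(nx)) + digamma(k) - mean(psi_terms)
  mi_nats / log(2)
}

#' Estimate mutual information between stimulus and response
#'
#' Plug-in MI on quantile-binned responses with jackknife bias correction
#' and a stratified percentile-bootstrap confidence interval over cells.
#' An optional nearest-neighbour estimator (discrete stimulus, continuous
#' response) is available via `method = "knn"`.
#'
#' @param samples A tibble with columns `stimulus_index` and `response`
#'   (e.g. from [simulate_population()]).
#' @param bins Number of quantile bins for the response (default 16).
#' @param method `"plugin"` (default) or `"knn"`.
#' @param k Neighbour count for the kNN estimator.
#' @param n_boot Bootstrap replicates (default 200; 0 skips the CI).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `mi_estimate`: list with `mi_bits` (plug-in or
#'   kNN point estimate), `mi_bits_bc` (bias-corrected, clamped to
#'   `[0, input entropy]`), `ci_lower`, `ci_upper`, and the settings.
#' @examples
#' df <- tibble::tibble(stimulus_index = rep(1:2, each = 50),
#'                      response = rep(c(0, 10), each = 50))
#' estimate_mi(df, n_boot = 0)
#' @export
estimate_mi <- function(samples, bins = 16, method = c("plugin", "knn"),
                        k = 3, n_boot = 200, conf = 0.95, seed = 1) {
  method <- match.arg(method)
  stop_if_not(all(c("stimulus_index", "response") %in% names(samples)),
              msg = "`samples` needs columns stimulus_index and response")
  s <- samples$stimulus_index
  x <- samples$response
  stop_if_not(all(is.finite(x)), msg = "responses must be finite")
  counts <- table(s)
  stop_if_not(length(counts) >= 2,
              msg = "need at least 2 stimulus levels")
  if (any(counts < 10)) {
    bad <- names(counts)[counts < 10]
    stop(sprintf("insufficient samples: stimulus level(s) %s have fewer than 10 cells",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  h_max <- input_entropy(length(counts), as.numeric(counts) / length(s))
  point <- function(s, x) {
    if (method == "knn") {
      mi <- .mi_knn(s, x, k = k)
      list(mi = mi, mi_bc = mi)
    } else {
      .mi_jackknife(s, .quantile_bins(x, bins))
    }
  }
  est <- point(s, x)
  clamp <- function(v) min(max(v, 0), h_max)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    lev_idx <- split(seq_along(s), s)
    boots <- vapply(seq_len(n_boot), function(b) {
      sel <- unlist(lapply(lev_idx, function(ii) sample(ii, length(ii),
                                                        replace = TRUE)))
      clamp(point(s[sel], x[sel])$mi_bc)
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha), type = 8))
  }
  structure(list(mi_bits = est$mi, mi_bits_bc = clamp(est$mi_bc),
                 ci_lower = ci[1], ci_upper = ci[2],
                 input_entropy_bits = h_max,
                 settings = list(method = method, bins = bins, k = k,
                                 n_boot = n_boot, conf = conf)),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("<mi_estimate> %.3f bits (bias-corrected %.3f; input entropy %.3f)\n",
              x$mi_bits, x$mi_bits_bc, x$input_entropy_bits))
  if (!is.na(x$ci_lower)) {
    cat(sprintf("  %d%% bootstrap CI [%.3f, %.3f], %s estimator\n",
                round(100 * x$settings$conf), x$ci_lower, x$ci_upper,
                x$settings$method))
  }
  invisible(x)
}

#' @method tidy mi_estimate
#' @export
tidy.mi_estimate <- function(x, ...) {
  tibble::tibble(mi_bits = x$mi_bits, mi_bits_bc = x$mi_bits_bc,
                 ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 input_entropy_bits = x$input_entropy_bits,
                 method = x$settings$method)
}

#' @export
glance.mi_estimate <- tidy.mi_estimate

#' @method autoplot cell_samples
#' @export
autoplot.cell_samples <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$stimulus_index),
                                       y = .data$response)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red", size = 2) +
    ggplot2::labs(x = "stimulus level", y = "single-cell response")
}
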