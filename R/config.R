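# Run configuration (YAML/JSON) and provenance-carrying CSV output.

.config_keys <- c("model", "params", "protocol", "gate", "scan", "population",
                  "seed", "output")
.protocol_keys <- c("amplitude_M", "width_min", "period_min", "horizon_min",
                    "baseline_M")

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration (decided by file extension, with YAML
#' as the fallback parser) and validates it. Recognised top-level keys:
#' `model` (`"minimal"` or `"network"`), `params` (named overrides for
#' [minimal_params()] / [network_params()]), `protocol` (`amplitude_M`,
#' `width_min`, `period_min`, `horizon_min`, `baseline_M`), `gate` (fields
#' of [gate_spec()] with `mode`), `scan`, `population`, `seed`, `output`.
#' Defaults are filled for anything omitted; unknown keys anywhere are
#' rejected, and all offending keys are reported together.
#'
#' @param path Path to a YAML or JSON file.
#' @return A validated `run_config` list with elements `model`, `params`
#'   (constructed parameter object), `protocol` ([pulse_protocol()]), `gate`
#'   ([gate_spec()] or `NULL`), `scan`, `population`, `seed`, `output`, plus
#'   attribute `hash` (MD5 of the normalised configuration).
#' @export
load_config <- function(path) {
  stop_if_not(file.exists(path), msg = sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
             error = function(e) stop(sprintf("failed to parse JSON config %s: %s",
                                              path, conditionMessage(e)), call. = FALSE))
  } else {
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop(sprintf("failed to parse YAML config %s: %s",
                                              path, conditionMessage(e)), call. = FALSE))
  }
  validate_config(raw, context = path)
}

#' Validate a configuration list
#'
#' @param raw A named list as parsed from YAML/JSON.
#' @param context Label used in error messages.
#' @return A validated `run_config` (see [load_config()]).
#' @export
validate_config <- function(raw, context = "config") {
  problems <- character(0)
  if (!is.list(raw) || is.null(names(raw))) {
    stop(sprintf("%s: configuration must be a named mapping", context), call. = FALSE)
  }
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  model <- raw$model %||% "network"
  if (!model %in% c("minimal", "network")) {
    problems <- c(problems, sprintf("model must be 'minimal' or 'network', got '%s'", model))
  }
  prot_raw <- raw$protocol %||% list()
  unknown_p <- setdiff(names(prot_raw), .protocol_keys)
  if (length(unknown_p)) {
    problems <- c(problems, paste0("unknown protocol key(s): ",
                                   paste(unknown_p, collapse = ", ")))
  }
  protocol <- NULL
  if (!length(problems)) {
    protocol <- tryCatch(
      pulse_protocol(prot_raw$amplitude_M %||% 1e-7,
                     width = prot_raw$width_min %||% 5,
                     period = prot_raw$period_min %||% 60,
                     horizon = prot_raw$horizon_min %||% 960,
                     baseline = prot_raw$baseline_M %||% 0),
      error = function(e) { problems <<- c(problems, conditionMessage(e)); NULL })
  }
  params <- NULL
  if (!length(problems)) {
    ctor <- if (model == "minimal") minimal_params else network_params
    params <- tryCatch(do.call(ctor, as.list(raw$params %||% list())),
                       error = function(e) { problems <<- c(problems, conditionMessage(e)); NULL })
  }
  gate <- NULL
  if (!is.null(raw$gate) && !length(problems)) {
    g <- as.list(raw$gate)
    if (!is.null(g$mode)) g$mode <- toupper(g$mode)
    gate <- tryCatch(do.call(gate_spec, g),
                     error = function(e) { problems <<- c(problems, paste0("gate: ", conditionMessage(e))); NULL })
  }
  population <- NULL
  if (!is.null(raw$population) && !length(problems)) {
    population <- tryCatch(do.call(population_spec, as.list(raw$population)),
                           error = function(e) { problems <<- c(problems, paste0("population: ", conditionMessage(e))); NULL })
  }
  if (length(problems)) {
    stop(sprintf("%s: invalid configuration:\n  - %s", context,
                 paste(problems, collapse = "\n  - ")), call. = FALSE)
  }
  cfg <- list(model = model, params = params, protocol = protocol, gate = gate,
              scan = raw$scan, population = population,
              seed = raw$seed %||% 1L, output = raw$output)
  attr(cfg, "hash") <- .config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

# internal: MD5 of the canonical JSON serialisation of a config
.config_hash <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
      x[order(names(x) %||% seq_along(x))]
    } else x
  }
  canon <- jsonlite::toJSON(strip(unclass(cfg)), auto_unbox = TRUE, digits = NA,
                            null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(canon), tf)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: provenance comment block
.provenance <- function(extra = list()) {
  base <- list(
    package = paste0("gnrhpulse ", as.character(utils::packageVersion("gnrhpulse"))),
    written = "deterministic output; AUCs are raw (non-baseline-subtracted)"
  )
  lines <- c(base, extra)
  paste0("# ", names(lines), ": ", vapply(lines, as.character, character(1)))
}

# internal: write a data frame as CSV with commented provenance header
.write_prov_csv <- function(df, path, extra = list()) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop(sprintf("cannot write to %s: %s", path,
                                                   conditionMessage(e)), call. = FALSE))
  on.exit(close(con))
  writeLines(.provenance(extra), con)
  df_fmt <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) format(col, digits = 15, scientific = TRUE, trim = TRUE)
    else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  names(df_fmt) <- names(df)
  write.csv(df_fmt, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated time course as CSV
#'
#' Writes a commented provenance header (package version, configuration hash
#' if supplied, solver tolerances, seed) followed by the data with at least
#' 12 significant digits. Network time courses use the column names
#' `time_min`, `HR_uM`, `PLC_uM`, `Ca_uM`, `ppERK_nuc_uM`, `NFAT_NF`,
#' `Egr1_uM`; minimal-model time courses `time_min`, `E1_star`, `E2_star`,
#' `E3_star`.
#'
#' @param timecourse A tibble from [simulate_network()],
#'   [simulate_minimal()] or [simulate_reporter()].
#' @param path Output file path.
#' @param config Optional `run_config`; its hash and seed are recorded.
#' @param extra Named list of additional provenance entries.
#' @return The path, invisibly.
#' @export
write_timecourse <- function(timecourse, path, config = NULL, extra = list()) {
  prov <- extra
  if (!is.null(config)) {
    prov$config_hash <- attr(config, "hash")
    prov$seed <- config$seed
  }
  prov$rtol <- prov$rtol %||% 1e-8
  prov$atol <- prov$atol %||% 1e-12
  .write_prov_csv(tibble::as_tibble(timecourse), path, prov)
}

#' Write a scan result as CSV
#'
#' @inheritParams write_timecourse
#' @param scan A `scan_result` tibble.
#' @return The path, invisibly.
#' @export
write_scan <- function(scan, path, config = NULL, extra = list()) {
  write_timecourse(scan, path, config = config, extra = extra)
}

#' Read a provenance-carrying CSV written by this package
#'
#' @param path File path.
#' @return A tibble; the provenance lines are attached as attribute
#'   `provenance`.
#' @export
read_prov_csv <- function(path) {
  stop_if_not(file.exists(path), msg = sprintf("file not found: %s", path))
  lines <- readLines(path)
  prov <- lines[startsWith(lines, "# ")]
  body <- lines[!startsWith(lines, "# ")]
  if (length(body) <= 1) {
    df <- tibble::tibble()
  } else {
    df <- tibble::as_tibble(read.csv(text = paste(body, collapse = "\n"),
                                     check.names = FALSE))
  }
  attr(df, "provenance") <- sub("^# ", "", prov)
  df
}
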