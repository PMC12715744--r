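.schemas <- list(
  nutation = list(cols = c("t_pulse_us", "signal"), monotone = "t_pulse_us"),
  cpmg = list(cols = c("tau_s", "echo_index", "amplitude"), monotone = NULL),
  ope = list(cols = c("tau_s", "integral"), monotone = "tau_s"),
  injection = list(cols = c("series", "rep", "integral"), monotone = NULL)
)

# Column-name suffix -> factor converting to base SI (seconds, Hz)
.unit_factor <- function(name) {
  if (grepl("_us$", name)) 1e-6
  else if (grepl("_ms$", name)) 1e-3
  else 1
}

#' Read a validated analysis time series from CSV
#'
#' Comma-separated, `.` decimal, UTF-8, with exactly the schema's column
#' names. Time-like columns are converted to seconds according to their
#' unit suffix (`_us`, `_ms`, `_s`) and renamed accordingly, so downstream
#' fitters always see seconds.
#'
#' Schemas: `nutation` (`t_pulse_us`, `signal`), `cpmg` (`tau_s`,
#' `echo_index`, `amplitude`), `ope` (`tau_s`, `integral`), `injection`
#' (`series`, `rep`, `integral`).
#'
#' @param path CSV file path.
#' @param schema One of `"nutation"`, `"cpmg"`, `"ope"`, `"injection"`.
#' @return Data frame in the schema's layout (times in seconds).
#' @export
read_timeseries <- function(path, schema = c("nutation", "cpmg", "ope",
                                             "injection")) {
  schema <- match.arg(schema)
  sc <- .schemas[[schema]]
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  missing <- setdiff(sc$cols, names(df))
  if (length(missing)) {
    stop(sprintf("schema '%s': missing column(s) %s", schema,
                 paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), sc$cols)
  if (length(extra)) {
    stop(sprintf("schema '%s': unexpected column(s) %s", schema,
                 paste(extra, collapse = ", ")))
  }
  df <- df[sc$cols]
  if (!is.null(sc$monotone)) {
    if (any(diff(df[[sc$monotone]]) <= 0)) {
      stop(sprintf("column '%s' must be strictly increasing", sc$monotone))
    }
  }
  for (nm in names(df)) {
    f <- .unit_factor(nm)
    if (f != 1) {
      df[[nm]] <- df[[nm]] * f
      names(df)[names(df) == nm] <- sub("_(us|ms)$", "_s", nm)
    }
  }
  df
}

#' Write an analysis time series to CSV
#'
#' Inverse of [read_timeseries()]: data frames carrying seconds are written
#' with the schema's native column units (`t_pulse_us` for nutation).
#'
#' @param df Data frame (seconds layout, as produced by the generators).
#' @param path Output CSV path.
#' @param schema One of `"nutation"`, `"cpmg"`, `"ope"`, `"injection"`.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(df, path, schema = c("nutation", "cpmg", "ope",
                                                  "injection")) {
  schema <- match.arg(schema)
  out <- df
  if (schema == "nutation" && "t_pulse_s" %in% names(out)) {
    out$t_pulse_s <- out$t_pulse_s * 1e6
    names(out)[names(out) == "t_pulse_s"] <- "t_pulse_us"
  }
  sc <- .schemas[[schema]]
  if (!all(sc$cols %in% names(out))) {
    stop(sprintf("data frame does not match schema '%s'", schema))
  }
  utils::write.csv(out[sc$cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Read a spin system from a plain-text configuration file
#'
#' Minimal sectioned key-value format:
#' \preformatted{
#' [field]
#' b0_t = 0.4454
#' ref_freq_hz = 18717000
#' coupling = scalar
#'
#' [spins]
#' CH3 = 1.26
#' OCH2 = 4.12
#'
#' [couplings]
#' CH3 OCH2 = 7.1
#' }
#' Shifts are in ppm, couplings in Hz; `#` starts a comment. Spin order
#' follows the order of the `[spins]` section.
#'
#' @param path Configuration file path.
#' @return A `phip_spin_system`.
#' @export
read_spin_system <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  spins <- character(); shifts <- numeric()
  coups <- list()
  field <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- tolower(gsub("\\[|\\]", "", ln))
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (section == "field") {
      field[[tolower(key)]] <- val
    } else if (section == "spins") {
      spins <- c(spins, key)
      shifts <- c(shifts, as.numeric(val))
    } else if (section == "couplings") {
      pairnames <- strsplit(key, "[[:space:],]+")[[1]]
      if (length(pairnames) != 2L) stop("coupling key must name two spins: ", ln)
      coups[[length(coups) + 1L]] <- list(pair = pairnames,
                                          j = as.numeric(val))
    } else {
      stop("unknown section for line: ", ln)
    }
  }
  if (length(spins) == 0L) stop("no [spins] section")
  if (is.null(field$b0_t) || is.null(field$ref_freq_hz)) {
    stop("[field] must define b0_t and ref_freq_hz")
  }
  n <- length(spins)
  jm <- matrix(0, n, n)
  for (cp in coups) {
    i <- match(cp$pair[1], spins); k <- match(cp$pair[2], spins)
    if (is.na(i) || is.na(k)) stop("coupling names unknown spin: ",
                                   paste(cp$pair, collapse = " "))
    jm[i, k] <- cp$j; jm[k, i] <- cp$j
  }
  build_spin_system(shifts, jm,
                    b0 = as.numeric(field$b0_t),
                    ref_freq = as.numeric(field$ref_freq_hz),
                    labels = spins,
                    coupling = if (is.null(field$coupling)) "scalar"
                               else field$coupling)
}

#' Write an analysis report as JSON
#'
#' Serializes fitted parameters together with the package version and the
#' seed, so a report fully identifies the computation that produced it.
#' Output is deterministic (byte-identical for identical inputs and
#' package version).
#'
#' @param results Named list of results (must be serializable).
#' @param path Output path.
#' @param seed Optional integer seed recorded in the report.
#' @param config Optional named list of configuration values; a digest-like
#'   stable hash of its serialization is recorded.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, seed = NULL, config = NULL) {
  meta <- list(package = "phiptools",
               version = as.character(utils::packageVersion("phiptools")))
  if (!is.null(seed)) meta$seed <- as.integer(seed)
  if (!is.null(config)) {
    meta$config_hash <- sprintf("%08x", sum(utf8ToInt(
      jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)) *
        seq_along(utf8ToInt(jsonlite::toJSON(config, auto_unbox = TRUE,
                                             digits = NA)))) %% 4294967291)
    meta$config <- config
  }
  out <- list(meta = meta, results = results)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
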