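# Domain types and long-format I/O for fermentation time-course data.
#
# A dataset holds one series per (treatment, replicate, variable): the
# observed time course of yeast counts (log10 cfu/ml), brine pH, or
# titratable acidity (g lactic acid / 100 ml) over the fermentation.

#' Construct a fermentation series
#'
#' A series is one replicate's observed time course of one variable:
#' strictly ascending observation times (days) with matching values and a
#' missing-value mask. Missing observations (e.g. unquantified plate counts)
#' keep their time point but carry no value.
#'
#' @param treatment Treatment code (e.g. `"CC"`, `"CI"`).
#' @param replicate Positive integer replicate id.
#' @param variable Variable name (`"yeast"`, `"pH"`, `"acidity"`, or any string).
#' @param times Strictly ascending numeric vector of observation days (> 0).
#' @param values Numeric vector, same length as `times`; `NA` where missing.
#' @param missing Logical mask, same length; defaults to `is.na(values)`.
#' @return An object of class `ferm_series`.
#' @export
ferm_series <- function(treatment, replicate, variable, times, values,
                        missing = is.na(values)) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  missing <- as.logical(missing)
  if (length(times) != length(values) || length(times) != length(missing))
    stop("times, values and missing must share length")
  if (any(times <= 0)) stop("observation times must be positive (days)")
  if (any(diff(times) <= 0)) stop("observation times must be strictly ascending")
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L) stop("replicate must be a positive integer")
  values[missing] <- NA_real_
  structure(
    list(treatment = as.character(treatment), replicate = replicate,
         variable = as.character(variable), times = times, values = values,
         missing = missing),
    class = "ferm_series")
}

#' @export
print.ferm_series <- function(x, ...) {
  cat(sprintf("<ferm_series> %s / repl %d / %s: %d points (%d missing) on days [%g, %g]\n",
              x$treatment, x$replicate, x$variable, length(x$times),
              sum(x$missing), min(x$times), max(x$times)))
  invisible(x)
}

#' Number of non-missing observations in a series
#' @param series A `ferm_series`.
#' @return Integer count.
#' @export
n_usable <- function(series) sum(!series$missing)

series_key <- function(s) paste(s$treatment, s$replicate, s$variable, sep = "\r")

#' Construct a fermentation dataset
#'
#' Bundles a list of [ferm_series()] with a common closed time domain
#' (days). The domain must cover every observed time; series with fewer
#' than 3 non-missing points are kept but flagged unusable for smoothing
#' (with a warning).
#'
#' @param series List of `ferm_series` objects with unique
#'   (treatment, replicate, variable) keys.
#' @param domain Length-2 numeric `c(t_min, t_max)`; defaults to the range
#'   of observed times.
#' @return An object of class `ferm_dataset` with elements `series`,
#'   `domain`, and `unusable` (keys of series too sparse to smooth).
#' @export
ferm_dataset <- function(series = list(), domain = NULL) {
  stopifnot(is.list(series))
  for (s in series) if (!inherits(s, "ferm_series")) stop("all elements must be ferm_series")
  keys <- vapply(series, series_key, "")
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1]
    stop("duplicate series key: ", gsub("\r", "/", dup))
  }
  all_t <- unlist(lapply(series, `[[`, "times"))
  if (is.null(domain)) {
    domain <- if (length(all_t)) range(all_t) else c(0, 1)
  }
  domain <- as.numeric(domain)
  if (length(domain) != 2 || diff(domain) < 0) stop("domain must be c(t_min, t_max)")
  if (length(all_t) && (min(all_t) < domain[1] || max(all_t) > domain[2]))
    stop("domain does not cover all observed times")
  unusable <- keys[vapply(series, n_usable, 0L) < 3L]
  if (length(unusable))
    warning(length(unusable), " series have fewer than 3 non-missing points and cannot be smoothed")
  structure(list(series = series, domain = domain,
                 unusable = gsub("\r", "/", unusable)),
            class = "ferm_dataset")
}

#' @export
print.ferm_dataset <- function(x, ...) {
  cat(sprintf("<ferm_dataset> %d series on days [%g, %g]\n",
              length(x$series), x$domain[1], x$domain[2]))
  if (length(x$series)) {
    df <- as.data.frame(x)
    cat("  treatments:", paste(unique(df$treatment), collapse = ", "), "\n")
    cat("  variables: ", paste(unique(df$variable), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten a dataset to a long-format data frame
#'
#' @param x A `ferm_dataset`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data frame with columns `treatment`, `replicate`, `variable`,
#'   `time_days`, `value` (`NA` where missing), `missing`.
#' @export
as.data.frame.ferm_dataset <- function(x, row.names = NULL, optional = FALSE, ...) {
  if (!length(x$series))
    return(data.frame(treatment = character(), replicate = integer(),
                      variable = character(), time_days = numeric(),
                      value = numeric(), missing = logical()))
  do.call(rbind, lapply(x$series, function(s)
    data.frame(treatment = s$treatment, replicate = s$replicate,
               variable = s$variable, time_days = s$times, value = s$values,
               missing = s$missing, stringsAsFactors = FALSE)))
}

#' Extract series from a dataset
#'
#' @param dataset A `ferm_dataset`.
#' @param treatment,replicate,variable Optional filters; `NULL` keeps all.
#' @return List of matching `ferm_series` (possibly empty).
#' @export
get_series <- function(dataset, treatment = NULL, replicate = NULL, variable = NULL) {
  keep <- vapply(dataset$series, function(s) {
    (is.null(treatment) || s$treatment %in% treatment) &&
      (is.null(replicate) || s$replicate %in% replicate) &&
      (is.null(variable) || s$variable %in% variable)
  }, TRUE)
  dataset$series[keep]
}

#' Read a long-format time-course table
#'
#' Expects a CSV with one observation per row. A configurable sentinel
#' string (default `"nd"`) marks missing values; by default such rows
#' become flagged-missing observations excluded from smoothing and
#' statistics, or they can be replaced by a detection-limit value via
#' `nd_policy`.
#'
#' @param path CSV file path.
#' @param schema Named character vector mapping the canonical column names
#'   `treatment`, `replicate`, `variable`, `time`, `value` to the file's
#'   column names. Defaults to the package's long format
#'   (`treatment,replicate,variable,time_days,value`).
#' @param sentinel String marking a missing value. Default `"nd"`.
#' @param nd_policy Either `"missing"` (default: sentinel rows are flagged
#'   missing) or a single number: the detection-limit value substituted for
#'   every sentinel entry (rows then count as observed).
#' @param domain Optional `c(t_min, t_max)`; defaults to the observed range.
#' @return A [ferm_dataset()].
#' @export
read_long_table <- function(path,
                            schema = c(treatment = "treatment", replicate = "replicate",
                                       variable = "variable", time = "time_days",
                                       value = "value"),
                            sentinel = "nd", nd_policy = "missing", domain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(raw) == 0) return(ferm_dataset(list(), domain = domain))
  needed <- c("treatment", "replicate", "variable", "time", "value")
  miss <- needed[!schema[needed] %in% names(raw)]
  if (length(miss))
    stop("cannot resolve column(s) ", paste(schema[miss], collapse = ", "),
         " in ", path)
  df <- data.frame(treatment = raw[[schema["treatment"]]],
                   replicate = raw[[schema["replicate"]]],
                   variable = raw[[schema["variable"]]],
                   time = raw[[schema["time"]]],
                   value = raw[[schema["value"]]],
                   stringsAsFactors = FALSE)
  is_nd <- trimws(df$value) == sentinel
  val <- suppressWarnings(as.numeric(df$value))
  bad <- which(!is_nd & is.na(val))
  if (length(bad))
    stop("malformed value '", df$value[bad[1]], "' at data row ", bad[1],
         " of ", path)
  tm <- suppressWarnings(as.numeric(df$time))
  if (anyNA(tm)) stop("malformed time at data row ", which(is.na(tm))[1], " of ", path)
  if (!identical(nd_policy, "missing")) {
    if (!is.numeric(nd_policy) || length(nd_policy) != 1)
      stop("nd_policy must be \"missing\" or a single detection-limit number")
    val[is_nd] <- nd_policy
    is_nd[] <- FALSE
  }
  key <- paste(df$treatment, df$replicate, df$variable, df$time, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("duplicate observation key at data row ", d, ": ",
         gsub("\r", "/", key[d]))
  }
  grp <- paste(df$treatment, df$replicate, df$variable, sep = "\r")
  series <- lapply(split(seq_len(nrow(df)), grp), function(idx) {
    idx <- idx[order(tm[idx])]
    ferm_series(df$treatment[idx[1]], as.integer(df$replicate[idx[1]]),
                df$variable[idx[1]], tm[idx], val[idx], is_nd[idx])
  })
  names(series) <- NULL
  ferm_dataset(series, domain = domain)
}

#' Write a dataset as a long-format CSV
#'
#' Round-trip property: re-reading the file with [read_long_table()]
#' reproduces the dataset exactly (full-precision values, missing flags
#' preserved via the sentinel).
#'
#' @param dataset A `ferm_dataset`.
#' @param path Output CSV path.
#' @param sentinel String written for missing values. Default `"nd"`.
#' @return Invisibly, `path`.
#' @export
write_long_table <- function(dataset, path, sentinel = "nd") {
  df <- as.data.frame(dataset)
  out <- data.frame(treatment = df$treatment, replicate = df$replicate,
                    variable = df$variable, time_days = df$time_days,
                    value = ifelse(df$missing, sentinel,
                                   vapply(df$value, format, "", digits = 17)),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.fixture_files <- c(yeast = "yeast.csv", pH = "ph.csv", acidity = "acidity.csv")

#' Load the bundled olive-fermentation fixtures
#'
#' The package ships the full monitoring dataset of a 380-day *Aloreña de
#' Málaga* table-olive fermentation experiment: five treatments (CC, CI,
#' CII, CT, RT) times two replicate vessels, observed at days
#' 1, 15, 38, 52, 80, 137, 250 and 380 for yeast counts (log10 cfu/ml),
#' pH, and titratable acidity (g lactic acid / 100 ml). Two early yeast
#' counts (CI and CII, replicate 2, day 1) are unquantified and load as
#' missing by default.
#'
#' @param name One of `"yeast"`, `"pH"`, `"acidity"`, or `"all"`.
#' @param nd_policy Passed to [read_long_table()]: `"missing"` (default) or
#'   a detection-limit value substituted for unquantified counts.
#' @return A [ferm_dataset()] with domain `[1, 380]`.
#' @export
load_fixture <- function(name = c("all", "yeast", "pH", "acidity"),
                         nd_policy = "missing") {
  name <- match.arg(name)
  files <- if (name == "all") .fixture_files else .fixture_files[name]
  series <- list()
  for (f in files) {
    p <- system.file("extdata", f, package = "fermcurve", mustWork = TRUE)
    ds <- read_long_table(p, nd_policy = nd_policy, domain = c(1, 380))
    series <- c(series, ds$series)
  }
  suppressWarnings(ferm_dataset(series, domain = c(1, 380)))
}
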