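.rectHeader <- c("frequency_hz", "z_real_ohm", "z_imag_ohm")
.polarHeader <- c("frequency_hz", "z_mod_ohm", "phase_deg")

#' Read an impedance spectrum CSV
#'
#' Two dialects are auto-detected by header: rectangular
#' (\code{frequency_hz,z_real_ohm,z_imag_ohm}) and polar
#' (\code{frequency_hz,z_mod_ohm,phase_deg}, signed phase in degrees). Rows
#' must be in ascending frequency.
#'
#' @param path CSV file path.
#' @return an [ImpedanceSpectrum].
#' @export
readSpectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  if (identical(colnames(d), .rectHeader)) {
    zr <- d$z_real_ohm
    zi <- d$z_imag_ohm
  } else if (identical(colnames(d), .polarHeader)) {
    rect <- toRectangular(d$z_mod_ohm, d$phase_deg)
    zr <- rect$zReal
    zi <- rect$zImag
  } else {
    stop("format error in ", path, ": expected header '",
         paste(.rectHeader, collapse = ","), "' or '",
         paste(.polarHeader, collapse = ","), "'")
  }
  f <- d$frequency_hz
  if (any(diff(f) <= 0))
    stop("format error in ", path, ": frequencies must be strictly ascending")
  impedanceSpectrum(f, zr, zi)
}

#' Write an impedance spectrum CSV
#'
#' Values are written with 12 significant digits so write/read round trips
#' are stable and files are diffable.
#'
#' @param spectrum an [ImpedanceSpectrum].
#' @param path output file path.
#' @param dialect \code{"rectangular"} or \code{"polar"}.
#' @export
writeSpectrum <- function(spectrum, path,
                          dialect = c("rectangular", "polar")) {
  dialect <- match.arg(dialect)
  stopifnot(is(spectrum, "ImpedanceSpectrum"))
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  d <- if (dialect == "rectangular") {
    data.frame(frequency_hz = fmt(frequencies(spectrum)),
               z_real_ohm = fmt(zReal(spectrum)),
               z_imag_ohm = fmt(zImag(spectrum)))
  } else {
    data.frame(frequency_hz = fmt(frequencies(spectrum)),
               z_mod_ohm = fmt(zMod(spectrum)),
               phase_deg = fmt(zPhase(spectrum)))
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset manifest
#'
#' The manifest CSV (\code{sample_id,label_wt_percent,file}) lists one
#' spectrum file per sample; paths are resolved relative to the manifest
#' location. All spectra must share one frequency grid.
#'
#' @param path manifest CSV path.
#' @return an [EISExperiment].
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  need <- c("sample_id", "label_wt_percent", "file")
  if (!all(need %in% colnames(d)))
    stop("format error in ", path, ": expected columns ",
         paste(need, collapse = ", "))
  base <- dirname(path)
  files <- ifelse(file.exists(d$file), d$file, file.path(base, d$file))
  missing <- !file.exists(files)
  if (any(missing))
    stop("manifest references missing files: ",
         paste(d$file[missing], collapse = ", "))
  spectra <- lapply(files, readSpectrum)
  grid <- frequencies(spectra[[1L]])
  bad <- !vapply(spectra, function(s)
    isTRUE(all.equal(frequencies(s), grid)), logical(1))
  if (any(bad))
    stop("grid mismatch across files; offending sample_ids: ",
         paste(d$sample_id[bad], collapse = ", "))
  EISExperiment(spectra, d$label_wt_percent, sampleIds = d$sample_id)
}

#' Write a dataset as per-sample CSVs plus manifest
#'
#' Writes one spectrum CSV per sample, \code{manifest.csv}
#' (\code{sample_id,label_wt_percent,file}) and, when ground-truth circuit
#' parameters are present, \code{truth.csv}.
#'
#' @param experiment an [EISExperiment].
#' @param dir output directory (created if absent).
#' @param dialect spectrum CSV dialect.
#' @return the manifest path, invisibly.
#' @export
writeDataset <- function(experiment, dir,
                         dialect = c("rectangular", "polar")) {
  dialect <- match.arg(dialect)
  stopifnot(is(experiment, "EISExperiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- colnames(experiment)
  files <- sprintf("%s.csv", ids)
  for (i in seq_along(ids))
    writeSpectrum(getSpectrum(experiment, i), file.path(dir, files[i]),
                  dialect = dialect)
  utils::write.csv(
    data.frame(sample_id = ids,
               label_wt_percent = mineralContent(experiment),
               file = files),
    file.path(dir, "manifest.csv"), row.names = FALSE, quote = FALSE)
  tp <- trueParams(experiment)
  if (!is.null(tp))
    utils::write.csv(cbind(sample_id = ids, signif(tp, 12)),
                     file.path(dir, "truth.csv"), row.names = FALSE,
                     quote = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Serialize an evaluation report to JSON
#'
#' Pretty JSON with a stable key order (accuracy, precision, per_class,
#' confusion), suitable for diffing across runs.
#'
#' @param report an [EvaluationReport].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "EvaluationReport"))
  obj <- list(
    accuracy = accuracy(report),
    precision_weighted = precisionScore(report),
    precision_macro = precisionScore(report, "macro"),
    per_class = perClassMetrics(report),
    class_order = rownames(confusionMatrix(report)),
    confusion = unname(apply(confusionMatrix(report), 1L, identity,
                             simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a serialized evaluation report
#'
#' @param path JSON path written by [writeReport()].
#' @return an [EvaluationReport].
#' @export
readReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- matrix(as.integer(t(obj$confusion)),
               nrow = length(obj$class_order), byrow = FALSE,
               dimnames = list(actual = obj$class_order,
                               predicted = obj$class_order))
  cm <- t(cm)
  dimnames(cm) <- list(actual = obj$class_order,
                       predicted = obj$class_order)
  new("EvaluationReport", accuracy = obj$accuracy,
      precisionWeighted = obj$precision_weighted,
      precisionMacro = obj$precision_macro, confusion = cm,
      perClass = as.data.frame(obj$per_class))
}

# Known flat-config keys and their parsers.
.runConfigKeys <- list(
  seed = as.integer, n_per_class = function(x)
    as.integer(strsplit(x, ";")[[1L]]),
  param_cv = as.numeric, noise_sd = as.numeric,
  f_min = as.numeric, f_max = as.numeric, n_points = as.integer,
  alpha = as.numeric, variance_threshold = as.numeric,
  n_restarts = as.integer, weighting = identity,
  feature_mode = identity, out_dir = identity)

#' Read a flat key=value run configuration
#'
#' One \code{key = value} pair per line; blank lines and \code{#} comments
#' are ignored; unknown keys are rejected with a message naming them.
#' Multi-valued entries (e.g. \code{n_per_class}) use \code{;} separators.
#'
#' @param path config file path.
#' @return named list of parsed settings.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop("format error: expected 'key = value', got: ", ln)
    key <- trimws(kv[1L])
    if (!key %in% names(.runConfigKeys))
      stop("unknown config key '", key, "'; known keys: ",
           paste(names(.runConfigKeys), collapse = ", "))
    out[[key]] <- .runConfigKeys[[key]](trimws(kv[2L]))
  }
  out
}
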