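# numeric formatting shared by all writers: 6 significant digits so
# re-running an identical configuration gives byte-identical files
.fmt <- function(x) {
  vapply(x, function(v) format(signif(v, 6), scientific = FALSE,
                               trim = TRUE), character(1))
}

# natural sort: "frame2.png" before "frame10.png"
.naturalSort <- function(paths) {
  base <- basename(paths)
  num <- suppressWarnings(as.numeric(gsub("\\D", "", base)))
  ord <- order(is.na(num), num, base)
  paths[ord]
}

# luminance grayscale conversion for RGB(A) arrays from png::readPNG
.toGray <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
}

#' Read a time-lapse image stack
#'
#' Reads either a multi-page grayscale TIFF or a directory (or vector) of
#' numbered PNG frames in natural sort order (frame2 before frame10). RGB
#' input is converted to grayscale by luminance. Intensities are returned
#' as 8-bit levels (0..255).
#'
#' @param path a multi-page TIFF file, a directory of PNG frames, or a
#'   character vector of frame files.
#' @param frameInterval seconds per frame; default 30 (the standard
#'   acquisition cadence) when the source carries no metadata.
#' @param startTime acquisition start (h).
#' @return An [ImageStack-class].
#' @export
readImageStack <- function(path, frameInterval = 30, startTime = 0) {
  if (length(path) == 1L && dir.exists(path))
    path <- list.files(path, pattern = "\\.(png|PNG)$", full.names = TRUE)
  if (length(path) == 1L && grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    frames <- lapply(pages, function(p) {
      p <- .toGray(p)
      if (max(p) <= 1) p * 255 else p
    })
  } else {
    path <- .naturalSort(path)
    frames <- lapply(path, function(f) {
      round(.toGray(png::readPNG(f)) * 255)
    })
  }
  if (length(frames) < 2L) stop("an image stack needs at least 2 frames")
  imageStack(frames, frameInterval = frameInterval, startTime = startTime,
             metadata = list(source = as.character(path)[1]))
}

#' Write an image stack as a multi-page 8-bit grayscale TIFF
#'
#' @param stack an [ImageStack-class] with intensities in 0..255.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeImageStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  n <- nFrames(stack)
  pages <- lapply(seq_len(n), function(i) getFrame(stack, i) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Read and write cumulative activity curves as CSV
#'
#' The curve CSV schema is two columns, `time_h` and `ca_au`. The writer
#' emits a JSON sidecar `<path>.json` recording the scale and window.
#'
#' @param path CSV file.
#' @param curve a [CumulativeActivityCurve-class].
#' @param sidecar list of extra provenance fields for the sidecar (e.g.
#'   threshold, ROI hash, k, frame interval); NULL suppresses the sidecar.
#' @return `readCurveCSV` returns a [CumulativeActivityCurve-class];
#'   `writeCurveCSV` invisibly returns `path`.
#' @export
readCurveCSV <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_h", "ca_au") %in% names(d)))
    stop("curve CSV must have columns time_h and ca_au: ", path)
  caCurve(d$time_h, d$ca_au)
}

#' @rdname readCurveCSV
#' @export
writeCurveCSV <- function(curve, path, sidecar = list()) {
  stopifnot(is(curve, "CumulativeActivityCurve"))
  d <- data.frame(time_h = .fmt(curve@times), ca_au = .fmt(curve@ca))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  if (!is.null(sidecar)) {
    sidecar$scale <- curve@scale
    sidecar$window_end_h <- curve@windowEnd
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write an activity series as CSV with a JSON sidecar
#'
#' Columns `time_h`, `count`; the sidecar records the threshold, total
#' pixels and any extra provenance supplied.
#'
#' @param series an [ActivitySeries-class].
#' @param path CSV file.
#' @param sidecar list of extra provenance fields.
#' @return Invisibly, `path`.
#' @export
writeActivityCSV <- function(series, path, sidecar = list()) {
  stopifnot(is(series, "ActivitySeries"))
  d <- data.frame(time_h = .fmt(series@times), count = .fmt(series@counts))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  sidecar$threshold <- series@threshold
  sidecar$n_pixels <- series@nPixels
  if (!is.null(series@roi))
    sidecar$roi_hash <- .hashObject(series@roi)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Serialize a fit result
#'
#' `fitResultRow` flattens a [TwoPhaseFit-class] into the one-row CSV
#' schema (condition, replicate, cIA, cCA, tx, tp, tc, tg, tc_censored,
#' colonization_absent, rel_colonization, rmse, r2); `writeFitCSV` writes
#' one row per fit; `writeFitJSON` writes the full result as JSON;
#' `readFitCSV` reads the CSV back.
#'
#' @param fit a [TwoPhaseFit-class].
#' @param condition,replicate labels recorded in the row.
#' @return `fitResultRow` a one-row data.frame.
#' @export
fitResultRow <- function(fit, condition = "cond", replicate = 1L) {
  stopifnot(is(fit, "TwoPhaseFit"))
  v <- paramVector(fit)
  data.frame(condition = condition, replicate = replicate,
             cIA = v[["cIA"]], cCA = v[["cCA"]], tx = v[["tx"]],
             tp = v[["tp"]], tc = v[["tc"]], tg = v[["tg"]],
             tc_censored = tcCensored(fit),
             colonization_absent = colonizationAbsent(fit),
             rel_colonization = relativeColonization(fit),
             rmse = fit@rmse, r2 = fit@rSquared,
             stringsAsFactors = FALSE)
}

#' @rdname fitResultRow
#' @param fits list of fits (or a single fit).
#' @param path output file.
#' @param conditions,replicates label vectors recycled over `fits`.
#' @export
writeFitCSV <- function(fits, path, conditions = "cond",
                        replicates = seq_along(fits)) {
  if (is(fits, "TwoPhaseFit")) fits <- list(fits)
  conditions <- rep_len(conditions, length(fits))
  rows <- do.call(rbind, Map(fitResultRow, fits, conditions, replicates))
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], .fmt)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname fitResultRow
#' @export
readFitCSV <- function(path) utils::read.csv(path)

#' @rdname fitResultRow
#' @export
writeFitJSON <- function(fit, path, condition = "cond") {
  stopifnot(is(fit, "TwoPhaseFit"))
  v <- as.list(paramVector(fit))
  jsonlite::write_json(
    list(condition = condition, params = v,
         raw_params = as.list(paramVector(rawParams(fit))),
         tc_censored = tcCensored(fit),
         colonization_absent = colonizationAbsent(fit),
         window_end_h = windowEnd(fit),
         rel_colonization = relativeColonization(fit),
         rmse = fit@rmse, r2 = fit@rSquared, n_points = fit@nPoints,
         converged = converged(fit), bounds_hit = fit@boundsHit,
         notes = fit@notes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a condition-by-parameter summary table
#'
#' Produces a wide table (conditions as columns, parameters as rows,
#' "mean ± dispersion" strings, censored rows as ">window") plus the
#' machine-readable long-format companion from [aggregateFits()].
#'
#' @param summaries list of data.frames from [aggregateFits()].
#' @param path output CSV; the long-format companion goes to
#'   `<path basename>_long.csv`.
#' @return Invisibly, `path`.
#' @export
writeSummaryTable <- function(summaries, path) {
  long <- do.call(rbind, summaries)
  wide <- stats::reshape(long[, c("metric", "condition", "display")],
                         idvar = "metric", timevar = "condition",
                         direction = "wide")
  names(wide) <- sub("^display\\.", "", names(wide))
  utils::write.csv(wide, path, row.names = FALSE)
  longPath <- sub("\\.csv$", "_long.csv", path)
  if (longPath == path) longPath <- paste0(path, "_long.csv")
  num <- vapply(long, is.numeric, logical(1))
  long[num] <- lapply(long[num], .fmt)
  utils::write.csv(long, longPath, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write compact letter display assignments
#'
#' @param comparison output of [compareConditions()].
#' @param path output CSV with columns condition, metric, letters.
#' @return Invisibly, `path`.
#' @export
writeLettersCSV <- function(comparison, path) {
  d <- data.frame(condition = comparison$condition,
                  metric = attr(comparison, "metric"),
                  letters = comparison$letters)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# recursively flatten S4 objects (scene specs, parameter sets) into plain
# lists so configurations serialize to JSON
.jsonSafe <- function(x) {
  if (isVirtualClass(class(x)[1]) || !isS4(x)) {
    if (is.list(x)) return(lapply(x, .jsonSafe))
    return(x)
  }
  out <- lapply(methods::slotNames(class(x)), function(s) slot(x, s))
  names(out) <- methods::slotNames(class(x))
  lapply(out, .jsonSafe)
}

# md5 of any R object via its serialization to a temp file
.hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' Write a run manifest
#'
#' Records the tool version, a hash of the configuration, hashes of input
#' files, a timestamp, and the per-stage numeric decisions (threshold, ROI
#' hash, bounds, seeds, optimizer settings) so a run can be audited and
#' reproduced.
#'
#' @param path output JSON file.
#' @param config the run configuration list.
#' @param inputs character vector of input file paths to hash.
#' @param stages named list of per-stage parameter records.
#' @return Invisibly, the manifest list.
#' @export
writeManifest <- function(path, config, inputs = character(0),
                          stages = list()) {
  manifest <- list(
    tool = "amoebaCA",
    version = as.character(utils::packageVersion("amoebaCA")),
    config_hash = .hashObject(config),
    config = .jsonSafe(config),
    input_hashes = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = stages)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
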