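# Training diagnostics: loss-curve overfitting analysis and the
# consolidated, deterministic training/QC report (markdown + JSON twin).

#' Read loss curves from a CSV log
#'
#' Expects columns `epoch`, `train_loss`, `val_loss` (extra columns are
#' ignored).
#'
#' @param path CSV path.
#' @return list with `epochs`, `train_loss`, `val_loss`.
#' @export
readLossCurves <- function(path) {
  df <- utils::read.csv(path)
  need <- c("epoch", "train_loss", "val_loss")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  list(epochs = df$epoch, train_loss = df$train_loss,
       val_loss = df$val_loss)
}

#' Detect overfitting from training/validation loss curves
#'
#' A model overfits when the validation loss rebounds from its minimum
#' while the training loss keeps falling: the verdict is
#' `final val > (1 + delta) * min val` AND
#' `final train <= train at the argmin epoch`.  The argmin epoch of the
#' validation loss is recommended as the best checkpoint.  The verdict is
#' invariant to positive rescaling of both curves.
#'
#' @param curves list with `epochs`, `train_loss`, `val_loss` (equal
#'   lengths >= 2, finite values), e.g. from [readLossCurves()].
#' @param delta relative tolerance on the validation-loss rebound
#'   (default 0.05).
#' @return list of class `"LossVerdict"`: `overfit`, `best_epoch`,
#'   `min_val_loss`, `final_val_loss`, `rebound_ratio`, `delta`.
#' @export
analyzeLoss <- function(curves, delta = 0.05) {
  stopifnot(delta > 0)
  ep <- curves$epochs; tl <- curves$train_loss; vl <- curves$val_loss
  if (length(ep) < 2L || length(tl) != length(ep) || length(vl) != length(ep)) {
    stop("curves must hold equal-length epoch/train/val sequences (>= 2)")
  }
  bad <- which(!is.finite(tl) | !is.finite(vl))
  if (length(bad)) {
    stop("non-finite loss at epoch ", ep[bad[1L]])
  }
  iMin <- which.min(vl)
  n <- length(vl)
  ratio <- vl[n] / vl[iMin]
  overfit <- (vl[n] > (1 + delta) * vl[iMin]) && (tl[n] <= tl[iMin])
  out <- list(overfit = overfit, best_epoch = ep[iMin],
              min_val_loss = vl[iMin], final_val_loss = vl[n],
              rebound_ratio = ratio, delta = delta)
  class(out) <- "LossVerdict"
  out
}

#' @export
print.LossVerdict <- function(x, ...) {
  cat(sprintf(
    "Loss analysis: %s (final/min val loss %.3f, delta %.2f); best epoch %s\n",
    if (x$overfit) "OVERFITTING" else "no overfitting detected",
    x$rebound_ratio, x$delta, format(x$best_epoch)))
  invisible(x)
}

# render one flat key-value set as markdown bullet lines, keys sorted
mdKeyValues <- function(x) {
  if (!length(x)) return("  (none)")
  keys <- sort(names(x))
  vapply(keys, function(k) {
    v <- x[[k]]
    v <- if (is.numeric(v)) paste(format(v, digits = 10), collapse = ", ")
         else paste(as.character(v), collapse = ", ")
    sprintf("- **%s**: %s", k, v)
  }, character(1L))
}

#' Build the consolidated training/QC report
#'
#' Collects every training parameter and QC scalar (with the configuration
#' it was computed under: thresholds, confidences, normalisation modes,
#' seeds) into a deterministic human-readable markdown document and a JSON
#' twin holding the same content.  Apart from the single timestamp line,
#' two runs with identical inputs produce byte-identical reports, so the
#' markdown can be pasted into a Methods section and the JSON diffed across
#' runs.
#'
#' @param config named list of training/run parameters, reported verbatim.
#' @param qc named list of QC result blocks; each element is a named list
#'   of scalars (e.g. `list(restoration = list(mssim_tp = 0.9, ...))`).
#' @param lossVerdict optional result of [analyzeLoss()].
#' @param timestamp report timestamp; pass a fixed string for byte-stable
#'   output.
#' @return list of class `"TrainingReport"` with `markdown` (character
#'   vector of lines) and `json` (the report as a list, serialisable with
#'   [writeReport()]).
#' @export
buildReport <- function(config = list(), qc = list(), lossVerdict = NULL,
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  ver <- as.character(utils::packageVersion("microQC"))
  scalarise <- function(block) {
    block <- block[vapply(block, function(v)
      is.atomic(v) && length(v) == 1L, logical(1L))]
    lapply(block, function(v) {
      if (is.numeric(v) || is.logical(v)) unname(v) else as.character(v)
    })
  }
  qcFlat <- lapply(qc, scalarise)
  json <- list(report_version = 1L, toolkit = "microQC",
               toolkit_version = ver, timestamp = timestamp,
               parameters = config, qc = qcFlat)
  md <- c("# Training and quality-control report", "",
          sprintf("Generated by microQC %s.", ver),
          sprintf("Timestamp: %s", timestamp), "",
          "## Training parameters", "", mdKeyValues(config), "")
  for (section in names(qcFlat)) {
    md <- c(md, sprintf("## QC: %s", section), "",
            mdKeyValues(qcFlat[[section]]), "")
  }
  if (!is.null(lossVerdict)) {
    json$loss <- lossVerdict[c("overfit", "best_epoch", "min_val_loss",
                               "final_val_loss", "rebound_ratio", "delta")]
    md <- c(md, "## Loss-curve analysis", "",
            mdKeyValues(json$loss), "")
  }
  out <- list(markdown = md, json = json)
  class(out) <- "TrainingReport"
  out
}

#' Write a training report to disk
#'
#' Writes `report.md` and `report.json` under `dir`.
#'
#' @param report a `TrainingReport` from [buildReport()].
#' @param dir output directory (created if absent).
#' @return the two file paths, invisibly.
#' @export
writeReport <- function(report, dir) {
  stopifnot(inherits(report, "TrainingReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mdPath <- file.path(dir, "report.md")
  jsonPath <- file.path(dir, "report.json")
  writeLines(report$markdown, mdPath)
  jsonlite::write_json(report$json, jsonPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(mdPath, jsonPath))
}

#' Check a report JSON structure
#'
#' Validates the structural contract of the report JSON twin (shipped as
#' `inst/schema/report-schema.json`): required top-level fields, their
#' types, and that every QC entry is a flat name/scalar map.
#'
#' @param json a report list (from [buildReport()] or re-read from disk).
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validateReport <- function(json) {
  need <- c("report_version", "toolkit", "toolkit_version", "timestamp",
            "parameters", "qc")
  miss <- setdiff(need, names(json))
  if (length(miss)) stop("report missing field(s): ",
                         paste(miss, collapse = ", "))
  if (!is.list(json$qc)) stop("qc must be an object")
  for (section in names(json$qc)) {
    block <- json$qc[[section]]
    ok <- vapply(block, function(v) is.atomic(v) && length(v) == 1L,
                 logical(1L))
    if (!all(ok)) stop("qc section '", section, "' must contain scalars only")
  }
  invisible(TRUE)
}
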