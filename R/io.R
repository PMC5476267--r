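# Plain-text model archives (TSV matrices + JSON metadata sidecar) and
# report serialization.

.writeMatrix <- function(M, path) {
  utils::write.table(M, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
}

.readMatrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Save / load an NMF model archive
#'
#' The archive is a directory holding \code{W.tsv} and \code{H.tsv} plus a
#' \code{meta.json} sidecar with the matrix shapes, divergence trace and
#' the configuration (including the seed), so a factorization can be
#' reloaded for feature extraction.
#'
#' @param model an \linkS4class{NMFModel}.
#' @param dir archive directory (created if missing).
#' @return \code{dir} (save) or the reloaded \linkS4class{NMFModel}
#'   (load), invisibly for save.
#' @export
saveNMFModel <- function(model, dir) {
  stopifnot(methods::is(model, "NMFModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeMatrix(model@W, file.path(dir, "W.tsv"))
  .writeMatrix(model@H, file.path(dir, "H.tsv"))
  meta <- list(type = "NMFModel",
               shapeW = dim(model@W), shapeH = dim(model@H),
               divergenceTrace = model@divergenceTrace,
               config = model@config)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname saveNMFModel
#' @export
loadNMFModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$type, "NMFModel")) stop("not an NMFModel archive: ", dir)
  methods::new("NMFModel",
               W = .readMatrix(file.path(dir, "W.tsv")),
               H = .readMatrix(file.path(dir, "H.tsv")),
               divergenceTrace = as.numeric(meta$divergenceTrace),
               config = as.list(meta$config))
}

#' Save / load a filter bank archive
#'
#' @param bank a \linkS4class{FilterBank}.
#' @param dir archive directory.
#' @return \code{dir}, or the reloaded \linkS4class{FilterBank}.
#' @export
saveFilterBank <- function(bank, dir) {
  stopifnot(methods::is(bank, "FilterBank"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeMatrix(bank@filters, file.path(dir, "filters.tsv"))
  jsonlite::write_json(list(type = "FilterBank", kind = bank@kind,
                            freqs = bank@freqs),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname saveFilterBank
#' @export
loadFilterBank <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$type, "FilterBank")) {
    stop("not a FilterBank archive: ", dir)
  }
  methods::new("FilterBank",
               filters = .readMatrix(file.path(dir, "filters.tsv")),
               kind = meta$kind, freqs = as.numeric(meta$freqs))
}

#' Save / load a per-class SBV model archive
#'
#' @param model an \linkS4class{SbvModel}.
#' @param dir archive directory.
#' @return \code{dir}, or the reloaded \linkS4class{SbvModel}.
#' @export
saveSbvModel <- function(model, dir) {
  stopifnot(methods::is(model, "SbvModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeMatrix(model@Wbs, file.path(dir, "Wbs.tsv"))
  jsonlite::write_json(list(type = "SbvModel",
                            classLabels = model@classLabels,
                            KPerClass = model@KPerClass),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname saveSbvModel
#' @export
loadSbvModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$type, "SbvModel")) stop("not an SbvModel archive: ", dir)
  methods::new("SbvModel",
               Wbs = .readMatrix(file.path(dir, "Wbs.tsv")),
               classLabels = as.character(meta$classLabels),
               KPerClass = as.integer(meta$KPerClass))
}

#' Write short-time or segmental features to CSV
#'
#' @param x a \linkS4class{ShortTimeFeatures} or a segmental feature
#'   data.frame/matrix with named columns.
#' @param path output CSV path; the header row names the layout.
#' @return \code{path}, invisibly.
#' @export
writeFeatures <- function(x, path) {
  df <- if (methods::is(x, "ShortTimeFeatures")) {
    as.data.frame(x@X)
  } else {
    as.data.frame(x)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize an evaluation report
#'
#' \code{writeReport} stores the full report (accuracies, confusion
#' matrix, fold bookkeeping, resolved configuration) as JSON;
#' \code{writeReportTables} renders per-fold, per-species and confusion
#' CSV tables alongside.
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
  stopifnot(methods::is(report, "EvaluationReport"))
  out <- list(frontend = report@frontend,
              overallAccuracy = report@overallAccuracy,
              foldAccuracy = report@foldAccuracy,
              speciesAccuracy = as.list(report@speciesAccuracy),
              confusion = list(classes = colnames(report@confusion),
                               percent = report@confusion),
              folds = report@folds,
              config = report@config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeReport
#' @param dir output directory for the CSV tables.
#' @export
writeReportTables <- function(report, dir) {
  stopifnot(methods::is(report, "EvaluationReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(fold = seq_along(report@foldAccuracy),
                              accuracy = report@foldAccuracy),
                   file.path(dir, "per_fold.csv"), row.names = FALSE)
  utils::write.csv(data.frame(species = names(report@speciesAccuracy),
                              accuracy = as.numeric(report@speciesAccuracy)),
                   file.path(dir, "per_species.csv"), row.names = FALSE)
  conf <- as.data.frame(report@confusion)
  conf <- cbind(hypothesized = rownames(report@confusion), conf)
  utils::write.csv(conf, file.path(dir, "confusion.csv"), row.names = FALSE)
  invisible(dir)
}
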