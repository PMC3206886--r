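# File formats and table IO: delimited time-series / matrix exchange with
# provenance headers, and the validated subject table.

.pkgVersion <- function() {
  as.character(utils::packageVersion("restnet"))
}

# small polynomial checksum so every output can carry a config fingerprint
.configHash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.provenanceLine <- function(stage, hash) {
  sprintf("# stage=%s package=restnet/%s config=%s", stage, .pkgVersion(),
          hash)
}

.writeTableWithHeader <- function(df, path, stage, hash, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceLine(stage, hash), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Write / read a regions x time series file
#'
#' Plain TSV with a provenance comment line, a header row, a leading
#' \code{region} column and one column per timepoint. The round trip
#' \code{readRoiTimeSeries(writeRoiTimeSeries(x))} reproduces the object.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param path output file.
#' @param stage,hash provenance fields stamped into the header comment.
#' @return \code{writeRoiTimeSeries} returns \code{path} invisibly;
#'   \code{readRoiTimeSeries} returns a \linkS4class{RoiTimeSeries}.
#' @export
writeRoiTimeSeries <- function(ts, path, stage = "export", hash = "none") {
  df <- data.frame(region = ts@regionLabels, ts@data, check.names = FALSE)
  colnames(df) <- c("region", sprintf("t%04d", seq_len(ncol(ts@data))))
  .writeTableWithHeader(df, path, stage, hash)
  invisible(path)
}

#' @rdname writeRoiTimeSeries
#' @param trSeconds sampling interval to attach on read (default 2).
#' @export
readRoiTimeSeries <- function(path, trSeconds = 2) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  stopifnot("region" %in% colnames(df))
  mat <- as.matrix(df[, setdiff(colnames(df), "region"), drop = FALSE])
  RoiTimeSeries(mat, df$region, trSeconds)
}

#' Write a square labeled matrix as TSV
#'
#' @param mat square matrix with row/column labels.
#' @param path output file.
#' @param stage,hash provenance fields.
#' @return \code{path}, invisibly.
#' @export
writeMatrixTsv <- function(mat, path, stage = "export", hash = "none") {
  df <- data.frame(region = rownames(mat), mat, check.names = FALSE)
  colnames(df) <- c("region", colnames(mat))
  .writeTableWithHeader(df, path, stage, hash)
  invisible(path)
}

#' @rdname writeMatrixTsv
#' @export
readMatrixTsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

.sexAliases <- c(female = "female", f = "female", male = "male", m = "male")
.groupAliases <- c(control = "control", hc = "control", healthy = "control",
                   patient = "patient", pm = "patient", migraine = "patient")

#' Read and validate a subject table
#'
#' Requires columns \code{subject_id}, \code{sex}, \code{group} and
#' \code{age}; clinical columns (\code{disease_duration},
#' \code{attack_frequency}, \code{attack_duration}, \code{pain_intensity})
#' are optional. Sex values like "F"/"female" and group values like
#' "HC"/"control"/"PM" are normalized to the canonical
#' \code{female/male} and \code{control/patient}. Duplicate subject ids or
#' unknown categories are errors naming the offending cell.
#'
#' @param path CSV file.
#' @return Validated data.frame.
#' @export
readSubjectTable <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("subject_id", "sex", "group", "age")
  miss <- setdiff(required, colnames(df))
  if (length(miss))
    stop("subject table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  norm <- function(vals, aliases, what) {
    key <- tolower(trimws(vals))
    out <- aliases[key]
    bad <- which(is.na(out))
    if (length(bad))
      stop(sprintf("unknown %s value '%s' for subject %s", what,
                   vals[bad[1]], df$subject_id[bad[1]]))
    unname(out)
  }
  df$sex <- norm(df$sex, .sexAliases, "sex")
  df$group <- norm(df$group, .groupAliases, "group")
  if (any(!is.finite(df$age) | df$age <= 0))
    stop("age must be positive for every subject")
  for (col in c("disease_duration", "attack_frequency", "attack_duration",
                "pain_intensity")) {
    if (!col %in% colnames(df)) df[[col]] <- NA_real_
  }
  df
}

#' Write a subject table (round-trips with readSubjectTable)
#' @param subjects data.frame as produced by \code{\link{generateCohort}}.
#' @param path output CSV.
#' @param stage,hash provenance fields.
#' @return \code{path}, invisibly.
#' @export
writeSubjectTable <- function(subjects, path, stage = "simulate",
                              hash = "none") {
  .writeTableWithHeader(subjects, path, stage, hash, sep = ",")
  invisible(path)
}

#' Write a cohort to a directory tree
#'
#' Emits the interchange layout every downstream stage reads: one
#' \code{subjects.csv}, one regions x time TSV per subject under
#' \code{timeseries/}, one 8-row nuisance TSV per subject under
#' \code{nuisance/}, and a JSON echo of the generating configuration.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  cfgList <- .configAsList(cohort@config)
  hash <- .configHash(cfgList)
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "nuisance"), showWarnings = FALSE)
  writeSubjectTable(cohort@subjects, file.path(dir, "subjects.csv"),
                    "simulate", hash)
  for (id in cohort@subjects$subject_id) {
    writeRoiTimeSeries(cohort@series[[id]],
                       file.path(dir, "timeseries", paste0(id, ".tsv")),
                       "simulate", hash)
    nu <- cohort@nuisance[[id]]
    nmat <- rbind(nu@motion, wm = nu@wmSignal, csf = nu@csfSignal)
    writeRoiTimeSeries(RoiTimeSeries(nmat, rownames(nmat),
                                     cohort@config@trSeconds),
                       file.path(dir, "nuisance", paste0(id, ".tsv")),
                       "simulate", hash)
  }
  jsonlite::write_json(cfgList, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = 12)
  invisible(dir)
}

.configAsList <- function(config) {
  slots <- slotNames(class(config))
  out <- lapply(slots, function(s) slot(config, s))
  names(out) <- slots
  out
}
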