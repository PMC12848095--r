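#' Read longitudinal karyotype counts from CSV
#'
#' Expects a header with columns `time_days`, `karyotype`, `count`.
#' Duplicate (time, karyotype) rows are summed with a warning; malformed
#' karyotypes and negative counts are reported with their row number.
#'
#' @param path CSV file path.
#' @return A [KaryoCounts-class] object.
#' @export
readKaryoCounts <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_days", "karyotype", "count")
  if (!all(need %in% colnames(df)))
    stop("counts file must have columns: ", paste(need, collapse = ", "))
  bad <- which(is.na(df$count) | df$count < 0 | df$count != round(df$count))
  if (length(bad))
    stop("invalid count at row ", bad[1L] + 1L, " of ", path)
  for (i in seq_len(nrow(df))) {
    ok <- try(parseKaryotype(df$karyotype[i]), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("malformed karyotype at row ", i + 1L, " of ", path, ": ",
           df$karyotype[i])
  }
  key <- paste(df$time_days, df$karyotype)
  if (anyDuplicated(key)) {
    warning("duplicate (time, karyotype) rows summed")
    df <- aggregate(count ~ time_days + karyotype, df, sum)
  }
  ts <- sort(unique(df$time_days))
  ks <- unique(df$karyotype)
  m <- matrix(0L, length(ks), length(ts), dimnames = list(ks, NULL))
  m[cbind(match(df$karyotype, ks), match(df$time_days, ts))] <-
    as.integer(df$count)
  KaryoCounts(m, ts)
}

#' Write longitudinal karyotype counts to CSV
#'
#' @param x a [KaryoCounts-class] object.
#' @param path output CSV path.
#' @export
writeKaryoCounts <- function(x, path) {
  m <- countsMatrix(x)
  ts <- passageTimes(x)
  df <- do.call(rbind, lapply(seq_along(ts), function(j) {
    nz <- m[, j] > 0
    data.frame(time_days = ts[j], karyotype = rownames(m)[nz],
               count = m[nz, j], row.names = NULL)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

LANDSCAPE_FORMAT_VERSION <- "1"

#' Write a fitted landscape's look-up table to disk
#'
#' Writes a CSV (karyotype, mean_fitness, sd, source) plus a JSON sidecar
#' (`<path>.json`) carrying the CV score, configuration and format version.
#'
#' @param fit a [FittedLandscape-class] object.
#' @param path output CSV path.
#' @export
writeLandscape <- function(fit, path) {
  write.csv(fit@lut, path, row.names = FALSE, quote = FALSE)
  meta <- list(version = LANDSCAPE_FORMAT_VERSION, cv_score = fit@cvScore,
               n_frequent = length(fit@frequent), config = fit@config)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a landscape look-up table from disk
#'
#' @param path CSV path written by [writeLandscape()].
#' @param policy out-of-table policy for the returned landscape.
#' @return A [LUTLandscape-class] with attributes `cvScore`, `config`,
#'   `source` (per-karyotype provenance) when the sidecar is present; a
#'   missing sidecar loads the table with a warning and default metadata.
#' @export
readLandscape <- function(path, policy = "lethal") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("karyotype", "mean_fitness", "sd", "source")
  if (!all(need %in% colnames(df)))
    stop("landscape file must have columns: ", paste(need, collapse = ", "))
  okSrc <- c("frequent", "neighbor", "interpolated")
  if (!all(df$source %in% okSrc))
    stop("unknown source tag: ",
         paste(setdiff(unique(df$source), okSrc), collapse = ", "))
  lut <- LUTLandscape(setNames(df$mean_fitness, df$karyotype),
                      policy = policy)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!identical(as.character(meta$version), LANDSCAPE_FORMAT_VERSION))
      warning("landscape format version mismatch: file has ", meta$version)
    attr(lut, "cvScore") <- meta$cv_score
    attr(lut, "config") <- meta$config
  } else {
    warning("no sidecar metadata (", side, "); loading table with defaults")
    attr(lut, "cvScore") <- NA_real_
  }
  attr(lut, "sd") <- setNames(df$sd, df$karyotype)
  attr(lut, "source") <- setNames(df$source, df$karyotype)
  lut
}
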