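#' @include sweep.R
NULL

## Sweep text format: '#'-prefixed key=value metadata lines followed by a
## whitespace-separated table with header time_ms voltage_mV current_pA.

#' Write a Sweep to a text file
#'
#' @param sweep a \linkS4class{Sweep}
#' @param path output file
#' @return \code{path}, invisibly
#' @seealso \code{\link{readSweep}}
#' @export
writeSweep <- function(sweep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(sweep@meta)) {
    v <- sweep@meta[[k]]
    if (is.numeric(v)) v <- format(v, digits = 17)
    writeLines(sprintf("# %s=%s", k, paste(v, collapse = ",")), con)
  }
  writeLines("time_ms\tvoltage_mV\tcurrent_pA", con)
  utils::write.table(
    data.frame(format(sweep@time, digits = 17),
               format(sweep@voltage, digits = 17),
               format(sweep@current, digits = 17)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a Sweep from a text file
#'
#' @param path file written by \code{\link{writeSweep}} (or any table with
#'   columns time_ms, voltage_mV, current_pA and '#' metadata lines)
#' @return a \linkS4class{Sweep}
#' @export
readSweep <- function(path) {
  lines <- readLines(path)
  isMeta <- grepl("^#", lines)
  meta <- list()
  for (l in sub("^#\\s*", "", lines[isMeta])) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) next
    val <- kv[2]
    num <- suppressWarnings(as.numeric(val))
    meta[[trimws(kv[1])]] <- if (!is.na(num)) num else val
  }
  body <- lines[!isMeta]
  tab <- utils::read.table(text = body, header = TRUE)
  need <- c("time_ms", "voltage_mV", "current_pA")
  if (!all(need %in% names(tab)))
    stop("sweep file must have columns: ", paste(need, collapse = ", "))
  Sweep(tab$time_ms, tab$voltage_mV, tab$current_pA, meta)
}

#' Write all sweeps of a RecordingSet to a directory
#'
#' Files are named \code{<prefix>_<index>.sweep.txt}.
#'
#' @param rs a \linkS4class{RecordingSet}
#' @param dir output directory (created if missing)
#' @param prefix file-name prefix
#' @return character vector of file paths, invisibly
#' @export
writeRecordingSet <- function(rs, dir, prefix = "sweep") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%03d.sweep.txt", prefix,
                                  seq_along(rs@sweeps)))
  for (i in seq_along(rs@sweeps)) writeSweep(rs@sweeps[[i]], paths[i])
  invisible(paths)
}

#' Read a directory (or explicit files) of sweep tables
#'
#' @param paths directory containing \code{*.sweep.txt} files, or a
#'   character vector of file paths
#' @return a \linkS4class{RecordingSet}
#' @export
readRecordingSet <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.sweep\\.txt$",
                             full.names = TRUE))
  if (!length(paths)) stop("no sweep files found")
  RecordingSet(lapply(paths, readSweep))
}
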