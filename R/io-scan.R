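#' Write a scan result as tab-separated text
#'
#' One data row per position with columns `marker`, `chr`, `cM`, `Mb`,
#' `LRS`, `LOD`, `additive` (numeric columns to 6 decimal places). Attached
#' thresholds and a peak report, when supplied, are written as a `#`-prefixed
#' header block.
#'
#' @param scan a non-empty `usv_scan`.
#' @param file output path or connection.
#' @param thresholds optional `scan_thresholds`.
#' @param peaks optional `qtl_peaks` data frame from [peak_report()].
#' @return the file path, invisibly.
#' @export
write_scan <- function(scan, file, thresholds = NULL, peaks = NULL) {
  stopifnot(inherits(scan, "usv_scan"))
  if (!nrow(scan)) stop("scan result is empty")
  con <- if (is.character(file)) base::file(file, "w") else file
  if (is.character(file)) on.exit(close(con))
  if (!is.null(thresholds)) {
    writeLines(sprintf("# significant_lrs\t%.6f", thresholds$significant), con)
    writeLines(sprintf("# suggestive_lrs\t%.6f", thresholds$suggestive), con)
  }
  if (!is.null(peaks) && nrow(peaks)) {
    for (k in seq_len(nrow(peaks)))
      writeLines(sprintf(
        "# peak\tchr=%s marker=%s Mb=%.6f LRS=%.6f ci=[%.6f,%.6f]",
        peaks$chr[k], peaks$marker[k], peaks$Mb[k], peaks$LRS[k],
        peaks$ci_lo_mb[k], peaks$ci_hi_mb[k]), con)
  }
  writeLines(paste(c("marker", "chr", "cM", "Mb", "LRS", "LOD", "additive"),
                   collapse = "\t"), con)
  for (k in seq_len(nrow(scan)))
    writeLines(paste(c(scan$marker[k], scan$chr[k],
                       sprintf("%.6f", scan$cM[k]),
                       sprintf("%.6f", scan$Mb[k]),
                       sprintf("%.6f", scan$LRS[k]),
                       sprintf("%.6f", scan$LOD[k]),
                       sprintf("%.6f", scan$additive[k])),
                     collapse = "\t"), con)
  invisible(if (is.character(file)) file else NULL)
}

#' Read a scan result written by [write_scan()]
#'
#' @param file path or connection.
#' @return a `usv_scan` data frame; thresholds from the header block, when
#'   present, are attached as attribute `thresholds`.
#' @export
read_scan <- function(file) {
  lines <- readLines(file, warn = FALSE)
  hdr <- grepl("^#", lines)
  thr <- list()
  for (ln in lines[hdr]) {
    f <- strsplit(sub("^#\\s*", "", ln), "\t")[[1]]
    if (f[1] == "significant_lrs") thr$significant <- as.numeric(f[2])
    if (f[1] == "suggestive_lrs") thr$suggestive <- as.numeric(f[2])
  }
  tab <- utils::read.table(text = lines[!hdr], sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          rep("numeric", 5)))
  class(tab) <- c("usv_scan", "data.frame")
  if (length(thr)) {
    class(thr) <- "scan_thresholds"
    attr(tab, "thresholds") <- thr
  }
  tab
}
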