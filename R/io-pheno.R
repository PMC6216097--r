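## delimiter auto-detection: tab or comma only
detect_sep <- function(header_line) {
  if (grepl("\t", header_line)) "\t"
  else if (grepl(",", header_line)) ","
  else stop("cannot detect delimiter (tab or comma required)")
}

#' Read an individual-level phenotype table
#'
#' Reads a comma- or tab-separated table with one record per pup per
#' recording day. Required columns: `strain`, `litter`, `pup`, `sex`,
#' `day`. Recognized optional columns: `weight_g`, the quantitative traits
#' (`ncalls`, `duration_ms`, `frequency_khz`, `amplitude_db`), and the ten
#' call-type count columns named as in [calltype_categories()].
#'
#' Validation: `sex` must be `F`/`M` (or `female`/`male`, case-insensitive),
#' call-type counts must be non-negative, and `(pup, day)` pairs must be
#' unique.
#'
#' @param file path or connection.
#' @param days allowed recording days; `NULL` disables the check.
#' @return a `data.frame` phenotype table.
#' @export
read_phenotypes <- function(file, days = c(7, 8, 9)) {
  lines <- readLines(file, warn = FALSE)
  if (!length(lines)) stop("empty file: header required")
  sep <- detect_sep(lines[1])
  if (length(lines) == 1L) {
    ## header-only file: empty table, not an error
    nm <- trimws(strsplit(lines[1], sep, fixed = TRUE)[[1]])
    tab <- as.data.frame(stats::setNames(rep(list(character(0)), length(nm)),
                                         nm), check.names = FALSE)
  } else {
    nm <- trimws(strsplit(lines[1], sep, fixed = TRUE)[[1]])
    ## identifier columns stay character ("F" must not become FALSE)
    cls <- ifelse(nm %in% c("strain", "litter", "pup", "sex"),
                  "character", NA)
    tab <- utils::read.table(text = lines, sep = sep, header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             colClasses = cls)
  }
  need <- c("strain", "litter", "pup", "sex", "day")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) return(tab)
  sx <- toupper(as.character(tab$sex))
  sx[sx == "FEMALE"] <- "F"; sx[sx == "MALE"] <- "M"
  bad <- !(sx %in% c("F", "M"))
  if (any(bad))
    stop("unknown sex token: ", paste(unique(tab$sex[bad]), collapse = ", "))
  tab$sex <- sx
  tab$day <- as.numeric(tab$day)
  if (!is.null(days) && any(!(tab$day %in% days)))
    stop("day outside allowed set {", paste(days, collapse = ","), "}")
  key <- paste(tab$pup, tab$day, sep = "|")
  if (anyDuplicated(key))
    stop("duplicated (pup, day) record: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  for (ct in intersect(calltype_categories(), names(tab))) {
    if (any(tab[[ct]] < 0, na.rm = TRUE))
      stop("negative count in column ", ct)
  }
  tab
}

#' Write an individual-level phenotype table
#'
#' @param table phenotype `data.frame`.
#' @param file output path or connection.
#' @param sep field delimiter, tab (default) or comma.
#' @return the file path, invisibly.
#' @export
write_phenotypes <- function(table, file, sep = "\t") {
  if (!sep %in% c("\t", ",")) stop("delimiter must be tab or comma")
  utils::write.table(table, file, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(if (is.character(file)) file else NULL)
}

#' Per-strain trait means
#'
#' Collapses an individual-level phenotype table to per-strain summary
#' statistics for one trait, either for a single recording day or averaged
#' across days per pup first (`day = "avg"`), matching the convention of
#' mapping strain means.
#'
#' @param table phenotype `data.frame`.
#' @param trait trait column name.
#' @param day a single day, or `"avg"` for the per-pup across-day average.
#' @return a `data.frame` of class `strain_means` with columns `strain`,
#'   `trait`, `day`, `mean`, `sd`, `se`, `n` (n = number of pups).
#' @export
strain_means <- function(table, trait, day = "avg") {
  if (!trait %in% names(table)) stop("trait column not found: ", trait)
  if (identical(day, "avg")) {
    per_pup <- stats::aggregate(table[[trait]],
                                by = list(strain = table$strain,
                                          pup = table$pup),
                                FUN = mean, na.rm = TRUE)
  } else {
    sub <- table[table$day == day, , drop = FALSE]
    if (!nrow(sub)) stop("no records for day ", day)
    per_pup <- data.frame(strain = sub$strain, pup = sub$pup, x = sub[[trait]])
  }
  ag <- stats::aggregate(per_pup$x, by = list(strain = per_pup$strain),
                         FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                             sd = stats::sd(v),
                                             n = sum(!is.na(v))))
  out <- data.frame(strain = ag$strain,
                    trait = trait,
                    day = if (identical(day, "avg")) "avg" else as.character(day),
                    mean = ag$x[, "mean"], sd = ag$x[, "sd"],
                    n = as.integer(ag$x[, "n"]),
                    stringsAsFactors = FALSE)
  out$se <- out$sd / sqrt(out$n)
  out <- out[, c("strain", "trait", "day", "mean", "sd", "se", "n")]
  rownames(out) <- NULL
  class(out) <- c("strain_means", "data.frame")
  out
}

#' Read a strain-mean table
#'
#' Comma- or tab-separated with a header; required columns `strain` and
#' `mean`; optional `trait`, `day`, `sd`, `se`, `n`. When `sd` and `n` are
#' present but `se` is absent, `se` is filled as `sd / sqrt(n)`.
#'
#' @param file path or connection.
#' @return a `strain_means` data frame.
#' @export
read_strain_means <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (!length(lines)) stop("empty file: header required")
  sep <- detect_sep(lines[1])
  tab <- utils::read.table(text = lines, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("strain", "mean"), names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!"n" %in% names(tab)) tab$n <- NA_integer_
  if (any(!is.na(tab$n) & tab$n < 1)) stop("replicate count n must be >= 1")
  if (!"se" %in% names(tab) && all(c("sd", "n") %in% names(tab)))
    tab$se <- tab$sd / sqrt(tab$n)
  class(tab) <- c("strain_means", "data.frame")
  tab
}

#' Write a strain-mean table
#'
#' @param means a `strain_means` data frame.
#' @param file output path or connection.
#' @param sep field delimiter, tab (default) or comma.
#' @return the file path, invisibly.
#' @export
write_strain_means <- function(means, file, sep = "\t") {
  if (!sep %in% c("\t", ",")) stop("delimiter must be tab or comma")
  utils::write.table(as.data.frame(means), file, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(if (is.character(file)) file else NULL)
}
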