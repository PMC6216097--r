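#' Winsorize outlying strain means
#'
#' Converts the strain means to z-scores (using the full set's mean and SD)
#' and replaces every value with |z| above the threshold by the nearest
#' retained value on the same side of the distribution: high outliers take
#' the largest retained value, low outliers the smallest. Applied two-sided.
#' A change log records each replacement.
#'
#' @param means a [strain_means()] data frame (column `mean` is adjusted),
#'   or a named numeric vector of strain means.
#' @param z_threshold standardized-unit threshold; default 2.5.
#' @return the adjusted object, with the change log (a data frame with
#'   columns `strain`, `old`, `new`) attached as attribute `winsor_log`.
#' @examples
#' x <- stats::setNames(c(rep(1, 9), 10), paste0("S", 1:10))
#' w <- winsorize_means(x)
#' attr(w, "winsor_log")
#' @export
winsorize_means <- function(means, z_threshold = 2.5) {
  df <- inherits(means, "data.frame")
  x <- if (df) means$mean else means
  nm <- if (df) means$strain else names(means)
  if (length(x) < 3) stop("at least 3 strains required")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance among strain means")
  z <- (x - mean(x)) / s
  out_i <- which(abs(z) > z_threshold)
  new_x <- x
  if (length(out_i)) {
    kept <- x[-out_i]
    if (!length(kept)) stop("no retained values to winsorize toward")
    new_x[out_i] <- ifelse(z[out_i] > 0, max(kept), min(kept))
  }
  log <- data.frame(strain = as.character(nm[out_i]),
                    old = x[out_i], new = new_x[out_i],
                    stringsAsFactors = FALSE)
  rownames(log) <- NULL
  if (df) means$mean <- new_x else means[] <- new_x
  attr(means, "winsor_log") <- log
  means
}

#' Render a winsorization change log
#'
#' Formats each replacement as `"<strain> from <old> to <new>"`, the style
#' used in trait descriptions (e.g. `"BXD86 from 55.419 to 56.192"`).
#'
#' @param log a change-log data frame from [winsorize_means()] (or an object
#'   carrying a `winsor_log` attribute).
#' @param digits decimal places; default 3.
#' @return character vector, one entry per replacement.
#' @export
format_winsor_log <- function(log, digits = 3) {
  if (!is.data.frame(log)) log <- attr(log, "winsor_log")
  if (is.null(log) || !nrow(log)) return(character(0))
  fmt <- function(v) format(round(v, digits), trim = TRUE)
  sprintf("%s from %s to %s", log$strain, fmt(log$old), fmt(log$new))
}
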