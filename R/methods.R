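#' @export
print.usv_scan <- function(x, ...) {
  cat("usv_scan:", nrow(x), "positions on",
      length(unique(x$chr)), "chromosome(s);",
      attr(x, "n"), "strains\n")
  top <- x[which.max(x$LRS), ]
  cat(sprintf("peak: %s (chr %s, %.1f Mb), LRS %.2f, LOD %.2f\n",
              top$marker, top$chr, top$Mb, top$LRS, top$LOD))
  invisible(x)
}

#' @export
summary.usv_scan <- function(object, thresholds = NULL, ...) {
  per_chr <- do.call(rbind, lapply(split(object, object$chr), function(d) {
    i <- which.max(d$LRS)
    d[i, c("chr", "marker", "cM", "Mb", "LRS", "LOD", "additive")]
  }))
  per_chr <- per_chr[order(-per_chr$LRS), ]
  rownames(per_chr) <- NULL
  if (!is.null(thresholds))
    per_chr$significant <- per_chr$LRS >= thresholds$significant
  per_chr
}

#' @export
plot.usv_scan <- function(x, thresholds = NULL, ...) {
  chrs <- unique(x$chr)
  off <- 0; xs <- numeric(nrow(x)); mids <- numeric(length(chrs))
  for (k in seq_along(chrs)) {
    i <- x$chr == chrs[k]
    xs[i] <- x$Mb[i] - min(x$Mb[i]) + off
    mids[k] <- off + diff(range(x$Mb[i])) / 2
    off <- off + diff(range(x$Mb[i])) + 5
  }
  graphics::plot(xs, x$LOD, type = "n", xaxt = "n", xlab = "chromosome",
                 ylab = "LOD", ...)
  for (k in seq_along(chrs)) {
    i <- x$chr == chrs[k]
    graphics::lines(xs[i], x$LOD[i], col = if (k %% 2) "steelblue4" else "grey40")
  }
  graphics::axis(1, at = mids, labels = chrs)
  if (!is.null(thresholds)) {
    graphics::abline(h = thresholds$significant_lod, col = "violetred", lty = 1)
    graphics::abline(h = thresholds$suggestive_lod, col = "grey60", lty = 2)
  }
  invisible(x)
}

#' @export
print.scan_thresholds <- function(x, ...) {
  cat(sprintf(
    "genome-wide thresholds (%s permutations):\n  significant (p<0.05): LRS %.2f / LOD %.2f\n  suggestive (p<0.63): LRS %.2f / LOD %.2f\n",
    format(x$n_perm, big.mark = ","), x$significant,
    lrs_to_lod(x$significant), x$suggestive, lrs_to_lod(x$suggestive)))
  invisible(x)
}

#' @export
print.qtl_peaks <- function(x, ...) {
  if (!nrow(x)) { cat("no peaks above the suggestive threshold\n"); return(invisible(x)) }
  cat("QTL peaks (suggestive or better):\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
print.boot_peaks <- function(x, top = 5, ...) {
  cat("bootstrap peak-location histogram:", sum(x), "resamples\n")
  nz <- sort(x[x > 0], decreasing = TRUE)
  print(utils::head(nz, top))
  invisible(x)
}

#' @export
print.variance_decomp <- function(x, ...) {
  df <- as.data.frame(x)
  df$fraction <- round(df$fraction, 4)
  print.data.frame(df, digits = 4)
  invisible(x)
}
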