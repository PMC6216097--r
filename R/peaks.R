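#' Report QTL peaks above the suggestive threshold
#'
#' Identifies contiguous runs of positions with LRS at or above the
#' suggestive threshold; each run is one peak (sibling peaks on a
#' chromosome are runs separated by a dip below the suggestive line). For
#' every peak the summit (lowest-coordinate position among equal maxima),
#' its LRS/LOD, whether it clears the significant threshold, and the
#' 1.5-LOD support interval are reported. For sibling peaks sharing a
#' chromosome, the number of discordant strains (opposite parental alleles
#' at the two peak markers) is counted against the nearest sibling, and
#' overlapping support intervals are flagged.
#'
#' @param scan a `usv_scan`.
#' @param thresholds a `scan_thresholds` object (or list with `significant`
#'   and `suggestive` on the LRS scale).
#' @param geno optional `geno_matrix` used for the discordant-strain count;
#'   peak positions falling on pseudomarkers are matched to the nearest
#'   genotyped marker.
#' @param drop LOD drop for the support interval; default 1.5.
#' @return a data frame of class `qtl_peaks`, possibly empty, with columns
#'   `chr`, `marker`, `cM`, `Mb`, `LRS`, `LOD`, `significant`, `ci_lo_mb`,
#'   `ci_hi_mb`, `sibling`, `discordant_n`, `overlaps_sibling`.
#' @export
peak_report <- function(scan, thresholds, geno = NULL, drop = 1.5) {
  stopifnot(inherits(scan, "usv_scan"))
  sug <- thresholds$suggestive
  sig <- thresholds$significant
  empty <- data.frame(chr = character(0), marker = character(0),
                      cM = numeric(0), Mb = numeric(0), LRS = numeric(0),
                      LOD = numeric(0), significant = logical(0),
                      ci_lo_mb = numeric(0), ci_hi_mb = numeric(0),
                      sibling = character(0), discordant_n = integer(0),
                      overlaps_sibling = logical(0),
                      stringsAsFactors = FALSE)
  rows <- list()
  for (cc in unique(scan$chr)) {
    idx <- which(scan$chr == cc)
    above <- scan$LRS[idx] >= sug
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      seg <- idx[starts[r]:ends[r]]
      top <- seg[which.max(scan$LRS[seg])]
      ci <- lod_support_interval(scan, scan$marker[top], drop = drop)
      rows[[length(rows) + 1L]] <- data.frame(
        chr = cc, marker = scan$marker[top], cM = scan$cM[top],
        Mb = scan$Mb[top], LRS = scan$LRS[top], LOD = scan$LOD[top],
        significant = scan$LRS[top] >= sig,
        ci_lo_mb = unname(ci["lower"]), ci_hi_mb = unname(ci["upper"]),
        sibling = NA_character_, discordant_n = NA_integer_,
        overlaps_sibling = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) { class(empty) <- c("qtl_peaks", "data.frame"); return(empty) }
  out <- do.call(rbind, rows)
  ## sibling bookkeeping per chromosome
  for (cc in unique(out$chr)) {
    pk <- which(out$chr == cc)
    if (length(pk) < 2) next
    for (i in pk) {
      others <- setdiff(pk, i)
      j <- others[which.min(abs(out$Mb[others] - out$Mb[i]))]
      out$sibling[i] <- out$marker[j]
      out$overlaps_sibling[i] <-
        out$ci_lo_mb[i] <= out$ci_hi_mb[j] && out$ci_hi_mb[i] >= out$ci_lo_mb[j]
      if (!is.null(geno))
        out$discordant_n[i] <- discordant_strains(geno, out$marker[i],
                                                  out$marker[j])
    }
  }
  rownames(out) <- NULL
  class(out) <- c("qtl_peaks", "data.frame")
  out
}

## count strains carrying opposite parental alleles at two positions;
## pseudomarker names are matched to the nearest genotyped marker by cM
discordant_strains <- function(geno, marker1, marker2) {
  pick <- function(mk) {
    if (mk %in% colnames(geno$geno)) return(mk)
    ## pseudomarker name of the form c<chr>_loc<cM>
    m <- regmatches(mk, regexec("^c(.+)_loc([0-9.]+)$", mk))[[1]]
    if (length(m) != 3L) stop("marker not found in genotypes: ", mk)
    onchr <- geno$map[geno$map$chr == m[2], , drop = FALSE]
    if (!nrow(onchr)) stop("marker not found in genotypes: ", mk)
    onchr$marker[which.min(abs(onchr$cM - as.numeric(m[3])))]
  }
  a <- geno$geno[, pick(marker1)]
  b <- geno$geno[, pick(marker2)]
  ok <- a %in% c("B", "D") & b %in% c("B", "D")
  sum(ok & a != b)
}
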