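#' Expected allele dosages at markers and pseudomarkers
#'
#' Prepares the regressor matrix for Haley-Knott scanning. At genotyped
#' markers the dosage is the observed code, `B` -> -1, `D` -> +1. On a grid
#' of pseudomarkers (every `step` cM) the dosage is the conditional
#' expectation of the allele given the nearest informative flanking markers,
#' using RI-expanded recombination fractions R = 4r/(1+6r) on the Haldane r
#' implied by each cM gap. Between concordant flanks the expectation equals
#' the flanking code (double-exchange configurations are not entertained);
#' between discordant flanks at distances giving expansions RL and RR the
#' probability of the left allele is RL'(1-RR')-style odds, so the midpoint
#' of a discordant pair has dosage 0. Heterozygous and unknown calls are
#' treated as missing and each position is mean-imputed across strains.
#'
#' @param geno a `geno_matrix`.
#' @param step pseudomarker spacing in cM (> 0); default 1.
#' @param interpolate if `TRUE`, use simple linear interpolation of flanking
#'   dosages in cM instead of the RI conditional probabilities.
#' @return an object of class `usv_dosage`: list with `dosage` (numeric
#'   matrix strains x positions) and `map` (data frame `marker`, `chr`,
#'   `cM`, `Mb`, `pseudo`).
#' @export
expected_dosages <- function(geno, step = 1, interpolate = FALSE) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (step <= 0) stop("step must be > 0")
  codes <- geno_codes(geno)
  map <- geno$map
  out_dos <- list(); out_map <- list()
  for (cc in unique(map$chr)) {
    idx <- which(map$chr == cc)
    if (!length(idx)) stop("chromosome with no markers: ", cc)
    cm <- map$cM[idx]; mb <- map$Mb[idx]
    grid <- sort(unique(c(cm, seq(min(cm), max(cm), by = step))))
    is_marker <- grid %in% cm
    ## physical positions for pseudomarkers by linear cM->Mb interpolation
    mb_grid <- if (length(idx) > 1L && diff(range(cm)) > 0)
      stats::approx(cm, mb, xout = grid, rule = 2, ties = "ordered")$y
    else rep(mb[1], length(grid))
    D <- matrix(NA_real_, nrow = nrow(codes), ncol = length(grid))
    mcodes <- codes[, idx, drop = FALSE]
    for (k in seq_along(grid)) {
      if (is_marker[k]) {
        D[, k] <- mcodes[, match(grid[k], cm)]
      } else {
        D[, k] <- pseudo_dosage(mcodes, cm, grid[k], interpolate)
      }
    }
    ## mean-impute residual missingness per position
    for (k in seq_len(ncol(D))) {
      na <- is.na(D[, k])
      if (all(na)) stop("position with all-missing dosage on chromosome ", cc)
      if (any(na)) D[na, k] <- mean(D[!na, k])
    }
    nm <- character(length(grid))
    nm[is_marker] <- map$marker[idx][match(grid[is_marker], cm)]
    nm[!is_marker] <- sprintf("c%s_loc%g", cc, grid[!is_marker])
    colnames(D) <- nm
    out_dos[[cc]] <- D
    out_map[[cc]] <- data.frame(marker = nm, chr = cc, cM = grid,
                                Mb = mb_grid, pseudo = !is_marker,
                                stringsAsFactors = FALSE)
  }
  dmap <- do.call(rbind, out_map)
  rownames(dmap) <- NULL
  dosage <- do.call(cbind, out_dos)
  rownames(dosage) <- rownames(codes)
  structure(list(dosage = dosage, map = dmap), class = "usv_dosage")
}

## conditional dosage at one pseudomarker position, per strain
pseudo_dosage <- function(mcodes, cm, pos, interpolate = FALSE) {
  n <- nrow(mcodes)
  out <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    obs <- which(!is.na(mcodes[s, ]))
    if (!length(obs)) next
    lef <- obs[cm[obs] <= pos]
    rig <- obs[cm[obs] >= pos]
    iL <- if (length(lef)) lef[which.max(cm[lef])] else NA_integer_
    iR <- if (length(rig)) rig[which.min(cm[rig])] else NA_integer_
    if (!is.na(iL) && !is.na(iR) && iL != iR) {
      gL <- mcodes[s, iL]; gR <- mcodes[s, iR]
      if (interpolate) {
        w <- (pos - cm[iL]) / (cm[iR] - cm[iL])
        out[s] <- (1 - w) * gL + w * gR
        next
      }
      if (gL == gR) { out[s] <- gL; next }
      RL <- ri_expand(haldane_r(pos - cm[iL]))
      RR <- ri_expand(haldane_r(cm[iR] - pos))
      ## single exchange somewhere in the interval: odds of it lying right
      pL <- (1 - RL) * RR / ((1 - RL) * RR + RL * (1 - RR))
      out[s] <- pL * gL + (1 - pL) * gR
    } else {
      i <- if (!is.na(iL)) iL else iR
      R <- ri_expand(haldane_r(abs(pos - cm[i])))
      out[s] <- (1 - 2 * R) * mcodes[s, i]
    }
  }
  out
}

## core vectorized single-QTL regression on strain means
## returns list(lrs, slope, rss0) given dosage matrix X (n x p) and y (n)
hk_core <- function(X, y) {
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  sxy <- as.numeric(crossprod(Xc, yc))
  ok <- sxx > 1e-12
  slope <- ifelse(ok, sxy / sxx, 0)
  expl <- ifelse(ok, sxy^2 / sxx, 0)
  rss1 <- pmax(syy - expl, syy * 1e-10)
  lrs <- if (syy <= 0) rep(0, length(sxx)) else n * log(syy / rss1)
  lrs[!ok] <- 0
  list(lrs = lrs, slope = slope, rss0 = syy, n = n)
}

## align a strain-mean phenotype with a dosage matrix; complete cases only
align_scan_input <- function(dosages, y) {
  stopifnot(inherits(dosages, "usv_dosage"))
  if (inherits(y, "strain_means") || is.data.frame(y)) {
    yv <- y$mean
    names(yv) <- y$strain
  } else {
    yv <- y
  }
  if (is.null(names(yv))) stop("phenotype must carry strain names")
  common <- intersect(rownames(dosages$dosage), names(yv))
  common <- common[!is.na(yv[common])]
  list(X = dosages$dosage[common, , drop = FALSE], y = yv[common])
}

#' Haley-Knott regression scan of strain means
#'
#' At every position, regresses the strain means on the expected allele
#' dosage (intercept plus slope). The association score is the likelihood
#' ratio statistic LRS = N ln(RSS0 / RSS1), converted to a LOD score by
#' dividing by 4.61. The additive coefficient is the regression slope under
#' the -1/+1 coding, i.e. half the difference between the D and B allele
#' classes; positive values mean the D allele increases the trait.
#'
#' @param dosages a `usv_dosage` from [expected_dosages()].
#' @param y strain phenotypes: a [strain_means()] data frame or a named
#'   numeric vector. Strains are matched by name; at least 4 complete
#'   strains are required.
#' @return a data frame of class `usv_scan` with one row per position:
#'   `marker`, `chr`, `cM`, `Mb`, `LRS`, `LOD`, `additive`; the number of
#'   strains used is attached as attribute `n`.
#' @examples
#' g <- simulate_ri_genotypes(20, sim_map(2, 10, 50), seed = 1)
#' y <- stats::setNames(rnorm(20), rownames(g$geno))
#' s <- hk_scan(expected_dosages(g, step = 5), y)
#' summary(s)
#' @export
hk_scan <- function(dosages, y) {
  ai <- align_scan_input(dosages, y)
  if (length(ai$y) < 4) stop("fewer than 4 strains with phenotype and genotype")
  fit <- hk_core(ai$X, ai$y)
  out <- dosages$map
  out$LRS <- fit$lrs
  out$LOD <- lrs_to_lod(fit$lrs)
  out$additive <- fit$slope
  attr(out, "n") <- fit$n
  class(out) <- c("usv_scan", "data.frame")
  out
}

#' Genome-wide permutation thresholds for a scan
#'
#' Permutes the strain-mean phenotype across strains, records the
#' genome-wide maximum LRS of each permuted scan, and returns the 95th
#' percentile of that null distribution as the genome-wide significant
#' threshold (p < 0.05) and the 37th percentile as the suggestive threshold
#' (p < 0.63, about one false QTL per genome scan).
#'
#' @inheritParams hk_scan
#' @param n_perm number of permutations (>= 100); default 5000.
#' @param seed integer seed or NULL.
#' @return a list of class `scan_thresholds`: `significant` and
#'   `suggestive` on the LRS scale, their LOD equivalents, `n_perm`, and
#'   the vector of permutation maxima (`max_lrs`).
#' @export
permutation_thresholds <- function(dosages, y, n_perm = 5000, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  ai <- align_scan_input(dosages, y)
  if (length(ai$y) < 4) stop("fewer than 4 strains with phenotype and genotype")
  with_seed(seed, {
    maxes <- perm_max_lrs(ai$X, ai$y, n_perm)
    structure(list(
      significant = unname(stats::quantile(maxes, 0.95)),
      suggestive = unname(stats::quantile(maxes, 0.37)),
      significant_lod = unname(lrs_to_lod(stats::quantile(maxes, 0.95))),
      suggestive_lod = unname(lrs_to_lod(stats::quantile(maxes, 0.37))),
      n_perm = n_perm, max_lrs = maxes), class = "scan_thresholds")
  })
}

## vectorized genome-wide max LRS over B phenotype permutations
perm_max_lrs <- function(X, y, n_perm) {
  n <- length(y)
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  ok <- sxx > 1e-12
  Y <- vapply(seq_len(n_perm), function(b) y[sample.int(n)], numeric(n))
  Yc <- sweep(Y, 2, colMeans(Y))
  syy <- colSums(Yc^2)
  sxy <- crossprod(Xc, Yc)              # p x B
  expl <- sxy^2 / sxx                   # recycles sxx down columns
  expl[!ok, ] <- 0
  tE <- t(expl)
  mx <- tE[cbind(seq_len(n_perm), max.col(tE, ties.method = "first"))]
  rss1 <- pmax(syy - mx, syy * 1e-10)
  ifelse(syy > 0, n * log(syy / rss1), 0)
}

#' LOD support interval around a peak
#'
#' Walks outward from a peak position along its chromosome and returns the
#' outermost contiguous region in which the LOD score stays within `drop`
#' LOD units of the peak value, truncated at the chromosome ends. Edges are
#' reported in Mb.
#'
#' @param scan a `usv_scan`.
#' @param peak marker name of the peak position (must be present in the
#'   scan).
#' @param drop LOD-unit drop defining the interval; default 1.5.
#' @return numeric vector `c(lower, upper)` in Mb.
#' @export
lod_support_interval <- function(scan, peak, drop = 1.5) {
  stopifnot(inherits(scan, "usv_scan"))
  i <- match(peak, scan$marker)
  if (is.na(i)) stop("peak position not in scan: ", peak)
  cc <- scan$chr[i]
  idx <- which(scan$chr == cc)
  lod <- scan$LOD[idx]
  k <- match(i, idx)
  cutoff <- lod[k] - drop
  lo <- k
  while (lo > 1 && lod[lo - 1] >= cutoff) lo <- lo - 1
  hi <- k
  while (hi < length(idx) && lod[hi + 1] >= cutoff) hi <- hi + 1
  c(lower = scan$Mb[idx[lo]], upper = scan$Mb[idx[hi]])
}

#' Bootstrap histogram of peak locations
#'
#' Resamples strains with replacement, recomputes the scan, and tallies the
#' genome-wide peak position of each resample (ties broken toward the
#' lowest-coordinate position). The resulting frequency histogram indicates
#' how stable the peak location is.
#'
#' @inheritParams hk_scan
#' @param n_boot number of resamples (>= 100); default 2000.
#' @param seed integer seed or NULL.
#' @return integer vector of class `boot_peaks`, one count per scan
#'   position (named by marker, summing to `n_boot`), with the position map
#'   attached as attribute `map`.
#' @export
bootstrap_peaks <- function(dosages, y, n_boot = 2000, seed = NULL) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  ai <- align_scan_input(dosages, y)
  if (length(ai$y) < 4) stop("fewer than 4 strains with phenotype and genotype")
  X <- ai$X; yv <- ai$y
  n <- length(yv); p <- ncol(X)
  with_seed(seed, {
    counts <- integer(p)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      fit <- hk_core(X[idx, , drop = FALSE], yv[idx])
      counts[which.max(fit$lrs)] <- counts[which.max(fit$lrs)] + 1L
    }
    names(counts) <- colnames(X)
    structure(counts, class = "boot_peaks", map = dosages$map)
  })
}
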