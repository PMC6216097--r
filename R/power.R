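#' Power to detect a QTL by panel simulation
#'
#' Simulates RI panels end to end — genotypes, strain-mean phenotypes with
#' a planted QTL, Haley-Knott scan, genome-wide threshold — and reports the
#' fraction of panels in which the causal region is detected.
#'
#' The strain-mean model: with total strain-mean variance 1, the planted
#' QTL carries `qtl_fraction` of the genetic variance and the genetic
#' variance is `strain_mean_h2` of the total, so the causal marker explains
#' `qtl_fraction * strain_mean_h2` of the strain-mean variance; the
#' remaining genetic variance and the strain-mean noise are both drawn as
#' independent strain deviates (neither is linked to the scanned markers,
#' so they are interchangeable for detection).
#'
#' Detection: with `qtl_fraction > 0`, the maximum LRS within `window_cm`
#' of the causal marker must exceed the threshold; at `qtl_fraction = 0`
#' the genome-wide maximum is used, so the returned value estimates the
#' genome-wide type-I error of the threshold policy.
#'
#' @param n_strains panel size.
#' @param strain_mean_h2 heritability of the strain means, in \[0, 1\].
#' @param qtl_fraction fraction of the genetic variance carried by the
#'   planted QTL, in \[0, 1\].
#' @param alpha_policy `"significant"` (permutation genome-wide p < 0.05),
#'   `"suggestive"` (permutation genome-wide p < 0.63), or `"pointwise"`
#'   (fixed chi-square threshold at `pointwise_alpha`).
#' @param replicates simulated panels (>= 100).
#' @param seed integer seed or NULL.
#' @param map genetic map scanned; default 10 chromosomes x 30 markers
#'   over 60 cM.
#' @param causal_marker marker carrying the QTL; default the middle marker
#'   of the first chromosome.
#' @param n_perm permutations per panel for the permutation policies;
#'   default 500.
#' @param pointwise_alpha alpha for the pointwise policy; default 0.05.
#' @param window_cm detection window around the causal marker; default 15.
#' @return a list of class `power_est`: `power`, `se` (Monte-Carlo standard
#'   error), `detections`, `replicates`, `threshold_policy`.
#' @export
power_by_simulation <- function(n_strains, strain_mean_h2, qtl_fraction,
                                alpha_policy = c("significant", "suggestive",
                                                 "pointwise"),
                                replicates = 200, seed = NULL,
                                map = sim_map(10, 30, 60),
                                causal_marker = NULL, n_perm = 500,
                                pointwise_alpha = 0.05, window_cm = 15) {
  alpha_policy <- match.arg(alpha_policy)
  if (strain_mean_h2 < 0 || strain_mean_h2 > 1 ||
      qtl_fraction < 0 || qtl_fraction > 1)
    stop("proportions must lie in [0, 1]")
  if (replicates < 100) stop("replicates must be >= 100")
  if (is.null(causal_marker)) {
    chr1 <- map[map$chr == map$chr[1], , drop = FALSE]
    causal_marker <- chr1$marker[ceiling(nrow(chr1) / 2)]
  }
  if (!causal_marker %in% map$marker)
    stop("causal marker not in map: ", causal_marker)
  cm0 <- map$cM[map$marker == causal_marker]
  chr0 <- map$chr[map$marker == causal_marker]
  a2 <- qtl_fraction * strain_mean_h2
  hits <- logical(replicates)
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      g <- simulate_ri_genotypes(n_strains, map)
      X <- geno_codes(g)
      X[is.na(X)] <- 0
      y <- sqrt(a2) * X[, causal_marker] +
        stats::rnorm(n_strains, 0, sqrt(1 - a2))
      fit <- hk_core(X, y)
      thr <- switch(alpha_policy,
        pointwise = stats::qchisq(1 - pointwise_alpha, df = 1),
        {
          maxes <- perm_max_lrs(X, y, n_perm)
          if (alpha_policy == "significant")
            stats::quantile(maxes, 0.95, names = FALSE)
          else stats::quantile(maxes, 0.37, names = FALSE)
        })
      if (qtl_fraction > 0) {
        near <- map$chr == chr0 & abs(map$cM - cm0) <= window_cm
        hits[r] <- max(fit$lrs[near]) > thr
      } else {
        hits[r] <- max(fit$lrs) > thr
      }
    }
  })
  p <- mean(hits)
  structure(list(power = p, se = sqrt(p * (1 - p) / replicates),
                 detections = sum(hits), replicates = replicates,
                 threshold_policy = alpha_policy),
            class = "power_est")
}

#' @export
print.power_est <- function(x, ...) {
  cat(sprintf("power = %.3f (MC se %.3f; %d/%d panels; policy %s)\n",
              x$power, x$se, x$detections, x$replicates, x$threshold_policy))
  invisible(x)
}
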