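#' Marker-based kinship matrix
#'
#' Centered-genotype cross-product relatedness (the "centered" kinship of
#' mixed-model association tools): marker codes (-1/+1, heterozygous and
#' unknown mean-imputed) are centered per marker and the strain-by-strain
#' cross-product is divided by the marker count. The result is symmetric and
#' positive semidefinite by construction, and is rescaled to unit mean
#' diagonal (the normalization is recorded in attribute `normalization`).
#'
#' @param geno a `geno_matrix` with at least 2 strains and 2 markers.
#' @return a strain-by-strain matrix of class `kinship_matrix`.
#' @export
kinship_matrix <- function(geno) {
  codes <- geno_codes(geno)
  if (nrow(codes) < 2 || ncol(codes) < 2)
    stop("at least 2 strains and 2 markers required")
  for (j in seq_len(ncol(codes))) {
    na <- is.na(codes[, j])
    if (all(na)) stop("all-missing marker: ", colnames(codes)[j])
    if (any(na)) codes[na, j] <- mean(codes[!na, j])
  }
  Gc <- sweep(codes, 2, colMeans(codes))
  K <- tcrossprod(Gc) / ncol(Gc)
  md <- mean(diag(K))
  norm <- "none"
  if (md > 0) { K <- K / md; norm <- "unit_mean_diagonal" }
  structure(K, class = c("kinship_matrix", class(K)),
            normalization = norm)
}

#' Kinship-adjusted mixed-model scan
#'
#' Single-random-effect linear mixed model y = mu + x b + u + e with
#' cov(u) proportional to the kinship matrix K. The variance ratio
#' delta = sigma_e^2 / sigma_g^2 is estimated once under the null
#' (intercept-only) model by restricted likelihood, via the spectral
#' decomposition of K and a one-dimensional search; the data are rotated by
#' the eigenvectors and every position is then tested by a generalized
#' least-squares likelihood ratio with those null weights held fixed
#' (refitting per position is available with `refit = TRUE`). Statistics are
#' reported on the LRS scale, LOD = LRS/4.61.
#'
#' When K is proportional to the identity the weights are constant and the
#' scan coincides with [hk_scan()].
#'
#' @inheritParams hk_scan
#' @param K a [kinship_matrix()] (symmetric positive semidefinite, rows and
#'   columns named by strain).
#' @param refit re-estimate delta under the alternative at every position.
#' @return a `usv_scan` data frame; the estimated null `delta` is attached
#'   as an attribute.
#' @export
kinship_lmm_scan <- function(dosages, y, K, refit = FALSE) {
  ai <- align_scan_input(dosages, y)
  if (length(ai$y) < 4) stop("fewer than 4 strains with phenotype and genotype")
  if (!isTRUE(all.equal(unname(as.matrix(K)), unname(t(as.matrix(K))),
                        tolerance = 1e-8)))
    stop("kinship matrix must be symmetric")
  strains <- names(ai$y)
  if (is.null(rownames(K)) || !all(strains %in% rownames(K)))
    stop("kinship matrix dimensions/names do not match strains")
  Km <- as.matrix(K)[strains, strains]
  eg <- eigen(Km, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("kinship matrix is not positive semidefinite")
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  n <- length(ai$y)
  ystar <- as.numeric(crossprod(U, ai$y))
  x0 <- as.numeric(crossprod(U, rep(1, n)))
  Xstar <- crossprod(U, ai$X)

  null_rss <- function(delta) {
    w <- 1 / (d + delta)
    b <- sum(w * x0 * ystar) / sum(w * x0^2)
    sum(w * (ystar - x0 * b)^2)
  }
  reml_crit <- function(ldelta) {
    delta <- exp(ldelta)
    w <- 1 / (d + delta)
    (n - 1) * log(null_rss(delta)) + sum(log(d + delta)) +
      log(sum(w * x0^2))
  }
  opt <- stats::optimize(reml_crit, interval = c(log(1e-5), log(1e5)))
  delta <- exp(opt$minimum)
  w <- 1 / (d + delta)

  gls_rss <- function(wts) {
    a00 <- sum(wts * x0^2)
    b0 <- sum(wts * x0 * ystar)
    syy <- sum(wts * ystar^2)
    a01 <- as.numeric(crossprod(Xstar, wts * x0))
    a11 <- colSums(wts * Xstar^2)
    b1 <- as.numeric(crossprod(Xstar, wts * ystar))
    det <- a00 * a11 - a01^2
    ok <- det > 1e-12 * a00 * pmax(a11, 1e-300)
    beta0 <- (a11 * b0 - a01 * b1) / det
    beta1 <- (a00 * b1 - a01 * b0) / det
    rss1 <- syy - (beta0 * b0 + beta1 * b1)
    rss0 <- syy - b0^2 / a00
    list(rss0 = rss0, rss1 = ifelse(ok, pmax(rss1, rss0 * 1e-10), rss0),
         slope = ifelse(ok, beta1, 0))
  }
  if (!refit) {
    g <- gls_rss(w)
    lrs <- n * log(g$rss0 / g$rss1)
    slope <- g$slope
  } else {
    p <- ncol(Xstar)
    lrs <- numeric(p); slope <- numeric(p)
    for (j in seq_len(p)) {
      alt_crit <- function(ldelta) {
        dj <- exp(ldelta)
        wj <- 1 / (d + dj)
        Xj <- cbind(x0, Xstar[, j])
        XtW <- t(Xj * wj)
        bj <- tryCatch(solve(XtW %*% Xj, XtW %*% ystar),
                       error = function(e) NULL)
        if (is.null(bj)) return(Inf)
        r <- ystar - Xj %*% bj
        n * log(sum(wj * r^2)) + sum(log(d + dj))
      }
      oj <- stats::optimize(alt_crit, interval = c(log(1e-5), log(1e5)))
      wj <- 1 / (d + exp(oj$minimum))
      gj <- gls_rss(wj)
      lrs[j] <- n * log(gj$rss0 / gj$rss1[j])
      slope[j] <- gj$slope[j]
    }
  }
  out <- dosages$map
  out$LRS <- pmax(lrs, 0)
  out$LOD <- lrs_to_lod(out$LRS)
  out$additive <- slope
  attr(out, "n") <- n
  attr(out, "delta") <- delta
  class(out) <- c("usv_scan", "data.frame")
  out
}
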