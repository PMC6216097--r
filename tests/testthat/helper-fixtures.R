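# shared fixture builders

# two strains, two litters each, values chosen so the sequential ANOVA
# partition is exactly strain 0.8 / litter 0.2 / residual 0
anova_fixture <- function() {
  data.frame(strain = rep(c("A", "B"), each = 4),
             litter = rep(c("a1", "a2", "b1", "b2"), each = 2),
             pup = paste0("p", 1:8), sex = rep(c("F", "M"), 4), day = 7,
             y = c(1, 1, 3, 3, 5, 5, 7, 7),
             stringsAsFactors = FALSE)
}

# dosage object wrapping an explicit matrix (markers already genotyped)
dosage_fixture <- function(X, chr = rep("1", ncol(X)),
                           cM = seq(0, by = 10, length.out = ncol(X)),
                           Mb = NULL) {
  if (is.null(Mb)) Mb <- cM * 2
  if (is.null(colnames(X))) colnames(X) <- paste0("m", seq_len(ncol(X)))
  if (is.null(rownames(X))) rownames(X) <- paste0("S", seq_len(nrow(X)))
  structure(list(dosage = X,
                 map = data.frame(marker = colnames(X), chr = chr, cM = cM,
                                  Mb = Mb, pseudo = FALSE,
                                  stringsAsFactors = FALSE)),
            class = "usv_dosage")
}

# minimal scan object from a LOD profile on one chromosome
scan_fixture <- function(lod, mb = seq_along(lod), chr = "1") {
  out <- data.frame(marker = paste0("m", seq_along(lod)), chr = chr,
                    cM = mb, Mb = mb, LRS = lod * 4.61, LOD = lod,
                    additive = 0, stringsAsFactors = FALSE)
  class(out) <- c("usv_scan", "data.frame")
  out
}

# least-squares oracle for the single-position regression LRS
lrs_oracle <- function(x, y) {
  rss0 <- sum((y - mean(y))^2)
  fit <- stats::lm(y ~ x)
  rss1 <- sum(stats::resid(fit)^2)
  list(lrs = length(y) * log(rss0 / rss1),
       slope = unname(stats::coef(fit)[2]))
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (k in seq_len(n)) {
    rest <- all_perms(n - 1)
    for (r in rest) out[[length(out) + 1L]] <- c(k, ifelse(r >= k, r + 1L, r))
  }
  out
}
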