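test_that("winsorization replaces outliers by the nearest retained value", {
  x <- stats::setNames(c(rep(1, 9), 10), paste0("S", 1:10))
  w <- winsorize_means(x)          # z of the 10 is ~2.85
  log <- attr(w, "winsor_log")
  expect_equal(unname(w[["S10"]]), 1)
  expect_equal(log$strain, "S10")
  expect_equal(log$old, 10)
  expect_equal(log$new, 1)
  expect_equal(format_winsor_log(w), "S10 from 10 to 1")

  # no outliers: identical output, empty log
  y <- stats::setNames(c(1, 2, 3, 4, 5), paste0("S", 1:5))
  w2 <- winsorize_means(y)
  expect_equal(unname(w2), unname(y), ignore_attr = TRUE)
  expect_equal(nrow(attr(w2, "winsor_log")), 0L)

  # two-sided: a low outlier is raised; rank order of retained values kept
  z <- stats::setNames(c(-10, rep(1:4, 3)), paste0("S", 1:13))
  w3 <- winsorize_means(z)
  expect_equal(unname(w3[["S1"]]), 1)
  kept <- names(z)[-1]
  expect_equal(rank(w3[kept]), rank(z[kept]))

  # strain_means data frames are adjusted in the mean column
  sm <- data.frame(strain = paste0("S", 1:10), mean = c(rep(1, 9), 10))
  class(sm) <- c("strain_means", "data.frame")
  w4 <- winsorize_means(sm)
  expect_equal(w4$mean[10], 1)

  expect_error(winsorize_means(rep(2, 5)), "zero variance")
  expect_error(winsorize_means(c(1, 2)), "3 strains")
})

test_that("expected dosages are exact at markers and symmetric between flanks", {
  codes <- matrix(c("B", "B", "D",
                    "B", "D", "D"), nrow = 3,
                  dimnames = list(c("s1", "s2", "s3"), c("mL", "mR")))
  g <- structure(
    list(geno = codes,
         map = gene_map(c("1", "1"), c("mL", "mR"), c(0, 20), c(0, 40))),
    class = "geno_matrix")
  d <- expected_dosages(g, step = 10)
  expect_equal(d$map$marker[c(1, 3)], c("mL", "mR"))
  # genotyped markers are exactly +/-1
  expect_equal(unname(d$dosage[, "mL"]), c(-1, -1, 1))
  # concordant flanks reproduce the flanking code
  expect_equal(unname(d$dosage["s1", 2]), -1, tolerance = 1e-6)
  expect_equal(unname(d$dosage["s3", 2]), 1, tolerance = 1e-6)
  # equidistant discordant flanks give dosage 0
  expect_equal(unname(d$dosage["s2", 2]), 0, tolerance = 1e-12)
  # pseudomarker physical position interpolates between flanks
  expect_equal(d$map$Mb[2], 20)

  # H/U are mean-imputed from the remaining strains at that position
  codes2 <- codes; codes2["s2", "mL"] <- "H"
  g2 <- structure(list(geno = codes2, map = g$map), class = "geno_matrix")
  d2 <- expected_dosages(g2, step = 20)
  expect_equal(unname(d2$dosage["s2", "mL"]), 0)  # mean of -1, +1
})

test_that("HK scan matches the least-squares oracle", {
  # hand-computed 6-strain example
  X <- matrix(c(-1, -1, -1, 1, 1, 1), ncol = 1)
  d <- dosage_fixture(X)
  y <- stats::setNames(as.numeric(0:5), paste0("S", 1:6))
  s <- hk_scan(d, y)
  expect_equal(s$LRS, 6 * log(17.5 / 4), tolerance = 1e-10)  # ~8.855
  expect_equal(s$LRS, 8.855, tolerance = 1e-3)
  expect_equal(s$LOD, s$LRS / 4.61)
  expect_equal(s$additive, 1.5)

  # random small instances against an lm-based oracle at every position
  set.seed(20)
  for (i in 1:5) {
    n <- sample(5:10, 1)
    p <- sample(3:20, 1)
    g <- simulate_ri_genotypes(n, sim_map(2, ceiling(p / 2), 50),
                               seed = 300 + i)
    dd <- dosage_fixture(geno_codes(g), chr = g$map$chr, cM = g$map$cM)
    yy <- stats::setNames(stats::rnorm(n), rownames(g$geno))
    sc <- hk_scan(dd, yy)
    for (j in seq_len(ncol(dd$dosage))) {
      x <- dd$dosage[, j]
      if (stats::var(x) < 1e-12) {
        expect_equal(sc$LRS[j], 0)
      } else {
        or <- lrs_oracle(x, yy[rownames(dd$dosage)])
        expect_equal(sc$LRS[j], or$lrs, tolerance = 1e-8)
        expect_equal(sc$additive[j], or$slope, tolerance = 1e-8)
      }
    }
  }

  # constant phenotype scans flat; strain reordering leaves the scan unchanged
  yc <- stats::setNames(rep(3, 6), paste0("S", 1:6))
  expect_true(all(hk_scan(d, yc)$LRS == 0))
  y2 <- y[sample(names(y))]
  expect_equal(hk_scan(d, y2)$LRS, s$LRS)
  expect_error(hk_scan(d, y[1:3]), "fewer than 4")
})

test_that("permutation thresholds match the exhaustive 4-strain null", {
  X <- matrix(c(-1, -1, 1, 1,
                -1, 1, -1, 1), ncol = 2,
              dimnames = list(paste0("S", 1:4), c("m1", "m2")))
  d <- dosage_fixture(X, chr = c("1", "2"), cM = c(0, 0))
  y <- stats::setNames(c(0.3, 1.1, 2.0, 4.2), paste0("S", 1:4))

  # exhaustive null: genome-wide max LRS over all 24 orderings
  ex <- vapply(all_perms(4), function(pm) {
    max(vapply(1:2, function(j) lrs_oracle(X[, j], unname(y)[pm])$lrs,
               numeric(1)))
  }, numeric(1))

  th <- permutation_thresholds(d, y, n_perm = 3000, seed = 2)
  # sampled maxima only take values from the exhaustive support, with
  # per-atom frequencies matching the exact null
  expect_true(all(vapply(th$max_lrs, function(v)
    any(abs(v - ex) < 1e-6), logical(1))))
  atoms <- sort(unique(round(ex, 9)))
  cdf_ex <- vapply(atoms, function(a) mean(ex <= a + 1e-9), numeric(1))
  cdf_obs <- vapply(atoms, function(a) mean(th$max_lrs <= a + 1e-9),
                    numeric(1))
  expect_lt(max(abs(cdf_ex - cdf_obs)), 0.03)
  # thresholds bracket the exact-null quantile atoms
  bracket <- function(p) {
    lo <- atoms[max(which(cdf_ex < p - 0.03), 1)]
    hi <- atoms[min(which(cdf_ex >= p - 0.03))]
    c(lo, hi)
  }
  b95 <- bracket(0.95); b37 <- bracket(0.37)
  expect_true(th$significant >= b95[1] - 1e-9 &&
                th$significant <= b95[2] + 1e-9)
  expect_true(th$suggestive >= b37[1] - 1e-9 &&
                th$suggestive <= b37[2] + 1e-9)

  expect_gte(th$significant, th$suggestive)
  th2 <- permutation_thresholds(d, y, n_perm = 3000, seed = 2)
  expect_identical(th$max_lrs, th2$max_lrs)
  expect_error(permutation_thresholds(d, y, n_perm = 50), "100")
})

test_that("LOD support intervals walk out to the drop cutoff", {
  s <- scan_fixture(c(0, 1, 3, 2.8, 1.2, 0.5))
  expect_equal(unname(lod_support_interval(s, "m3")), c(3, 4))
  # flat profile spans the chromosome; peak at the first position starts there
  flat <- scan_fixture(rep(2, 5))
  expect_equal(unname(lod_support_interval(flat, "m2")), c(1, 5))
  edge <- scan_fixture(c(3, 1, 0.5, 0.2))
  expect_equal(unname(lod_support_interval(edge, "m1"))[1], 1)
  expect_error(lod_support_interval(s, "nope"), "not in scan")
})

test_that("bootstrap peak histograms conserve counts and locate strong QTLs", {
  g <- simulate_ri_genotypes(41, sim_map(3, 15, 60), seed = 40)
  X <- geno_codes(g)
  set.seed(41)
  y <- stats::setNames(sqrt(0.5) * X[, "c2_m08"] +
                         stats::rnorm(41, 0, sqrt(0.5)), rownames(X))
  d <- dosage_fixture(X, chr = g$map$chr, cM = g$map$cM, Mb = g$map$Mb)
  bp <- bootstrap_peaks(d, y, n_boot = 300, seed = 42)
  expect_equal(sum(bp), 300L)
  bp2 <- bootstrap_peaks(d, y, n_boot = 300, seed = 42)
  expect_identical(as.integer(bp), as.integer(bp2))
  # modal bin at or adjacent to the causal marker
  modal <- names(bp)[which.max(bp)]
  expect_true(modal %in% c("c2_m07", "c2_m08", "c2_m09"))
})

test_that("kinship matrix matches direct arithmetic and flags structure", {
  codes <- matrix(c("B", "B", "D", "D",
                    "B", "D", "B", "D",
                    "B", "B", "B", "D"), nrow = 3, byrow = TRUE,
                  dimnames = list(c("s1", "s2", "s3"), NULL))
  colnames(codes) <- paste0("m", 1:4)
  g <- structure(list(geno = codes,
                      map = gene_map(rep("1", 4), paste0("m", 1:4),
                                     c(0, 10, 20, 30))),
                 class = "geno_matrix")
  K <- kinship_matrix(g)
  # oracle: centered cross-product / m, rescaled to unit mean diagonal
  M <- matrix(c(-1, -1, 1, 1, -1, 1, -1, 1, -1, -1, -1, 1), 3, byrow = TRUE)
  Mc <- sweep(M, 2, colMeans(M))
  K0 <- tcrossprod(Mc) / 4
  K0 <- K0 / mean(diag(K0))
  expect_equal(unname(as.matrix(K)), unname(K0), tolerance = 1e-12,
               ignore_attr = TRUE)

  # identical strains have off-diagonal equal to the diagonal
  codes2 <- rbind(codes, s4 = codes["s1", ])
  g2 <- structure(list(geno = codes2, map = g$map), class = "geno_matrix")
  K2 <- kinship_matrix(g2)
  expect_equal(K2["s1", "s4"], K2["s1", "s1"])

  # independent genotypes: off-diagonals near the centering offset -1/(n-1)
  big <- simulate_ri_genotypes(20, sim_map(20, 40, 1e5), seed = 50)
  K3 <- kinship_matrix(big)
  expect_true(all(abs(K3[upper.tri(K3)] + 1 / 19) < 0.15))
})

test_that("kinship-adjusted scan reduces inflation and collapses to HK", {
  g <- simulate_ri_genotypes(30, sim_map(3, 12, 60), seed = 60)
  X <- geno_codes(g)
  d <- dosage_fixture(X, chr = g$map$chr, cM = g$map$cM, Mb = g$map$Mb)
  set.seed(61)
  y <- stats::setNames(stats::rnorm(30), rownames(X))

  # K proportional to the identity: statistics equal the HK scan
  KI <- diag(30); dimnames(KI) <- list(rownames(X), rownames(X))
  class(KI) <- c("kinship_matrix", class(KI))
  s_lmm <- kinship_lmm_scan(d, y, KI)
  s_hk <- hk_scan(d, y)
  expect_equal(s_lmm$LRS, s_hk$LRS, tolerance = 1e-6)
  expect_gt(stats::cor(s_lmm$LRS, s_hk$LRS, method = "spearman"), 0.99)
  expect_equal(which.max(s_lmm$LRS), which.max(s_hk$LRS))

  # two-cluster relatedness with polygenic signal: mean null statistic is
  # smaller under the mixed model than under plain HK
  set.seed(62)
  cl <- rep(c(0, 1), each = 15)
  Kc <- 0.9 * outer(cl, cl, "==") + 0.1 * diag(30)
  dimnames(Kc) <- list(rownames(X), rownames(X))
  class(Kc) <- c("kinship_matrix", class(Kc))
  infl_hk <- numeric(10); infl_lmm <- numeric(10)
  for (i in 1:10) {
    yp <- stats::setNames(2 * cl + stats::rnorm(30, 0, 0.7), rownames(X))
    infl_hk[i] <- mean(hk_scan(d, yp)$LRS)
    infl_lmm[i] <- mean(kinship_lmm_scan(d, yp, Kc)$LRS)
  }
  expect_lt(mean(infl_lmm), mean(infl_hk))

  # invalid kinship inputs are rejected
  Kbad <- diag(30); Kbad[1, 1] <- -2
  dimnames(Kbad) <- list(rownames(X), rownames(X))
  expect_error(kinship_lmm_scan(d, y, Kbad), "positive semidefinite")
  Kasym <- KI; Kasym[1, 2] <- 0.5
  expect_error(kinship_lmm_scan(d, y, Kasym), "symmetric")
})

test_that("peak report splits sibling peaks and counts discordant strains", {
  # no position above suggestive: empty report
  s0 <- scan_fixture(c(0.2, 0.3, 0.1))
  th0 <- list(significant = 15, suggestive = 10)
  expect_equal(nrow(peak_report(s0, th0)), 0L)

  # constructed two-peak chromosome with 8 planted recombinant strains
  n <- 20
  alle1 <- rep(c("B", "D"), each = 10)
  alle2 <- alle1
  flip <- c(1:4, 11:14)         # 8 strains discordant between the peaks
  alle2[flip] <- ifelse(alle1[flip] == "B", "D", "B")
  codes <- cbind(p1 = alle1, mid = alle1, p2 = alle2)
  rownames(codes) <- paste0("S", 1:n)
  gmap <- gene_map(rep("14", 3), c("p1", "mid", "p2"), c(0, 10, 20),
                   c(55, 62, 70))
  g <- structure(list(geno = codes, map = gmap), class = "geno_matrix")

  lodp <- c(4, 1.2, 3.8)        # dips below suggestive between peaks
  s <- scan_fixture(lodp, mb = c(55, 62, 70), chr = "14")
  s$marker <- c("p1", "mid", "p2")
  th <- list(significant = 3.5 * 4.61, suggestive = 1.5 * 4.61)
  pk <- peak_report(s, th, g)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$marker, c("p1", "p2"))
  expect_equal(pk$discordant_n, c(8L, 8L))
  expect_true(all(pk$significant))

  # overlap flag responds to interval arithmetic: with the dip inside both
  # peaks' 1.5-LOD drop, the sibling intervals meet at the middle marker
  s2 <- scan_fixture(c(4, 2.6, 3.8), mb = c(55, 62, 70), chr = "14")
  s2$marker <- c("p1", "mid", "p2")
  pk2 <- peak_report(s2, list(significant = 30, suggestive = 3.0 * 4.61), g)
  expect_equal(nrow(pk2), 2L)
  expect_true(all(pk2$overlaps_sibling))
})
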