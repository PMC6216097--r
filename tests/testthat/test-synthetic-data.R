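test_that("RI genotype mosaics follow the sib-mating recombination model", {
  # zero map distance forbids recombination: constant rows
  m0 <- gene_map(rep("1", 4), paste0("m", 1:4), rep(5, 4), rep(10, 4))
  g0 <- simulate_ri_genotypes(20, m0, seed = 1)
  expect_true(all(apply(g0$geno, 1, function(r) length(unique(r)) == 1L)))

  # discordance at r matches the expansion 4r/(1+6r); r = 0.5 gives 0.5
  expect_equal(ri_expand(0.5), 0.5)
  expect_equal(ri_expand(0.1), 0.25)
  for (r in c(0.01, 0.05, 0.1, 0.2)) {
    d <- -50 * log(1 - 2 * r)  # invert Haldane
    m <- gene_map(c("1", "1"), c(sprintf("a%g", r), sprintf("b%g", r)),
                  c(0, d))
    g <- simulate_ri_genotypes(2000, m, seed = round(1000 * r))
    disc <- mean(g$geno[, 1] != g$geno[, 2])
    expect_equal(disc, ri_expand(r), tolerance = 0.02 / max(ri_expand(r), 0.1))
  }

  # allele frequency per marker ~ 0.5 (binomial 4-sigma band at n = 2000)
  m <- sim_map(2, 10, 50)
  g <- simulate_ri_genotypes(2000, m, seed = 7)
  freq <- colMeans(g$geno == "D")
  expect_true(all(abs(freq - 0.5) < 4 * sqrt(0.25 / 2000)))

  # reproducible under a fixed seed, errors on bad input
  g2 <- simulate_ri_genotypes(2000, m, seed = 7)
  expect_identical(g$geno, g2$geno)
  expect_error(simulate_ri_genotypes(1, m), "n_strains")
  expect_error(gene_map(c("1", "1"), c("a", "b"), c(5, 1)), "non-monotone")
})

test_that("RI phenotypes realize the configured variance structure", {
  g <- simulate_ri_genotypes(10, sim_map(1, 5, 40), seed = 1)

  # all fractions zero and no QTL: every value is the grand mean
  cfg0 <- sim_config(variance_fractions = c(strain_background = 0,
                                            litter = 0, maternal = 0,
                                            residual = 0),
                     day_effects = c(0, 0, 0), grand_mean = 42, seed = 2)
  p0 <- simulate_ri_phenotypes(g, cfg0)
  expect_true(all(p0$amplitude_db == 42))
  expect_equal(sort(unique(p0$day)), c(7, 8, 9))

  # litters nested in strains; every pup seen on every day
  expect_true(all(startsWith(p0$litter, p0$strain)))
  expect_true(all(table(p0$pup) == 3L))

  # R^2 of strain means on the causal marker ~ its share of genetic variance
  big <- simulate_ri_genotypes(400, sim_map(1, 5, 40), seed = 3)
  q <- 0.5
  cfg <- sim_config(qtl_spec = c(c1_m03 = q),
                    variance_fractions = c(strain_background = 1, litter = 0,
                                           maternal = 0, residual = 0),
                    day_effects = c(0, 0, 0), seed = 4)
  p <- simulate_ri_phenotypes(big, cfg)
  sm <- strain_means(p, "amplitude_db", day = 7)
  x <- geno_codes(big)[sm$strain, "c1_m03"]
  r2 <- summary(stats::lm(sm$mean ~ x))$r.squared
  expect_equal(r2, q, tolerance = 0.08)

  # unknown QTL marker and bad fractions are rejected
  expect_error(simulate_ri_phenotypes(g, sim_config(qtl_spec = c(nope = 0.5))),
               "absent")
  expect_error(sim_config(variance_fractions = c(strain_background = 0.9,
                                                 litter = 0.9, maternal = 0,
                                                 residual = 0)),
               "sum")
})

test_that("diallel simulation encodes maternal and parent-of-origin structure", {
  # bookkeeping: configured litters and pups per group, alternating sexes
  cfg <- diallel_config(litters_per_group = 3, pups_per_litter = 4, seed = 1)
  d <- simulate_diallel(cfg)
  d8 <- d[d$day == 8, ]
  expect_equal(unname(table(d8$strain)), rep(12L, 4), ignore_attr = TRUE)
  expect_equal(length(unique(d8$litter)), 12L)
  expect_equal(unname(table(d8$sex[d8$litter == d8$litter[1]])), c(2L, 2L),
               ignore_attr = TRUE)

  # zero maternal and POE deviations: reciprocal F1 means converge
  big0 <- simulate_diallel(diallel_config(litters_per_group = 200,
                                          pups_per_litter = 5,
                                          residual_sd = 1, seed = 2))
  dd <- mean(big0$amplitude_db[big0$strain == "B6D2F1"]) -
    mean(big0$amplitude_db[big0$strain == "D2B6F1"])
  expect_lt(abs(dd), 0.15)

  # maternal deviations +1/-1, nothing else: E[B6D2F1 - D2B6F1] = 2
  big1 <- simulate_diallel(diallel_config(litters_per_group = 50,
                                          pups_per_litter = 5,
                                          maternal_dev = c(B6 = 1, D2 = -1),
                                          residual_sd = 0.5, seed = 3))
  dd1 <- mean(big1$amplitude_db[big1$strain == "B6D2F1"]) -
    mean(big1$amplitude_db[big1$strain == "D2B6F1"])
  expect_equal(dd1, 2, tolerance = 0.15)

  # POE deviation contributes with opposite sign to the reciprocal groups
  big2 <- simulate_diallel(diallel_config(litters_per_group = 50,
                                          pups_per_litter = 5,
                                          maternal_dev = c(B6 = 1, D2 = -1),
                                          poe_dev = 0.5,
                                          residual_sd = 0.5, seed = 4))
  dd2 <- mean(big2$amplitude_db[big2$strain == "B6D2F1"]) -
    mean(big2$amplitude_db[big2$strain == "D2B6F1"])
  expect_equal(dd2, 2 * (1 + 0.5), tolerance = 0.15)
})

test_that("call-type counts are multinomial over the ten categories", {
  # degenerate profile: all calls in one category
  pr <- rep(0, 10); names(pr) <- calltype_categories(); pr["complex"] <- 1
  cts <- simulate_calltype_counts(pr, 57, seed = 1)
  expect_equal(unname(cts["complex"]), 57L)
  expect_equal(sum(cts), 57L)

  # conservation for arbitrary draws
  u <- rep(0.1, 10)
  expect_equal(sum(simulate_calltype_counts(u, 123, seed = 2)), 123L)

  # chi-square goodness of fit non-rejection near the nominal rate
  rej <- vapply(1:200, function(i) {
    cts <- simulate_calltype_counts(u, 10000, seed = i)
    suppressWarnings(stats::chisq.test(cts, p = u)$p.value) < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.05)

  expect_error(simulate_calltype_counts(rep(0.11, 10), 10), "sum to 1")
  expect_error(simulate_calltype_counts(u, -1), "non-negative")
})
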