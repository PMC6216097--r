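#' Simulation configuration for RI phenotypes
#'
#' Defines the variance structure used by [simulate_ri_phenotypes()]. Each
#' pup x day value is the sum of grand mean, QTL additive effects, strain
#' polygenic deviate, litter deviate, maternal (dam) deviate, day shift,
#' and residual,
#' with component variances scaled so the realized fractions of total
#' variance match `variance_fractions` in expectation. QTL effects are
#' nested inside the strain-level fraction: a QTL declared at fraction q
#' accounts for q of the strain-level (genetic) variance, the remainder
#' being the polygenic strain deviate.
#'
#' @param qtl_spec named numeric vector: fractions of the strain-level
#'   genetic variance attributed to additive QTLs, named by causal marker.
#'   May be empty.
#' @param variance_fractions named numeric vector with entries
#'   `strain_background`, `litter`, `maternal`, `residual`, each in \[0,1\]
#'   and summing to at most 1. Defaults (0.6, 0.2, 0, 0.2) reflect a
#'   strongly heritable USV trait with substantial litter effects.
#' @param litters_per_strain litters per strain (default 4).
#' @param pups_per_litter pups per litter (default 2).
#' @param days recording days; default postnatal days 7, 8, 9.
#' @param day_effects fixed additive shifts per day, on the trait scale;
#'   default small shifts worth about 1 percent of total variance.
#' @param pup_day_cor within-pup day-to-day correlation of the residual
#'   component, at least 0 and below 1; default 0.
#' @param trait name of the generated trait column.
#' @param grand_mean trait grand mean.
#' @param total_var total phenotypic variance to target.
#' @param seed integer seed or NULL.
#' @return a list of class `sim_config`.
#' @examples
#' sim_config(qtl_spec = c(c1_m05 = 0.5))
#' @export
sim_config <- function(qtl_spec = numeric(0),
                       variance_fractions = c(strain_background = 0.6,
                                              litter = 0.2,
                                              maternal = 0,
                                              residual = 0.2),
                       litters_per_strain = 4,
                       pups_per_litter = 2,
                       days = c(7, 8, 9),
                       day_effects = NULL,
                       pup_day_cor = 0,
                       trait = "amplitude_db",
                       grand_mean = 0,
                       total_var = 1,
                       seed = NULL) {
  need <- c("strain_background", "litter", "maternal", "residual")
  if (!all(need %in% names(variance_fractions)))
    stop("variance_fractions must name: ", paste(need, collapse = ", "))
  vf <- variance_fractions[need]
  if (any(vf < 0 | vf > 1)) stop("variance fractions must lie in [0, 1]")
  if (sum(vf) > 1 + 1e-8) stop("variance fractions must sum to at most 1")
  if (length(qtl_spec)) {
    if (is.null(names(qtl_spec)) || any(!nzchar(names(qtl_spec))))
      stop("qtl_spec must be named by marker")
    if (any(qtl_spec < 0 | qtl_spec > 1))
      stop("QTL fractions must lie in [0, 1]")
    if (sum(qtl_spec) > 1 + 1e-8)
      stop("QTL fractions (of genetic variance) must sum to at most 1")
  }
  if (pup_day_cor < 0 || pup_day_cor >= 1)
    stop("pup_day_cor must lie in [0, 1)")
  if (is.null(day_effects)) {
    ## small fixed day shifts: spread worth ~1% of total variance
    s <- sqrt(0.01 * total_var)
    day_effects <- s * seq(-1, 1, length.out = length(days)) * sqrt(1.5)
  }
  if (length(day_effects) != length(days))
    stop("day_effects must match days in length")
  structure(list(qtl_spec = qtl_spec, variance_fractions = vf,
                 litters_per_strain = as.integer(litters_per_strain),
                 pups_per_litter = as.integer(pups_per_litter),
                 days = days, day_effects = day_effects,
                 pup_day_cor = pup_day_cor, trait = trait,
                 grand_mean = grand_mean, total_var = total_var,
                 seed = seed),
            class = "sim_config")
}

#' Simulate phenotypes for an RI panel
#'
#' Generates one record per pup per recording day, with litters nested in
#' strains and the variance structure declared in the [sim_config()].
#'
#' @param geno a `geno_matrix` from [simulate_ri_genotypes()] or
#'   [read_geno()].
#' @param config a [sim_config()].
#' @return a `data.frame` phenotype table with columns `strain`, `litter`,
#'   `pup`, `sex`, `day`, `weight_g`, and the configured trait column.
#' @examples
#' g <- simulate_ri_genotypes(6, sim_map(1, 5, 40), seed = 1)
#' p <- simulate_ri_phenotypes(g, sim_config(seed = 2))
#' head(p)
#' @export
simulate_ri_phenotypes <- function(geno, config = sim_config()) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(config, "sim_config"))
  vf <- config$variance_fractions
  V <- config$total_var
  qs <- config$qtl_spec
  if (length(qs)) {
    miss <- setdiff(names(qs), colnames(geno$geno))
    if (length(miss))
      stop("QTL marker(s) absent from genotypes: ",
           paste(miss, collapse = ", "))
  }
  strains <- rownames(geno$geno)
  S <- length(strains)
  L <- config$litters_per_strain
  P <- config$pups_per_litter
  days <- config$days
  with_seed(config$seed, {
    v_strain <- vf[["strain_background"]] * V
    ## additive QTL effect sizes: dosage is +/-1, so var(a * x) = a^2
    g_strain <- numeric(S)
    if (length(qs)) {
      a <- sqrt(qs * v_strain)
      dos <- geno_codes(geno)[, names(qs), drop = FALSE]
      dos[is.na(dos)] <- 0
      g_strain <- as.numeric(dos %*% a)
    }
    v_poly <- v_strain * (1 - if (length(qs)) sum(qs) else 0)
    g_strain <- g_strain + stats::rnorm(S, 0, sqrt(v_poly))

    lit_id <- sprintf("%s_L%d", rep(strains, each = L), rep(seq_len(L), S))
    lit_eff <- stats::rnorm(S * L, 0, sqrt(vf[["litter"]] * V)) +
      stats::rnorm(S * L, 0, sqrt(vf[["maternal"]] * V))

    n_pups <- S * L * P
    pup_strain <- rep(strains, each = L * P)
    pup_litter <- rep(lit_id, each = P)
    pup_id <- sprintf("%s_p%d", pup_litter, rep(seq_len(P), S * L))
    pup_sex <- rep(c("F", "M"), length.out = n_pups)

    v_res <- vf[["residual"]] * V
    rho <- config$pup_day_cor
    pup_eff <- stats::rnorm(n_pups, 0, sqrt(rho * v_res))

    nd <- length(days)
    strain_g <- g_strain[match(pup_strain, strains)]
    litter_e <- lit_eff[match(pup_litter, lit_id)]
    base <- config$grand_mean + strain_g + litter_e + pup_eff

    out <- data.frame(
      strain = rep(pup_strain, times = nd),
      litter = rep(pup_litter, times = nd),
      pup = rep(pup_id, times = nd),
      sex = rep(pup_sex, times = nd),
      day = rep(days, each = n_pups),
      weight_g = rep(stats::rnorm(n_pups, 5, 0.4), times = nd) +
        0.5 * (rep(days, each = n_pups) - days[1]),
      stringsAsFactors = FALSE
    )
    out[[config$trait]] <- rep(base, times = nd) +
      rep(config$day_effects, each = n_pups) +
      stats::rnorm(n_pups * nd, 0, sqrt((1 - rho) * v_res))
    out <- out[order(out$strain, out$litter, out$pup, out$day), ]
    rownames(out) <- NULL
    out
  })
}
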