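#' Configuration for a reciprocal diallel simulation
#'
#' The diallel comprises four pup genotypes: the two parental strains (`B6`,
#' `D2`) and the reciprocal F1 hybrids (`B6D2F1`: B6 dam x D2 sire;
#' `D2B6F1`: D2 dam x B6 sire). The reciprocal F1s share an identical
#' autosomal genetic value by construction; they differ only through the
#' dam's maternal deviation and a parent-of-origin deviation applied with
#' opposite sign to the two reciprocal groups.
#'
#' Default strain means and residual scale follow a call-amplitude-like
#' trait (parental means around -36 and -23 dB, hybrids around -39 dB,
#' residual SD 8 dB) with six litters of five pups per group.
#'
#' @param litters_per_group litters per genotype group (default 6).
#' @param pups_per_litter pups per litter (default 5).
#' @param strain_means named numeric vector with entries `B6`, `D2`, `F1`
#'   (the shared genetic value of both reciprocal hybrids).
#' @param maternal_dev named numeric vector `c(B6 = ..., D2 = ...)`: deviation
#'   added to every pup raised by a dam of that strain (F1 pups receive their
#'   dam's deviation; parental pups their own strain's).
#' @param poe_dev parent-of-origin deviation: added to `B6D2F1` pups and
#'   subtracted from `D2B6F1` pups.
#' @param residual_sd residual standard deviation (default 8).
#' @param litter_sd SD of a shared random litter deviate (default 0).
#' @param days recording days (default 7, 8, 9).
#' @param trait generated trait column name.
#' @param seed integer seed or NULL.
#' @return a list of class `diallel_config`.
#' @export
diallel_config <- function(litters_per_group = 6, pups_per_litter = 5,
                           strain_means = c(B6 = -36, D2 = -23, F1 = -39),
                           maternal_dev = c(B6 = 0, D2 = 0),
                           poe_dev = 0, residual_sd = 8, litter_sd = 0,
                           days = c(7, 8, 9), trait = "amplitude_db",
                           seed = NULL) {
  if (!all(c("B6", "D2", "F1") %in% names(strain_means)))
    stop("strain_means must name B6, D2 and F1")
  if (!all(c("B6", "D2") %in% names(maternal_dev)))
    stop("maternal_dev must name B6 and D2")
  stopifnot(litters_per_group >= 1, pups_per_litter >= 1, residual_sd >= 0,
            litter_sd >= 0)
  structure(list(litters_per_group = as.integer(litters_per_group),
                 pups_per_litter = as.integer(pups_per_litter),
                 strain_means = strain_means, maternal_dev = maternal_dev,
                 poe_dev = poe_dev, residual_sd = residual_sd,
                 litter_sd = litter_sd, days = days, trait = trait,
                 seed = seed),
            class = "diallel_config")
}

#' Simulate a reciprocal diallel cross
#'
#' Generates pup x day records for the four diallel groups. Genetic values:
#' parental pups receive their strain mean and both reciprocal F1 groups the
#' shared `F1` mean. `B6D2F1` pups receive the B6 maternal deviation plus the
#' parent-of-origin deviation; `D2B6F1` pups the D2 maternal deviation minus
#' it. Sexes alternate female/male within each litter.
#'
#' The expected reciprocal-F1 mean difference (B6-dam group minus D2-dam
#' group) is therefore `(maternal_dev["B6"] - maternal_dev["D2"]) + 2 * poe_dev`,
#' i.e. twice the sum of the maternal contrast and the parent-of-origin
#' deviation.
#'
#' @param config a [diallel_config()].
#' @return a phenotype `data.frame` with columns `strain` (the group label),
#'   `litter`, `pup`, `sex`, `day`, `weight_g` and the trait column.
#' @examples
#' d <- simulate_diallel(diallel_config(seed = 1))
#' table(d$strain[d$day == 8])
#' @export
simulate_diallel <- function(config = diallel_config()) {
  stopifnot(inherits(config, "diallel_config"))
  groups <- c("B6", "D2", "B6D2F1", "D2B6F1")
  dam_of <- c(B6 = "B6", D2 = "D2", B6D2F1 = "B6", D2B6F1 = "D2")
  gval <- c(B6 = unname(config$strain_means["B6"]),
            D2 = unname(config$strain_means["D2"]),
            B6D2F1 = unname(config$strain_means["F1"]),
            D2B6F1 = unname(config$strain_means["F1"]))
  poe <- c(B6 = 0, D2 = 0, B6D2F1 = config$poe_dev, D2B6F1 = -config$poe_dev)
  L <- config$litters_per_group
  P <- config$pups_per_litter
  days <- config$days
  with_seed(config$seed, {
    grp <- rep(groups, each = L * P)
    lit <- sprintf("%s_L%d", rep(groups, each = L * P),
                   rep(rep(seq_len(L), each = P), length(groups)))
    pup <- sprintf("%s_p%d", lit, rep(seq_len(P), length(groups) * L))
    sex <- rep(rep(c("F", "M"), length.out = P), length(groups) * L)
    lit_ids <- unique(lit)
    lit_eff <- stats::rnorm(length(lit_ids), 0, config$litter_sd)
    base <- gval[grp] + config$maternal_dev[dam_of[grp]] + poe[grp] +
      lit_eff[match(lit, lit_ids)]
    n <- length(grp)
    nd <- length(days)
    out <- data.frame(
      strain = rep(grp, times = nd),
      litter = rep(lit, times = nd),
      pup = rep(pup, times = nd),
      sex = rep(sex, times = nd),
      day = rep(days, each = n),
      weight_g = rep(stats::rnorm(n, 5, 0.4), times = nd) +
        0.5 * (rep(days, each = n) - days[1]),
      stringsAsFactors = FALSE
    )
    out[[config$trait]] <- rep(base, times = nd) +
      stats::rnorm(n * nd, 0, config$residual_sd)
    out <- out[order(out$strain, out$litter, out$pup, out$day), ]
    rownames(out) <- NULL
    out
  })
}

#' The ten USV call-type categories
#'
#' Syllable categories used for qualitative call classification.
#' @return character vector of length 10.
#' @export
calltype_categories <- function() {
  c("complex", "two_syllable", "upward", "downward", "chevron", "short",
    "flat", "frequency_steps", "harmonics", "composite")
}

#' Simulate multinomial call-type counts
#'
#' Draws a vector of counts over the ten call-type categories from a
#' multinomial distribution.
#'
#' @param profile numeric vector of 10 category probabilities summing to 1
#'   (within 1e-9); names default to [calltype_categories()].
#' @param total total number of calls (>= 0).
#' @param seed integer seed or NULL.
#' @return named integer vector of 10 counts summing to `total`.
#' @examples
#' simulate_calltype_counts(rep(0.1, 10), 100, seed = 1)
#' @export
simulate_calltype_counts <- function(profile, total, seed = NULL) {
  if (length(profile) != 10L) stop("profile must have 10 probabilities")
  if (any(profile < 0)) stop("profile probabilities must be non-negative")
  if (abs(sum(profile) - 1) > 1e-9)
    stop("profile probabilities must sum to 1 (within 1e-9)")
  if (total < 0) stop("total must be non-negative")
  if (is.null(names(profile))) names(profile) <- calltype_categories()
  with_seed(seed, {
    counts <- as.integer(stats::rmultinom(1, size = as.integer(total),
                                          prob = profile))
    names(counts) <- names(profile)
    counts
  })
}
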