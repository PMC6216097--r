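#' Sequential ANOVA variance partition
#'
#' Fits a fixed-effects linear model with the caller's terms in the given
#' order and partitions the total sum of squares sequentially (type-I), so
#' each factor is adjusted only for those preceding it. The fraction of
#' total SS explained by each term, including the residual, sums to 1.
#'
#' Character columns are coerced to factors; `day` is also treated as a
#' factor. Interaction terms may be given with `:` notation.
#'
#' @param table phenotype `data.frame`.
#' @param trait trait column name.
#' @param factors ordered character vector of model terms, e.g.
#'   `c("strain", "litter")` or
#'   `c("strain", "litter", "sex", "day", "weight_g", "strain:sex")`.
#' @return a data frame of class `variance_decomp` with columns `term`,
#'   `df`, `sumsq`, `meansq`, `statistic` (F), `p.value`, `fraction`.
#' @examples
#' p <- data.frame(strain = rep(c("A", "B"), each = 4),
#'                 litter = rep(c("a1", "a2", "b1", "b2"), each = 2),
#'                 y = c(1, 1, 3, 3, 5, 5, 7, 7))
#' variance_partition(p, "y", c("strain", "litter"))
#' @export
variance_partition <- function(table, trait, factors) {
  if (!trait %in% names(table)) stop("trait column not found: ", trait)
  y <- table[[trait]]
  if (all(is.na(y)) || stats::var(y, na.rm = TRUE) == 0)
    stop("zero total variance in trait ", trait)
  dat <- table
  base_terms <- unique(unlist(strsplit(factors, ":", fixed = TRUE)))
  miss <- setdiff(base_terms, names(dat))
  if (length(miss)) stop("factor column(s) not found: ",
                         paste(miss, collapse = ", "))
  for (f in base_terms) {
    if (is.character(dat[[f]]) || is.logical(dat[[f]]) || f == "day")
      dat[[f]] <- factor(dat[[f]])
    if (is.factor(dat[[f]]) && nlevels(droplevels(dat[[f]])) < 2)
      stop("factor with a single level: ", f)
  }
  fml <- stats::as.formula(paste(trait, "~", paste(factors, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  an <- stats::anova(fit)
  out <- data.frame(term = rownames(an), df = an$Df, sumsq = an$`Sum Sq`,
                    meansq = an$`Mean Sq`, statistic = an$`F value`,
                    p.value = an$`Pr(>F)`, stringsAsFactors = FALSE)
  out$fraction <- out$sumsq / sum(out$sumsq)
  rownames(out) <- NULL
  class(out) <- c("variance_decomp", "data.frame")
  out
}

#' Broad-sense heritability from a strain-only ANOVA
#'
#' H2 is the fraction of total phenotypic sum of squares explained by
#' strain in a strain-only partition. The between- and within-strain
#' variance components backing the strain-mean heritability are extracted
#' from the mean squares by the balanced-design moment estimator:
#' Va = (MS_strain - MS_within) / n (floored at 0) with n the mean
#' per-strain record count, and Ve = MS_within.
#'
#' @param table phenotype `data.frame` (subset rows to a single day, or
#'   average per pup first, as required).
#' @param trait trait column name.
#' @param day optional: restrict to one recording day before fitting.
#' @return an object of class `herit_est`: list with `estimator`
#'   (`"H2_strain_only"`), `value`, `Va`, `Ve`, `n`, `day`, `ci`
#'   (NA until filled by [subsample_ci()]).
#' @examples
#' p <- data.frame(strain = rep(c("A", "B"), each = 4),
#'                 y = c(1, 1, 3, 3, 5, 5, 7, 7))
#' broad_h2(p, "y")$value  # 0.8
#' @export
broad_h2 <- function(table, trait, day = NULL) {
  if (!is.null(day)) table <- table[table$day == day, , drop = FALSE]
  counts <- table(table$strain[!is.na(table[[trait]])])
  if (length(counts) < 2 || any(counts < 2))
    stop("at least 2 strains with at least 2 records each required")
  vp <- variance_partition(table, trait, "strain")
  ms_strain <- vp$meansq[vp$term == "strain"]
  ms_within <- vp$meansq[vp$term == "Residuals"]
  nbar <- mean(counts)
  va <- max((ms_strain - ms_within) / nbar, 0)
  structure(list(estimator = "H2_strain_only",
                 value = vp$fraction[vp$term == "strain"],
                 Va = va, Ve = ms_within, n = nbar,
                 day = if (is.null(day)) NA else day,
                 ci = c(NA_real_, NA_real_)),
            class = "herit_est")
}

#' @export
print.herit_est <- function(x, digits = 3, ...) {
  cat(sprintf("%s = %.*f", x$estimator, digits, x$value))
  if (!is.na(x$day)) cat("  (day", x$day, ")")
  cat(sprintf("\n  Va = %.*f, Ve = %.*f, n = %.2f\n",
              digits, x$Va, digits, x$Ve, x$n))
  if (!anyNA(x$ci))
    cat(sprintf("  95%% CI [%.*f, %.*f]\n", digits, x$ci[1], digits, x$ci[2]))
  invisible(x)
}

#' Heritability of strain means
#'
#' For replicated inbred lines the same genome is sampled n times, so the
#' heritability of the strain mean exceeds the individual-level value:
#' HRIxbar2 = Va / (Va + Ve / n), where Va is the between-strain (genetic)
#' variance, Ve the within-strain (environmental) variance, and n the
#' number of within-line replicates. With n = 1 this reduces to the
#' individual-level ratio Va / (Va + Ve).
#'
#' @param Va between-strain variance component (>= 0).
#' @param Ve within-strain variance (>= 0); `Va + Ve` must be positive.
#' @param n within-line replicate count (>= 1).
#' @return heritability of the strain mean, in \[0, 1\].
#' @examples
#' hri2(1, 1, 4)      # 0.8
#' hri2(0.2, 0.8, 1)  # 0.2
#' @export
hri2 <- function(Va, Ve, n) {
  if (Va < 0 || Ve < 0) stop("variance components must be non-negative")
  if (Va + Ve <= 0) stop("Va + Ve must be positive")
  if (n < 1) stop("n must be >= 1")
  Va / (Va + Ve / n)
}

#' Subsample confidence interval for a table statistic
#'
#' Recomputes a statistic on repeated random subsets of the records
#' (without replacement, `keep_fraction` of the rows each time) and returns
#' the 2.5th and 97.5th percentiles of the resampled values as an empirical
#' 95 percent interval.
#'
#' @param table phenotype `data.frame`.
#' @param statistic function mapping a table to a single numeric value.
#' @param iterations number of subsets (>= 100).
#' @param keep_fraction fraction of rows kept per subset, in (0, 1\];
#'   default 0.95.
#' @param seed integer seed or NULL.
#' @return named numeric `c(lower, upper)`, with the resampled statistics
#'   attached as attribute `samples`.
#' @export
subsample_ci <- function(table, statistic, iterations = 1000,
                         keep_fraction = 0.95, seed = NULL) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must lie in (0, 1]")
  if (iterations < 100) stop("iterations must be >= 100")
  N <- nrow(table)
  m <- floor(keep_fraction * N)
  if (m < 1) stop("subset too small for the statistic")
  with_seed(seed, {
    vals <- vapply(seq_len(iterations), function(i) {
      statistic(table[sample.int(N, m), , drop = FALSE])
    }, numeric(1))
    out <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
    names(out) <- c("lower", "upper")
    attr(out, "samples") <- vals
    out
  })
}

#' Inverse-squared-error weighted mean of heritability estimates
#'
#' Combines per-day heritability estimates into a single value, weighting
#' each by the inverse square of its standard error. Entries with a missing
#' standard error are excluded.
#'
#' @param estimates numeric vector of heritability values.
#' @param ses standard errors of the same length (positive or NA).
#' @return the weighted mean.
#' @examples
#' combine_across_days(c(0.4, 0.6), c(0.1, 0.2))  # 0.44
#' @export
combine_across_days <- function(estimates, ses) {
  if (length(estimates) != length(ses))
    stop("estimates and ses must have equal length")
  ok <- !is.na(estimates) & !is.na(ses)
  if (any(ses[ok] <= 0)) stop("standard errors must be positive")
  if (!any(ok)) stop("no usable entries")
  w <- 1 / ses[ok]^2
  sum(estimates[ok] * w) / sum(w)
}

#' Z-scores and normal-probability coordinates for strain means
#'
#' Standardizes the values and pairs the sorted empirical quantiles with
#' their theoretical normal counterparts, the coordinates of a normal
#' probability (q-q) plot. The largest successive gap between sorted
#' z-scores is returned as a simple bimodality indicator: a trait under a
#' single large-effect locus tends to split into two modes, which shows up
#' as a jump in the normal probability plot.
#'
#' @param values numeric vector of strain means (>= 3, non-constant).
#' @return a list of class `trait_diag`: `z` (z-scores in input order),
#'   `qq` (data frame `theoretical`, `empirical`, both ascending), and
#'   `max_gap` (largest successive gap between sorted z-scores).
#' @export
trait_diagnostics <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("at least 3 values required")
  s <- stats::sd(values)
  if (s == 0) stop("zero variance input")
  z <- (values - mean(values)) / s
  emp <- sort(z)
  theo <- stats::qnorm(stats::ppoints(length(z)))
  structure(list(z = z,
                 qq = data.frame(theoretical = theo, empirical = emp),
                 max_gap = max(diff(emp))),
            class = "trait_diag")
}

#' @export
plot.trait_diag <- function(x, ...) {
  graphics::plot(x$qq$theoretical, x$qq$empirical,
                 xlab = "theoretical normal quantile",
                 ylab = "empirical quantile (z)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
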