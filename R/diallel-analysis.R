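#' Compare a quantitative trait across groups
#'
#' Runs the rank-based overall test (Kruskal-Wallis), unadjusted pairwise
#' Wilcoxon rank-sum tests, and the parametric Tukey honest significant
#' difference contrasts from a one-way ANOVA, together with per-group
#' summary statistics.
#'
#' @param table phenotype `data.frame`.
#' @param trait trait column name.
#' @param grouping grouping column; default `"strain"`.
#' @return a list of class `group_comparison`: `kruskal` (htest),
#'   `pairwise_wilcox` (symmetric matrix of raw p-values), `tukey` (data
#'   frame of adjusted pairwise contrasts), `groups` (summary data frame).
#' @export
group_comparison <- function(table, trait, grouping = "strain") {
  if (!trait %in% names(table)) stop("trait column not found: ", trait)
  g <- factor(table[[grouping]])
  y <- table[[trait]]
  keep <- !is.na(y) & !is.na(g)
  g <- droplevels(g[keep]); y <- y[keep]
  cnt <- table(g)
  if (length(cnt) < 2) stop("at least 2 groups required")
  if (any(cnt < 2)) stop("group with fewer than 2 observations: ",
                         paste(names(cnt)[cnt < 2], collapse = ", "))
  kw <- stats::kruskal.test(y ~ g)
  pw <- stats::pairwise.wilcox.test(y, g, p.adjust.method = "none",
                                    exact = FALSE)
  lv <- levels(g)
  mat <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in rownames(pw$p.value)) for (j in colnames(pw$p.value)) {
    v <- pw$p.value[i, j]
    if (!is.na(v)) { mat[i, j] <- v; mat[j, i] <- v }
  }
  tk <- stats::TukeyHSD(stats::aov(y ~ g))$g
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p.adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(lv, function(l) {
    v <- y[g == l]
    data.frame(group = l, n = length(v), mean = mean(v), sd = stats::sd(v),
               se = stats::sd(v) / sqrt(length(v)), median = stats::median(v),
               stringsAsFactors = FALSE)
  }))
  structure(list(kruskal = kw, pairwise_wilcox = mat, tukey = tukey,
                 groups = groups),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.3f, df = %d, p = %.3g\n",
              unname(x$kruskal$statistic), unname(x$kruskal$parameter),
              x$kruskal$p.value))
  cat("groups:\n"); print(x$groups, digits = 4)
  invisible(x)
}

#' Reciprocal-F1 parent-of-origin test
#'
#' Two-sample rank (Wilcoxon) test between the reciprocal F1 groups
#' `B6D2F1` (B6 dam) and `D2B6F1` (D2 dam). The reciprocal F1 females carry
#' identical nuclear genomes, so a female-restricted difference points to
#' parental effects or imprinting rather than inherited alleles; males also
#' differ in their Y chromosome.
#'
#' @param table phenotype `data.frame` containing both reciprocal groups in
#'   its `strain` column.
#' @param trait trait column name.
#' @param females_only restrict to female records before testing.
#' @param day optional: restrict to one recording day.
#' @return a list of class `poe_test`: `statistic`, `p.value`, `direction`
#'   (sign of the B6-dam-minus-D2-dam mean difference), `diff` (that mean
#'   difference), `n` (per-group counts), `females_only`.
#' @export
parent_of_origin_test <- function(table, trait, females_only = FALSE,
                                  day = NULL) {
  if (!is.null(day)) table <- table[table$day == day, , drop = FALSE]
  if (females_only) table <- table[table$sex == "F", , drop = FALSE]
  a <- table[[trait]][table$strain == "B6D2F1"]
  b <- table[[trait]][table$strain == "D2B6F1"]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop("a reciprocal F1 group is absent or empty after filtering")
  wt <- stats::wilcox.test(a, b, exact = FALSE)
  d <- mean(a) - mean(b)
  structure(list(statistic = unname(wt$statistic), p.value = wt$p.value,
                 direction = sign(d), diff = d,
                 n = c(B6D2F1 = length(a), D2B6F1 = length(b)),
                 females_only = females_only),
            class = "poe_test")
}

#' @export
print.poe_test <- function(x, ...) {
  cat(sprintf(
    "reciprocal-F1 Wilcoxon W = %.1f, p = %.3g; B6dam - D2dam = %.3f (%s)%s\n",
    x$statistic, x$p.value, x$diff,
    if (x$direction >= 0) "B6-dam higher" else "D2-dam higher",
    if (x$females_only) " [females only]" else ""))
  invisible(x)
}

#' Call-type percentage profiles by group
#'
#' For every subject (pup), converts the ten call-type counts to
#' percentages of that subject's total calls, then averages the per-subject
#' percentages within each group (mean of ratios, not ratio of sums), so
#' that every subject contributes equally regardless of how much it called.
#' Subjects with zero total calls are excluded with a warning (or rejected
#' when `strict = TRUE`).
#'
#' @param table phenotype `data.frame` carrying the call-type count columns
#'   ([calltype_categories()]); counts are summed per subject across rows.
#' @param grouping grouping column; default `"strain"`.
#' @param strict error (instead of warn-and-drop) on zero-call subjects.
#' @return a list of class `calltype_profile`: `group_means` (matrix,
#'   groups x 10 categories, in percent) and `subjects` (per-subject
#'   percentage data frame; each row sums to 100).
#' @export
calltype_profile <- function(table, grouping = "strain", strict = FALSE) {
  cats <- intersect(calltype_categories(), names(table))
  if (length(cats) == 0) stop("no call-type count columns present")
  ag <- stats::aggregate(table[cats],
                         by = list(group = table[[grouping]],
                                   subject = table$pup),
                         FUN = sum, na.rm = TRUE)
  tot <- rowSums(ag[cats])
  zero <- tot == 0
  if (any(zero)) {
    msg <- paste("subject(s) with zero total calls:",
                 paste(ag$subject[zero], collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; excluded")
    ag <- ag[!zero, , drop = FALSE]
    tot <- tot[!zero]
  }
  if (!nrow(ag)) stop("no subjects with calls")
  pct <- as.matrix(ag[cats]) / tot * 100
  subjects <- cbind(ag[c("group", "subject")], as.data.frame(pct))
  gm <- do.call(rbind, lapply(split(as.data.frame(pct), ag$group), colMeans))
  structure(list(group_means = gm, subjects = subjects),
            class = "calltype_profile")
}

#' Volume from serial-section areas
#'
#' Estimates a structure's volume from area measurements on equally spaced
#' serial sections: the sum of the products of each area (mm^2) and the
#' distance to the next section level (mm).
#'
#' @param areas numeric vector of section areas in mm^2 (at least one).
#' @param spacing distance between section levels in mm (> 0).
#' @return volume in mm^3.
#' @examples
#' section_volume(c(2, 3, 4), 0.05)  # 0.45
#' @export
section_volume <- function(areas, spacing) {
  if (!length(areas)) stop("at least one area required")
  if (any(is.na(areas)) || any(areas < 0)) stop("areas must be non-negative")
  if (spacing <= 0) stop("spacing must be positive")
  sum(areas) * spacing
}
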