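#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Rank-based comparison of two or more groups: the Kruskal-Wallis H
#' statistic (with tie correction, delegated to [stats::kruskal.test()])
#' followed by Dunn's pairwise z tests on the mean ranks,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t)` over tie groups, with multiplicity adjustment.
#'
#' @param table A data frame with a numeric `value` column and a `group`
#'   label column.
#' @param adjust Multiplicity adjustment for the Dunn p-values, any method
#'   accepted by [stats::p.adjust()] (default `"holm"`; `"bonferroni"` and
#'   `"sidak"` are common alternatives — `"sidak"` is applied directly since
#'   `p.adjust` does not provide it).
#' @return An object of class `kruskal_dunn`; see
#'   [tidy()][generics::tidy] (pairwise table with `comparison`, `z`,
#'   `p.value`, `p.adj`, `stars`) and [glance()][generics::glance]
#'   (`statistic` H, `df`, `p.value`).
#' @examples
#' tab <- data.frame(value = 1:9, group = rep(c("a", "b", "c"), each = 3))
#' glance(kruskal_dunn(tab))  # H = 7.2
#' @export
kruskal_dunn <- function(table, adjust = "holm") {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("value", "group") %in% names(table)),
            !anyNA(table$value))
  g <- factor(table$group)
  if (nlevels(g) < 2) stop("at least two groups are required")
  if (any(tabulate(g) < 2)) stop("every group needs n >= 2")

  lev0 <- levels(g)
  if (length(unique(table$value)) == 1L) {
    # all observations tied: no rank information at all
    cmb0 <- utils::combn(seq_along(lev0), 2)
    pairwise <- tibble::tibble(
      comparison = apply(cmb0, 2, function(ij) paste(lev0[ij[1]], lev0[ij[2]],
                                                     sep = " - ")),
      z = 0, p.value = 1, p.adj = 1, stars = "ns")
    return(structure(list(statistic = 0, df = nlevels(g) - 1L, p.value = 1,
                          pairwise = pairwise, adjust = adjust),
                     class = "kruskal_dunn"))
  }

  kw <- stats::kruskal.test(table$value, g)

  r <- rank(table$value)
  N <- length(r)
  mean_ranks <- tapply(r, g, mean)
  n_g <- tabulate(g)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term

  lev <- levels(g)
  cmb <- utils::combn(seq_along(lev), 2)
  z <- apply(cmb, 2, function(ij) {
    (mean_ranks[ij[1]] - mean_ranks[ij[2]]) /
      sqrt(var_base * (1 / n_g[ij[1]] + 1 / n_g[ij[2]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- if (identical(adjust, "sidak")) {
    1 - (1 - p)^length(p)
  } else {
    stats::p.adjust(p, method = adjust)
  }
  pairwise <- tibble::tibble(
    comparison = apply(cmb, 2, function(ij) paste(lev[ij[1]], lev[ij[2]],
                                                  sep = " - ")),
    z = as.numeric(z),
    p.value = as.numeric(p),
    p.adj = pmin(as.numeric(p_adj), 1),
    stars = significance_stars(pmin(as.numeric(p_adj), 1))
  )
  structure(list(statistic = unname(kw$statistic), df = unname(kw$parameter),
                 p.value = kw$p.value, pairwise = pairwise, adjust = adjust),
            class = "kruskal_dunn")
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p.value))
  cat("Dunn's comparisons (", x$adjust, "-adjusted):\n", sep = "")
  print(x$pairwise)
  invisible(x)
}

#' @rdname kruskal_dunn
#' @param x A `kruskal_dunn` object.
#' @param ... Unused.
#' @export
tidy.kruskal_dunn <- function(x, ...) x$pairwise

#' @rdname kruskal_dunn
#' @export
glance.kruskal_dunn <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value)
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' Fits `value ~ group` by [stats::aov()] and compares every group against
#' the stated control with Dunnett's test (single-step adjusted p-values via
#' the multivariate t distribution, delegated to \pkg{multcomp}).
#'
#' @param table A data frame with `value` and `group` columns.
#' @param control Label of the control group.
#' @return An object of class `anova_dunnett`; `glance()` gives the F
#'   statistic, degrees of freedom and p-value, `tidy()` the per-comparison
#'   estimates with adjusted p-values and stars.
#' @export
anova_dunnett <- function(table, control) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("value", "group") %in% names(table)))
  if (!control %in% table$group) {
    stop("control group '", control, "' not present in the table")
  }
  g <- stats::relevel(factor(table$group), ref = control)
  if (any(tabulate(g) < 2)) stop("every group needs n >= 2")
  d <- data.frame(value = table$value, group = g)
  fit <- stats::aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  s <- summary(glht)
  comparisons <- tibble::tibble(
    comparison = names(s$test$coefficients),
    estimate = as.numeric(s$test$coefficients),
    std.error = as.numeric(s$test$sigma),
    statistic = as.numeric(s$test$tstat),
    p.adj = as.numeric(s$test$pvalues),
    stars = significance_stars(as.numeric(s$test$pvalues))
  )
  structure(list(statistic = an$`F value`[1],
                 df = unname(an$Df),
                 p.value = an$`Pr(>F)`[1],
                 comparisons = comparisons, control = control),
            class = "anova_dunnett")
}

#' @export
print.anova_dunnett <- function(x, ...) {
  cat(sprintf("One-way ANOVA F(%d, %d) = %.4g, p = %.3g\n",
              x$df[1], x$df[2], x$statistic, x$p.value))
  cat("Dunnett comparisons vs '", x$control, "':\n", sep = "")
  print(x$comparisons)
  invisible(x)
}

#' @rdname anova_dunnett
#' @param x An `anova_dunnett` object.
#' @param ... Unused.
#' @export
tidy.anova_dunnett <- function(x, ...) x$comparisons

#' @rdname anova_dunnett
#' @export
glance.anova_dunnett <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df1 = x$df[1], df2 = x$df[2],
                 p.value = x$p.value)
}

#' Chi-squared rate comparisons against a control group
#'
#' Collapses a groups-by-phenotype count table into per-group 2x2 tables
#' against the control and applies Pearson's chi-squared test (no continuity
#' correction) to each.
#'
#' @param counts A matrix or data frame of counts with one row per group and
#'   two phenotype columns (e.g. `error` / `ok`); row names (or a `group`
#'   column) label the groups.
#' @param control Row label of the control group.
#' @return A tibble with one row per non-control group: `group`,
#'   `statistic`, `df`, `p.value`, `stars`.
#' @examples
#' m <- matrix(c(10, 90, 30, 70), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("control", "mutant"), c("yes", "no")))
#' rate_test(m, "control")  # chi-squared = 12.5
#' @export
rate_test <- function(counts, control) {
  if (is.data.frame(counts) && "group" %in% names(counts)) {
    rn <- counts$group
    counts <- as.matrix(counts[setdiff(names(counts), "group")])
    rownames(counts) <- rn
  } else {
    counts <- as.matrix(counts)
  }
  stopifnot(ncol(counts) == 2, !is.null(rownames(counts)))
  if (!control %in% rownames(counts)) stop("control row '", control, "' absent")
  if (any(rowSums(counts) == 0) || any(counts < 0)) {
    stop("every group needs a positive total count")
  }
  others <- setdiff(rownames(counts), control)
  purrr::map_dfr(others, function(gname) {
    tab <- counts[c(control, gname), , drop = FALSE]
    if (any(colSums(tab) == 0)) stop("zero-margin 2x2 table for ", gname)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tibble::tibble(group = gname, statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p.value = ct$p.value,
                   stars = significance_stars(ct$p.value))
  })
}

#' Classify chromosome-alignment phenotype
#'
#' Maps a count of misaligned chromosomes to the standard three categories:
#' 0 misaligned is complete alignment, one to three is mild misalignment and
#' more than three is severe misalignment.
#'
#' @param n_misaligned Non-negative integer vector.
#' @return A factor with levels `complete`, `mild`, `severe`.
#' @examples
#' classify_alignment(c(0, 2, 4))
#' @export
classify_alignment <- function(n_misaligned) {
  if (any(n_misaligned < 0) || any(n_misaligned != round(n_misaligned))) {
    stop("n_misaligned must be non-negative integers")
  }
  factor(ifelse(n_misaligned == 0, "complete",
                ifelse(n_misaligned <= 3, "mild", "severe")),
         levels = c("complete", "mild", "severe"))
}

#' Significance stars
#'
#' The conventional mapping: `****` for p <= 0.0001, `***` for p <= 0.001,
#' `**` for p <= 0.01, `*` for p <= 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  cut_lab <- function(x) {
    if (is.na(x)) return(NA_character_)
    if (x <= 1e-4) "****" else if (x <= 1e-3) "***" else
      if (x <= 1e-2) "**" else if (x <= 0.05) "*" else "ns"
  }
  vapply(p, cut_lab, character(1))
}
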