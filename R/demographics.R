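#' Pearson chi-square test on a contingency table
#'
#' No continuity correction is applied (the corrected statistic is not what
#' classic cohort tables report for 2x2 sex comparisons).
#'
#' @param counts non-negative integer matrix, groups x categories, at least
#'   2 x 2, with no zero margins.
#' @return A list with `chi2`, `df` = (rows-1)(cols-1), and `p`.
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  check_table(counts)
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

check_table <- function(counts) {
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (any(counts < 0) || sum(counts) == 0)
    stop("counts must be non-negative with positive total")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: zero row or column margin")
  invisible(counts)
}

#' Fisher's exact test on a contingency table
#'
#' Two-sided p: the total probability, under the hypergeometric /
#' multivariate distribution with fixed margins, of all tables at most as
#' probable as the observed one.
#'
#' @param counts non-negative integer matrix, at least 2 x 2, total <= 500
#'   (larger tables should use [chi_square_test()]).
#' @return The two-sided p-value.
#' @export
fisher_exact_test <- function(counts) {
  counts <- as.matrix(counts)
  check_table(counts)
  if (sum(counts) > 500)
    stop("table total exceeds 500; use chi_square_test for large tables")
  stats::fisher.test(counts)$p.value
}

#' Two-group one-way analysis of variance
#'
#' With two groups the one-way F statistic equals the square of the pooled
#' two-sample t, on (1, n_a + n_b - 2) degrees of freedom.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return A list with `F`, `df` (length-2), and `p`.
#' @export
two_group_anova <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  y <- c(values_a, values_b)
  g <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
  fit <- suppressWarnings(stats::anova(stats::aov(y ~ g)))
  if (!is.finite(fit$`F value`[1]))
    stop("degenerate input: no within-group variance")
  list(F = fit$`F value`[1], df = c(fit$Df[1], fit$Df[2]),
       p = fit$`Pr(>F)`[1])
}

#' Group-comparison demographics table
#'
#' Summarises a cohort manifest the way clinical papers report their
#' Table 1: continuous variables as mean +/- sd per group with a one-way
#' ANOVA p-value; categorical variables as counts (within-group %) with a
#' Pearson chi-square p-value, switched to Fisher's exact test when any
#' expected cell count is below 5.
#'
#' @param manifest data.frame with a `group` column (exactly two levels)
#'   plus the variables to compare, or a path to a TSV with those columns.
#' @param continuous character vector of continuous column names.
#' @param categorical character vector of categorical column names.
#' @param path optional TSV output path.
#' @return A data.frame with columns `variable`, `level`, one summary
#'   column per group, `test` and `p`.
#' @export
cohort_table <- function(manifest, continuous = "age",
                         categorical = c("sex", "education"), path = NULL) {
  if (is.character(manifest))
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("group", continuous, categorical)
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  groups <- sort(unique(manifest$group))
  if (length(groups) != 2L) stop("manifest must contain exactly two groups")
  ga <- manifest[manifest$group == groups[1], , drop = FALSE]
  gb <- manifest[manifest$group == groups[2], , drop = FALSE]

  rows <- list()
  add <- function(variable, level, sa, sb, test, p)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = level, a = sa, b = sb,
      test = test, p = p, stringsAsFactors = FALSE)

  for (v in continuous) {
    res <- two_group_anova(ga[[v]], gb[[v]])
    add(v, "",
        sprintf("%.1f ± %.1f", mean(ga[[v]]), stats::sd(ga[[v]])),
        sprintf("%.1f ± %.1f", mean(gb[[v]]), stats::sd(gb[[v]])),
        "anova", res$p)
  }
  for (v in categorical) {
    tab <- table(manifest$group, manifest[[v]])
    if (ncol(tab) < 2L) {       # single observed level: nothing to compare
      use_exact <- FALSE
      p <- NA_real_
    } else {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      use_exact <- any(expected < 5)
      p <- if (use_exact) fisher_exact_test(tab) else chi_square_test(tab)$p
    }
    for (lev in colnames(tab)) {
      ca <- tab[as.character(groups[1]), lev]
      cb <- tab[as.character(groups[2]), lev]
      add(v, lev,
          sprintf("%d (%.1f%%)", ca, 100 * ca / nrow(ga)),
          sprintf("%d (%.1f%%)", cb, 100 * cb / nrow(gb)),
          if (is.na(p)) "none" else if (use_exact) "fisher_exact" else "chi_square",
          p)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[3:4] <- paste0(groups, " (n = ", c(nrow(ga), nrow(gb)), ")")
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  out
}
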