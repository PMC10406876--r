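#' Group sample container
#'
#' @param name Group name.
#' @param values Numeric vector of per-cell measurements (colocalized
#'   fractions or PLA counts), length >= 2, finite.
#' @export
group_sample <- function(name, values) {
  values <- as.numeric(values)
  if (length(values) < 2) abort_validation("each group needs n >= 2")
  if (!all(is.finite(values))) abort_validation("group values must be finite")
  structure(list(name = as.character(name), values = values,
                 n = length(values)), class = "group_sample")
}

as_group_samples <- function(groups) {
  if (inherits(groups, "group_sample")) abort_validation("need >= 2 groups")
  lapply(groups, function(g) {
    if (inherits(g, "group_sample")) g else group_sample(g$name, g$values)
  })
}

#' One-way analysis of variance
#'
#' Classical fixed-effects ANOVA: the ratio of between- to within-group
#' mean squares on (k - 1, N - k) degrees of freedom, with the p-value
#' from the F distribution. Computed from explicit sums of squares.
#'
#' @param groups List of [group_sample()] objects (>= 2).
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_samples(groups)
  if (length(groups) < 2) abort_validation("need >= 2 groups")
  values <- unlist(lapply(groups, `[[`, "values"))
  n <- vapply(groups, `[[`, integer(1), "n")
  k <- length(groups); N <- sum(n)
  grand <- mean(values)
  means <- vapply(groups, function(g) mean(g$values), numeric(1))
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g$values - mean(g$values))^2),
                          numeric(1)))
  df1 <- k - 1; df2 <- N - k
  if (ss_within == 0 && ss_between == 0)
    abort_degenerate("all observations identical: F undefined")
  if (ss_within == 0) return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
  Fstat <- (ss_between / df1) / (ss_within / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Variance-gated two-sample t-test
#'
#' A two-sided F-test of variance equality decides the t-test variant:
#' pooled-variance (homoscedastic) Student's t when the F-test does not
#' reject at `alpha_var`, Welch's (heteroscedastic) t otherwise. Both
#' t-tests are two-tailed.
#'
#' @param a,b [group_sample()] objects.
#' @param alpha_var Significance level of the variance gate
#'   (default 0.05).
#' @return List with `variance_F_p`, `t_variant`
#'   ("homoscedastic"/"heteroscedastic"), `t_stat`, `t_p`.
#' @export
variance_gate_t_test <- function(a, b, alpha_var = 0.05) {
  if (!inherits(a, "group_sample")) a <- group_sample(a$name, a$values)
  if (!inherits(b, "group_sample")) b <- group_sample(b$name, b$values)
  va <- stats::var(a$values); vb <- stats::var(b$values)
  if (va == 0 && vb == 0) {
    if (mean(a$values) == mean(b$values))
      abort_degenerate("zero variance in both groups with equal means: t undefined")
    return(list(variance_F_p = 1, t_variant = "homoscedastic",
                t_stat = Inf * sign(mean(a$values) - mean(b$values)), t_p = 0))
  }
  vf <- stats::var.test(a$values, b$values)
  homo <- vf$p.value >= alpha_var
  tt <- stats::t.test(a$values, b$values, var.equal = homo,
                      alternative = "two.sided")
  list(variance_F_p = vf$p.value,
       t_variant = if (homo) "homoscedastic" else "heteroscedastic",
       t_stat = unname(tt$statistic), t_p = tt$p.value)
}

#' Bonferroni-corrected per-comparison significance level
#'
#' `alpha_family / m`; for the family level 0.05 over the three pairwise
#' comparisons of three groups this is 0.05/3 ~ 0.0167.
#'
#' @param alpha_family Family-wise level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @export
bonferroni_alpha <- function(alpha_family = 0.05, m) {
  if (!is.numeric(alpha_family) || alpha_family <= 0 || alpha_family >= 1)
    abort_validation("alpha_family must be in (0, 1)")
  if (m < 1) abort_validation("m must be >= 1")
  alpha_family / m
}

#' Omnibus ANOVA plus all pairwise variance-gated t-tests
#'
#' Reproduces the group-comparison procedure: one-way ANOVA across all
#' groups, then for every pair an F-test-gated two-sample t-test, with
#' pairs flagged significant when their t p-value falls below the
#' Bonferroni-corrected level `alpha_family / n_pairs` (applied at full
#' precision). The omnibus p is reported alongside; significance flags
#' come from the corrected pairwise tests.
#'
#' @param groups List of [group_sample()] objects.
#' @param alpha_family Family-wise level (default 0.05).
#' @param alpha_var Variance-gate level (default 0.05).
#' @return An object of class `comparison_report`: list with `anova_F`,
#'   `anova_p`, `pairwise` (data frame: group_a, group_b, variance_F_p,
#'   t_variant, t_stat, t_p, significant), `alpha_family`,
#'   `alpha_bonferroni`.
#' @export
compare_groups <- function(groups, alpha_family = 0.05, alpha_var = 0.05) {
  groups <- as_group_samples(groups)
  if (length(groups) < 2) abort_validation("need >= 2 groups")
  aov_res <- one_way_anova(groups)
  pairs <- utils::combn(length(groups), 2)
  alpha_b <- bonferroni_alpha(alpha_family, ncol(pairs))
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tt <- variance_gate_t_test(groups[[i]], groups[[j]], alpha_var)
    data.frame(group_a = groups[[i]]$name, group_b = groups[[j]]$name,
               variance_F_p = tt$variance_F_p, t_variant = tt$t_variant,
               t_stat = tt$t_stat, t_p = tt$t_p,
               significant = tt$t_p < alpha_b,
               stringsAsFactors = FALSE)
  })
  structure(list(anova_F = aov_res$F, anova_p = aov_res$p,
                 pairwise = do.call(rbind, rows),
                 alpha_family = alpha_family, alpha_bonferroni = alpha_b),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> ANOVA F = %.4g, p = %.4g; alpha_bonf = %.4g\n",
              x$anova_F, x$anova_p, x$alpha_bonferroni))
  print(x$pairwise)
  invisible(x)
}
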