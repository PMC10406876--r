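test_that("one-way ANOVA matches the independent lm/oneway oracle", {
  set.seed(201)
  for (k in 1:5) {
    gs <- lapply(1:3, function(i) group_sample(paste0("g", i),
                                               stats::rnorm(5, mean = i)))
    res <- one_way_anova(gs)
    vals <- unlist(lapply(gs, `[[`, "values"))
    grp <- factor(rep(1:3, each = 5))
    oracle <- stats::oneway.test(vals ~ grp, var.equal = TRUE)
    expect_equal(res$F, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(res$p, oracle$p.value, tolerance = 1e-10)
  }
})

test_that("ANOVA limit cases behave", {
  same <- lapply(1:3, function(i) group_sample(paste0("g", i), c(1, 2, 3)))
  res <- one_way_anova(same)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  sep <- list(group_sample("a", rep(0, 4)), group_sample("b", rep(1e6, 4)))
  expect_lt(one_way_anova(sep)$p, 1e-6)
  expect_error(one_way_anova(list(group_sample("a", c(2, 2)),
                                  group_sample("b", c(2, 2)))),
               class = "iccscoloc_degenerate_error")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(202)
  a <- group_sample("a", stats::rnorm(12)); b <- group_sample("b", stats::rnorm(9, 1))
  res <- one_way_anova(list(a, b))
  tt <- stats::t.test(a$values, b$values, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
})

test_that("pooled t statistic matches a hand computation", {
  a <- c(30.02, 29.99, 30.11, 29.97, 30.01, 29.99)
  b <- c(29.89, 29.93, 29.72, 29.98, 30.02, 29.98)
  res <- variance_gate_t_test(group_sample("a", a), group_sample("b", b))
  # hand-computed pooled-variance t
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(res$t_stat, t_hand, tolerance = 1e-6)
  expect_equal(res$t_variant, "homoscedastic")
})

test_that("the variance gate selects Welch's t when variances differ", {
  set.seed(203)
  hetero <- vapply(1:40, function(i) {
    a <- group_sample("a", stats::rnorm(50, sd = 1))
    b <- group_sample("b", stats::rnorm(50, sd = 10))
    variance_gate_t_test(a, b)$t_variant == "heteroscedastic"
  }, logical(1))
  expect_gte(mean(hetero), 0.95)
  # identical samples: p = 1, pooled variant
  x <- group_sample("x", c(1, 2, 3, 4))
  same <- variance_gate_t_test(x, x)
  expect_equal(same$t_p, 1)
  expect_equal(same$t_variant, "homoscedastic")
  expect_error(variance_gate_t_test(group_sample("a", c(2, 2)),
                                    group_sample("b", c(2, 2))),
               class = "iccscoloc_degenerate_error")
})

test_that("bonferroni_alpha divides the family level", {
  expect_equal(round(bonferroni_alpha(0.05, 3), 4), 0.0167)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 5), 0.002)
  expect_error(bonferroni_alpha(1.2, 3), class = "iccscoloc_validation_error")
  expect_error(bonferroni_alpha(0.05, 0), class = "iccscoloc_validation_error")
})

test_that("compare_groups composes the procedure deterministically", {
  set.seed(204)
  gs <- lapply(1:3, function(i) group_sample(paste0("g", i), stats::rnorm(8)))
  rep1 <- compare_groups(gs)
  expect_equal(rep1$alpha_bonferroni, 0.05 / 3)
  expect_equal(nrow(rep1$pairwise), 3)
  expect_equal(rep1$pairwise$significant, rep1$pairwise$t_p < 0.05 / 3)
  # identical groups: nothing significant
  same <- lapply(1:3, function(i) group_sample(paste0("g", i), c(1, 2, 3, 4)))
  expect_false(any(compare_groups(same)$pairwise$significant))
  # invariance to group order, up to row permutation
  rep2 <- compare_groups(rev(gs))
  key <- function(p) {
    k <- apply(cbind(p$group_a, p$group_b), 1, function(r) paste(sort(r), collapse = "|"))
    p$t_p[order(k)]
  }
  expect_equal(key(rep1$pairwise), key(rep2$pairwise), tolerance = 1e-12)
  # Bonferroni flags are a subset of uncorrected flags
  expect_true(all(!rep1$pairwise$significant | rep1$pairwise$t_p < 0.05))
})

test_that("pairwise p-values are uniform under the null", {
  set.seed(205)
  ps <- vapply(1:500, function(i) {
    # identical continuous distributions in both groups (integer counts
    # would tie the KS statistic)
    coh <- simulate_cohort(list(cohort_group("a", 20, 20, 5, 0.5, 0.1),
                                cohort_group("b", 20, 20, 5, 0.5, 0.1)),
                           seed = 3000 + i)
    gs <- split(coh$f_iccs, coh$group)
    variance_gate_t_test(group_sample("a", gs$a), group_sample("b", gs$b))$t_p
  }, numeric(1))
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("the enhancer-mark cohort shows the published non-significance", {
  # MCF7 vs MDA-MB-231 PLA counts barely differ (16.5 vs 17.3): the pair
  # should come out non-significant in most replicate cohorts
  nonsig <- vapply(1:100, function(s) {
    coh <- simulate_cohort(cohort_preset_h3k27ac(), seed = s)
    gs <- split(coh$pla_count, coh$group)
    rep_ <- compare_groups(lapply(names(gs), function(nm) group_sample(nm, gs[[nm]])))
    p <- rep_$pairwise
    !p$significant[p$group_a == "MCF7" & p$group_b == "MDA-MB-231"]
  }, logical(1))
  expect_gte(mean(nonsig), 0.7)
})
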