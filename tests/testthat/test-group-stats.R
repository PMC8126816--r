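# Exact Mann-Whitney, Monte-Carlo Dunnett, damage-score aggregation.

test_that("exact Mann-Whitney reproduces small-sample enumeration values", {
  # complete separation at 4 vs 4: the smallest achievable two-sided level
  sep44 <- mann_whitney_exact(c(2.1, 2.3, 2.0, 2.5), c(1.2, 1.3, 1.1, 1.4))
  expect_equal(sep44$p_two_sided, 2 / 70)
  expect_equal(sep44$u_statistic, 16)
  expect_equal(round(sep44$p_two_sided, 4), 0.0286)

  # 3 vs 3 separation: 2 / C(6,3)
  expect_equal(mann_whitney_exact(4:6, 1:3)$p_two_sided, 2 / 20)
  # 1 vs 1: both arrangements equally extreme
  expect_equal(mann_whitney_exact(2, 1)$p_two_sided, 1)
  # identical groups
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))$p_two_sided, 1)
})

test_that("enumeration agrees exactly with wilcox.test on tie-free data", {
  set.seed(202)
  for (rep in 1:20) {
    n_a <- sample(2:6, 1); n_b <- sample(2:6, 1)
    x <- rnorm(n_a); y <- rnorm(n_b)
    ours <- mann_whitney_exact(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$u_statistic, unname(ref$statistic))
  }
})

test_that("U and p are invariant under strictly increasing transforms", {
  set.seed(7)
  x <- rnorm(5); y <- rnorm(4)
  base <- mann_whitney_exact(x, y)
  for (f in list(exp, function(v) rank(c(v))[seq_along(v)] * 0 + v,
                 function(v) v^3 + 10 * v)) {
    tr <- mann_whitney_exact(f(x), f(y))
    expect_equal(tr$u_statistic, base$u_statistic)
    expect_equal(tr$p_two_sided, base$p_two_sided)
  }
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(31)
  x <- rnorm(10); y <- rnorm(9, 0.8)
  ours <- mann_whitney_exact(x, y)
  expect_equal(ours$method, "normal approximation")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-9)
})

test_that("ties are counted as half-wins in U", {
  res <- mann_whitney_exact(c(1, 2, 2), c(2, 3, 0))
  # pairwise wins: 1>0; 2>0, 2=2 (x2 halves); total U = 1 + 1 + 0.5 + 1 + 0.5 = 4
  expect_equal(res$u_statistic, 4)
  expect_true(res$p_two_sided > 0 && res$p_two_sided <= 1)
})

test_that("Dunnett with two groups converges to the pooled t-test", {
  set.seed(12)
  for (shift in c(0, 0.8, 2.5)) {
    d <- data.frame(v = c(rnorm(5), rnorm(6, shift)),
                    g = rep(c("naive", "fus"), c(5, 6)))
    res <- anova_dunnett(d, v, g, control = "naive", ndraws = 1e5, seed = 2)
    tt <- stats::t.test(v ~ g, data = d, var.equal = TRUE)
    expect_equal(res$comparisons$p_adjusted, tt$p.value, tolerance = 0.012)
    expect_equal(res$comparisons$p_unadjusted, tt$p.value, tolerance = 1e-9)
  }
})

test_that("Dunnett-adjusted p sits between the unadjusted t and Bonferroni", {
  set.seed(91)
  for (rep in 1:5) {
    k <- sample(3:5, 1)
    d <- data.frame(
      v = rnorm(4 * k, mean = rep(runif(k, 0, 1.5), each = 4)),
      g = rep(c("naive", paste0("g", seq_len(k - 1))), each = 4)
    )
    res <- anova_dunnett(d, v, g, control = "naive", ndraws = 2e4, seed = rep)
    cmp <- res$comparisons
    # small MC slack on the lower bound; Bonferroni bound with the same slack
    expect_true(all(cmp$p_adjusted >= cmp$p_unadjusted - 0.01))
    expect_true(all(cmp$p_adjusted <=
                      pmin(1, (nrow(cmp)) * cmp$p_unadjusted) + 0.01))
  }
})

test_that("Monte-Carlo Dunnett agrees with the multivariate-t reference", {
  skip_if_not_installed("multcomp")
  set.seed(55)
  d <- data.frame(v = c(rnorm(5), rnorm(5, 1.2), rnorm(5, 0.3)),
                  g = factor(rep(c("naive", "a", "b"), each = 5),
                             levels = c("naive", "a", "b")))
  ours <- anova_dunnett(d, v, g, control = "naive", ndraws = 2e5, seed = 3)
  ref <- summary(multcomp::glht(stats::aov(v ~ g, d),
                                linfct = multcomp::mcp(g = "Dunnett")))
  ref_p <- as.numeric(ref$test$pvalues)
  ord <- match(c("a", "b"), ours$comparisons$group)
  expect_equal(ours$comparisons$p_adjusted[ord], ref_p, tolerance = 0.01)
})

test_that("separated groups are detected and near-null groups are not", {
  set.seed(77)
  d <- data.frame(
    v = c(rnorm(4), rnorm(4, 0.05), rnorm(4, 10)),
    g = rep(c("naive", "g1", "g2"), each = 4)
  )
  res <- anova_dunnett(d, v, g, control = "naive", ndraws = 1e5, seed = 1)
  cmp <- res$comparisons
  expect_lt(cmp$p_adjusted[cmp$group == "g2"], 0.001)
  expect_gt(cmp$p_adjusted[cmp$group == "g1"], 0.5)
})

test_that("zero-variance input warns and reports p = 1", {
  d <- data.frame(v = rep(2, 8), g = rep(c("naive", "fus"), each = 4))
  expect_warning(res <- anova_dunnett(d, v, g, control = "naive", seed = 1),
                 "zero residual variance")
  expect_equal(res$p, 1)
  expect_equal(res$comparisons$p_adjusted, 1)
})

test_that("Dunnett input validation", {
  d <- data.frame(v = rnorm(8), g = rep(c("a", "b"), each = 4))
  expect_error(anova_dunnett(d, v, g, control = "naive"), "control")
  d2 <- data.frame(v = rnorm(5), g = c("naive", "naive", "naive", "naive", "t"))
  expect_error(anova_dunnett(d2, v, g, control = "naive"), "at least 2")
})

test_that("damage scores aggregate hierarchically with correct SEM", {
  one <- data.frame(group = "FUS", subject_id = "m1", section_id = "s1",
                    image_id = paste0("i", 1:4),
                    endpoint = "vacuolation", score = c(0, 1, 2, 3))
  img <- aggregate_scores(one, level = "image")
  expect_equal(img$mean, 1.5)
  expect_equal(img$sem, sd(c(0, 1, 2, 3)) / 2)
  expect_equal(img$sem, 0.6455, tolerance = 1e-4)

  zeros <- dplyr::mutate(one, score = 0L)
  z <- aggregate_scores(zeros, level = "image")
  expect_equal(z$mean, 0)
  expect_equal(z$sem, 0)

  # unbalanced hierarchy: oracle computed by explicit nested means
  sc <- data.frame(
    group = "FUS",
    subject_id = rep(c("m1", "m2"), c(6, 2)),
    section_id = rep(c("s1", "s2", "s3"), c(4, 2, 2)),
    image_id = paste0("i", 1:8),
    endpoint = "rbc_extravasation",
    score = c(0, 1, 2, 3, 2, 2, 1, 3)
  )
  sec_means <- c(mean(c(0, 1, 2, 3)), mean(c(2, 2)), mean(c(1, 3)))
  subj_means <- c(mean(sec_means[1:2]), sec_means[3])
  subj <- aggregate_scores(sc, level = "subject")
  expect_equal(subj$n, 2L)
  expect_equal(subj$mean, mean(subj_means))
  expect_equal(subj$sem, sd(subj_means) / sqrt(2))
  sect <- aggregate_scores(sc, level = "section")
  expect_equal(sect$n, 3L)
  expect_equal(sect$mean, mean(sec_means))

  expect_error(aggregate_scores(dplyr::mutate(one, score = score + 2)),
               "0:3")
})

test_that("the damage rubric maps values to the four severity labels", {
  r <- damage_rubric()
  expect_equal(r$value, 0:3)
  expect_equal(r$label[r$value == 2], "moderate")
  expect_equal(r$label, c("none", "mild", "moderate", "severe"))
})

test_that("tidy and glance methods return one-row summaries", {
  mw <- mann_whitney_exact(c(2, 3, 4), c(1, 1.5, 0.5), labels = c("Iso", "KD"))
  td <- tidy(mw)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$group_a, "Iso")
  expect_equal(td$p_two_sided, mw$p_two_sided)

  set.seed(4)
  d <- data.frame(v = rnorm(12), g = rep(c("naive", "a", "b"), each = 4))
  res <- anova_dunnett(d, v, g, control = "naive", ndraws = 1e4, seed = 1)
  expect_equal(nrow(tidy(res)), 2L)
  expect_equal(glance(res)$df_residual, 9L)
})
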