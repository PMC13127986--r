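test_that("ANOVA F and Kruskal-Wallis H match brute-force formulas", {
  # hand-checked cases
  expect_equal(brute_force_f(list(c(0, 0), c(1, 3))), 4)
  r <- anova_tukey(c(0, 0, 1, 3), c("A", "A", "B", "B"))
  expect_equal(r$statistic, 4)
  expect_equal(r$df, c(1, 2))
  expect_equal(brute_force_h(list(c(1, 2), c(3, 4))), 2.4)
  h <- kw_dunn(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(h$statistic, 2.4, tolerance = 1e-12)
  # random small tables, continuous and tied
  set.seed(21)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    gs <- lapply(seq_len(k), function(j) rnorm(sample(3:8, 1)))
    v <- unlist(gs)
    g <- rep(letters[seq_len(k)], vapply(gs, length, 1L))
    expect_equal(anova_tukey(v, g)$statistic, brute_force_f(gs),
                 tolerance = 1e-10)
    expect_equal(kw_dunn(v, g)$statistic, brute_force_h(gs),
                 tolerance = 1e-10)
    vt <- round(v, 1)                       # force ties
    gst <- split(vt, g)
    expect_equal(kw_dunn(vt, g)$statistic, brute_force_h(unname(gst)),
                 tolerance = 1e-10)
  }
})

test_that("degenerate group tables are handled as documented", {
  # no between-group variance
  expect_equal(anova_tukey(c(1, 2, 1, 2), c("A", "A", "B", "B"))$statistic,
               1 * 0, tolerance = 1e-12)
  expect_equal(anova_tukey(c(5, 5, 5, 5), c("A", "A", "B", "B"))$statistic, 0)
  # zero within-group variance with unequal means -> infinite F flag
  r <- anova_tukey(c(1, 1, 2, 2), c("A", "A", "B", "B"))
  expect_true(is.infinite(r$statistic))
  expect_equal(r$p_value, 0)
  # complete ties -> H = 0
  expect_equal(kw_dunn(rep(3, 6), rep(c("A", "B"), 3))$statistic, 0)
  # constant groups break the normality gate
  expect_error(normality_gate(rep(1, 6), rep(c("A", "B"), each = 3)),
               "degenerate")
  expect_error(normality_gate(c(1, 2, 3, 4), c("A", "A", "B", "B")),
               "at least 3")
})

test_that("normality gate routes normal and bimodal samples correctly", {
  set.seed(31)
  para <- vapply(1:100, function(i) {
    v <- rnorm(30)
    g <- rep(c("A", "B", "C"), each = 10)
    normality_gate(v, g) == "parametric"
  }, logical(1))
  expect_gte(mean(para), 0.80)  # three joint tests at alpha 0.05
  bimodal <- vapply(1:40, function(i) {
    v <- c(rnorm(50, sample(c(-5, 5), 50, TRUE)), rnorm(50))
    g <- rep(c("A", "B"), each = 50)
    normality_gate(v, g) == "nonparametric"
  }, logical(1))
  expect_gte(mean(bimodal), 0.95)
})

test_that("Tukey and Dunn post hocs run only on significant omnibus", {
  set.seed(41)
  # equal-mean groups: no post hoc, and a null contrast has p ~ 1
  r0 <- anova_tukey(rnorm(20), rep(c("A", "B"), each = 10))
  expect_null(r0$posthoc)
  # forced post hoc at alpha = 1 on two equal-mean groups
  r1 <- anova_tukey(c(rnorm(10), rnorm(10)), rep(c("A", "B"), each = 10),
                    alpha = 1)
  expect_gt(r1$posthoc$p_adj[1], 0.05)
  # strong effect: post hoc produced, adjusted p monotone in raw p
  v <- c(rnorm(8), rnorm(8, 3), rnorm(8, 9) * 4)  # non-normal-ish spread
  g <- rep(c("A", "B", "C"), each = 8)
  rk <- kw_dunn(v, g)
  expect_false(is.null(rk$posthoc))
  o <- order(rk$posthoc$p_raw)
  expect_true(all(diff(rk$posthoc$p_adj[o]) >= -1e-12))
  expect_true(all(rk$posthoc$p_adj >= rk$posthoc$p_raw))
})

test_that("balanced repeated-measures ANOVA separates group and day", {
  set.seed(51)
  animals <- paste0("r", 1:9)
  grp <- rep(c("A", "B", "C"), each = 3)
  days <- 1:4
  # group shifts only (plus small noise): group F large, day F small
  d1 <- expand.grid(animal = animals, day = days)
  d1$group <- grp[match(d1$animal, animals)]
  d1$value <- c(A = 0, B = 5, C = 10)[d1$group] + rnorm(nrow(d1), 0, 0.3)
  r1 <- rm_anova_balanced(d1)
  expect_lt(r1$group$p_value, 0.001)
  expect_gt(r1$day$p_value, 0.05)
  # day trend only: day F large, group F small
  d2 <- d1
  d2$value <- as.numeric(d2$day) * 2 + rnorm(nrow(d2), 0, 0.3)
  r2 <- rm_anova_balanced(d2)
  expect_lt(r2$day$p_value, 0.001)
  expect_gt(r2$group$p_value, 0.05)
  # missing cell errors towards mixed models
  expect_error(rm_anova_balanced(d1[-1, ]), "unbalanced|incomplete")
})

test_that("programmed group-by-day interactions are detected with power", {
  hits <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    animals <- paste0("r", 1:8)
    grp <- rep(c("A", "B"), each = 4)
    d <- expand.grid(animal = animals, day = 1:3)
    d$group <- grp[match(d$animal, animals)]
    slope <- ifelse(d$group == "A", 0, 3)      # interaction effect
    d$value <- slope * as.numeric(d$day) + rnorm(nrow(d), 0, 1)
    rm_anova_balanced(d)$interaction$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("correlation behaves at the identity, reflection and null", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  expect_equal(correlate_metrics(x, x)$r, 1)
  expect_equal(correlate_metrics(x, -x)$r, -1)
  expect_error(correlate_metrics(x, rep(2, 5)), "zero-variance")
  set.seed(61)
  sims <- t(vapply(1:300, function(i) {
    r <- correlate_metrics(rnorm(20), rnorm(20))
    c(abs(r$r), r$p < 0.05)
  }, numeric(2)))
  expect_equal(mean(sims[, 1]), sqrt(2 / (pi * 19)), tolerance = 0.25)
  expect_lt(mean(sims[, 2]), 0.10)
})

test_that("mean_sem matches the defining formulas", {
  ms <- mean_sem(c(1, 2, 3))
  expect_equal(ms$mean, 2)
  expect_equal(ms$sem, 1 / sqrt(3))
  expect_equal(mean_sem(rep(4, 5))$sem, 0)
  single <- mean_sem(7)
  expect_equal(single$mean, 7)
  expect_true(is.na(single$sem))
})
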