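test_that("size classes split 3/2/3 with deterministic tie-breaks", {
  w <- seq(10, 80, by = 10)
  cls <- assign_size_classes(w)
  expect_equal(as.character(cls),
               c("small", "small", "small", "medium", "medium",
                 "large", "large", "large"))
  # all weights equal: classes assigned by pig_id order
  cls2 <- assign_size_classes(rep(50, 8), pig_ids = sprintf("p%d", 1:8))
  expect_equal(as.character(cls2),
               c("small", "small", "small", "medium", "medium",
                 "large", "large", "large"))
  # non-8 pens keep the 37.5/25/37.5 split, remainder to the middle
  cls6 <- assign_size_classes(1:6)
  expect_equal(as.vector(table(cls6)), c(2, 2, 2))
})

test_that("aggregated size class is modal with middle-period tie-break", {
  expect_equal(aggregate_size_class(c("small", "small", "medium")), "small")
  expect_equal(aggregate_size_class(c("small", "medium", "large")), "medium")
  expect_equal(aggregate_size_class(c("large", "large", "large")), "large")
})

test_that("correlation screen drops one member of highly correlated pairs", {
  set.seed(6)
  df <- data.frame(a = rnorm(500), b = rnorm(500), c = rnorm(500))
  df$dup <- df$a
  scr <- correlation_screen(df, c("a", "b", "c", "dup"))
  expect_equal(scr$retained, c("a", "b", "c"))
  expect_equal(scr$dropped$dropped, "dup")
  # independent columns retained
  scr2 <- correlation_screen(df, c("a", "b", "c"))
  expect_equal(scr2$retained, c("a", "b", "c"))
  expect_equal(nrow(scr2$dropped), 0)
  # unweighted member of an (unweighted, weighted) pair is dropped even
  # when listed first
  df$u_deg <- df$b + rnorm(500, sd = 0.05)
  scr3 <- correlation_screen(df, c("u_deg", "b", "c"),
                             unweighted = "u_deg")
  expect_false("u_deg" %in% scr3$retained)
  expect_true("b" %in% scr3$retained)
  # constant column reported, retained
  df$k <- 1
  scr4 <- correlation_screen(df, c("a", "k"))
  expect_equal(scr4$constant, "k")
  expect_true("k" %in% scr4$retained)
  # row-order stability
  scr5 <- correlation_screen(df[sample(nrow(df)), ],
                             c("a", "b", "c", "dup"))
  expect_equal(scr5$retained, scr$retained)
})

test_that("Kruskal-Wallis H matches the hand-ranked example", {
  kw <- kruskal_wallis(1:9, rep(c("g1", "g2", "g3"), each = 3))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2)
  # invariance under group relabeling with identical distributions
  v <- c(5, 1, 3, 2, 4, 9, 8, 6, 7)
  g <- rep(c("a", "b", "c"), each = 3)
  perm <- c(b = "c", c = "a", a = "b")
  expect_equal(kruskal_wallis(v, g)$H,
               kruskal_wallis(v, unname(perm[g]))$H)
  # invariance under strictly monotone transforms of the values
  expect_equal(kruskal_wallis(exp(v), g)$H, kruskal_wallis(v, g)$H)
  # degenerate cases
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
  allsame <- kruskal_wallis(rep(3, 6), rep(c("a", "b"), 3))
  expect_equal(allsame$H, 0)
  expect_equal(allsame$p_value, 1)
})

test_that("Kruskal-Wallis post hoc separates shifted groups", {
  set.seed(10)
  v <- c(rnorm(15, 0), rnorm(15, 0), rnorm(15, 3))
  g <- rep(c("a", "b", "c"), each = 15)
  kw <- kruskal_wallis(v, g)
  ph <- kw$posthoc
  expect_equal(nrow(ph), 3)
  ac <- ph$p_value[ph$group_a == "a" & ph$group_b == "c"]
  ab <- ph$p_value[ph$group_a == "a" & ph$group_b == "b"]
  expect_lt(ac, 0.01)
  expect_gt(ab, 0.05)
  bon <- kruskal_wallis(v, g, posthoc_adjust = "bonferroni")$posthoc
  expect_true(all(bon$p_value >= ph$p_value - 1e-12))
})

sim_lmm_data <- function(n_pens, delta, sd_pen = 0.5, sd_e = 0.5,
                         seed = 1) {
  set.seed(seed)
  trt <- rep(c("A", "B"), length.out = n_pens)
  pen_eff <- rnorm(n_pens, 0, sd_pen)
  do.call(rbind, lapply(seq_len(n_pens), function(p) {
    data.frame(pen_id = sprintf("pen%02d", p), treatment = trt[p],
               period = factor(rep(c(15, 19, 23), each = 1)),
               y = (trt[p] == "B") * delta + pen_eff[p] + rnorm(3, 0, sd_e))
  }))
}

test_that("LMM estimated marginal means equal cell means on balanced data", {
  # pure group shifts with negligible noise: EMMs = arithmetic cell means
  dat <- sim_lmm_data(12, delta = 1, sd_pen = 0, sd_e = 1e-3)
  fit <- suppressWarnings(suppressMessages(
    fit_metric_lmm(dat, "y", fixed = c("treatment", "period"),
                   grouping = "pen_id")))
  emm <- fit$emmeans
  cell <- tapply(dat$y, dat$treatment, mean)
  expect_equal(emm$emmean[match(c("A", "B"), emm$treatment)],
               as.vector(cell[c("A", "B")]), tolerance = 1e-3)
  expect_false(fit$converged)  # zero pen variance flagged as singular
})

test_that("LMM recovers a treatment shift across replicates", {
  diffs <- vapply(1:20, function(s) {
    dat <- sim_lmm_data(30, delta = 1, seed = s)
    fit <- suppressWarnings(suppressMessages(
      fit_metric_lmm(dat, "y", fixed = c("treatment", "period"),
                     grouping = "pen_id")))
    emm <- fit$emmeans
    emm$emmean[emm$treatment == "B"] - emm$emmean[emm$treatment == "A"]
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 1), 2 * sd(diffs) / sqrt(length(diffs)) + 0.05)
})

test_that("fixed-effect sets translate into the model matrix as requested", {
  dat <- sim_lmm_data(12, delta = 0)
  fit <- suppressWarnings(suppressMessages(
    fit_metric_lmm(dat, "y", fixed = "treatment", grouping = "pen_id")))
  expect_false(any(grepl("period", rownames(fit$coefficients))))
  fit2 <- suppressWarnings(suppressMessages(
    fit_metric_lmm(dat, "y", fixed = c("treatment", "period"),
                   grouping = "pen_id")))
  expect_true(any(grepl("period", rownames(fit2$coefficients))))
})

rordinal <- function(n, beta, seed) {
  # latent-logistic ordinal generator with 4 levels; cutpoints fixed
  set.seed(seed)
  x <- rnorm(n)
  eta <- beta * x
  u <- rlogis(n)
  y <- findInterval(eta + u, c(-1.2, 0.5, 1.8))
  data.frame(mts = y, x = x)
}

test_that("proportional-odds model recovers simulated coefficients", {
  for (beta in c(0, 0.4)) {
    est <- vapply(1:60, function(s) {
      dat <- rordinal(400, beta, seed = 1000 * beta + s)
      fit <- fit_ordinal_mts(dat, predictors = "x")
      fit$coefficients["x", "Value"]
    }, numeric(1))
    mc_se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - beta), 2 * mc_se + 0.02)
  }
})

test_that("ordinal model guards its degenerate inputs and flags the PO test", {
  dat <- rordinal(300, 0.3, seed = 2)
  fit <- fit_ordinal_mts(dat, predictors = "x")
  expect_true(all(c("odds_ratios", "po_test", "reported") %in% names(fit)))
  expect_true(all(fit$odds_ratios$ci_lower <= fit$odds_ratios$ci_upper))
  expect_equal(fit$odds_ratios$odds_ratio,
               exp(fit$odds_ratios$estimate))
  single <- data.frame(mts = rep(1L, 50), x = rnorm(50))
  expect_error(fit_ordinal_mts(single, predictors = "x"), "single")
  # collapse option merges sparse top levels
  dat$mts[dat$mts >= 2] <- 3L
  fit2 <- fit_ordinal_mts(dat, predictors = "x", collapse_sparse = TRUE)
  expect_equal(length(fit2$model$zeta), 2L)
})

sim_victim_data <- function(n_pens, beta, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_pens), function(p) {
    x <- rnorm(8)
    pe <- rnorm(1, 0, 0.5)
    pr <- plogis(-0.5 + beta * x + pe)
    data.frame(pen_id = sprintf("pen%02d", p), in_strength = x,
               victim = runif(8) < pr)
  }))
}

test_that("victim logit detects a positive in-strength effect", {
  hits <- vapply(1:40, function(s) {
    dat <- sim_victim_data(40, beta = 0.7, seed = s)
    fit <- suppressWarnings(suppressMessages(
      fit_victim_logit(dat, predictors = "in_strength")))
    fit$odds_ratios$odds_ratio[fit$odds_ratios$term == "in_strength"] > 1
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("victim logit CIs cover the null when there is no effect", {
  cover <- vapply(1:40, function(s) {
    dat <- sim_victim_data(40, beta = 0, seed = 500 + s)
    fit <- suppressWarnings(suppressMessages(
      fit_victim_logit(dat, predictors = "in_strength")))
    or <- fit$odds_ratios[fit$odds_ratios$term == "in_strength", ]
    or$ci_lower <= 1 && 1 <= or$ci_upper
  }, logical(1))
  expect_gte(mean(cover), 0.85)
  expect_error(
    fit_victim_logit(data.frame(pen_id = "a", in_strength = rnorm(8),
                                victim = rep(FALSE, 8)),
                     predictors = "in_strength"),
    "constant")
})

test_that("AIC comparison ranks models and enforces identical data", {
  set.seed(3)
  dat <- sim_victim_data(30, beta = 0.8, seed = 9)
  dat$noise <- rnorm(nrow(dat))
  f1 <- suppressWarnings(suppressMessages(
    fit_victim_logit(dat, predictors = "in_strength")))
  f2 <- suppressWarnings(suppressMessages(
    fit_victim_logit(dat, predictors = c("in_strength", "noise"))))
  cmp <- compare_models_aic(f1, f2)
  expect_equal(cmp$delta_aic[1], 0)
  expect_equal(nrow(cmp), 2)
  expect_true(all(diff(cmp$AIC) >= 0))
  expect_error(compare_models_aic(f1), "two fits")
  f3 <- suppressWarnings(suppressMessages(
    fit_victim_logit(dat[1:200, ], predictors = "in_strength")))
  expect_error(compare_models_aic(f1, f3), "differing")
})

test_that("the metric table joins metrics, design factors, size class, and injury", {
  sim <- simulate_study(sim_config(n_pens = 2, seed = 13))
  nets <- build_all_bite_networks(sim$bites, sim$herd$pigs)
  pm <- do.call(rbind, lapply(nets, pig_metrics))
  tab <- build_metric_table(pm, sim$herd$pigs, sim$scores,
                            weights = sim$herd$weights)
  expect_equal(nrow(tab), 16)
  expect_false(any(duplicated(tab$pig_id)))
  expect_true(all(c("treatment", "sex", "size_class", "in_strength",
                    "mts", "victim") %in% names(tab)))
  # 3/2/3 size split within each pen
  expect_equal(as.vector(table(tab$size_class, tab$pen_id)),
               rep(c(3, 2, 3), 2))
  # per-period variant: association metrics carry one row per pig-period
  aggs <- aggregate_all_scans(sim$scans)
  pa <- do.call(rbind, lapply(lapply(aggs, build_association_network),
                              pig_metrics))
  tab2 <- build_metric_table(pa, sim$herd$pigs, sim$scores,
                             weights = sim$herd$weights)
  expect_equal(nrow(tab2), 16 * 3)
  expect_false(any(is.na(tab2$size_class)))
})
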