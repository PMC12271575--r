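test_that("percentile mapping uses mid-ranks against the reference", {
  expect_equal(to_percentiles(2.5, c(1, 2, 3, 4))$percentile, 50)
  expect_equal(to_percentiles(99, c(1, 2, 3, 4))$percentile, 100)
  ref <- sort(rnorm(101))
  med <- stats::median(ref)
  expect_lt(abs(to_percentiles(med, ref)$percentile - 50), 100 / (2 * 101) + 1e-9)
  # monotone: higher score, no lower percentile
  set.seed(71)
  s <- rnorm(50); r <- rnorm(200)
  p <- to_percentiles(s, r)$percentile
  o <- order(s)
  expect_true(all(diff(p[o]) >= 0))
  # every sample maps to exactly one tertile
  strata <- to_percentiles(s, r)
  expect_false(anyNA(strata$tertile))
  expect_equal(levels(strata$tertile), c("T1", "T2", "T3"))
})

test_that("null hazard bins recover HR 1 and planted tertile risk is monotone", {
  set.seed(72)
  n <- 4000
  # identical hazards in both bins
  age <- 40 + rexp(n, 1 / 30)
  df <- data.frame(age = age, event = rbinom(n, 1, 0.8))
  strata <- to_percentiles(rnorm(n), rnorm(n))
  hr <- bin_hazard_ratios(strata, df, scheme = "tertiles")
  expect_true(all(hr$HR > 0.85 & hr$HR < 1.15))
  expect_true(all(hr$lower < 1 & hr$upper > 1))

  # monotone planted risk across tertiles
  score <- rnorm(n)
  pct <- to_percentiles(score, score)
  haz <- exp(0.8 * as.integer(pct$tertile))
  age2 <- 40 + rexp(n, haz / 60)
  df2 <- data.frame(age = age2, event = 1L)
  hr2 <- bin_hazard_ratios(pct, df2, scheme = "tertiles")
  expect_true(all(diff(c(1, hr2$HR)) > 0))
})

test_that("percentile-scheme bins compare against the 45-55 reference band", {
  set.seed(73)
  n <- 6000
  score <- rnorm(n)
  strata <- to_percentiles(score, score)
  # hazard rises with the score so top bins must show HR > 1
  age <- 40 + rexp(n, exp(score) / 40)
  df <- data.frame(age = age, event = 1L)
  hr <- bin_hazard_ratios(strata, df, scheme = "percentiles")
  expect_equal(hr$bin, c("top55", "top20", "top10", "top5", "top1"))
  expect_true(all(hr$HR > 1))
  expect_true(all(diff(hr$HR) > 0))  # nested bins concentrate risk
})

test_that("empty-event bins yield NA hazard ratios with a warning", {
  set.seed(79)
  n <- 60
  score <- seq_len(n)
  strata <- to_percentiles(score, score)
  df <- data.frame(age = 40 + rexp(n, 1 / 20), event = rbinom(n, 1, 0.6))
  df$event[strata$tertile == "T3"] <- 0
  expect_warning(hr <- bin_hazard_ratios(strata, df, scheme = "tertiles"),
                 "no events")
  expect_true(is.na(hr$HR[hr$bin == "T3"]))
  expect_false(is.na(hr$HR[hr$bin == "T2"]))
})

test_that("c_index matches brute-force pair enumeration", {
  # perfectly anti-ranked: higher score, earlier event
  age <- c(60, 65, 70, 80)
  ev <- c(1, 1, 1, 1)
  sc <- c(4, 3, 2, 1)
  expect_equal(c_index(sc, age, ev), 1)
  # 4-sample hand fixture: events at 60 and 70, censored at 65 and 80
  age2 <- c(60, 65, 70, 80); ev2 <- c(1, 0, 1, 0); sc2 <- c(0.9, 0.1, 0.6, 0.2)
  expect_equal(c_index(sc2, age2, ev2), c_index_oracle(sc2, age2, ev2))
  expect_equal(c_index(sc2, age2, ev2), 1)  # all 5 permissible pairs concordant
  # random fixtures with ties, n <= 200
  set.seed(74)
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)
    age <- sample(50:90, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.5)
    if (sum(ev) == 0) next
    expect_equal(c_index(sc, age, ev), c_index_oracle(sc, age, ev),
                 tolerance = 1e-12)
  }
  expect_error(c_index(1, 50, 0), "no permissible pairs")
})

test_that("Kaplan-Meier incidence matches hand-worked and exact cases", {
  # 3 samples: events at 60 and 70, one censored later (80):
  # S(60) = 2/3, S(70) = 2/3 * 1/2 -> incidence 1/3 then 2/3
  df <- data.frame(age = c(60, 80, 70), event = c(1, 0, 1))
  ci <- cumulative_incidence(df, rep("all", 3))$all
  expect_equal(ci$incidence[ci$times == 60], 1 / 3, tolerance = 1e-12)
  expect_equal(ci$incidence[ci$times == 70], 2 / 3, tolerance = 1e-12)
  # censoring *before* the second event removes it from the risk set
  df2 <- data.frame(age = c(60, 65, 70), event = c(1, 0, 1))
  ci2 <- cumulative_incidence(df2, rep("all", 3))$all
  expect_equal(ci2$incidence[ci2$times == 70], 1, tolerance = 1e-12)
  # no events -> identically zero
  df0 <- data.frame(age = c(50, 60, 70), event = c(0, 0, 0))
  expect_true(all(cumulative_incidence(df0, rep("g", 3))$g$incidence == 0))
  # no censoring -> the empirical event-age CDF
  set.seed(75)
  ages <- sample(50:90, 40, replace = TRUE)
  dfc <- data.frame(age = ages, event = 1L)
  ci2 <- cumulative_incidence(dfc, rep("g", 40))$g
  expect_equal(ci2$incidence, stats::ecdf(ages)(ci2$times), tolerance = 1e-12)
  # incidence is non-decreasing and within [0, 1]
  expect_true(all(diff(ci2$incidence) >= 0))
  expect_true(all(ci2$incidence >= 0 & ci2$incidence <= 1))
})

test_that("a harder-hazard subgroup dominates at every age", {
  set.seed(76)
  n <- 3000
  grp <- rep(c("hard", "easy"), each = n / 2)
  rate <- ifelse(grp == "hard", 2, 1) / 30
  df <- data.frame(age = 40 + rexp(n, rate), event = 1L)
  ci <- cumulative_incidence(df, grp)
  # compare on the common age grid
  grid <- seq(41, 70, by = 1)
  step_at <- function(est, t) {
    i <- findInterval(t, est$times)
    ifelse(i == 0, 0, est$incidence[pmax(i, 1)])
  }
  hard <- step_at(ci$hard, grid); easy <- step_at(ci$easy, grid)
  expect_true(all(hard >= easy))
})

test_that("risk subgroups cross extremes with covariate flags", {
  strata <- to_percentiles(1:100, 1:100)
  flags <- rep(c(TRUE, FALSE), 50)
  g <- risk_subgroups(strata, flags)
  expect_true(all(is.na(g[11:90])))
  expect_setequal(unique(na.omit(g)),
                  c("top+flag", "top-flag", "bottom+flag", "bottom-flag"))
})

test_that("Cox CIs cover 1 under group-label permutations", {
  set.seed(77)
  n <- 400
  age <- 40 + rexp(n, 1 / 25)
  event <- rbinom(n, 1, 0.7)
  cover <- 0
  for (b in 1:100) {
    grp <- sample(rep(0:1, each = n / 2))
    fit <- survival::coxph(survival::Surv(age, event) ~ grp,
                           data = data.frame(age, event, grp))
    beta <- coef(fit)[1]; se <- sqrt(vcov(fit)[1, 1])
    if (beta - 1.96 * se < 0 && beta + 1.96 * se > 0) cover <- cover + 1
  }
  expect_gte(cover, 90)
})

test_that("attention reports obey the normalisation contract", {
  w <- random_tiny_world(n = 6, seed = 78)
  cfg <- model_config(d = 6L)
  params <- init_model_params(ncol(w$states), cfg, seed = 79)
  model <- structure(list(params = params, cfg = cfg, groups = w$groups),
                     class = "mg_model")
  rep1 <- chromosome_attention_report(model, w$states)
  expect_equal(nrow(rep1), 22L)
  expect_equal(max(rep1$normalized), 1)
  expect_equal(min(rep1$normalized), 0)
  expect_true(all(rep1$raw >= 0))
  # the literal raw sum is the SNP count per chromosome: degenerate under
  # equal m, flagged
  expect_warning(rep_raw <- chromosome_attention_report(model, w$states,
                                                        weighting = "raw"),
                 "degenerate")
  expect_true(attr(rep_raw, "degenerate"))
  expect_equal(rep_raw$raw, rep1$m + 0)  # mass == m_j exactly
  # unsupported representation mode
  cfg_oh <- model_config(mode = "one_hot")
  model_oh <- structure(list(params = init_model_params(ncol(w$states), cfg_oh),
                             cfg = cfg_oh, groups = w$groups),
                        class = "mg_model")
  expect_error(chromosome_attention_report(model_oh, w$states),
               "attention-based")
})

test_that("c_index_by_task_combination yields one row per combination", {
  spec <- spec_shared_factor(seed = 80)
  sim <- simulate_cohort(300, spec)
  tbl <- c_index_by_task_combination(
    sim$G, sim$cohort,
    combinations = list("IS", c("IS", "HT"), DISEASES),
    cfg = model_config(d = 4L, width = 6L), seed = 2, epochs = 2L)
  expect_equal(nrow(tbl), 3L)
  expect_equal(tbl$combination, c("IS", "IS+HT", "All MRFs"))
  expect_true(all(tbl$c_index >= 0 & tbl$c_index <= 1))
  expect_error(c_index_by_task_combination(sim$G, sim$cohort,
                                           combinations = list("HT"),
                                           cfg = model_config(d = 4L)),
               "include IS")
})
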