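test_that("Kendall tau matches exhaustive pair counting", {
  # identity and reversal
  expect_equal(kendall_tau(1:4, c(10, 20, 30, 40))$tau_b, 1)
  expect_equal(kendall_tau(1:4, 4:1)$tau_b, -1)

  # tied example, all 6 pairs enumerated by the oracle
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  r <- kendall_tau(x, y)
  o <- brute_kendall(x, y)
  expect_equal(r$S, o$S)
  expect_equal(r$tau_a, o$tau_a)
  expect_equal(r$tau_b, o$tau_b)

  # random vectors with ties, against the oracle and stats::cor.test
  with_seed_local(15, {
    for (rep in 1:10) {
      n <- sample(4:10, 1)
      x <- sample(1:5, n, replace = TRUE)
      y <- sample(1:5, n, replace = TRUE)
      if (var(x) == 0 || var(y) == 0) next
      r <- kendall_tau(x, y)
      o <- brute_kendall(x, y)
      expect_equal(r$S, o$S)
      expect_equal(r$tau_b, o$tau_b)
      expect_equal(r$tau_b, unname(cor(x, y, method = "kendall")),
                   tolerance = 1e-12)
    }
  })

  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
  expect_error(kendall_tau(1:3, 1:4), "equal length")
})

test_that("tau-b is invariant under increasing affine maps", {
  with_seed_local(16, x <- rnorm(40))
  expect_equal(kendall_tau(x, 3 * x + 2)$tau_b, 1)
  expect_equal(kendall_tau(x, -x)$tau_b, -1)
})

test_that("AUC equals the Mann-Whitney pair concordance", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.7, 8), rep(c(0, 1), 4))$auc, 0.5)
  expect_equal(roc_auc(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1))$auc, 0.75)

  with_seed_local(17, {
    for (rep in 1:10) {
      n <- sample(6:10, 1)
      s <- sample(seq(0, 1, 0.25), n, replace = TRUE)
      t <- rbinom(n, 1, 0.5)
      if (sum(t) %in% c(0, n)) next
      expect_equal(roc_auc(s, t)$auc, brute_auc(s, t))
    }
  })
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("the Hanley-McNeil standard error follows the documented formula", {
  s <- c(0.1, 0.3, 0.35, 0.6, 0.7, 0.9)
  t <- c(0, 0, 1, 0, 1, 1)
  r <- roc_auc(s, t)
  a <- brute_auc(s, t)
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + 2 * (q1 - a^2) + 2 * (q2 - a^2)) / 9)
  expect_equal(r$se, se)
  expect_equal(r$lower, max(0, a - 1.96 * se))
  expect_equal(r$upper, min(1, a + 1.96 * se))
})

test_that("scoring-based status is perfectly separated by its own score", {
  d <- generate_survey(default_config(n_total = 500, seed = 8))
  s <- compute_scores(d, weni_schema("weni33"))
  if (length(unique(s$status)) == 2) {
    expect_equal(roc_auc(s$composite, s$status)$auc, 1)
  }
})

test_that("outcome regressions apply the documented restrictions", {
  with_seed_local(19, {
    n <- 300
    d <- data.frame(respondent_id = as.character(1:n),
                    site = sample(c("A", "B"), n, TRUE),
                    group = sample(c("index_woman", "spouse"), n, TRUE),
                    age = sample(20:60, n, TRUE),
                    pregnant = FALSE,
                    bmi = rnorm(n, 21, 1.5),
                    food_groups = rbinom(n, 10, 0.5))
    st <- rbinom(n, 1, 0.5)
  })
  d$bmi[1] <- 27   # one overweight respondent
  base <- outcome_regression(d, st, "bmi")
  expect_equal(base$n, sum(d$bmi < 25))
  expect_equal(base$model, "ols")
  # adding one more overweight respondent shrinks n by one
  d2 <- d; d2$bmi[2] <- 26
  expect_equal(outcome_regression(d2, st, "bmi")$n, base$n - 1)
  # pregnant respondents leave the BMI-family sample
  d3 <- d; d3$pregnant[3:10] <- TRUE
  expect_equal(outcome_regression(d3, st, "bmi")$n,
               sum(d3$bmi < 25 & !d3$pregnant))
  # mdd keeps the full sample and uses probit
  m <- outcome_regression(d, st, "mdd")
  expect_equal(m$n, n)
  expect_equal(m$model, "probit")
  expect_true("pregnant" %in% m$coefficients$term ||
                all(d$pregnant == FALSE))
  # log-bmi regresses the log transform
  lb <- outcome_regression(d, st, "log-bmi")
  expect_equal(lb$model, "ols")
})

test_that("a balanced probit outcome gives an intercept near zero", {
  with_seed_local(23, {
    n <- 800
    d <- data.frame(respondent_id = as.character(1:n), site = "A",
                    group = "index_woman", age = 30, pregnant = FALSE,
                    bmi = rnorm(n, 21, 1),
                    food_groups = rep(c(0L, 10L), n / 2))  # exactly half meet MDD
    st <- rbinom(n, 1, 0.5)
  })
  m <- outcome_regression(d, st, "mdd", controls = character(0))
  ic <- m$coefficients[m$coefficients$term == "(Intercept)", ]
  # Phi(0) = 0.5: intercept should sit within its own confidence band of 0
  expect_lt(abs(ic$estimate), 1.96 * ic$robust_se + 0.05)
})

test_that("HC1 robust errors match the textbook formula on a small fit", {
  with_seed_local(29, {
    n <- 60
    d <- data.frame(respondent_id = as.character(1:n), site = "A",
                    group = "g", age = sample(20:50, n, TRUE),
                    pregnant = FALSE, bmi = rnorm(n, 21, 2),
                    food_groups = 5L)
    st <- rbinom(n, 1, 0.5)
  })
  r <- outcome_regression(d, st, "bmi", controls = "age")
  keep <- d$bmi < 25
  f <- lm(bmi ~ emp + age, data = data.frame(bmi = d$bmi, emp = st, age = d$age)[keep, ])
  X <- model.matrix(f); e <- residuals(f)
  V <- nrow(X) / (nrow(X) - ncol(X)) *
    solve(crossprod(X)) %*% crossprod(X * e) %*% solve(crossprod(X))
  expect_equal(r$coefficients$robust_se, sqrt(diag(V)), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("probit separation is reported as an error naming the variable", {
  with_seed_local(31, {
    n <- 200
    st <- rbinom(n, 1, 0.5)
    d <- data.frame(respondent_id = as.character(1:n), site = "A",
                    group = "index_woman", age = 30, pregnant = FALSE,
                    bmi = 21, food_groups = ifelse(st == 1, 8L, 2L))
  })
  expect_error(suppressWarnings(
    outcome_regression(d, st, "mdd", controls = character(0))),
    "separat")
})

test_that("parameter recovery: the configured BMI effect sits in its robust CI", {
  cfg <- default_config(n_total = 4000, seed = 33)
  d <- generate_survey(cfg)
  s <- compute_scores(d, weni_schema("weni33"))
  st <- s$status[match(d$respondent_id, s$respondent_id)]
  r <- outcome_regression(d, st, "bmi")
  b <- r$coefficients[r$coefficients$term == "empowered", ]
  expect_gt(cfg$bmi$effect, b$estimate - 1.96 * b$robust_se)
  expect_lt(cfg$bmi$effect, b$estimate + 1.96 * b$robust_se)
})

test_that("group tests reproduce hand-computed statistics", {
  # identical outcome distributions by construction: p = 1
  base <- data.frame(respondent_id = as.character(1:40), site = "A",
                     group = "g", age = 30, pregnant = FALSE,
                     bmi = rep(c(19, 20, 21, 22), 10), food_groups = 5L)
  st <- rep(c(0, 1), each = 20)
  base$bmi <- rep(rep(c(19, 20, 21, 22), 5), 2)   # same values in both arms
  gt <- group_tests(base, st)
  expect_true(all(abs(gt$p_value - 1) < 1e-12))

  # pooled proportion z against the closed form (0.57 of 305 vs 0.78 of 210)
  x1 <- round(0.57 * 305); x2 <- round(0.78 * 210)
  z <- prop_z_test(x1, 305, x2, 210)
  p1 <- x1 / 305; p2 <- x2 / 210; pp <- (x1 + x2) / 515
  zhand <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 305 + 1 / 210))
  expect_equal(z$z, zhand)
  expect_equal(z$p_value, 2 * pnorm(-abs(zhand)))

  # Welch means test against stats::t.test on a constructed fixture
  with_seed_local(37, {
    b0 <- rnorm(305, 19.88, 2); b1 <- rnorm(210, 21.66, 2.5)
  })
  d <- data.frame(respondent_id = as.character(1:515), site = "A",
                  group = "g", age = 30, pregnant = FALSE,
                  bmi = c(b0, b1), food_groups = 5L)
  st2 <- rep(c(0, 1), c(305, 210))
  gt2 <- group_tests(d, st2)
  row <- gt2[gt2$test == "mean_bmi" & gt2$group == "all", ]
  expect_equal(row$p_value, t.test(b0, b1)$p.value)
  expect_equal(row$disempowered, mean(b0))
  expect_equal(c(row$n_disempowered, row$n_empowered), c(305L, 210L))
})

test_that("one-class strata are flagged, not fatal", {
  d <- data.frame(respondent_id = as.character(1:10), site = "A",
                  group = rep(c("a", "b"), each = 5), age = 30,
                  pregnant = FALSE, bmi = rnorm(10, 21), food_groups = 5L)
  st <- c(rep(1, 5), rep(c(0, 1), c(2, 3)))   # group "a" has empowered only
  gt <- group_tests(d, st)
  a_rows <- gt[gt$group == "a", ]
  expect_true(all(a_rows$degenerate))
  expect_true(all(is.na(a_rows$p_value)))
})

test_that("DD comparison tables match direct counts", {
  sc <- toy_schema()
  vals <- matrix(c(1, 1, 1, 1, 1, 1, 1,
                   1, 0, 0, 1, 1, 1, 0,
                   0, 0, 0, 0, 0, 0, 0,
                   1, 1, 0, 0, 1, 0, 0), 4, byrow = TRUE)
  d <- toy_survey(sc, vals)
  s_full <- compute_scores(d, sc)
  sub <- new_schema(sc$indicators[sc$indicators$name %in%
                                    c("FAa", "FKa", "HRa", "HRb"), ])
  s_sub <- compute_scores(d, sub)
  cmp <- dd_comparison(s_full, s_sub)
  # full FA scores: 1, 1/3, 0, 2/3 -> 25% at the 0.5 cutoff... (1 and 2/3 pass)
  expect_equal(cmp$full_pct[cmp$measure == "Food Agency"], 50)
  # subset FA = FAa alone: 1, 1, 0, 1 -> 75%
  expect_equal(cmp$abbreviated_pct[cmp$measure == "Food Agency"], 75)
  # identity comparison gives identical columns
  cmp_id <- dd_comparison(s_full, s_full)
  expect_equal(cmp_id$full_pct, cmp_id$abbreviated_pct)
  # saturation: every proportion 100
  ones <- toy_survey(sc, matrix(1, 3, 7))
  s1 <- compute_scores(ones, sc)
  cmp1 <- dd_comparison(s1, s1)
  expect_true(all(cmp1$full_pct == 100))
  # mismatched respondents error
  expect_error(dd_comparison(s_full, s_sub[1:3, ]), "different respondents")
})

test_that("the selected subset tracks the full index better than random subsets", {
  d <- generate_survey(default_config(n_total = 800, seed = 44))
  sc <- weni_schema("weni33")
  rep <- run_abbreviation(d, sc, k = 20, train_sites = c("site1", "site2"),
                          approaches = "bic")
  expect_false(rep$failed)
  s_full <- compute_scores(d, sc)
  tau_of <- function(nm) {
    sub <- new_schema(sc$indicators[sc$indicators$name %in% nm, ])
    kendall_tau(s_full$composite, compute_scores(d, sub)$composite)$tau_b
  }
  tau_sel <- tau_of(rep$chosen$names)
  wins <- with_seed_local(45, {
    vapply(1:20, function(i) {
      tau_sel > tau_of(sample(indicator_names(sc), 20))
    }, NA)
  })
  expect_gte(mean(wins), 0.95)
})

test_that("robust confidence intervals attain nominal coverage over replicates", {
  # Pseudo-truths are the large-sample estimands of each regression: the
  # BMI < 25 restriction truncates on the outcome, so the empowerment-BMI
  # coefficient it estimates is a mildly attenuated version of the generator
  # effect; coverage is a property of the interval around that estimand.
  sc <- weni_schema("weni33")
  dref <- generate_survey(default_config(n_total = 150000, seed = 9999))
  sref <- compute_scores(dref, sc)
  stref <- sref$status[match(dref$respondent_id, sref$respondent_id)]
  truth <- vapply(c("bmi", "mdd"), function(o) {
    b <- outcome_regression(dref, stref, o)$coefficients
    b$estimate[b$term == "empowered"]
  }, 0)
  # truncation attenuates, but only mildly
  expect_lt(abs(truth[["bmi"]] - default_config()$bmi$effect), 0.15)

  nrep <- 200
  cov <- matrix(NA, nrep, 2, dimnames = list(NULL, c("bmi", "mdd")))
  for (i in seq_len(nrep)) {
    d <- generate_survey(default_config(n_total = 1200, seed = 5000 + i))
    s <- compute_scores(d, sc)
    st <- s$status[match(d$respondent_id, s$respondent_id)]
    for (o in c("bmi", "mdd")) {
      rb <- outcome_regression(d, st, o)$coefficients
      b <- rb[rb$term == "empowered", ]
      cov[i, o] <- abs(b$estimate - truth[[o]]) <= 1.96 * b$robust_se
    }
  }
  expect_gte(mean(cov[, "bmi"]), 0.91)
  expect_lte(mean(cov[, "bmi"]), 0.99)
  expect_gte(mean(cov[, "mdd"]), 0.91)
  expect_lte(mean(cov[, "mdd"]), 0.99)
})
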