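#' Kendall rank correlation between two score vectors
#'
#' Computes the Kendall score `S` (concordant minus discordant pairs),
#' tau-a (`S` over all pairs), tau-b (tie-corrected, the statistic used to
#' compare an abbreviated index against its parent), the null standard
#' error of `S` with the standard tie terms, and a two-sided p-value from
#' the normal approximation with continuity correction.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return A list of class `tau_result`: `tau_a`, `tau_b`, `S`, `se_S`,
#'   `p_value`, `n`.
#' @examples
#' kendall_tau(c(1, 2, 2, 3), c(1, 3, 2, 4))
#' @export
kendall_tau <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2) stop("need at least two observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("tau-b is undefined for a constant vector")
  }
  S <- 0
  for (i in seq_len(n - 1)) {
    idx <- (i + 1):n
    S <- S + sum(sign(x[idx] - x[i]) * sign(y[idx] - y[i]))
  }
  n0 <- n * (n - 1) / 2
  ## tie counts under exact numeric equality (table() would round through
  ## its character representation and disagree with sign())
  tie_sizes <- function(v) {
    t <- tabulate(match(v, v))
    t[t > 0]
  }
  tx <- tie_sizes(x); ty <- tie_sizes(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau_a <- S / n0
  tau_b <- S / sqrt((n0 - n1) * (n0 - n2))
  ## Var(S) under the null, with tie corrections
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- if (n > 2) {
    sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
  } else 0
  var_S <- (v0 - vt - vu) / 18 + v1 + v2
  se_S <- sqrt(max(var_S, 0))
  p <- if (se_S > 0) {
    2 * stats::pnorm(-(abs(S) - 1) / se_S)   # continuity-corrected
  } else NA_real_
  p <- min(max(p, 0), 1)
  structure(list(tau_a = tau_a, tau_b = tau_b, S = S, se_S = se_S,
                 p_value = p, n = n),
            class = "tau_result")
}

#' @export
print.tau_result <- function(x, ...) {
  cat(sprintf("Kendall rank correlation (n=%d)\n", x$n))
  cat(sprintf("  tau-a %.4f  tau-b %.4f  S %.0f (se %.2f)  p %.3g\n",
              x$tau_a, x$tau_b, x$S, x$se_S, x$p_value))
  invisible(x)
}

#' ROC area under the curve with Hanley-McNeil standard error
#'
#' The AUC is computed as the Mann-Whitney concordance probability (ties
#' count one half): the probability that a randomly chosen positive scores
#' above a randomly chosen negative.  The standard error uses the
#' Hanley-McNeil formula and the confidence bounds are
#' `auc +/- 1.96 * se`, clipped to `[0, 1]`.
#'
#' @param score numeric classifier score.
#' @param truth 0/1 (or logical) reference classification; both classes must
#'   be present.
#' @return A list of class `auc_result`: `auc`, `se`, `lower`, `upper`,
#'   `n_positive`, `n_negative`.
#' @examples
#' roc_auc(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1))
#' @export
roc_auc <- function(score, truth) {
  score <- as.numeric(score)
  truth <- as.integer(as.logical(as.numeric(truth)))
  if (length(score) != length(truth)) stop("score and truth must have equal length")
  if (anyNA(score) || anyNA(truth)) stop("missing values not allowed")
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present in truth")
  r <- rank(score)   # midranks: ties count 1/2
  auc <- (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  structure(list(auc = auc, se = se,
                 lower = max(0, auc - 1.96 * se),
                 upper = min(1, auc + 1.96 * se),
                 n_positive = n1, n_negative = n0),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (se %.4f, 95%% CI %.4f-%.4f; %d pos / %d neg)\n",
              x$auc, x$se, x$lower, x$upper, x$n_positive, x$n_negative))
  invisible(x)
}

## HC1 heteroskedasticity-robust covariance for lm
hc1_vcov <- function(fit) {
  X <- stats::model.matrix(fit)
  X <- X[, !is.na(stats::coef(fit)), drop = FALSE]   # drop aliased columns
  e <- stats::residuals(fit)
  n <- nrow(X); kk <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  meat <- crossprod(X * e)
  n / (n - kk) * XtXinv %*% meat %*% XtXinv
}

## Sandwich covariance for glm (probit): bread = inverse information from the
## glm fit, meat = outer product of per-observation scores, with an n/(n-k)
## small-sample factor.
glm_sandwich_vcov <- function(fit) {
  X <- stats::model.matrix(fit)
  X <- X[, !is.na(stats::coef(fit)), drop = FALSE]   # drop aliased columns
  mu <- stats::fitted(fit)
  eta <- fit$linear.predictors
  yy <- fit$y
  mu.eta <- fit$family$mu.eta(eta)
  v <- fit$family$variance(mu)
  score <- X * ((yy - mu) * mu.eta / v)
  bread <- stats::summary.glm(fit)$cov.unscaled
  n <- nrow(X); kk <- ncol(X)
  n / (n - kk) * bread %*% crossprod(score) %*% bread
}

#' Outcome regressions linking empowerment status to nutrition
#'
#' Fits the validation regressions of nutritional outcomes on binary
#' empowerment status plus demographic controls, with
#' heteroskedasticity-robust standard errors (HC1 for least squares, a
#' score-based sandwich for probit):
#' * `"bmi"`, `"log-bmi"`: least squares on the subsample that is neither
#'   overweight nor obese (BMI < 25) and not pregnant.
#' * `"normal-bmi"`: probit on the same subsample, outcome 1 for normal BMI
#'   (18.5 to 25) versus 0 for underweight.
#' * `"mdd"`: probit for minimum dietary diversity (`food_groups >=
#'   mdd_cutoff`, default 5 of 10) on the full sample, with pregnancy as an
#'   additional control.
#'
#' @param data survey data frame with columns for the outcome (`bmi` or
#'   `food_groups`) and any requested controls.
#' @param status 0/1 empowerment status, aligned with `data` rows.
#' @param outcome one of `"bmi"`, `"normal-bmi"`, `"log-bmi"`, `"mdd"`.
#' @param controls subset of `c("site", "group", "age", "pregnant")`.
#' @param mdd_cutoff food-group count defining minimum dietary diversity.
#' @return An object of class `weni_regression`: `model` (`"ols"` or
#'   `"probit"`), `outcome`, `coefficients` (estimate, robust SE, statistic,
#'   p-value), `fit_stat` (R2/adjusted R2 or model chi-square), `n`,
#'   `restriction`, `reference_levels`.
#' @export
outcome_regression <- function(data, status,
                               outcome = c("bmi", "normal-bmi", "log-bmi", "mdd"),
                               controls = c("site", "group", "age"),
                               mdd_cutoff = 5) {
  outcome <- match.arg(outcome)
  allowed <- c("site", "group", "age", "pregnant")
  bad <- setdiff(controls, allowed)
  if (length(bad)) stop("unsupported control(s): ", paste(bad, collapse = ", "))
  status <- as.numeric(status)
  if (length(status) != nrow(data)) stop("status must align with data rows")
  d <- data
  d$empowered <- status

  bmi_family <- outcome %in% c("bmi", "normal-bmi", "log-bmi")
  if (bmi_family) {
    if (!"bmi" %in% names(d)) stop("data has no 'bmi' column")
    keep <- !is.na(d$bmi) & d$bmi < 25
    if ("pregnant" %in% names(d)) keep <- keep & !(d$pregnant %in% TRUE)
    restriction <- "BMI < 25, non-pregnant, BMI observed"
    controls <- setdiff(controls, "pregnant")
  } else {
    if (!"food_groups" %in% names(d)) stop("data has no 'food_groups' column")
    keep <- !is.na(d$food_groups)
    restriction <- "food-group count observed"
    if ("pregnant" %in% names(d) && !"pregnant" %in% controls &&
        length(unique(d$pregnant[keep])) > 1) {
      controls <- c(controls, "pregnant")
    }
  }
  d <- d[keep, , drop = FALSE]
  if (!nrow(d)) stop("no observations remain after the sample restriction")

  d$y <- switch(outcome,
    "bmi" = d$bmi,
    "log-bmi" = log(d$bmi),
    "normal-bmi" = as.integer(d$bmi >= 18.5 & d$bmi < 25),
    "mdd" = as.integer(d$food_groups >= mdd_cutoff))

  for (v in intersect(c("site", "group"), controls)) d[[v]] <- factor(d[[v]])
  if ("pregnant" %in% controls) d$pregnant <- as.integer(d$pregnant %in% TRUE)
  fml <- stats::reformulate(c("empowered", controls), response = "y")
  model <- if (outcome %in% c("normal-bmi", "mdd")) "probit" else "ols"

  if (model == "ols") {
    fit <- stats::lm(fml, data = d)
    V <- hc1_vcov(fit)
    est <- stats::coef(fit)
    fit_stat <- c(r_squared = summary(fit)$r.squared,
                  adj_r_squared = summary(fit)$adj.r.squared)
  } else {
    fit <- stats::glm(fml, data = d, family = stats::binomial(link = "probit"))
    check_separation(fit)
    V <- glm_sandwich_vcov(fit)
    est <- stats::coef(fit)
    fit_stat <- c(chi_squared = fit$null.deviance - fit$deviance)
  }
  est <- est[!is.na(est)]
  se <- sqrt(diag(V))
  stat <- est / se
  pval <- 2 * stats::pnorm(-abs(stat))
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      robust_se = unname(se), statistic = unname(stat),
                      p_value = unname(pval), stringsAsFactors = FALSE)
  refs <- vapply(intersect(c("site", "group"), controls),
                 function(v) levels(d[[v]])[1], "")
  structure(list(model = model, outcome = outcome, coefficients = coefs,
                 fit_stat = fit_stat, n = nrow(d), restriction = restriction,
                 reference_levels = refs, fit = fit),
            class = "weni_regression")
}

check_separation <- function(fit) {
  mu <- stats::fitted(fit)
  degenerate <- mu < 1e-8 | mu > 1 - 1e-8
  if (!fit$converged || any(degenerate)) {
    est <- stats::coef(fit)[-1]
    worst <- names(est)[which.max(abs(est))]
    stop("probit fit is (quasi-)separated; suspect variable: ", worst)
  }
  invisible(fit)
}

#' @export
print.weni_regression <- function(x, ...) {
  cat(sprintf("%s regression of %s (n=%d; %s)\n",
              toupper(x$model), x$outcome, x$n, x$restriction))
  print.data.frame(x$coefficients, row.names = FALSE, digits = 4)
  cat("  ", paste(sprintf("%s=%.4f", names(x$fit_stat), x$fit_stat),
                  collapse = "  "), "\n")
  if (length(x$reference_levels)) {
    cat("  reference levels:",
        paste(sprintf("%s=%s", names(x$reference_levels), x$reference_levels),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Group-wise tests of nutritional outcomes by empowerment status
#'
#' For each demographic group and pooled: a Welch (unequal-variance)
#' two-sample t test of mean BMI between disempowered and empowered
#' respondents, and a pooled two-sample z test of the proportion with
#' normal BMI (18.5 to 25).  Strata where one status class is absent are
#' reported with missing p-values and flagged.
#'
#' @param data survey data frame with `bmi` and a grouping column.
#' @param status 0/1 empowerment status aligned with `data` rows.
#' @param group_col name of the grouping column (default `"group"`).
#' @return A data frame with one row per group per test plus pooled rows:
#'   `test`, `group`, means/proportions, counts, `p_value`, `degenerate`.
#' @export
group_tests <- function(data, status, group_col = "group") {
  if (!"bmi" %in% names(data)) stop("data has no 'bmi' column")
  if (!group_col %in% names(data)) stop("data has no '", group_col, "' column")
  status <- as.numeric(status)
  keep <- !is.na(data$bmi)
  d <- data[keep, , drop = FALSE]
  st <- status[keep]
  groups <- c(as.list(unique(as.character(d[[group_col]]))), list(NULL))
  rows <- lapply(groups, function(g) {
    sel <- if (is.null(g)) rep(TRUE, nrow(d)) else d[[group_col]] == g
    label <- if (is.null(g)) "all" else g
    b0 <- d$bmi[sel & st == 0]; b1 <- d$bmi[sel & st == 1]
    nb0 <- as.integer(d$bmi[sel & st == 0] >= 18.5 & d$bmi[sel & st == 0] < 25)
    nb1 <- as.integer(d$bmi[sel & st == 1] >= 18.5 & d$bmi[sel & st == 1] < 25)
    degen <- length(b0) < 2 || length(b1) < 2
    p_mean <- if (degen) NA_real_ else stats::t.test(b0, b1)$p.value
    p_prop <- if (degen) NA_real_ else prop_z_test(sum(nb0), length(nb0),
                                                   sum(nb1), length(nb1))$p_value
    rbind(
      data.frame(test = "mean_bmi", group = label,
                 disempowered = mean(b0), empowered = mean(b1),
                 n_disempowered = length(b0), n_empowered = length(b1),
                 p_value = p_mean, degenerate = degen,
                 stringsAsFactors = FALSE),
      data.frame(test = "prop_normal_bmi", group = label,
                 disempowered = mean(nb0), empowered = mean(nb1),
                 n_disempowered = length(nb0), n_empowered = length(nb1),
                 p_value = p_prop, degenerate = degen,
                 stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled two-sample proportion z test
#'
#' `z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2))` with `p` the pooled
#' proportion; two-sided p-value from the normal distribution.
#'
#' @param x1,n1 successes and trials in sample 1.
#' @param x2,n2 successes and trials in sample 2.
#' @return A list with `z`, `p_value`, `p1`, `p2`, `pooled`.
#' @export
prop_z_test <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  p <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  z <- if (se > 0) (p1 - p2) / se else 0
  list(z = z, p_value = if (se > 0) 2 * stats::pnorm(-abs(z)) else 1,
       p1 = p1, p2 = p2, pooled = p)
}

#' Per-DD empowerment proportions under the full and abbreviated index
#'
#' Side-by-side percentage of respondents whose DD score reaches the
#' threshold under each index, plus the overall composite row.  DD-level
#' empowerment uses the same cutoff as the composite (reported in the
#' `threshold` attribute; the choice is a package convention, recorded in
#' the output metadata).
#'
#' @param full_scores,abbrev_scores `weni_scores` data frames on the same
#'   respondents (checked by `respondent_id`).
#' @param threshold cutoff applied to DD scores; defaults to the full score
#'   set's threshold.
#' @return A data frame with columns `measure`, `full_pct`,
#'   `abbreviated_pct`, attribute `threshold`.
#' @export
dd_comparison <- function(full_scores, abbrev_scores, threshold = NULL) {
  if (!setequal(full_scores$respondent_id, abbrev_scores$respondent_id) ||
      nrow(full_scores) != nrow(abbrev_scores)) {
    stop("full and abbreviated score sets cover different respondents")
  }
  abbrev_scores <- abbrev_scores[match(full_scores$respondent_id,
                                       abbrev_scores$respondent_id), ]
  if (is.null(threshold)) threshold <- attr(full_scores, "threshold")
  dds <- intersect(DD_LEVELS, names(full_scores))
  pct <- function(v) 100 * mean(v >= threshold)
  rows <- lapply(dds, function(d) {
    data.frame(measure = unname(DD_LABELS[d]),
               full_pct = pct(full_scores[[d]]),
               abbreviated_pct = if (d %in% names(abbrev_scores)) {
                 pct(abbrev_scores[[d]])
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  rows <- c(list(data.frame(measure = "Nutritional Empowerment",
                            full_pct = pct(full_scores$composite),
                            abbreviated_pct = pct(abbrev_scores$composite),
                            stringsAsFactors = FALSE)), rows)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, threshold = threshold)
}
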