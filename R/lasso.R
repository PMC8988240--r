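#' Lasso engine configuration
#'
#' Collects the tuning constants of the penalized-regression engine.  The
#' objective minimized throughout is
#' \deqn{\frac{1}{n}\sum_i (y_i - \beta_0 - x_i'\beta)^2 +
#'       \frac{\lambda}{n}\sum_j \varphi_j |\beta_j|,}
#' with predictor-specific penalty loadings \eqn{\varphi_j} (unit by
#' default) applied to the standardized-scale coefficients.  Under this
#' parametrization the smallest penalty that zeroes every slope is
#' \eqn{\lambda_{null} = 2\,\max_j |\tilde x_j' y| / \varphi_j} (see
#' [lambda_null()]).
#'
#' @param nlambda number of penalty-grid points (log-spaced).
#' @param lambda_min_ratio ratio of the smallest to the largest grid penalty.
#' @param standardize center and scale predictors to unit (population)
#'   variance before fitting; coefficients are reported back on the original
#'   scale.
#' @param loadings optional per-predictor penalty loadings (positive).
#' @param cv_folds number of cross-validation folds (>= 2).
#' @param cv_seed integer seed for respondent-level fold assignment.
#' @param ebic_xi the EBIC indicator-count exponent \eqn{\xi \in [0,1]}.
#' @param rigorous_c slack constant of the plug-in penalty (default 1.1).
#' @param rigorous_gamma tail probability; default `0.1 / log(max(p, n))`,
#'   resolved at fit time when `NULL`.
#' @param rigorous_iter maximum residual-variance iterations of the plug-in
#'   penalty (default 15).
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param max_iter maximum coordinate-descent sweeps.
#' @return A list of class `lasso_config`.
#' @export
lasso_config <- function(nlambda = 100L, lambda_min_ratio = 1e-4,
                         standardize = TRUE, loadings = NULL,
                         cv_folds = 10L, cv_seed = 1L, ebic_xi = 0.5,
                         rigorous_c = 1.1, rigorous_gamma = NULL,
                         rigorous_iter = 15L, tol = 1e-8, max_iter = 10000L) {
  stopifnot(nlambda >= 2, lambda_min_ratio > 0, lambda_min_ratio < 1,
            cv_folds >= 2, tol > 0, max_iter >= 1,
            ebic_xi >= 0, ebic_xi <= 1, rigorous_c > 0)
  structure(list(nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 standardize = isTRUE(standardize), loadings = loadings,
                 cv_folds = as.integer(cv_folds), cv_seed = as.integer(cv_seed),
                 ebic_xi = ebic_xi, rigorous_c = rigorous_c,
                 rigorous_gamma = rigorous_gamma,
                 rigorous_iter = as.integer(rigorous_iter),
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "lasso_config")
}

## Precompute the sufficient statistics of the centered (optionally
## standardized) problem.  Zero-variance columns are kept but frozen at 0.
lasso_prep <- function(x, y, standardize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("lasso inputs must not contain missing values")
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  n <- nrow(x); p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  xm <- colMeans(x)
  xc <- sweep(x, 2L, xm)
  sx <- sqrt(colMeans(xc^2))
  constant <- sx < 1e-12
  if (standardize) {
    scale_used <- ifelse(constant, 1, sx)
    xc <- sweep(xc, 2L, scale_used, "/")
  } else {
    scale_used <- rep(1, p)
  }
  ym <- mean(y)
  yc <- y - ym
  list(Sxx = crossprod(xc) / n, Sxy = drop(crossprod(xc, yc)) / n,
       ymsq = mean(yc^2), n = n, p = p, xm = xm, ym = ym,
       scale = scale_used, constant = constant, names = colnames(x),
       standardize = standardize)
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

## Cyclic coordinate descent on the precomputed problem; beta on the working
## (standardized) scale.  Errors on non-convergence, reporting the last
## objective and sweep count.
cd_solve <- function(prep, lambda, phi, beta = NULL, tol = 1e-8,
                     max_iter = 10000L) {
  p <- prep$p
  if (is.null(beta)) beta <- numeric(p)
  Sxx <- prep$Sxx; Sxy <- prep$Sxy
  diagS <- diag(Sxx)
  thr <- lambda * phi / (2 * prep$n)
  grad_part <- drop(Sxx %*% beta)   # Sxx %*% beta, maintained incrementally
  for (it in seq_len(max_iter)) {
    delta_max <- 0
    for (j in seq_len(p)) {
      if (prep$constant[j] || diagS[j] < 1e-12) next
      z <- Sxy[j] - grad_part[j] + diagS[j] * beta[j]
      bj <- soft_threshold(z, thr[j]) / diagS[j]
      d <- bj - beta[j]
      if (d != 0) {
        grad_part <- grad_part + Sxx[, j] * d
        beta[j] <- bj
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < tol) {
      return(list(beta = beta, iterations = it, converged = TRUE))
    }
  }
  obj <- cd_objective(prep, beta, lambda, phi)
  stop(sprintf(
    "coordinate descent did not converge in %d sweeps (last objective %.6g)",
    max_iter, obj))
}

cd_objective <- function(prep, beta, lambda, phi) {
  mse <- prep$ymsq - 2 * sum(beta * prep$Sxy) +
    drop(crossprod(beta, prep$Sxx %*% beta))
  mse + lambda / prep$n * sum(phi * abs(beta))
}

resolve_loadings <- function(loadings, p, names) {
  if (is.null(loadings)) loadings <- rep(1, p)
  if (!is.null(base::names(loadings)) && !is.null(names)) {
    loadings <- loadings[names]
  }
  if (length(loadings) != p || any(!is.finite(loadings)) || any(loadings <= 0)) {
    stop("loadings must be ", p, " positive finite values")
  }
  unname(loadings)
}

finish_fit <- function(prep, beta, lambda, phi, iterations) {
  mse <- prep$ymsq - 2 * sum(beta * prep$Sxy) +
    drop(crossprod(beta, prep$Sxx %*% beta))
  mse <- max(mse, 0)
  coef_orig <- beta / prep$scale
  names(coef_orig) <- prep$names
  intercept <- prep$ym - sum(coef_orig * prep$xm)
  g <- 2 * (drop(prep$Sxx %*% beta) - prep$Sxy)
  lim <- lambda * phi / prep$n
  kkt <- ifelse(beta == 0, pmax(abs(g) - lim, 0), abs(g + lim * sign(beta)))
  structure(list(intercept = intercept, coefficients = coef_orig,
                 beta_std = stats::setNames(beta, prep$names),
                 lambda = lambda, loadings = stats::setNames(phi, prep$names),
                 active = prep$names[beta != 0], df = sum(beta != 0),
                 in_rmse = sqrt(mse),
                 objective = mse + lambda / prep$n * sum(phi * abs(beta)),
                 kkt_max = max(kkt), n = prep$n, p = prep$p,
                 iterations = iterations),
            class = "lasso_fit")
}

#' Fit the penalized regression at a fixed penalty level
#'
#' Cyclic coordinate descent with soft-thresholding for the objective
#' `mean((y - b0 - x b)^2) + lambda/n * sum(phi_j * |b_j|)`.  The intercept
#' is unpenalized; coefficients are returned on the original predictor scale.
#'
#' @param x numeric predictor matrix (no missing values).
#' @param y numeric response vector.
#' @param lambda penalty level (>= 0).
#' @param loadings optional positive per-predictor penalty loadings
#'   \eqn{\varphi_j}; default all 1.
#' @param standardize standardize predictors internally (default `TRUE`).
#' @param tol,max_iter convergence control; non-convergence is an error.
#' @return An object of class `lasso_fit` with elements `intercept`,
#'   `coefficients`, `beta_std` (standardized scale), `lambda`, `loadings`,
#'   `active`, `df`, `in_rmse`, `objective`, `kkt_max`, `n`, `p`,
#'   `iterations`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 50, 4)
#' y <- x[, 1] - 2 * x[, 3] + rnorm(50, sd = 0.1)
#' fit_lasso(x, y, lambda = 5)$active
#' @export
fit_lasso <- function(x, y, lambda, loadings = NULL, standardize = TRUE,
                      tol = 1e-8, max_iter = 10000L) {
  if (lambda < 0) stop("lambda must be non-negative")
  prep <- lasso_prep(x, y, standardize)
  phi <- resolve_loadings(loadings, prep$p, prep$names)
  sol <- cd_solve(prep, lambda, phi, tol = tol, max_iter = max_iter)
  finish_fit(prep, sol$beta, lambda, phi, sol$iterations)
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> lambda=%.4g df=%d/%d in-RMSE=%.4g kkt=%.2g\n",
              x$lambda, x$df, x$p, x$in_rmse, x$kkt_max))
  invisible(x)
}

#' @export
predict.lasso_fit <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (!is.null(colnames(newx)) && all(names(object$coefficients) %in% colnames(newx))) {
    newx <- newx[, names(object$coefficients), drop = FALSE]
  }
  drop(object$intercept + newx %*% object$coefficients)
}

#' @export
coef.lasso_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Smallest penalty with an empty active set
#'
#' Under the objective documented in [lasso_config()], all slopes are zero
#' exactly when `lambda >= 2 * max_j |t(x_j) %*% (y - mean(y))| / phi_j`
#' (predictors standardized).
#'
#' @inheritParams fit_lasso
#' @return The null-model penalty threshold.
#' @export
lambda_null <- function(x, y, loadings = NULL, standardize = TRUE) {
  prep <- lasso_prep(x, y, standardize)
  phi <- resolve_loadings(loadings, prep$p, prep$names)
  2 * prep$n * max(abs(prep$Sxy) / phi)
}

path_grid <- function(l0, nlambda, ratio) {
  ## the top of the grid sits a hair above the null threshold so the first
  ## fit is the empty model even under floating-point rounding
  exp(seq(log(l0 * (1 + 1e-9)), log(l0 * ratio), length.out = nlambda))
}

## Fit the whole path (descending lambdas, warm starts).  Internal workhorse;
## returns list(lambdas, fits, summary).
fit_path <- function(prep, lambdas, phi, tol, max_iter) {
  beta <- numeric(prep$p)
  fits <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    sol <- cd_solve(prep, lambdas[i], phi, beta = beta, tol = tol,
                    max_iter = max_iter)
    beta <- sol$beta
    fits[[i]] <- finish_fit(prep, beta, lambdas[i], phi, sol$iterations)
  }
  summary <- data.frame(lambda = lambdas,
                        df = vapply(fits, `[[`, 0L, "df"),
                        in_rmse = vapply(fits, `[[`, 0, "in_rmse"),
                        objective = vapply(fits, `[[`, 0, "objective"))
  list(lambdas = lambdas, fits = fits, summary = summary)
}

#' Trace the penalty path
#'
#' Fits the lasso along a strictly decreasing log-spaced penalty grid
#' starting at the null-model threshold, with warm starts.
#'
#' @inheritParams fit_lasso
#' @param lambdas optional explicit penalty grid (strictly decreasing);
#'   otherwise built from `config`.
#' @param config a [lasso_config()].
#' @return A list of class `lasso_path`: `lambdas`, `fits` (list of
#'   `lasso_fit`), `summary` (data frame with `lambda`, `df`, `in_rmse`,
#'   `objective`).
#' @export
lasso_path <- function(x, y, lambdas = NULL, loadings = NULL,
                       config = lasso_config()) {
  prep <- lasso_prep(x, y, config$standardize)
  phi <- resolve_loadings(loadings %||% config$loadings, prep$p, prep$names)
  if (is.null(lambdas)) {
    l0 <- 2 * prep$n * max(abs(prep$Sxy) / phi)
    if (l0 <= 0) l0 <- 1     # degenerate: y uncorrelated with every predictor
    lambdas <- path_grid(l0, config$nlambda, config$lambda_min_ratio)
  }
  if (is.unsorted(rev(lambdas), strictly = TRUE)) {
    stop("lambda grid must be strictly decreasing")
  }
  out <- fit_path(prep, lambdas, phi, config$tol, config$max_iter)
  structure(c(out, list(prep = prep, phi = phi)), class = "lasso_path")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

refit_rss <- function(x, y, active) {
  if (!length(active)) return(sum((y - mean(y))^2))
  f <- stats::lm.fit(cbind(1, x[, active, drop = FALSE]), y)
  sum(f$residuals^2)
}

ic_value <- function(ic, n, p, rss, df, xi = 0.5) {
  base <- n * log(pmax(rss, 1e-300) / n)
  switch(ic,
    aic  = base + 2 * df,
    aicc = base + 2 * df + ifelse(n - df - 1 > 0,
                                  2 * df * (df + 1) / (n - df - 1), Inf),
    bic  = base + df * log(n),
    ebic = base + df * log(n) + 2 * xi * df * log(p),
    stop("unknown information criterion: ", ic))
}

#' Select the penalty level
#'
#' Three families of penalty selection:
#' * `"cv"`: k-fold cross-validation; respondent-level random fold
#'   assignment from `config$cv_seed`; the penalty minimizing the mean
#'   held-out squared error (no one-standard-error rule).
#' * `"aic"`, `"aicc"`, `"bic"`, `"ebic"`: the stated information criterion
#'   computed along the penalty path with degrees of freedom equal to the
#'   active-set size; the residual sum of squares entering the criterion
#'   comes from a least-squares refit on each active set, so the criterion
#'   ranks supports rather than shrinkage levels.
#' * `"rigorous"`: the theory-driven plug-in penalty
#'   `lambda = 2 c sigma-hat sqrt(n) qnorm(1 - gamma/(2p))` with
#'   heteroskedasticity-aware loadings
#'   `phi_j = sqrt(mean(x_j^2 eps^2)) / sigma-hat`, the residual scale
#'   iterated to convergence (no grid search).
#'
#' @inheritParams lasso_path
#' @param approach one of `"cv"`, `"aic"`, `"aicc"`, `"bic"`, `"ebic"`,
#'   `"rigorous"`.
#' @return A list of class `lambda_selection`: `lambda`, `fit` (a
#'   `lasso_fit` on the full data), `approach`, and `details` (the CV curve,
#'   IC path, or plug-in iteration trace).
#' @export
select_lambda <- function(x, y,
                          approach = c("cv", "aic", "aicc", "bic", "ebic", "rigorous"),
                          config = lasso_config()) {
  approach <- match.arg(approach)
  x <- as.matrix(x)
  if (approach == "rigorous") {
    return(select_lambda_rigorous(x, y, config))
  }
  path <- lasso_path(x, y, config = config)
  if (approach == "cv") {
    n <- nrow(x)
    folds <- with_local_seed(config$cv_seed,
                             sample(rep_len(seq_len(config$cv_folds), n)))
    mse <- matrix(NA_real_, length(path$lambdas), config$cv_folds)
    for (f in seq_len(config$cv_folds)) {
      tr <- folds != f
      if (stats::var(y[tr]) < 1e-12) {
        warning("fold ", f, " skipped: constant response in training part")
        next
      }
      prep_f <- lasso_prep(x[tr, , drop = FALSE], y[tr], config$standardize)
      phi <- resolve_loadings(config$loadings, prep_f$p, prep_f$names)
      pf <- fit_path(prep_f, path$lambdas, phi, config$tol, config$max_iter)
      xv <- x[!tr, , drop = FALSE]
      yv <- y[!tr]
      mse[, f] <- vapply(pf$fits, function(fit) {
        mean((yv - predict(fit, xv))^2)
      }, 0)
    }
    if (all(is.na(mse))) stop("all cross-validation folds were degenerate")
    cvm <- rowMeans(mse, na.rm = TRUE)
    i <- which.min(cvm)
    details <- data.frame(lambda = path$lambdas, cv_mse = cvm,
                          df = path$summary$df)
  } else {
    ## the criterion is evaluated on an active-set least-squares refit, so it
    ## measures support quality rather than shrinkage bias
    rss <- vapply(path$fits, function(f) refit_rss(x, y, f$active), 0)
    crit <- ic_value(approach, n = path$prep$n, p = path$prep$p,
                     rss = rss, df = path$summary$df, xi = config$ebic_xi)
    i <- which.min(crit)
    details <- data.frame(lambda = path$lambdas, criterion = crit,
                          df = path$summary$df)
  }
  structure(list(lambda = path$lambdas[i], fit = path$fits[[i]],
                 approach = approach, details = details),
            class = "lambda_selection")
}

select_lambda_rigorous <- function(x, y, config) {
  prep <- lasso_prep(x, y, config$standardize)
  n <- prep$n; p <- prep$p
  gamma <- config$rigorous_gamma %||% (0.1 / log(max(p, n)))
  cconst <- config$rigorous_c
  ## standardized design for the loading formula
  xs <- sweep(sweep(as.matrix(x), 2L, prep$xm), 2L, prep$scale, "/")
  eps <- y - prep$ym
  sigma <- sqrt(mean(eps^2))
  trace <- data.frame(iter = integer(), sigma = numeric(), lambda = numeric())
  fit <- NULL
  for (it in seq_len(config$rigorous_iter)) {
    phi <- sqrt(colMeans(xs^2 * eps^2)) / sigma
    phi <- pmax(phi, 1e-4)
    lambda <- rigorous_lambda(n, p, cconst, gamma, sigma)
    sol <- cd_solve(prep, lambda, phi, tol = config$tol,
                    max_iter = config$max_iter)
    fit <- finish_fit(prep, sol$beta, lambda, phi, sol$iterations)
    eps <- y - (fit$intercept + drop(as.matrix(x) %*% fit$coefficients))
    sigma_new <- sqrt(mean(eps^2))
    trace <- rbind(trace, data.frame(iter = it, sigma = sigma_new,
                                     lambda = lambda))
    if (abs(sigma_new - sigma) < 1e-4 * max(sigma, 1e-12)) {
      sigma <- sigma_new
      break
    }
    sigma <- sigma_new
  }
  structure(list(lambda = fit$lambda, fit = fit, approach = "rigorous",
                 details = trace,
                 constants = list(c = cconst, gamma = gamma, sigma = sigma)),
            class = "lambda_selection")
}

#' Closed form of the plug-in ("rigorous") penalty
#'
#' `lambda = 2 * c * sigma * sqrt(n) * qnorm(1 - gamma / (2 * p))`.
#'
#' @param n,p sample size and number of predictors.
#' @param c slack constant (default 1.1).
#' @param gamma tail probability (default `0.1 / log(max(p, n))`).
#' @param sigma residual scale.
#' @return The penalty level.
#' @export
rigorous_lambda <- function(n, p, c = 1.1, gamma = 0.1 / log(max(p, n)),
                            sigma = 1) {
  2 * c * sigma * sqrt(n) * stats::qnorm(1 - gamma / (2 * p))
}

#' Select an active set of exactly k predictors
#'
#' Searches the penalty path for a support of the prescribed size: first the
#' standard log-spaced grid, then (if the support size jumps past `k`
#' between adjacent grid points) up to 60 bisection steps between the
#' bracketing penalties.  If the path never visits a support of size `k`,
#' the smallest support larger than `k` is taken and its predictors with the
#' smallest standardized absolute coefficients are dropped (ties broken by
#' column order); this fallback is reported via the `fallback` element and a
#' message.  For `approach = "rigorous"` the search is run under that
#' approach's converged penalty loadings; the other approaches share the
#' unit-loading path.
#'
#' @inheritParams select_lambda
#' @param k required active-set size, `0 <= k <= ncol(x)`.
#' @return A list of class `exact_k_fit`: `names` (selected predictors in
#'   column order), `fit` (`lasso_fit`), `lambda`, `approach`, `fallback`.
#' @export
exact_k_select <- function(x, y, k,
                           approach = c("cv", "aic", "aicc", "bic", "ebic", "rigorous"),
                           config = lasso_config()) {
  approach <- match.arg(approach)
  x <- as.matrix(x)
  p <- ncol(x)
  k <- as.integer(k)
  if (k < 0 || k > p) stop("k must be between 0 and ", p)
  prep <- lasso_prep(x, y, config$standardize)
  if (approach == "rigorous") {
    phi <- unname(select_lambda_rigorous(x, y, config)$fit$loadings)
  } else {
    phi <- resolve_loadings(config$loadings, prep$p, prep$names)
  }
  l0 <- 2 * prep$n * max(abs(prep$Sxy) / phi)
  if (l0 <= 0) l0 <- 1

  if (k == 0L) {
    l0 <- l0 * (1 + 1e-9)
    sol <- cd_solve(prep, l0, phi, tol = config$tol, max_iter = config$max_iter)
    fit <- finish_fit(prep, sol$beta, l0, phi, sol$iterations)
    return(structure(list(names = character(0), fit = fit, lambda = l0,
                          approach = approach, fallback = FALSE),
                     class = "exact_k_fit"))
  }

  lambdas <- path_grid(l0, config$nlambda, config$lambda_min_ratio)
  path <- fit_path(prep, lambdas, phi, config$tol, config$max_iter)
  dfs <- path$summary$df

  hit <- which(dfs == k)
  if (length(hit)) {
    fit <- path$fits[[hit[1]]]   # largest penalty achieving size k
    return(structure(list(names = active_in_order(fit, prep$names), fit = fit,
                          lambda = fit$lambda, approach = approach,
                          fallback = FALSE),
                     class = "exact_k_fit"))
  }

  ## extend the grid downward if even the smallest penalty is too sparse
  extra <- 0L
  while (max(dfs) < k && extra < 3L && utils::tail(lambdas, 1) > 1e-12 * l0) {
    lo <- utils::tail(lambdas, 1)
    more <- path_grid(lo * 0.999, config$nlambda, config$lambda_min_ratio)
    mp <- fit_path(prep, more, phi, config$tol, config$max_iter)
    lambdas <- c(lambdas, more)
    path$fits <- c(path$fits, mp$fits)
    dfs <- c(dfs, mp$summary$df)
    hit <- which(dfs == k)
    if (length(hit)) {
      fit <- path$fits[[hit[1]]]
      return(structure(list(names = active_in_order(fit, prep$names),
                            fit = fit, lambda = fit$lambda,
                            approach = approach, fallback = FALSE),
                       class = "exact_k_fit"))
    }
    extra <- extra + 1L
  }

  ## bisect across the first bracket where the support size jumps past k
  br <- which(dfs[-length(dfs)] < k & dfs[-1] > k)[1]
  if (!is.na(br)) {
    hi <- lambdas[br]; lo <- lambdas[br + 1]
    beta <- path$fits[[br]]$beta_std
    for (step in seq_len(60L)) {
      mid <- sqrt(hi * lo)
      sol <- cd_solve(prep, mid, phi, beta = unname(beta), tol = config$tol,
                      max_iter = config$max_iter)
      fit <- finish_fit(prep, sol$beta, mid, phi, sol$iterations)
      if (fit$df == k) {
        return(structure(list(names = active_in_order(fit, prep$names),
                              fit = fit, lambda = mid, approach = approach,
                              fallback = FALSE),
                         class = "exact_k_fit"))
      }
      if (fit$df < k) hi <- mid else lo <- mid
    }
  }

  ## fallback: smallest support exceeding k, drop weakest coefficients
  over <- which(dfs > k)
  if (!length(over)) {
    stop("support of size ", k, " is unreachable; nearest achievable sizes: ",
         paste(sort(unique(dfs[order(abs(dfs - k))][1:2])), collapse = ", "))
  }
  best <- over[which.min(dfs[over])]
  fit0 <- path$fits[[best]]
  b <- fit0$beta_std
  act <- which(b != 0)
  drop_n <- length(act) - k
  ord <- act[order(abs(b[act]), seq_along(act))]   # smallest |coef|, ties by column order
  keep <- setdiff(act, ord[seq_len(drop_n)])
  message("exact-k fallback used: path jumped past k=", k,
          "; dropped ", drop_n, " weakest coefficient(s) from a support of ",
          length(act))
  ## refit restricted to the kept support at the same penalty
  prep_k <- lasso_prep(x[, keep, drop = FALSE], y, config$standardize)
  phi_k <- phi[keep]
  sol <- cd_solve(prep_k, fit0$lambda, phi_k, tol = config$tol,
                  max_iter = config$max_iter)
  fit_k <- finish_fit(prep_k, sol$beta, fit0$lambda, phi_k, sol$iterations)
  ## embed back into full coefficient vector
  coefs <- stats::setNames(numeric(p), prep$names)
  coefs[keep] <- fit_k$coefficients
  fit_k$coefficients <- coefs
  bstd <- stats::setNames(numeric(p), prep$names)
  bstd[keep] <- fit_k$beta_std
  fit_k$beta_std <- bstd
  fit_k$p <- p
  fit_k$active <- prep$names[keep]
  structure(list(names = prep$names[sort(keep)], fit = fit_k,
                 lambda = fit0$lambda, approach = approach, fallback = TRUE),
            class = "exact_k_fit")
}

active_in_order <- function(fit, names) {
  names[names %in% fit$active]
}
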