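# Shared fixtures and independent brute-force oracles.

## A small three-DD schema used where the full 33-indicator fixture is overkill.
toy_schema <- function(threshold = 0.5) {
  new_schema(data.frame(
    name = c("FAa", "FAb", "FAc", "FKa", "HRa", "HRb", "HRc"),
    dd = c("FA", "FA", "FA", "FK", "HR", "HR", "HR"),
    theme = c("say", "say", "money", "nutrition", "water", "illness", "illness"),
    description = paste("toy indicator", 1:7)))
}

## Survey rows with explicit indicator values for a given schema.
toy_survey <- function(schema, values, site = "A", group = "index_woman") {
  stopifnot(ncol(values) == n_indicators(schema))
  colnames(values) <- indicator_names(schema)
  data.frame(respondent_id = sprintf("r%d", seq_len(nrow(values))),
             site = site, group = group, age = 30, pregnant = FALSE,
             values, stringsAsFactors = FALSE, check.names = FALSE)
}

## Brute-force minimizer of the penalized objective over a coefficient grid
## (p = 2), blocked to keep memory modest.  Independent of the solver: it
## evaluates mean((y - b0 - X b)^2) + lambda/n * sum(phi |b_std|) directly,
## profiling out the intercept at each grid point via centering.
brute_lasso_p2 <- function(x, y, lambda, phi = c(1, 1), lim = 3, res = 1e-3) {
  n <- nrow(x)
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm)
  sx <- sqrt(colMeans(xc^2))
  xs <- sweep(xc, 2, sx, "/")
  yc <- y - mean(y)
  g <- seq(-lim, lim, by = res)
  s11 <- mean(xs[, 1]^2); s22 <- mean(xs[, 2]^2); s12 <- mean(xs[, 1] * xs[, 2])
  sy1 <- mean(xs[, 1] * yc); sy2 <- mean(xs[, 2] * yc)
  ymsq <- mean(yc^2)
  best <- Inf; best_b <- c(NA, NA)
  f1 <- s11 * g^2 - 2 * sy1 * g + lambda / n * phi[1] * abs(g)
  f2 <- s22 * g^2 - 2 * sy2 * g + lambda / n * phi[2] * abs(g)
  block <- 400
  for (i0 in seq(1, length(g), by = block)) {
    ii <- i0:min(i0 + block - 1, length(g))
    vals <- outer(f1[ii], f2, "+") + 2 * s12 * outer(g[ii], g)
    m <- which.min(vals)
    if (vals[m] < best) {
      best <- vals[m]
      r <- (m - 1) %% length(ii) + 1
      cc <- (m - 1) %/% length(ii) + 1
      best_b <- c(g[ii][r], g[cc])
    }
  }
  list(objective = best + ymsq, beta_std = best_b,
       beta = best_b / sx)
}

## Exhaustive pair-count Kendall statistics.
brute_kendall <- function(x, y) {
  n <- length(x)
  S <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    S <- S + sign(x[j] - x[i]) * sign(y[j] - y[i])
  }
  n0 <- n * (n - 1) / 2
  tx <- as.numeric(table(x)); ty <- as.numeric(table(y))
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  list(S = S, tau_a = S / n0, tau_b = S / sqrt((n0 - n1) * (n0 - n2)))
}

## Exhaustive positive-negative pair counting AUC (ties count one half).
brute_auc <- function(score, truth) {
  pos <- score[truth == 1]; neg <- score[truth == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

## Small correlated binary design for lasso tests.
sim_design <- function(n, p, seed = 1) {
  with_seed_local(seed, {
    z <- stats::rnorm(n)
    x <- matrix(stats::rbinom(n * p, 1, stats::plogis(0.5 * z)), n, p)
    colnames(x) <- paste0("v", seq_len(p))
    x
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
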