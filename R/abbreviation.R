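#' Partition a survey by site
#'
#' The abbreviation design trains on a subset of sites and validates on the
#' remaining ones, so that the selected indicator list is tested away from
#' the context that produced it.
#'
#' @param data survey data frame with a `site` column.
#' @param train_sites character vector of training-site labels; must be a
#'   non-empty proper subset of the observed sites.
#' @return A list with elements `train` and `validation` (disjoint,
#'   exhaustive by site).
#' @export
split_by_site <- function(data, train_sites) {
  if (!"site" %in% names(data)) stop("data has no 'site' column")
  sites <- unique(as.character(data$site))
  train_sites <- as.character(train_sites)
  unknown <- setdiff(train_sites, sites)
  if (length(unknown)) stop("unknown site label(s): ", paste(unknown, collapse = ", "))
  if (!length(train_sites)) stop("train_sites must be non-empty")
  if (length(setdiff(sites, train_sites)) == 0) {
    stop("train_sites covers every site: validation set would be empty")
  }
  in_train <- data$site %in% train_sites
  list(train = data[in_train, , drop = FALSE],
       validation = data[!in_train, , drop = FALSE])
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

## Rows usable for the regression stage: all schema indicators observed.
complete_indicator_rows <- function(data, schema) {
  x <- indicator_matrix(data, schema)
  keep <- stats::complete.cases(x)
  if (any(!keep)) {
    message(sum(!keep), " respondent(s) with incomplete indicators dropped ",
            "from the regression stage")
  }
  data[keep, , drop = FALSE]
}

#' Abbreviate the index: per-approach exact-k selection and audit
#'
#' End-to-end abbreviation: the composite score (or binary status) computed
#' from the full schema on the training sites is regressed, with an L1
#' penalty tuned to an active set of exactly `k` indicators, on the full
#' indicator matrix; each selection approach is audited with its in-sample
#' (training) and out-of-sample (validation) RMSE and with the theme
#' coverage of its selected subset.  The chosen subset is the one with the
#' lowest out-of-sample RMSE among approaches passing the coverage rule,
#' ties broken in favour of cross-validation and then by schema order of
#' the subset.  An unpenalized least-squares fit on all indicators is
#' reported alongside as the `ols` baseline row.
#'
#' @param data survey data frame (see [read_survey()]).
#' @param schema the full `weni_schema`.
#' @param k required number of indicators in the abbreviated index.
#' @param train_sites site labels used for training (see [split_by_site()]).
#' @param approaches subset of
#'   `c("cv", "aic", "aicc", "bic", "ebic", "rigorous")`.
#' @param response `"score"` (the continuous composite, default) or
#'   `"status"` (the 0/1 empowerment status, run through the same linear
#'   machinery).
#' @param config a [lasso_config()].
#' @param coverage_cutoff minimum per-DD theme coverage percent (default 50).
#' @param threshold empowerment cutoff used to compute the response;
#'   defaults to the schema threshold.
#' @return An object of class `abbreviation_report`: a list with `table`
#'   (one row per approach plus the `ols` baseline), `selected` (named list
#'   of indicator subsets), `coverage` (named list of [theme_coverage()]
#'   results), `chosen` (`approach`, `names`, or `NULL` with `failed = TRUE`
#'   when no approach passes coverage), sample sizes and the echoed
#'   configuration.
#' @examples
#' d <- generate_survey(default_config(n_total = 400))
#' rep <- run_abbreviation(d, weni_schema("weni33"), k = 20,
#'                         train_sites = c("site1", "site2"),
#'                         approaches = "bic")
#' rep$table
#' @export
run_abbreviation <- function(data, schema, k, train_sites,
                             approaches = c("cv", "aic", "aicc", "bic",
                                            "ebic", "rigorous"),
                             response = c("score", "status"),
                             config = lasso_config(),
                             coverage_cutoff = 50, threshold = NULL) {
  stopifnot(inherits(schema, "weni_schema"))
  response <- match.arg(response)
  approaches <- match.arg(approaches, several.ok = TRUE)
  p <- n_indicators(schema)
  if (k > p) stop("k must not exceed the ", p, " schema indicators")

  split <- split_by_site(data, train_sites)
  train <- complete_indicator_rows(split$train, schema)
  valid <- complete_indicator_rows(split$validation, schema)

  resp_of <- function(d) {
    s <- compute_scores(d, schema, threshold = threshold)
    if (response == "score") s$composite else as.numeric(s$status)
  }
  y_tr <- resp_of(train)
  y_va <- resp_of(valid)
  x_tr <- indicator_matrix(train, schema)
  x_va <- indicator_matrix(valid, schema)

  rows <- list()
  selected <- list()
  coverage <- list()
  fits <- list()

  for (ap in approaches) {
    sel <- exact_k_select(x_tr, y_tr, k, approach = ap, config = config)
    cov <- theme_coverage(schema, sel$names, cutoff = coverage_cutoff)
    refit <- refit_ols(x_tr, y_tr, x_va, y_va, sel$names)
    rows[[ap]] <- data.frame(
      approach = ap, n_selected = length(sel$names),
      n_dropped = p - length(sel$names),
      in_rmse = rmse(y_tr, predict(sel$fit, x_tr)),
      out_rmse = rmse(y_va, predict(sel$fit, x_va)),
      in_rmse_refit = refit$in_rmse, out_rmse_refit = refit$out_rmse,
      coverage_min = attr(cov, "min_coverage"),
      coverage_pass = attr(cov, "passes"),
      fallback = sel$fallback, stringsAsFactors = FALSE)
    selected[[ap]] <- sel$names
    coverage[[ap]] <- cov
    fits[[ap]] <- sel$fit
  }

  ## unpenalized least-squares baseline on the full indicator set
  ols <- refit_ols(x_tr, y_tr, x_va, y_va, colnames(x_tr))
  rows[["ols"]] <- data.frame(
    approach = "ols", n_selected = p, n_dropped = 0L,
    in_rmse = ols$in_rmse, out_rmse = ols$out_rmse,
    in_rmse_refit = ols$in_rmse, out_rmse_refit = ols$out_rmse,
    coverage_min = 100, coverage_pass = TRUE, fallback = FALSE,
    stringsAsFactors = FALSE)

  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  chosen <- choose_subset(table[table$approach != "ols", , drop = FALSE],
                          selected, schema)
  structure(list(table = table, selected = selected, coverage = coverage,
                 fits = fits, chosen = chosen$chosen,
                 failed = chosen$failed, k = k, response = response,
                 n_train = nrow(train), n_validation = nrow(valid),
                 train_sites = train_sites,
                 coverage_cutoff = coverage_cutoff,
                 threshold = threshold %||% schema$threshold,
                 config = config),
            class = "abbreviation_report")
}

refit_ols <- function(x_tr, y_tr, x_va, y_va, nm) {
  if (!length(nm)) {
    mu <- mean(y_tr)
    return(list(in_rmse = rmse(y_tr, mu), out_rmse = rmse(y_va, mu)))
  }
  df_tr <- data.frame(y = y_tr, x_tr[, nm, drop = FALSE], check.names = TRUE)
  fit <- stats::lm(y ~ ., data = df_tr)
  df_va <- data.frame(x_va[, nm, drop = FALSE], check.names = TRUE)
  pr_va <- stats::predict(fit, newdata = df_va)
  list(in_rmse = rmse(y_tr, stats::fitted(fit)), out_rmse = rmse(y_va, pr_va))
}

choose_subset <- function(tab, selected, schema) {
  pass <- tab$coverage_pass
  if (!any(pass)) {
    return(list(chosen = NULL, failed = TRUE))
  }
  cand <- tab[pass, , drop = FALSE]
  best <- min(cand$out_rmse)
  cand <- cand[cand$out_rmse <= best + 1e-12, , drop = FALSE]
  if ("cv" %in% cand$approach) {
    ap <- "cv"
  } else if (nrow(cand) == 1) {
    ap <- cand$approach[1]
  } else {
    ## break remaining ties by schema order of the subsets
    full <- indicator_names(schema)
    keys <- vapply(cand$approach, function(a) {
      paste(sprintf("%03d", sort(match(selected[[a]], full))), collapse = "")
    }, "")
    ap <- cand$approach[order(keys)][1]
  }
  list(chosen = list(approach = ap, names = selected[[ap]]), failed = FALSE)
}

#' @export
print.abbreviation_report <- function(x, ...) {
  cat(sprintf("Abbreviation to k=%d indicators (response: %s)\n", x$k, x$response))
  cat(sprintf("  training n=%d (sites: %s), validation n=%d\n", x$n_train,
              paste(x$train_sites, collapse = ", "), x$n_validation))
  print.data.frame(x$table, row.names = FALSE, digits = 4)
  if (isTRUE(x$failed)) {
    cat("No approach passed the theme-coverage rule: no subset chosen.\n")
  } else {
    cat(sprintf("Chosen (%s): %s\n", x$chosen$approach,
                paste(x$chosen$names, collapse = ", ")))
  }
  invisible(x)
}

#' Sensitivity sweeps over threshold, subset size or training sites
#'
#' Re-runs the abbreviation pipeline over a grid:
#' * `mode = "threshold"`: empowerment cutoffs (e.g. 0.50 to 0.70 by 0.05);
#'   each row reports the empowerment prevalence at that cutoff and the
#'   chosen subset's performance.
#' * `mode = "k"`: subset sizes (e.g. 10, 15, 20, 25).
#' * `mode = "site-swap"`: alternative training-site sets; each row reports
#'   the symmetric-difference size between that run's chosen subset and the
#'   baseline run's (the one trained on `train_sites`).
#'
#' @inheritParams run_abbreviation
#' @param mode one of `"threshold"`, `"k"`, `"site-swap"`.
#' @param grid thresholds in `(0, 1)`, integer subset sizes, or a list of
#'   training-site character vectors, per `mode`.
#' @return A data frame of class `weni_sweep`, one row per grid point.
#' @export
sensitivity_sweep <- function(data, schema, mode = c("threshold", "k", "site-swap"),
                              grid, train_sites, k = 20,
                              approaches = c("cv", "aic", "aicc", "bic",
                                             "ebic", "rigorous"),
                              response = c("score", "status"),
                              config = lasso_config(), coverage_cutoff = 50) {
  mode <- match.arg(mode)
  response <- match.arg(response)
  if (!length(grid)) stop("empty sweep grid")
  run1 <- function(k., sites., thr.) {
    run_abbreviation(data, schema, k = k., train_sites = sites.,
                     approaches = approaches, response = response,
                     config = config, coverage_cutoff = coverage_cutoff,
                     threshold = thr.)
  }
  rows <- switch(mode,
    threshold = lapply(grid, function(t) {
      stopifnot(t > 0, t < 1)
      rep <- run1(k, train_sites, t)
      prev <- prevalence(compute_scores(data, schema, threshold = t))
      data.frame(threshold = t, prevalence = prev, sweep_row(rep))
    }),
    k = lapply(grid, function(kk) {
      rep <- run1(as.integer(kk), train_sites, NULL)
      data.frame(k = as.integer(kk), sweep_row(rep))
    }),
    `site-swap` = {
      if (!is.list(grid)) grid <- list(grid)
      base <- run1(k, train_sites, NULL)
      base_names <- if (base$failed) character(0) else base$chosen$names
      lapply(grid, function(sites) {
        rep <- run1(k, sites, NULL)
        nm <- if (rep$failed) character(0) else rep$chosen$names
        data.frame(train_sites = paste(sites, collapse = "+"),
                   sweep_row(rep),
                   symmetric_difference = length(setdiff(nm, base_names)) +
                     length(setdiff(base_names, nm)))
      })
    })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("weni_sweep", "data.frame")
  out
}

sweep_row <- function(rep) {
  if (rep$failed) {
    return(data.frame(chosen_approach = NA_character_, n_selected = NA_integer_,
                      out_rmse = NA_real_, coverage_pass = FALSE,
                      stringsAsFactors = FALSE))
  }
  row <- rep$table[rep$table$approach == rep$chosen$approach, , drop = FALSE]
  data.frame(chosen_approach = rep$chosen$approach,
             n_selected = row$n_selected, out_rmse = row$out_rmse,
             coverage_pass = row$coverage_pass, stringsAsFactors = FALSE)
}
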