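#' Synthetic multi-site survey configuration
#'
#' Describes the data-generating world used for testing: a latent
#' empowerment factor per respondent (site-shifted normal), binary
#' indicators drawn from a logistic measurement model with a shared
#' within-DD perturbation (so indicators in one domain-dimension co-move),
#' and nutritional outcomes (BMI, food-group count) positively tied to
#' empowerment.
#'
#' @param sites data frame with columns `name`, `n`, `shift` (site offset on
#'   the latent scale).
#' @param latent_sd standard deviation of the latent factor within site.
#' @param loading_a per-indicator difficulty (intercept on the logit scale).
#' @param loading_b per-indicator slope on the latent factor.
#' @param dd_sd standard deviation of the shared per-DD logit perturbation.
#' @param missing_rate probability that an indicator cell is missing.
#' @param bmi list: `intercept` (kg/m2), `effect` (empowered-vs-not shift),
#'   `group_effects` (named, per demographic group), `sd` (residual noise).
#' @param mdd list: `intercept`, `slope` -- logit-scale parameters of the
#'   per-food-group success probability (count is Binomial(10, .)).
#' @param group_mix named probabilities over demographic groups.
#' @param pregnant_rate probability that an index woman is pregnant.
#' @param schema the `weni_schema` whose indicators are generated.
#' @param target_prevalence the empowerment prevalence the calibrated
#'   defaults aim for (recorded, not enforced).
#' @param seed integer seed making [generate_survey()] deterministic.
#' @return A list of class `weni_sim_config`.
#' @export
weni_sim_config <- function(sites, latent_sd = 1, loading_a, loading_b,
                            dd_sd = 0.35, missing_rate = 0,
                            bmi = list(intercept = 20, effect = 0.8,
                                       group_effects = c(index_woman = 0,
                                                         spouse = 0.6,
                                                         mother_in_law = 0.9,
                                                         older_woman = 0.2),
                                       sd = 2),
                            mdd = list(intercept = -0.2, slope = 0.5),
                            group_mix = c(index_woman = 0.4, spouse = 0.2,
                                          mother_in_law = 0.2,
                                          older_woman = 0.2),
                            pregnant_rate = 0.15,
                            schema = weni_schema("weni33"),
                            target_prevalence = 0.45, seed = 101L) {
  stopifnot(is.data.frame(sites), all(c("name", "n", "shift") %in% names(sites)),
            all(sites$n >= 1), latent_sd > 0, dd_sd >= 0,
            missing_rate >= 0, missing_rate <= 1,
            bmi$sd > 0, pregnant_rate >= 0, pregnant_rate <= 1,
            abs(sum(group_mix) - 1) < 1e-8, all(group_mix >= 0),
            inherits(schema, "weni_schema"))
  p <- n_indicators(schema)
  if (length(loading_a) != p || length(loading_b) != p) {
    stop("loading_a and loading_b must have one entry per schema indicator (", p, ")")
  }
  structure(list(sites = sites, latent_sd = latent_sd,
                 loading_a = loading_a, loading_b = loading_b, dd_sd = dd_sd,
                 missing_rate = missing_rate, bmi = bmi, mdd = mdd,
                 group_mix = group_mix, pregnant_rate = pregnant_rate,
                 schema = schema, target_prevalence = target_prevalence,
                 seed = as.integer(seed)),
            class = "weni_sim_config")
}

#' Default synthetic-survey configuration
#'
#' Five sites totalling 2398 respondents by default, the first two shifted
#' down on the latent scale (training-like sites with lower empowerment),
#' indicator difficulties spread so that marginal prevalences vary, and
#' item discriminations varying over a fixed 7-value cycle so that every
#' domain-dimension holds some highly informative indicators (without such
#' heterogeneity the whole food-resources block, whose indicators carry the
#' smallest composite weights, is substitutable and an unconstrained
#' selection can drop it wholesale).  The difficulty spread is calibrated
#' once so that overall empowerment prevalence is about 45% at the 0.5
#' cutoff.  The empowerment effect on BMI defaults to 0.8 kg/m2.
#'
#' @param n_total total sample size; site sizes are scaled proportionally
#'   from the default `c(486, 485, 476, 476, 475)`.
#' @param seed integer seed stored in the configuration.
#' @param ... overrides passed on to [weni_sim_config()].
#' @return A `weni_sim_config`.
#' @export
default_config <- function(n_total = 2398L, seed = 101L, ...) {
  base_n <- c(486, 485, 476, 476, 475)
  n <- pmax(1L, round(base_n / sum(base_n) * n_total))
  sites <- data.frame(name = paste0("site", 1:5), n = n,
                      shift = c(-0.45, -0.45, 0.25, 0.25, 0.25))
  schema <- weni_schema("weni33")
  p <- n_indicators(schema)
  args <- list(...)
  if (is.null(args$schema)) args$schema <- schema
  defaults <- list(sites = sites,
                   loading_a = seq(-1.1, 0.9, length.out = p),
                   loading_b = rep(c(1.5, 0.7, 1.1, 1.6, 0.8, 1.3, 0.6),
                                   length.out = p),
                   dd_sd = 0.5,
                   seed = seed)
  do.call(weni_sim_config, utils::modifyList(defaults, args))
}

#' Generate a synthetic multi-site survey
#'
#' Deterministic given `(config, seed)`: latent empowerment
#' `theta ~ Normal(site shift, latent_sd)`; indicator `j` is
#' `Bernoulli(plogis(a_j + b_j * theta + u_dd))` with one shared
#' `u_dd ~ Normal(0, dd_sd)` per DD per respondent; BMI is
#' `intercept + effect * 1{composite >= threshold} + group effect + noise`;
#' the food-group count is `Binomial(10, plogis(mdd intercept + slope *
#' theta))`.  No upper truncation is applied to BMI: the analysis stage's
#' BMI < 25 restriction is what creates the analysed subsample.
#'
#' @param config a [weni_sim_config()].
#' @param seed overrides `config$seed` when given.
#' @return A survey data frame: `respondent_id`, `site`, `group`, `age`,
#'   `pregnant`, `bmi`, `food_groups`, `theta` (the latent factor, kept for
#'   diagnostics), and one 0/1 column per schema indicator.
#' @examples
#' d <- generate_survey(default_config(n_total = 100))
#' table(d$site)
#' @export
generate_survey <- function(config, seed = NULL) {
  stopifnot(inherits(config, "weni_sim_config"))
  seed <- seed %||% config$seed
  schema <- config$schema
  nm <- indicator_names(schema)
  dd <- dd_of(schema)
  dds <- intersect(DD_LEVELS, unique(dd))
  n <- sum(config$sites$n)

  with_local_seed(seed, {
    site <- rep(config$sites$name, config$sites$n)
    shift <- rep(config$sites$shift, config$sites$n)
    theta <- stats::rnorm(n, shift, config$latent_sd)

    grp <- sample(names(config$group_mix), n, replace = TRUE,
                  prob = config$group_mix)
    age_range <- list(index_woman = c(20, 35), spouse = c(22, 50),
                      mother_in_law = c(40, 65), older_woman = c(70, 85))
    age <- vapply(grp, function(g) {
      r <- age_range[[g]] %||% c(18, 80)
      round(stats::runif(1, r[1], r[2]))
    }, 0)
    pregnant <- grp == "index_woman" &
      stats::runif(n) < config$pregnant_rate

    u <- matrix(stats::rnorm(n * length(dds), 0, config$dd_sd), n,
                dimnames = list(NULL, dds))
    eta <- outer(theta, config$loading_b) +
      matrix(config$loading_a, n, length(nm), byrow = TRUE) +
      u[, dd, drop = FALSE]
    pr <- stats::plogis(eta)
    clipped <- sum(pr < 0 | pr > 1)    # cannot occur through plogis; guard anyway
    if (clipped > 0) {
      pr <- pmin(pmax(pr, 0), 1)
      message(clipped, " indicator probabilit(ies) clipped to [0, 1]")
    }
    x <- matrix(stats::rbinom(n * length(nm), 1, pr), n,
                dimnames = list(NULL, nm))

    ## composite under the full schema (complete data: exact linear form)
    w <- linear_weights(schema)
    composite <- drop(x %*% w[nm])
    empowered <- as.integer(composite >= schema$threshold)

    bmi <- config$bmi$intercept + config$bmi$effect * empowered +
      unname(config$bmi$group_effects[grp]) +
      stats::rnorm(n, 0, config$bmi$sd)
    food_groups <- stats::rbinom(
      n, 10, stats::plogis(config$mdd$intercept + config$mdd$slope * theta))

    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(n * length(nm)) < config$missing_rate,
                     n, length(nm))
      x[mask] <- NA_integer_
    }

    data.frame(respondent_id = sprintf("R%05d", seq_len(n)),
               site = site, group = grp, age = age, pregnant = pregnant,
               bmi = round(bmi, 2), food_groups = food_groups,
               theta = theta, x, stringsAsFactors = FALSE,
               check.names = FALSE)
  })
}
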