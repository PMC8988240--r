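#' Read a respondent-level survey table
#'
#' Surveys are delimited text (comma or tab, sniffed from the header) with a
#' header row, one row per respondent and empty cells read as missing.
#' Expected columns are `respondent_id`, `site`, `group`, `age`, `pregnant`,
#' optionally `bmi` and `food_groups`, plus one 0/1 column per indicator.
#'
#' @param path file path.
#' @return A data frame.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    na.strings = c("", "NA"), fileEncoding = "UTF-8",
                    stringsAsFactors = FALSE)
}

#' Write a survey or score table
#'
#' @param x data frame.
#' @param path output path.
#' @param sep field separator, default comma.
#' @return `path`, invisibly.
#' @export
write_survey <- function(x, path, sep = ",") {
  utils::write.table(x, path, sep = sep, row.names = FALSE, na = "",
                     qmethod = "double", fileEncoding = "UTF-8")
  invisible(path)
}

## Extract and check the indicator matrix for `schema` from a survey table.
indicator_matrix <- function(data, schema) {
  nm <- indicator_names(schema)
  missing_cols <- setdiff(nm, names(data))
  if (length(missing_cols)) {
    stop("survey data lacks indicator column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(data[, nm, drop = FALSE])
  storage.mode(x) <- "double"
  bad <- !(is.na(x) | x == 0 | x == 1)
  if (any(bad)) {
    stop("indicator values must be 0, 1 or missing; offending column(s): ",
         paste(unique(colnames(x)[which(bad, arr.ind = TRUE)[, 2]]), collapse = ", "))
  }
  x
}

#' Compute domain-dimension scores, composite score and empowerment status
#'
#' The scoring engine of the index: each DD score is the proportion of that
#' DD's indicators on which the respondent is empowered; the composite score
#' is the unweighted mean of the DD scores (each DD counts equally regardless
#' of how many indicators it holds); empowerment status is 1 when the
#' composite reaches the threshold (inclusive: a score exactly at the cutoff
#' is empowered).
#'
#' Missing indicators are handled by `missing_policy`:
#' * `"renormalize"` (default): a missing indicator is dropped from its DD's
#'   denominator.  A respondent with an entire DD missing cannot be scored;
#'   such rows are removed and counted in the `n_dropped` attribute.
#' * `"complete"`: respondents with any missing schema indicator are dropped.
#'
#' @param data survey data frame containing one 0/1 column per schema
#'   indicator (see [read_survey()]).
#' @param schema a `weni_schema`.
#' @param missing_policy `"renormalize"` or `"complete"`.
#' @param threshold empowerment cutoff; defaults to the schema's threshold.
#' @return A data frame of class `weni_scores`: `respondent_id`, one column
#'   per DD code, `composite`, `status`; attributes `threshold`,
#'   `missing_policy`, `n_dropped`, `dropped_id`.
#' @examples
#' sc <- weni_schema("weni33")
#' d <- generate_survey(default_config(n_total = 50))
#' head(compute_scores(d, sc))
#' @export
compute_scores <- function(data, schema,
                           missing_policy = c("renormalize", "complete"),
                           threshold = NULL) {
  stopifnot(inherits(schema, "weni_schema"))
  missing_policy <- match.arg(missing_policy)
  if (is.null(threshold)) threshold <- schema$threshold
  x <- indicator_matrix(data, schema)
  id <- if ("respondent_id" %in% names(data)) {
    as.character(data$respondent_id)
  } else {
    as.character(seq_len(nrow(data)))
  }

  if (missing_policy == "complete") {
    keep <- stats::complete.cases(x)
  } else {
    keep <- rep(TRUE, nrow(x))
  }

  dd <- dd_of(schema)
  dds <- intersect(DD_LEVELS, unique(dd))
  dd_score <- matrix(NA_real_, nrow(x), length(dds),
                     dimnames = list(NULL, dds))
  for (d in dds) {
    cols <- x[, names(dd)[dd == d], drop = FALSE]
    ones <- rowSums(cols == 1, na.rm = TRUE)
    denom <- rowSums(!is.na(cols))
    dd_score[, d] <- ifelse(denom > 0, ones / denom, NA_real_)
  }
  ## whole-DD-missing rows cannot be renormalized
  scoreable <- rowSums(is.na(dd_score)) == 0
  keep <- keep & scoreable

  composite <- rowMeans(dd_score)
  status <- as.integer(composite >= threshold)

  out <- data.frame(respondent_id = id, dd_score, composite = composite,
                    status = status, stringsAsFactors = FALSE,
                    check.names = FALSE)
  dropped <- out$respondent_id[!keep]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (length(dropped)) {
    message(length(dropped), " respondent(s) dropped (unscoreable under policy '",
            missing_policy, "')")
  }
  structure(out, class = c("weni_scores", "data.frame"),
            threshold = threshold, missing_policy = missing_policy,
            n_dropped = length(dropped), dropped_id = dropped)
}

#' Per-indicator linear weights of the composite score
#'
#' On complete data the composite score is an exact linear function of the
#' indicators: indicator `j` carries weight `1 / (D * n_d(j))`, where `D` is
#' the number of DDs in the schema and `n_d(j)` the number of indicators in
#' `j`'s DD.  Weights sum to 1 over any schema.
#'
#' @param schema a `weni_schema`.
#' @return Named numeric vector of weights in schema order.
#' @export
linear_weights <- function(schema) {
  stopifnot(inherits(schema, "weni_schema"))
  dd <- dd_of(schema)
  counts <- dd_counts(schema)
  D <- length(counts)
  stats::setNames(1 / (D * counts[dd]), names(dd))
}

#' Empowerment prevalence of a score set
#'
#' @param scores a `weni_scores` data frame.
#' @return Fraction of respondents with status 1.
#' @export
prevalence <- function(scores) mean(scores$status)
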