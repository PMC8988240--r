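#' Index schemas: the indicator -> theme -> domain-dimension hierarchy
#'
#' A WENI-style index schema maps each binary indicator to one of the seven
#' domain-dimensions (DDs) -- food/health/institutions crossed with
#' agency/knowledge/resources, institutions undivided -- and, within a DD, to
#' a thematic sub-grouping.  Schemas are ordinary data frames wrapped in a
#' light S3 class so that scoring and coverage functions can validate their
#' inputs once.
#'
#' Two fixtures ship with the package: `"weni33"`, the full 33-indicator
#' nutritional-empowerment schema, and `"aweni20"`, its 20-indicator
#' abridgement (a strict subset of the full schema).
#'
#' @param indicators data frame with columns `name`, `dd`, `theme`,
#'   `description` (one row per indicator, order meaningful).
#' @param threshold empowerment cutoff on the composite score, in `[0, 1]`.
#' @return An object of class `weni_schema`: a list with elements
#'   `indicators` (data frame) and `threshold`.
#' @examples
#' sc <- weni_schema("weni33")
#' n_indicators(sc)
#' dd_counts(sc)
#' @export
new_schema <- function(indicators, threshold = 0.5) {
  stopifnot(is.data.frame(indicators))
  req <- c("name", "dd", "theme", "description")
  missing_cols <- setdiff(req, names(indicators))
  if (length(missing_cols)) {
    stop("schema is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  indicators <- indicators[, req]
  indicators[] <- lapply(indicators, as.character)
  rownames(indicators) <- NULL
  obj <- structure(list(indicators = indicators, threshold = threshold),
                   class = "weni_schema")
  validate_schema(obj)
}

validate_schema <- function(schema) {
  ind <- schema$indicators
  if (anyDuplicated(ind$name)) {
    dup <- unique(ind$name[duplicated(ind$name)])
    stop("duplicate indicator name(s) in schema: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(ind$name))) stop("schema contains an empty indicator name")
  bad_dd <- setdiff(unique(ind$dd), DD_LEVELS)
  if (length(bad_dd)) {
    stop("unknown domain-dimension code(s): ", paste(bad_dd, collapse = ", "),
         " (expected one of ", paste(DD_LEVELS, collapse = ", "), ")")
  }
  if (any(!nzchar(ind$theme))) {
    stop("indicator(s) without a theme: ",
         paste(ind$name[!nzchar(ind$theme)], collapse = ", "))
  }
  if (!is.numeric(schema$threshold) || length(schema$threshold) != 1 ||
      is.na(schema$threshold) || schema$threshold < 0 || schema$threshold > 1) {
    stop("threshold must be a single number in [0, 1]")
  }
  schema
}

#' Load a packaged index schema by name
#'
#' @param name `"weni33"` (full 33-indicator schema) or `"aweni20"`
#'   (20-indicator abridgement).
#' @param threshold empowerment cutoff, default 0.5.
#' @return A [new_schema()] object.
#' @export
weni_schema <- function(name = c("weni33", "aweni20"), threshold = 0.5) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "weni",
                      mustWork = TRUE)
  sc <- load_schema(path, threshold = threshold)
  attr(sc, "fixture") <- name
  sc
}

#' Read an index schema from a delimited file
#'
#' The schema dialect is a UTF-8 delimited table (comma or tab, sniffed from
#' the header line) with a header row and columns `name`, `dd`, `theme`,
#' `description`.  A blank `theme` cell inherits the nearest non-blank theme
#' above it within the same DD block (the usual merged-cell convention for
#' printed indicator tables).
#'
#' @param path file path.
#' @param threshold empowerment cutoff stored on the schema, default 0.5.
#' @return A validated [new_schema()] object; indicator order is preserved.
#' @export
load_schema <- function(path, threshold = 0.5) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  ind <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", na.strings = character(),
                           fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  ind$theme <- inherit_themes(ind$theme, ind$dd)
  new_schema(ind, threshold = threshold)
}

## Fill blank theme cells downward within runs of the same DD code.
inherit_themes <- function(theme, dd) {
  theme <- trimws(theme)
  current <- ""
  current_dd <- NA_character_
  for (i in seq_along(theme)) {
    if (!identical(dd[i], current_dd)) {
      current <- ""
      current_dd <- dd[i]
    }
    if (nzchar(theme[i])) current <- theme[i] else theme[i] <- current
  }
  theme
}

#' Write a schema back to a delimited file
#'
#' Inverse of [load_schema()]: `load_schema(write_schema(s, f))` reproduces
#' an equivalent schema (same names, DDs, themes, order).
#'
#' @param schema a `weni_schema`.
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path, sep = ",") {
  stopifnot(inherits(schema, "weni_schema"))
  utils::write.table(schema$indicators, path, sep = sep, row.names = FALSE,
                     qmethod = "double", fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.weni_schema <- function(x, ...) {
  cat(sprintf("<weni_schema> %d indicators, %d domain-dimensions, threshold %.2f\n",
              n_indicators(x), length(unique(x$indicators$dd)), x$threshold))
  counts <- dd_counts(x)
  cat("  ", paste(sprintf("%s=%d", names(counts), counts), collapse = " "), "\n")
  invisible(x)
}

#' Schema accessors
#'
#' @param schema a `weni_schema`.
#' @return `indicator_names()`: character vector in schema order;
#'   `n_indicators()`: integer; `dd_counts()`: named integer vector of
#'   indicators per DD; `dd_of()`: named character vector mapping indicator
#'   name to DD code.
#' @export
indicator_names <- function(schema) schema$indicators$name

#' @rdname indicator_names
#' @export
n_indicators <- function(schema) nrow(schema$indicators)

#' @rdname indicator_names
#' @export
dd_counts <- function(schema) {
  dd <- factor(schema$indicators$dd, levels = intersect(DD_LEVELS, schema$indicators$dd))
  tab <- table(dd)
  stats::setNames(as.integer(tab), names(tab))
}

#' @rdname indicator_names
#' @export
dd_of <- function(schema) {
  stats::setNames(schema$indicators$dd, schema$indicators$name)
}

#' Theme coverage of an indicator subset
#'
#' The abbreviation rule requires a candidate subset to represent at least
#' half of the themes in every domain-dimension of the full schema.  For each
#' DD, coverage is `100 * (# themes with at least one subset indicator) /
#' (# themes in that DD)`.
#'
#' @param full the full `weni_schema` against which coverage is measured.
#' @param subset character vector of indicator names (or a `weni_schema`
#'   whose indicators are used); must be drawn from `full`.
#' @param cutoff minimum per-DD coverage percentage required to pass
#'   (default 50).
#' @return A data frame of class `theme_coverage` with columns `dd`,
#'   `themes_total`, `themes_covered`, `coverage`, and attributes
#'   `min_coverage`, `passes`, `cutoff`.
#' @examples
#' cov <- theme_coverage(weni_schema("weni33"), weni_schema("aweni20"))
#' attr(cov, "passes")
#' @export
theme_coverage <- function(full, subset, cutoff = 50) {
  stopifnot(inherits(full, "weni_schema"))
  if (inherits(subset, "weni_schema")) subset <- indicator_names(subset)
  subset <- as.character(subset)
  unknown <- setdiff(subset, indicator_names(full))
  if (length(unknown)) {
    stop("indicator(s) not in the full schema: ", paste(unknown, collapse = ", "))
  }
  ind <- full$indicators
  dds <- intersect(DD_LEVELS, unique(ind$dd))
  res <- lapply(dds, function(d) {
    themes <- unique(ind$theme[ind$dd == d])
    covered <- unique(ind$theme[ind$dd == d & ind$name %in% subset])
    data.frame(dd = d, themes_total = length(themes),
               themes_covered = length(covered),
               coverage = 100 * length(covered) / length(themes))
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  min_cov <- min(res$coverage)
  structure(res, class = c("theme_coverage", "data.frame"),
            min_coverage = min_cov, cutoff = cutoff,
            passes = min_cov >= cutoff)
}

#' @export
print.theme_coverage <- function(x, ...) {
  cat("Theme coverage by domain-dimension:\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("minimum coverage %.1f%% -> %s at cutoff %g%%\n",
              attr(x, "min_coverage"),
              if (attr(x, "passes")) "PASSES" else "FAILS",
              attr(x, "cutoff")))
  invisible(x)
}
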