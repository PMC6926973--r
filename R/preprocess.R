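#' BMI categories, low to high
#' @export
BMI_CATEGORIES <- c("underweight", "normal", "overweight", "obese")

#' Load the 2007 adolescent growth chart
#'
#' Age- and sex-specific 5th/85th/95th BMI percentile cutoffs (kg/m^2) for
#' ages 12--18, shipped with the package as a CSV. The chart is validated on
#' load: all 14 (age, sex) cells present and `p5 < p85 < p95` everywhere.
#'
#' @param path optional path to an alternative chart CSV with columns
#'   `age, sex, p5, p85, p95`.
#' @return a data frame of class `gbn_growth_chart`.
#' @export
growth_chart <- function(path = NULL) {
  path <- path %||% system.file("extdata", "growth_chart_2007.csv",
                                package = "gbnwhatif", mustWork = TRUE)
  ch <- utils::read.csv(path, stringsAsFactors = FALSE)
  gbn_assert(all(c("age", "sex", "p5", "p85", "p95") %in% names(ch)),
             "out_of_chart", "chart must have columns age, sex, p5, p85, p95")
  gbn_assert(all(ch$p5 < ch$p85) && all(ch$p85 < ch$p95), "out_of_chart",
             "chart cutoffs must satisfy p5 < p85 < p95")
  need <- expand.grid(age = 12:18, sex = c("boy", "girl"))
  key <- paste(ch$age, ch$sex)
  gbn_assert(all(paste(need$age, need$sex) %in% key), "out_of_chart",
             "chart must cover ages 12-18 for both sexes")
  class(ch) <- c("gbn_growth_chart", "data.frame")
  ch
}

#' Body mass index
#'
#' @param weight body weight in kilograms (> 0).
#' @param height height in metres (> 0).
#' @return `weight / height^2` in kg/m^2 (vectorised).
#' @examples
#' compute_bmi(60, 1.60)  # 23.4375
#' @export
compute_bmi <- function(weight, height) {
  gbn_assert(all(is.finite(weight)) && all(is.finite(height)) &&
               all(weight > 0) && all(height > 0),
             "invalid_anthropometry", "weight and height must be positive")
  weight / height^2
}

#' Look up a growth-chart cutoff
#'
#' @param chart a [growth_chart()].
#' @param age age in whole years, 12--18.
#' @param sex `"boy"` or `"girl"`.
#' @param percentile one of 5, 85, 95.
#' @return the BMI cutoff in kg/m^2.
#' @examples
#' lookup_cutoff(growth_chart(), 13, "boy", 95)  # 27.02
#' @export
lookup_cutoff <- function(chart, age, sex, percentile) {
  gbn_assert(percentile %in% c(5, 85, 95), "out_of_chart",
             "percentile must be one of 5, 85, 95")
  i <- which(chart$age == age & chart$sex == sex)
  gbn_assert(length(i) == 1, "out_of_chart",
             paste0("no chart entry for age ", age, ", sex ", sex,
                    " (chart covers ages 12-18)"))
  chart[[paste0("p", percentile)]][i]
}

#' Categorise BMI against the growth chart
#'
#' Intervals are closed on the left: below `p5` underweight, `[p5, p85)`
#' normal, `[p85, p95)` overweight, and at or above `p95` obese.
#'
#' @param bmi BMI in kg/m^2 (vectorised; `age`/`sex` recycled).
#' @inheritParams lookup_cutoff
#' @return character vector of categories from [BMI_CATEGORIES].
#' @examples
#' classify_bmi(27.02, 13, "boy", growth_chart())  # "obese" (at the cutoff)
#' @export
classify_bmi <- function(bmi, age, sex, chart = growth_chart()) {
  n <- max(length(bmi), length(age), length(sex))
  bmi <- rep_len(bmi, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  vapply(seq_len(n), function(i) {
    p5 <- lookup_cutoff(chart, age[i], sex[i], 5)
    p85 <- lookup_cutoff(chart, age[i], sex[i], 85)
    p95 <- lookup_cutoff(chart, age[i], sex[i], 95)
    if (bmi[i] < p5) "underweight"
    else if (bmi[i] < p85) "normal"
    else if (bmi[i] < p95) "overweight"
    else "obese"
  }, "")
}

#' Row filtering with a reconciliation report
#'
#' Applies the survey cleaning rules in order: (1) drop rows with any missing
#' value (an `NA` or a declared marker token anywhere), (2) drop rows flagged
#' as never-users of a smartphone, (3) drop rows answering "don't know" on
#' smartphone usage. Each row is counted against the first rule it violates,
#' so the report's counts always reconcile with the row totals.
#'
#' @param data survey data frame.
#' @param missing_markers character tokens treated as missing anywhere.
#' @param smartphone_rules list with `column` (name of the usage column),
#'   `nonuser` (token flagging no prior use) and `dontknow` (token for a
#'   "don't know" answer); `NULL` disables rules 2--3.
#' @return list with `data` (the surviving rows) and `report` (class
#'   `gbn_filter_report`: `rows_in`, `rows_dropped_missing`,
#'   `rows_dropped_nonuser`, `rows_dropped_dontknow`, `rows_out`).
#' @export
filter_rows <- function(data, missing_markers = c("", "NA", "-9"),
                        smartphone_rules = NULL) {
  n <- nrow(data)
  chr <- as_character_df(data)
  miss <- rep(FALSE, n)
  for (col in chr) miss <- miss | is.na(col) | col %in% missing_markers
  nonuser <- dontknow <- rep(FALSE, n)
  if (!is.null(smartphone_rules)) {
    colname <- smartphone_rules$column
    gbn_assert(is_string(colname) && colname %in% names(chr), "unknown_node",
               "smartphone_rules$column must name a data column")
    col <- chr[[colname]]
    if (!is.null(smartphone_rules$nonuser))
      nonuser <- !miss & col %in% smartphone_rules$nonuser
    if (!is.null(smartphone_rules$dontknow))
      dontknow <- !miss & !nonuser & col %in% smartphone_rules$dontknow
  }
  keep <- !(miss | nonuser | dontknow)
  if (!any(keep)) message("filter_rows: no rows survive filtering")
  report <- structure(list(rows_in = n,
                           rows_dropped_missing = sum(miss),
                           rows_dropped_nonuser = sum(nonuser),
                           rows_dropped_dontknow = sum(dontknow),
                           rows_out = sum(keep)),
                      class = "gbn_filter_report")
  list(data = data[keep, , drop = FALSE], report = report)
}

#' @export
print.gbn_filter_report <- function(x, ...) {
  cat("Filter report:", x$rows_in, "rows in ->", x$rows_out, "rows out\n")
  cat("  dropped missing:   ", x$rows_dropped_missing, "\n")
  cat("  dropped non-user:  ", x$rows_dropped_nonuser, "\n")
  cat("  dropped don't-know:", x$rows_dropped_dontknow, "\n")
  invisible(x)
}

#' Attribute-merge specification
#'
#' Describes how several ordinal source columns collapse into one derived
#' attribute: combine by `ordinal_sum` or `mean`, then quantile-bin the
#' combined value into `bins` ordered categories.
#'
#' @param new_name name of the derived column.
#' @param source_columns character vector of source column names (>= 1).
#' @param combine `"ordinal_sum"` or `"mean"`.
#' @param bins number of output categories (>= 2).
#' @return an object of class `gbn_merge_spec`.
#' @export
merge_spec <- function(new_name, source_columns,
                       combine = c("ordinal_sum", "mean"), bins = 3L) {
  combine <- match.arg(combine)
  gbn_assert(is_string(new_name), "config", "new_name must be a single name")
  gbn_assert(length(source_columns) >= 1, "config",
             "need at least one source column")
  gbn_assert(bins >= 2, "config", "bins must be >= 2")
  structure(list(new_name = new_name,
                 source_columns = as.character(source_columns),
                 combine = combine, bins = as.integer(bins)),
            class = "gbn_merge_spec")
}

ordinal_codes <- function(col, name) {
  if (is.ordered(col)) return(as.integer(col))
  if (is.numeric(col)) return(col)
  suppressWarnings(num <- as.numeric(as.character(col)))
  if (!anyNA(num)) return(num)
  gbn_abort("merge_type",
            paste0("column ", name, " is not ordinal-coded (integers or ",
                   "ordered factor required)"))
}

#' Merge ordinal attributes into binned composites
#'
#' For each [merge_spec()], combines the source columns (`ordinal_sum` or
#' `mean`), quantile-bins the combined score into `bins` ordered categories
#' labelled `L1 < L2 < ...`, drops the source columns and appends the derived
#' column. Row count and order are preserved; untouched columns pass through.
#'
#' @param data survey data frame.
#' @param specs a [merge_spec()] or list of them.
#' @return the transformed data frame.
#' @export
merge_attributes <- function(data, specs) {
  if (inherits(specs, "gbn_merge_spec")) specs <- list(specs)
  out <- data
  for (sp in specs) {
    gbn_assert(all(sp$source_columns %in% names(out)), "unknown_node",
               paste0("merge source column(s) missing: ",
                      paste(setdiff(sp$source_columns, names(out)),
                            collapse = ", ")))
    codes <- vapply(sp$source_columns,
                    function(cn) as.numeric(ordinal_codes(out[[cn]], cn)),
                    numeric(nrow(out)))
    if (is.null(dim(codes))) codes <- matrix(codes, nrow = nrow(out))
    combined <- if (sp$combine == "ordinal_sum") rowSums(codes)
                else rowMeans(codes)
    br <- unique(stats::quantile(combined, probs = seq(0, 1, length.out = sp$bins + 1),
                                 names = FALSE))
    if (length(br) - 1 < sp$bins) {
      warning("merge_attributes: ties reduced ", sp$new_name, " to ",
              length(br) - 1, " bins")
    }
    binned <- cut(combined, breaks = br, include.lowest = TRUE,
                  labels = paste0("L", seq_len(length(br) - 1)))
    out <- out[, setdiff(names(out), sp$source_columns), drop = FALSE]
    out[[sp$new_name]] <- as.character(binned)
  }
  out
}

#' Weekly-average minutes from weekday/weekend pairs
#'
#' Combines paired weekday/weekend daily durations into a single weekly
#' average, weighting weekdays 5 and weekend days 2:
#' `(5 * weekday + 2 * weekend) / 7`.
#'
#' @param weekday_minutes,weekend_minutes non-negative daily minutes
#'   (vectorised).
#' @return weekly-average minutes.
#' @examples
#' combine_weekday_weekend(70, 0)  # 50
#' @export
combine_weekday_weekend <- function(weekday_minutes, weekend_minutes) {
  gbn_assert(all(is.finite(weekday_minutes)) && all(is.finite(weekend_minutes)) &&
               all(weekday_minutes >= 0) && all(weekend_minutes >= 0),
             "invalid_duration", "durations must be non-negative")
  (5 * weekday_minutes + 2 * weekend_minutes) / 7
}
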