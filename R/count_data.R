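#' Validate aggregate disease count data
#'
#' The observable the likelihood consumes: binomial numerators and
#' denominators by age, outcome measure, and optionally area and gender.
#'
#' @param data Data frame with columns \code{age}, \code{measure} (one of
#'   \code{"inc"}, \code{"prev"}, \code{"mort"}, \code{"rem"}), \code{num},
#'   \code{denom}, and optionally \code{area} and \code{gender}
#'   (\code{"female"}/\code{"male"}, or a single level).  Missing
#'   \code{area}/\code{gender} columns default to one group.
#' @return The validated data frame (columns completed and typed) with class
#'   \code{"count_data"}.
#' @export
count_data <- function(data) {
  data <- as.data.frame(data)
  need <- c("age", "measure", "num", "denom")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("count data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"area" %in% names(data)) data$area <- "all"
  if (!"gender" %in% names(data)) data$gender <- "all"
  data <- data[c("area", "gender", "age", "measure", "num", "denom")]
  data$area <- as.character(data$area)
  data$gender <- as.character(data$gender)
  bad <- which(!data$measure %in% c("inc", "prev", "mort", "rem"))
  if (length(bad))
    stop("invalid measure label(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": ",
         paste(unique(data$measure[bad]), collapse = ", "), call. = FALSE)
  for (col in c("age", "num", "denom")) {
    x <- data[[col]]
    bad <- which(!is.finite(x) | x < 0 | x != round(x))
    if (length(bad))
      stop("column '", col, "' must hold nonnegative integers; bad row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    data[[col]] <- as.integer(round(x))
  }
  bad <- which(data$num > data$denom)
  if (length(bad))
    stop("numerator exceeds denominator at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  key <- paste(data$area, data$gender, data$age, data$measure)
  if (anyDuplicated(key))
    stop("duplicate (area, gender, age, measure) record(s), e.g. ",
         key[anyDuplicated(key)], call. = FALSE)
  class(data) <- c("count_data", "data.frame")
  data
}

#' Read disease count data from CSV
#'
#' Accepts either the count schema (\code{area, gender, age, measure, num,
#' denom}; \code{area}/\code{gender} optional) or the estimate schema
#' (\code{agegroup_start, agegroup_end, measure, est, lower, upper} plus
#' optional \code{area}/\code{gender}), which is converted to counts via
#' \code{\link{counts_from_estimate}} and
#' \code{\link{disaggregate_age_groups}}.
#'
#' @param path CSV file.
#' @return A \code{\link{count_data}} data frame.
#' @export
read_disease_data <- function(path) {
  df <- utils::read.csv(path)
  if (all(c("est", "lower", "upper") %in% names(df)))
    return(estimates_to_counts(df))
  out <- tryCatch(count_data(df), error = function(e)
    stop("schema error reading ", path, ": ", conditionMessage(e),
         call. = FALSE))
  out
}

#' Write a results or data table to CSV
#' @param x Data frame.
#' @param path Output file.
#' @export
write_results <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

group_key <- function(area, gender) paste(area, gender, sep = ":")
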