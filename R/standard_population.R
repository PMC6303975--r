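#' The 2013 European Standard Population
#'
#' Returns the 2013 European Standard Population (ESP2013): 19 five-year
#' age groups (0-4, 5-9, ..., 90+) with weights summing to 100,000
#' persons. This is the default standard used throughout the package.
#'
#' @return A `standard_pop` object: a data frame with columns `age_group`
#'   (character) and `weight` (numeric).
#' @examples
#' sp <- esp2013()
#' sum(sp$weight)  # 100000
#' @export
esp2013 <- function() {
  standard_pop(
    age_group = c(
      "0-4", "5-9", "10-14", "15-19", "20-24", "25-29", "30-34",
      "35-39", "40-44", "45-49", "50-54", "55-59", "60-64", "65-69",
      "70-74", "75-79", "80-84", "85-89", "90+"
    ),
    weight = c(
      5000, 5500, 5500, 5500, 6000, 6000, 6500, 7000, 7000, 7000,
      7000, 6500, 6000, 5500, 5000, 4000, 2500, 1500, 1000
    )
  )
}

#' Construct a standard population
#'
#' A standard population is an ordered set of stratum (age-group) labels
#' and strictly positive weights: the person counts of a reference
#' population used to standardize stratum-specific rates.
#'
#' @param age_group character vector of unique stratum labels, in order.
#' @param weight numeric vector of strictly positive weights, one per group.
#' @return A `standard_pop` object (data frame with the two columns).
#' @seealso [esp2013()], [read_standard_pop()]
#' @export
standard_pop <- function(age_group, weight) {
  age_group <- as.character(age_group)
  weight <- as.numeric(weight)
  if (length(age_group) != length(weight)) {
    stop("`age_group` and `weight` must have the same length", call. = FALSE)
  }
  if (length(weight) < 1L) {
    stop("a standard population needs at least one group", call. = FALSE)
  }
  if (anyNA(age_group) || anyNA(weight)) {
    stop("`age_group` and `weight` must not contain missing values",
         call. = FALSE)
  }
  if (anyDuplicated(age_group)) {
    stop("age-group labels must be unique", call. = FALSE)
  }
  if (any(weight <= 0)) {
    stop("all standard-population weights must be strictly positive",
         call. = FALSE)
  }
  out <- data.frame(age_group = age_group, weight = weight,
                    stringsAsFactors = FALSE)
  class(out) <- c("standard_pop", "data.frame")
  out
}

#' Read a standard population from CSV
#'
#' The file must have a header row with columns `age_group` and `weight`.
#' Round-tripping the built-in ESP2013 through [write_standard_pop()] and
#' back reproduces it exactly.
#'
#' @param path path to a CSV file.
#' @return A `standard_pop` object.
#' @export
read_standard_pop <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "numeric"))
  need <- c("age_group", "weight")
  if (!all(need %in% names(df))) {
    stop("standard-population CSV must have columns 'age_group' and 'weight'",
         call. = FALSE)
  }
  standard_pop(df$age_group, df$weight)
}

#' Write a standard population to CSV
#'
#' @param sp a `standard_pop` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_standard_pop <- function(sp, path) {
  sp <- as_standard_pop(sp)
  utils::write.csv(as.data.frame(sp)[, c("age_group", "weight")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Accept either a standard_pop, a bare data frame with the right columns,
# or a (possibly named) numeric weight vector.
as_standard_pop <- function(sp) {
  if (inherits(sp, "standard_pop")) return(sp)
  if (is.data.frame(sp)) {
    if (!all(c("age_group", "weight") %in% names(sp))) {
      stop("data frame standard population needs columns 'age_group' and 'weight'",
           call. = FALSE)
    }
    return(standard_pop(sp$age_group, sp$weight))
  }
  if (is.numeric(sp)) {
    labs <- names(sp)
    if (is.null(labs)) labs <- paste0("group", seq_along(sp))
    return(standard_pop(labs, unname(sp)))
  }
  stop("cannot interpret `stdpop`: supply a standard_pop, a data frame, or a numeric weight vector",
       call. = FALSE)
}

#' @export
print.standard_pop <- function(x, ...) {
  cat(sprintf("Standard population: %d groups, total weight %s\n",
              nrow(x), format(sum(x$weight), big.mark = ",")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
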