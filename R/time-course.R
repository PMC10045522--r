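#' Germination time course for one replicate
#'
#' A germination test scores, once per day, how many new seeds germinated
#' in a Petri dish. A `germination_time_course` holds those daily counts
#' for one replicate together with the number of seeds sown, and is the
#' input to all germination indices.
#'
#' @param counts Integer vector, newly germinated seeds scored at each
#'   observation time (`n_i`). Non-negative; their sum cannot exceed
#'   `total_seeds`.
#' @param times Numeric vector of observation times in days (`t_i`),
#'   strictly increasing and positive. Defaults to daily scoring
#'   `1, 2, ..., length(counts)`; irregular monitoring is supported.
#' @param total_seeds Number of seeds sown in the replicate (default 20).
#' @param species,treatment,replicate Optional labels carried through to
#'   summaries and the pipeline feature table.
#'
#' @return An object of class `germination_time_course`: a list with
#'   elements `species`, `treatment`, `replicate`, `total_seeds`,
#'   `times`, `counts`.
#' @examples
#' tc <- germination_time_course(c(10, 5, 5))
#' germinability(tc)
#' mean_germination_time(tc)
#' @export
germination_time_course <- function(counts, times = seq_along(counts),
                                    total_seeds = 20L, species = NA_character_,
                                    treatment = NA_character_,
                                    replicate = NA_character_) {
  counts <- as.numeric(counts)
  times <- as.numeric(times)
  if (length(times) != length(counts))
    stop("`times` and `counts` must have the same length", call. = FALSE)
  if (length(counts) < 1L)
    stop("a time course needs at least one observation", call. = FALSE)
  if (anyNA(counts) || anyNA(times))
    stop("`times` and `counts` must not contain missing values", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be non-negative integers", call. = FALSE)
  if (any(times <= 0) || any(diff(times) <= 0))
    stop("`times` must be strictly increasing and positive", call. = FALSE)
  if (!is.numeric(total_seeds) || length(total_seeds) != 1L || total_seeds <= 0)
    stop("`total_seeds` must be a single positive count", call. = FALSE)
  if (sum(counts) > total_seeds)
    stop("sum of `counts` exceeds `total_seeds`", call. = FALSE)
  structure(
    list(species = as.character(species), treatment = as.character(treatment),
         replicate = as.character(replicate),
         total_seeds = as.numeric(total_seeds),
         times = times, counts = counts),
    class = "germination_time_course"
  )
}

#' @export
print.germination_time_course <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$species, x$treatment, x$replicate)),
               collapse = " / ")
  cat("Germination time course", if (nzchar(lab)) paste0("(", lab, ")"), "\n")
  cat(sprintf("  %d seeds sown, %d germinated over %d observation day(s)\n",
              as.integer(x$total_seeds), as.integer(sum(x$counts)),
              length(x$times)))
  print(stats::setNames(as.integer(x$counts), paste0("d", x$times)))
  invisible(x)
}

is_time_course <- function(x) inherits(x, "germination_time_course")

as_time_course <- function(x) {
  if (is_time_course(x)) return(x)
  stop("expected a `germination_time_course` object", call. = FALSE)
}
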