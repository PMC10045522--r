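#' The seven germination indices
#'
#' Classical indices summarising the speed, extent and uniformity of a
#' germination time course. With daily counts `n_i` at times `t_i`
#' (days), `N = sum(n_i)` germinated seeds and frequencies
#' `f_i = n_i / N`:
#'
#' * **G** (germinability, %): `100 * N / total_seeds`.
#' * **PV** (peak value, seeds/day): maximum over observation days of
#'   the cumulative germinated count divided by elapsed time.
#' * **MGT** (mean germination time, days): `sum(n_i * t_i) / N`, the
#'   count-weighted mean day of germination among germinated seeds.
#' * **MGR** (mean germination rate, 1/day): `1 / MGT`.
#' * **CVG** (coefficient of velocity, %/day): `100 * MGR`.
#' * **U** (uncertainty index, bits): Shannon entropy
#'   `-sum(f_i * log2(f_i))` of the germination-day distribution; low U
#'   means germination concentrated in few days.
#' * **Z** (synchrony index, dimensionless in `[0, 1]`): the fraction
#'   `sum(choose(n_i, 2)) / choose(N, 2)` of pairs of germinated seeds
#'   that germinated on the same day; 1 is perfect synchrony.
#'
#' Seeds that never germinate during the monitoring window enter G and
#' PV (through `total_seeds` and elapsed time) but are excluded from
#' MGT/MGR/CVG/U/Z, which are defined on germinated seeds only.
#'
#' Degenerate cases follow the conventions used when reporting
#' heat-shocked (non-germinating) seed lots: with `N == 0`, G, PV, U and
#' Z are 0 while MGT, MGR and CVG are not defined (`NA`, rendered
#' `"n.d."`); U is 0 whenever `N <= 1` or all germination falls on one
#' day, and Z is 0 whenever `N < 2`.
#'
#' @param tc A [germination_time_course()].
#' @param base Logarithm base for the uncertainty index (default 2,
#'   i.e. bits).
#' @return A single numeric value; `NA_real_` marks a not-defined index.
#' @examples
#' tc <- germination_time_course(c(10, 5, 5))
#' c(G = germinability(tc), PV = peak_value(tc),
#'   MGT = mean_germination_time(tc), U = uncertainty_index(tc),
#'   Z = synchrony_index(tc))
#' @name germination-indices
NULL

#' @rdname germination-indices
#' @export
germinability <- function(tc) {
  tc <- as_time_course(tc)
  100 * sum(tc$counts) / tc$total_seeds
}

#' @rdname germination-indices
#' @export
peak_value <- function(tc) {
  tc <- as_time_course(tc)
  if (sum(tc$counts) == 0) return(0)
  max(cumsum(tc$counts) / tc$times)
}

#' @rdname germination-indices
#' @export
mean_germination_time <- function(tc) {
  tc <- as_time_course(tc)
  n <- sum(tc$counts)
  if (n == 0) return(NA_real_)
  sum(tc$counts * tc$times) / n
}

#' @rdname germination-indices
#' @export
mean_germination_rate <- function(tc) {
  mgt <- mean_germination_time(tc)
  if (is.na(mgt)) NA_real_ else 1 / mgt
}

#' @rdname germination-indices
#' @export
coefficient_of_velocity <- function(tc) {
  mgr <- mean_germination_rate(tc)
  if (is.na(mgr)) NA_real_ else 100 * mgr
}

#' @rdname germination-indices
#' @export
uncertainty_index <- function(tc, base = 2) {
  tc <- as_time_course(tc)
  n <- tc$counts[tc$counts > 0]
  if (sum(n) <= 1) return(0)
  f <- n / sum(n)
  -sum(f * log(f, base = base))
}

#' @rdname germination-indices
#' @export
synchrony_index <- function(tc) {
  tc <- as_time_course(tc)
  n <- sum(tc$counts)
  if (n < 2) return(0)
  sum(choose(tc$counts, 2)) / choose(n, 2)
}

#' Compute all germination indices for one replicate
#'
#' @param tc A [germination_time_course()].
#' @param base Logarithm base for the uncertainty index (default 2).
#' @return A one-row data frame with the replicate labels and columns
#'   `G`, `PV`, `MGT`, `MGR`, `CVG`, `U`, `Z`. Not-defined indices
#'   (zero-germination replicates) are `NA`.
#' @examples
#' germination_indices(germination_time_course(c(10, 5, 5)))
#' @export
germination_indices <- function(tc, base = 2) {
  tc <- as_time_course(tc)
  data.frame(
    species = tc$species, treatment = tc$treatment, replicate = tc$replicate,
    G = germinability(tc), PV = peak_value(tc),
    MGT = mean_germination_time(tc), MGR = mean_germination_rate(tc),
    CVG = coefficient_of_velocity(tc), U = uncertainty_index(tc, base = base),
    Z = synchrony_index(tc),
    stringsAsFactors = FALSE
  )
}

index_columns <- c("G", "PV", "MGT", "MGR", "CVG", "U", "Z")

#' Summarise germination indices across replicates of one treatment
#'
#' Indices are computed per replicate and then averaged -- counts are
#' never pooled across dishes. This is why, in published summary
#' tables, the mean CVG of a treatment is generally not exactly 100
#' times the reciprocal of the mean MGT even though the identity holds
#' exactly within every replicate. A replicate with a not-defined index
#' (no germination) propagates to a not-defined summary, rendered
#' `"n.d."` by [format_treatment_summary()].
#'
#' @param indices Data frame of per-replicate indices from
#'   [germination_indices()] (rows = replicates of a single treatment).
#' @param control Optional data frame of control-replicate indices; when
#'   given, a two-sided equal-variance Student t-test per index at
#'   `alpha` sets the significance flag.
#' @param alpha Significance level for the t-tests (default 0.05).
#' @param dispersion `"sd"` (sample standard deviation, default) or
#'   `"sem"` (standard error of the mean).
#' @return A data frame with one row per index: `index`, `mean`,
#'   `dispersion`, `n`, and (when `control` is given) `p_value` and
#'   `sig_vs_control`.
#' @examples
#' reps <- lapply(list(c(8, 4, 2), c(7, 5, 2), c(9, 4, 1)), function(n)
#'   germination_indices(germination_time_course(n, treatment = "CTRL")))
#' summarize_treatment(do.call(rbind, reps))
#' @export
summarize_treatment <- function(indices, control = NULL, alpha = 0.05,
                                dispersion = c("sd", "sem")) {
  dispersion <- match.arg(dispersion)
  if (!is.data.frame(indices) || !all(index_columns %in% names(indices)))
    stop("`indices` must be a data frame of per-replicate germination indices",
         call. = FALSE)
  tr <- unique(stats::na.omit(indices$treatment))
  if (length(tr) > 1)
    stop("`indices` mixes treatments: ", paste(tr, collapse = ", "),
         call. = FALSE)
  n_rep <- nrow(indices)
  if (n_rep < 1) stop("need at least one replicate", call. = FALSE)

  disp_fun <- function(x) {
    s <- stats::sd(x)
    if (dispersion == "sem") s / sqrt(length(x)) else s
  }
  out <- do.call(rbind, lapply(index_columns, function(ix) {
    x <- indices[[ix]]
    if (anyNA(x)) {
      data.frame(index = ix, mean = NA_real_, dispersion = NA_real_, n = n_rep,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(index = ix, mean = mean(x),
                 dispersion = if (n_rep > 1) disp_fun(x) else NA_real_,
                 n = n_rep, stringsAsFactors = FALSE)
    }
  }))
  if (!is.null(control)) {
    if (!is.data.frame(control) || !all(index_columns %in% names(control)))
      stop("`control` must be a data frame of per-replicate indices",
           call. = FALSE)
    pv <- vapply(index_columns, function(ix) {
      x <- indices[[ix]]; y <- control[[ix]]
      if (anyNA(x) || anyNA(y) || length(x) < 2 || length(y) < 2)
        return(NA_real_)
      safe_t_test(x, y)
    }, numeric(1))
    out$p_value <- pv
    out$sig_vs_control <- !is.na(pv) & pv < alpha
  }
  attr(out, "treatment") <- if (length(tr)) tr else NA_character_
  out
}

#' Format a treatment summary the way germination tables print it
#'
#' Values are shown as `mean ± dispersion` rounded to two decimals,
#' not-defined indices as `"n.d."`, and significant differences versus
#' the control with an asterisk.
#'
#' @param summary A data frame from [summarize_treatment()].
#' @param digits Decimal places (default 2).
#' @return A character vector named by index.
#' @export
format_treatment_summary <- function(summary, digits = 2) {
  fmt <- vapply(seq_len(nrow(summary)), function(i) {
    m <- summary$mean[i]
    if (is.na(m)) return("n.d.")
    s <- summary$dispersion[i]
    txt <- paste0(round(m, digits), " ± ",
                  if (is.na(s)) "NA" else round(s, digits))
    if (!is.null(summary$sig_vs_control) && isTRUE(summary$sig_vs_control[i]))
      txt <- paste(txt, "*")
    txt
  }, character(1))
  stats::setNames(fmt, summary$index)
}
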