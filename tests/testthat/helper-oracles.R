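# Independent oracles, deliberately coded differently from the package.

# Synchrony by brute-force pair enumeration: expand every germinated
# seed to its day label and count same-day pairs among all pairs.
brute_synchrony <- function(counts, times = seq_along(counts)) {
  days <- rep(times, counts)
  n <- length(days)
  if (n < 2) return(0)
  same <- 0L; total <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1L
    if (days[i] == days[j]) same <- same + 1L
  }
  same / total
}

# Shannon entropy by direct summation over days.
brute_entropy <- function(counts, base = 2) {
  n_tot <- sum(counts)
  if (n_tot <= 1) return(0)
  acc <- 0
  for (n_i in counts) {
    if (n_i > 0) {
      f <- n_i / n_tot
      acc <- acc - f * log(f) / log(base)
    }
  }
  acc
}

random_time_course <- function(max_days = 6, total_seeds = 40) {
  k <- sample(2:max_days, 1)
  counts <- stats::rmultinom(1, sample(0:total_seeds, 1),
                             prob = runif(k))[, 1]
  germination_time_course(counts, total_seeds = total_seeds)
}

# Classical per-sample 2^-dCt with a single reference gene, coded from
# the textbook definition: dCt per biological sample (technical
# replicates averaged on the cycle scale), 2^-dCt averaged per group,
# treatment group expressed relative to the control group.
ddct_oracle <- function(ct_data, target, reference, control) {
  dct <- vapply(unique(ct_data$sample), function(s) {
    d <- ct_data[ct_data$sample == s, ]
    mean(d$ct[d$gene == target]) - mean(d$ct[d$gene == reference])
  }, numeric(1))
  trt_of <- vapply(unique(ct_data$sample), function(s)
    ct_data$treatment[ct_data$sample == s][1], character(1))
  ctrl_mean <- mean(2^-dct[trt_of == control])
  vapply(setdiff(unique(ct_data$treatment), control), function(tr)
    mean(2^-dct[trt_of == tr]) / ctrl_mean, numeric(1))
}

# Tukey-Kramer adjusted p for one pair, straight from the studentized
# range distribution with the unequal-n correction.
tukey_kramer_p <- function(mi, mj, ni, nj, mse, df, k) {
  se <- sqrt(mse / 2 * (1 / ni + 1 / nj))
  stats::ptukey(abs(mi - mj) / se, nmeans = k, df = df, lower.tail = FALSE)
}

zero_course <- function(days = 3, total_seeds = 20, treatment = "HS",
                        replicate = NA) {
  germination_time_course(rep(0L, days), total_seeds = total_seeds,
                          treatment = treatment,
                          replicate = as.character(replicate))
}
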