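# Equal-variance two-sided t-test p-value that tolerates zero-variance
# groups: identical constant data -> p = 1, constant but different -> p = 0.
safe_t_test <- function(x, y) {
  if (stats::var(c(x, y)) == 0) return(1)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    return(if (mean(x) == mean(y)) 1 else 0)
  stats::t.test(x, y, var.equal = TRUE)$p.value
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
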