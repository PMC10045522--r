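#' Student t-tests of every group against a control
#'
#' Two-sided, equal-variance Student t-tests of each treatment group
#' against the control, flagging groups with `p < alpha`.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`.
#' @param control Label of the control group.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with one row per non-control group: `group`,
#'   `mean`, `p_value`, `significant`.
#' @examples
#' t_test_vs_control(c(2.1, 2.2, 2.3, 1.1, 1.2, 1.3),
#'                   rep(c("CTRL", "HP"), each = 3), control = "CTRL")
#' @export
t_test_vs_control <- function(values, groups, control, alpha = 0.05) {
  groups <- as.character(groups)
  if (length(values) != length(groups))
    stop("`values` and `groups` must have the same length", call. = FALSE)
  if (!control %in% groups)
    stop("control group `", control, "` not present", call. = FALSE)
  ctrl <- values[groups == control]
  others <- setdiff(unique(groups), control)
  sizes <- table(groups)
  if (any(sizes[c(control, others)] < 2))
    stop("every tested group needs at least 2 observations", call. = FALSE)
  do.call(rbind, lapply(others, function(g) {
    x <- values[groups == g]
    p <- safe_t_test(x, ctrl)
    data.frame(group = g, mean = mean(x), p_value = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  }))
}

#' Two-way ANOVA with Tukey-Kramer comparisons and letter display
#'
#' Fits a fixed-effects ANOVA (`stats::aov`) with one or two crossed
#' factors -- the interaction is included when every factor cell has at
#' least two replicates, otherwise the model is additive -- and runs
#' Tukey-Kramer pairwise comparisons on the first factor's means.
#' `stats::TukeyHSD` supplies the studentized-range p-values with the
#' Kramer unequal-n correction; the compact letter display is derived
#' from the resulting significance matrix with a deterministic
#' insert-and-absorb procedure (groups ordered by descending mean, ties
#' broken by label), so two groups share a letter if and only if their
#' comparison is non-significant at `alpha`.
#'
#' @param data Data frame holding the response and factor columns.
#' @param response Name of the numeric response column.
#' @param factors Character vector of one or two factor column names;
#'   letters are computed for the first.
#' @param alpha Familywise significance level (default 0.05).
#' @return A list of class `anova_cld` with elements `anova_table`,
#'   `comparisons` (pairwise differences, confidence bounds, adjusted
#'   p-values), `letters` (data frame `group`, `mean`, `letters`),
#'   `model`, and `alpha`.
#' @examples
#' d <- data.frame(y = c(rnorm(6), rnorm(6, 5)),
#'                 trt = rep(c("A", "B"), each = 6),
#'                 batch = rep(c("b1", "b2"), 6))
#' anova_tukey_kramer(d, "y", c("trt", "batch"))$letters
#' @export
anova_tukey_kramer <- function(data, response, factors, alpha = 0.05) {
  if (!is.data.frame(data) || !response %in% names(data) ||
      !all(factors %in% names(data)))
    stop("`response` and `factors` must be columns of `data`", call. = FALSE)
  if (!length(factors) %in% 1:2)
    stop("`factors` must name one or two columns", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)", call. = FALSE)
  d <- data
  for (f in factors) {
    d[[f]] <- factor(d[[f]])
    if (nlevels(d[[f]]) < 2)
      stop("factor `", f, "` needs at least 2 levels", call. = FALSE)
  }
  y <- d[[response]]
  if (!is.numeric(y) || anyNA(y))
    stop("response must be numeric without missing values", call. = FALSE)

  if (length(factors) == 2) {
    cells <- table(d[[factors[1]]], d[[factors[2]]])
    if (any(cells == 0))
      stop("degenerate design: empty ", factors[1], " x ", factors[2],
           " cell(s); the two-way model is inestimable", call. = FALSE)
    with_interaction <- all(cells >= 2)
    rhs <- paste(factors, collapse = if (with_interaction) " * " else " + ")
  } else {
    rhs <- factors
  }
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::aov(fml, data = d)
  if (stats::df.residual(fit) < 1)
    stop("degenerate design: no residual degrees of freedom", call. = FALSE)

  tuk <- stats::TukeyHSD(fit, which = factors[1], conf.level = 1 - alpha)
  cmp <- as.data.frame(tuk[[factors[1]]])
  pair <- strsplit(rownames(cmp), "-", fixed = TRUE)
  comparisons <- data.frame(
    group1 = vapply(pair, `[`, "", 1), group2 = vapply(pair, `[`, "", 2),
    diff = cmp$diff, lwr = cmp$lwr, upr = cmp$upr, p_adj = cmp$`p adj`,
    significant = cmp$`p adj` < alpha, stringsAsFactors = FALSE)

  means <- tapply(y, d[[factors[1]]], mean)
  letters <- compact_letters(comparisons, means, alpha = alpha)

  structure(list(
    anova_table = as.data.frame(summary(fit)[[1]]),
    comparisons = comparisons, letters = letters,
    model = fit, alpha = alpha, factor = factors[1]
  ), class = "anova_cld")
}

#' @export
print.anova_cld <- function(x, ...) {
  cat("Two-way ANOVA with Tukey-Kramer comparisons on `", x$factor,
      "` (alpha = ", x$alpha, ")\n\n", sep = "")
  print(round(x$anova_table, 4))
  cat("\nCompact letter display:\n")
  print(x$letters, row.names = FALSE)
  invisible(x)
}

# Piepho-style insert-and-absorb compact letter display from a pairwise
# significance table. Deterministic: groups sorted by descending mean,
# ties by label; letters assigned in column order.
compact_letters <- function(comparisons, means, alpha = 0.05) {
  ord <- order(-means, names(means))
  grp <- names(means)[ord]
  cols <- list(stats::setNames(rep(TRUE, length(grp)), grp))
  sig <- comparisons[comparisons$significant, , drop = FALSE]
  if (nrow(sig)) {
    for (k in seq_len(nrow(sig))) {
      a <- sig$group1[k]; b <- sig$group2[k]
      for (j in seq_along(cols)) {
        if (isTRUE(cols[[j]][a]) && isTRUE(cols[[j]][b])) {
          dup <- cols[[j]]
          cols[[j]][a] <- FALSE
          dup[b] <- FALSE
          # absorb: keep the duplicate only if not a subset of another column
          keep <- !any(vapply(seq_along(cols), function(m) {
            m != j && all(cols[[m]][dup])
          }, logical(1)))
          if (keep) cols[[length(cols) + 1L]] <- dup
          # the shrunk original may itself have become a subset
        }
      }
      # absorb pass: drop columns that are subsets of another column
      drop <- rep(FALSE, length(cols))
      for (m in seq_along(cols)) {
        for (m2 in seq_along(cols)) {
          if (m != m2 && !drop[m2] &&
              all(cols[[m2]][cols[[m]]]) && sum(cols[[m]]) < sum(cols[[m2]])) {
            drop[m] <- TRUE
            break
          }
        }
      }
      cols <- cols[!drop]
    }
  }
  # order letter columns by first appearance down the sorted group list
  first <- vapply(cols, function(cl) min(match(names(cl)[cl], grp)), numeric(1))
  cols <- cols[order(first)]
  lab <- vapply(grp, function(g) {
    paste(letters[which(vapply(cols, function(cl) isTRUE(cl[g]), logical(1)))],
          collapse = "")
  }, character(1))
  data.frame(group = grp, mean = unname(means[grp]), letters = unname(lab),
             stringsAsFactors = FALSE)
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise-complete Pearson correlations between feature columns, with
#' two-sided p-values from the t-transform `t = r * sqrt((n - 2) /
#' (1 - r^2))` on `n - 2` degrees of freedom. P-values are reported raw
#' by default; set `adjust = "BH"` for Benjamini-Hochberg adjustment of
#' the upper triangle.
#'
#' @param data Data frame of observations.
#' @param columns Character vector of numeric feature columns (default:
#'   all numeric columns).
#' @param adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return List of class `pearson_matrix` with symmetric matrices `r`,
#'   `p` and `n` (pairwise complete sample sizes). Zero-variance
#'   columns yield `NA` correlations with a warning.
#' @examples
#' pearson_matrix(data.frame(x = 1:10, y = (1:10)^1.5, z = rnorm(10)))
#' @export
pearson_matrix <- function(data, columns = NULL, adjust = "none") {
  if (is.null(columns))
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  x <- as.matrix(data[columns])
  if (ncol(x) < 2) stop("need at least 2 feature columns", call. = FALSE)
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("zero-variance column(s): ",
            paste(columns[which(sds == 0)], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  ok <- !is.na(x)
  n <- crossprod(ok)
  if (any(n < 3 & row(n) != col(n)))
    warning("some column pairs have fewer than 3 complete observations",
            call. = FALSE)
  tstat <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = pmax(n - 2, 1))
  p[r == 1 & row(n) != col(n)] <- 0  # exact collinearity
  diag(p) <- NA_real_
  if (adjust != "none") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  structure(list(r = r, p = p, n = n), class = "pearson_matrix")
}

#' @export
print.pearson_matrix <- function(x, digits = 3, ...) {
  cat("Pearson correlation matrix (", nrow(x$r), " features)\n", sep = "")
  print(round(x$r, digits))
  invisible(x)
}

#' Standardized principal component analysis of the feature table
#'
#' Z-score standardization per column followed by singular-value
#' decomposition (`stats::prcomp` on the correlation scale), the usual
#' choice when features live on incommensurate units (percent, days,
#' uM, RFU). Constant columns are dropped with a warning before
#' standardization; rows with missing cells are dropped (listwise).
#' Each component's sign is fixed so that its largest-magnitude loading
#' is positive, making scores reproducible across platforms.
#'
#' @param data Data frame of replicate-level observations.
#' @param columns Character vector of numeric feature columns (default:
#'   all numeric columns).
#' @return List of class `seed_pca` with `scores`, `loadings`,
#'   `var_explained` (fractions summing to 1), `sdev`, and the `groups`
#'   column (`treatment`, if present in `data`) for plotting.
#' @examples
#' d <- data.frame(a = rnorm(9), b = rnorm(9))
#' pca_features(d)$var_explained
#' @export
pca_features <- function(data, columns = NULL) {
  if (is.null(columns))
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(columns) < 2) stop("need at least 2 feature columns", call. = FALSE)
  x <- as.matrix(data[columns])
  complete <- stats::complete.cases(x)
  if (!all(complete)) {
    warning(sum(!complete), " row(s) with missing cells dropped",
            call. = FALSE)
    x <- x[complete, , drop = FALSE]
  }
  if (nrow(x) < 3) stop("need at least 3 complete rows", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant column(s) dropped: ",
            paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) < 2) stop("fewer than 2 variable columns remain", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = pc$x, loadings = pc$rotation, sdev = pc$sdev,
    var_explained = ve,
    groups = if ("treatment" %in% names(data))
      data$treatment[complete] else NULL
  ), class = "seed_pca")
}

#' @export
print.seed_pca <- function(x, ...) {
  cat("Standardized PCA:", ncol(x$loadings), "components over",
      nrow(x$scores), "observations\n")
  ve <- round(100 * x$var_explained, 1)
  cat("  variance explained (%):", paste(ve, collapse = ", "), "\n")
  invisible(x)
}

#' @param x A `seed_pca` object.
#' @param type `"scores"` for the score plot, `"biplot"` to overlay
#'   loading arrows.
#' @param ... Passed to [plot()].
#' @rdname pca_features
#' @export
plot.seed_pca <- function(x, type = c("scores", "biplot"), ...) {
  type <- match.arg(type)
  s <- x$scores
  grp <- x$groups %||% rep("obs", nrow(s))
  cols <- as.integer(factor(grp))
  ve <- round(100 * x$var_explained[1:2], 1)
  plot(s[, 1], s[, 2], col = cols, pch = 19,
       xlab = paste0("PC1 (", ve[1], "%)"),
       ylab = paste0("PC2 (", ve[2], "%)"), ...)
  if (type == "biplot") {
    sc <- max(abs(s[, 1:2])) / max(abs(x$loadings[, 1:2]))
    graphics::arrows(0, 0, x$loadings[, 1] * sc * 0.8,
                     x$loadings[, 2] * sc * 0.8, length = 0.08, col = "grey40")
    graphics::text(x$loadings[, 1] * sc * 0.88, x$loadings[, 2] * sc * 0.88,
                   rownames(x$loadings), cex = 0.8)
  }
  if (!is.null(x$groups))
    graphics::legend("topright", legend = levels(factor(grp)),
                     col = seq_along(levels(factor(grp))), pch = 19, cex = 0.8)
  invisible(x)
}
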