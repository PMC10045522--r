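read_table_checked <- function(x, required, what) {
  d <- if (is.data.frame(x)) x else {
    if (!file.exists(x)) stop(what, " file not found: ", x, call. = FALSE)
    utils::read.csv(x, stringsAsFactors = FALSE)
  }
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("malformed ", what, " table: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  d
}

violation <- function(table, row, problem) {
  data.frame(table = table, row = row, problem = problem,
             stringsAsFactors = FALSE)
}

#' Read and validate a germination-count table
#'
#' Long format, one row per replicate x day: columns `species`,
#' `treatment`, `replicate`, `day`, `new_germinated`, `total_seeds`.
#' Row-level violations (non-numeric or negative counts, duplicate
#' replicate-days, counts exceeding seeds sown) abort with a report
#' listing every offending row.
#'
#' @param x Path to a CSV file, or an equivalent data frame.
#' @return A named list of [germination_time_course()] objects, one per
#'   species x treatment x replicate.
#' @export
read_germination_counts <- function(x) {
  req <- c("species", "treatment", "replicate", "day", "new_germinated",
           "total_seeds")
  d <- read_table_checked(x, req, "germination-count")
  v <- list()
  num_bad <- !is.finite(suppressWarnings(as.numeric(d$new_germinated))) |
    !is.finite(suppressWarnings(as.numeric(d$day)))
  if (any(num_bad))
    v[[length(v) + 1L]] <- violation("counts", which(num_bad),
                                     "non-numeric day or count")
  d$new_germinated <- suppressWarnings(as.numeric(d$new_germinated))
  d$day <- suppressWarnings(as.numeric(d$day))
  neg <- !is.na(d$new_germinated) & d$new_germinated < 0
  if (any(neg))
    v[[length(v) + 1L]] <- violation("counts", which(neg), "negative count")
  key <- interaction(d$species, d$treatment, d$replicate, d$day, drop = TRUE)
  dup <- duplicated(key)
  if (any(dup))
    v[[length(v) + 1L]] <- violation("counts", which(dup),
                                     "duplicate replicate-day row")
  if (length(v)) {
    rep <- do.call(rbind, v)
    stop(nrow(rep), " validation error(s) in germination counts:\n",
         paste(utils::capture.output(print(rep, row.names = FALSE)),
               collapse = "\n"), call. = FALSE)
  }
  grp <- interaction(d$species, d$treatment, d$replicate, drop = TRUE)
  out <- lapply(split(d, grp), function(g) {
    g <- g[order(g$day), , drop = FALSE]
    germination_time_course(g$new_germinated, times = g$day,
                            total_seeds = g$total_seeds[1],
                            species = g$species[1], treatment = g$treatment[1],
                            replicate = as.character(g$replicate[1]))
  })
  out
}

#' Read and validate a plate-reader table
#'
#' Columns `sample`, `treatment`, `assay` (`"FOX1"` or `"DCF"`),
#' `value`, `is_standard`, `standard_conc_uM`.
#'
#' @param x Path to a CSV file, or an equivalent data frame.
#' @return The validated data frame.
#' @export
read_assay_readings <- function(x) {
  req <- c("sample", "treatment", "assay", "value", "is_standard",
           "standard_conc_uM")
  d <- read_table_checked(x, req, "assay-reading")
  d$is_standard <- as.logical(d$is_standard)
  if (!all(d$assay %in% c("FOX1", "DCF")))
    stop("unknown assay label(s): ",
         paste(setdiff(unique(d$assay), c("FOX1", "DCF")), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(d$value)))
    stop(sum(!is.finite(d$value)), " non-finite assay value(s)", call. = FALSE)
  d
}

#' Read and validate a qPCR Ct table
#'
#' Columns `sample`, `treatment`, `gene`, `tech_replicate`, `ct`.
#' Undetermined Ct values may be blank/NA (handled downstream); known
#' gene labels are checked when `genes` is supplied.
#'
#' @param x Path to a CSV file, or an equivalent data frame.
#' @param genes Optional character vector of admissible gene labels.
#' @return The validated data frame.
#' @export
read_ct_values <- function(x, genes = NULL) {
  req <- c("sample", "treatment", "gene", "tech_replicate", "ct")
  d <- read_table_checked(x, req, "qPCR Ct")
  d$ct <- suppressWarnings(as.numeric(d$ct))
  bad <- !is.na(d$ct) & d$ct <= 0
  if (any(bad))
    stop(sum(bad), " non-positive Ct value(s)", call. = FALSE)
  if (!is.null(genes) && !all(d$gene %in% genes))
    stop("unknown gene label(s): ",
         paste(setdiff(unique(d$gene), genes), collapse = ", "),
         call. = FALSE)
  d
}

# Cyclic pseudo-replicate assignment: per-seed assay samples carry no
# replicate label, so sorted sample ids within treatment x assay are
# dealt round-robin into n_rep groups and averaged per group.
assign_pseudo_replicates <- function(samples, n_rep) {
  idx <- order(samples)
  rep_id <- integer(length(samples))
  rep_id[idx] <- ((seq_along(samples) - 1L) %% n_rep) + 1L
  rep_id
}

#' Run the full seed-quality analysis pipeline
#'
#' Executes every stage in order -- germination indices and treatment
#' summaries, FOX-1 calibration and inverse prediction, DCFH-DA
#' baseline subtraction, X0-method relative expression (optional),
#' feature join, and the statistical layer (two-way ANOVA with
#' Tukey-Kramer letters on the ROS measurements, Pearson correlation
#' matrix, standardized PCA) -- and optionally writes every table plus
#' a machine-readable run manifest to `out_dir`. Re-running with
#' identical inputs and config reproduces the outputs byte for byte.
#'
#' @param counts Germination-count CSV path or data frame
#'   (see [read_germination_counts()]).
#' @param assays Assay-reading CSV path or data frame
#'   (see [read_assay_readings()]).
#' @param ct Optional qPCR Ct CSV path or data frame; when absent the
#'   expression stage is skipped with a message.
#' @param control Control treatment label (default `"CTRL"`).
#' @param reference_genes qPCR reference genes
#'   (default `c("CYP", "RP40S")`).
#' @param alpha Significance level throughout (default 0.05).
#' @param dispersion `"sd"` or `"sem"` for germination summaries.
#' @param efficiency qPCR amplification efficiency (scalar or named
#'   per-gene vector, default 1).
#' @param out_dir Optional output directory for the CSV reports and
#'   `manifest.json`.
#' @return A list of class `seedvigor_run` with elements
#'   `replicate_indices`, `summaries` (per treatment),
#'   `summary_table` (formatted analogue of a germination-parameter
#'   table), `calibration`, `fox`, `dcf`, `expression` (or `NULL`),
#'   `features`, `ros_anova`, `ros_letters` (per assay), `correlation`,
#'   `pca`, and `log` (character vector of decisions taken).
#' @examples
#' tpl <- study_template("soybean", seed = 42)
#' run <- run_pipeline(simulate_study(tpl)$counts,
#'                     simulate_study(tpl)$assays)
#' run$summary_table
#' @export
run_pipeline <- function(counts, assays, ct = NULL, control = "CTRL",
                         reference_genes = c("CYP", "RP40S"), alpha = 0.05,
                         dispersion = "sd", efficiency = 1, out_dir = NULL) {
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)", call. = FALSE)
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))

  ## --- germination stage ---
  tcs <- read_germination_counts(counts)
  idx <- do.call(rbind, lapply(tcs, germination_indices))
  rownames(idx) <- NULL
  treatments <- unique(idx$treatment)
  if (!control %in% treatments)
    stop("control treatment `", control, "` absent from counts", call. = FALSE)
  ctrl_idx <- idx[idx$treatment == control, , drop = FALSE]
  summaries <- stats::setNames(lapply(treatments, function(tr) {
    ind <- idx[idx$treatment == tr, , drop = FALSE]
    summarize_treatment(ind,
                        control = if (tr == control) NULL else ctrl_idx,
                        alpha = alpha, dispersion = dispersion)
  }), treatments)
  summary_table <- do.call(cbind, lapply(summaries, format_treatment_summary))

  ## --- ROS stage ---
  ad <- read_assay_readings(assays)
  std <- ad[ad$assay == "FOX1" & ad$is_standard, , drop = FALSE]
  if (nrow(std) < 3) stop("no usable FOX-1 calibration standards", call. = FALSE)
  std$a560 <- std$value
  calibration <- fit_calibration(std)
  note(sprintf("FOX-1 calibration: slope %.4f AU/uM, R^2 %.4f on %d standards",
               calibration$slope, calibration$r_squared, calibration$n_points))
  fox_samples <- ad[ad$assay == "FOX1" & !ad$is_standard, , drop = FALSE]
  fox <- cbind(fox_samples[c("sample", "treatment")],
               predict_concentration(calibration, fox_samples$value))
  if (any(fox$clipped))
    note(sum(fox$clipped), " FOX-1 prediction(s) clipped at 0 uM: ",
         paste(fox$sample[fox$clipped], collapse = ", "))
  dcf_all <- ad[ad$assay == "DCF", , drop = FALSE]
  blank_rows <- dcf_all[dcf_all$is_standard, , drop = FALSE]
  if (nrow(blank_rows) < 1) stop("no DCF blank reading found", call. = FALSE)
  blank <- mean(blank_rows$value)
  note(sprintf("DCF baseline from %d blank well(s): %.2f RFU",
               nrow(blank_rows), blank))
  dcf_samples <- dcf_all[!dcf_all$is_standard, , drop = FALSE]
  dcf_samples$rfu_raw <- dcf_samples$value
  dcf <- subtract_baseline(dcf_samples[c("sample", "treatment", "rfu_raw")],
                           blank)
  if (any(dcf$below_blank))
    note(sum(dcf$below_blank), " DCF reading(s) below blank: ",
         paste(dcf$sample[dcf$below_blank], collapse = ", "))

  ## --- expression stage (optional) ---
  expression <- NULL
  if (!is.null(ct) && !(is.character(ct) && !file.exists(ct))) {
    ctd <- read_ct_values(ct)
    expression <- relative_to_control(ctd, reference_genes = reference_genes,
                                      control = control,
                                      efficiency = efficiency, alpha = alpha)
  } else {
    note("qPCR input absent: expression stage skipped")
  }

  ## --- join: one row per treatment x replicate ---
  n_rep <- max(table(idx$treatment))
  ros_long <- rbind(
    data.frame(treatment = fox$treatment, assay = "FOX1", value = fox$rooh_uM,
               sample = fox$sample, stringsAsFactors = FALSE),
    data.frame(treatment = dcf$treatment, assay = "DCF", value = dcf$rfu_net,
               sample = dcf$sample, stringsAsFactors = FALSE))
  ros_long$replicate <- NA_integer_
  for (k in split(seq_len(nrow(ros_long)),
                  interaction(ros_long$treatment, ros_long$assay, drop = TRUE)))
    ros_long$replicate[k] <- assign_pseudo_replicates(ros_long$sample[k], n_rep)
  ros_wide <- stats::aggregate(value ~ treatment + replicate + assay,
                               data = ros_long, FUN = mean)
  features <- idx
  features$replicate <- as.character(features$replicate)
  for (a in c("FOX1", "DCF")) {
    sub <- ros_wide[ros_wide$assay == a, , drop = FALSE]
    col <- if (a == "FOX1") "FOX1_rooh_uM" else "DCF_rfu"
    m <- match(paste(features$treatment, features$replicate),
               paste(sub$treatment, sub$replicate))
    features[[col]] <- sub$value[m]
  }
  if (!is.null(expression)) {
    # per-sample control-relative expression mapped onto matching
    # treatment x biological-replicate rows (samples named <trt>_<rep>)
    ps <- attr(expression, "per_sample")
    ps$replicate <- sub("^.*_", "", ps$sample)
    for (g in unique(ps$gene)) {
      sub <- ps[ps$gene == g, , drop = FALSE]
      m <- match(paste(features$treatment, features$replicate),
                 paste(sub$treatment, sub$replicate))
      features[[paste0("expr_", g)]] <- sub$rel[m]
    }
  }

  ## --- statistical layer on the ROS measurements ---
  # z-score within assay so the two readouts share a scale, then the
  # generic two-factor interface: treatment x assay
  ros_long$z <- stats::ave(ros_long$value, ros_long$assay,
                           FUN = function(v) (v - mean(v)) / stats::sd(v))
  ros_anova <- anova_tukey_kramer(ros_long, "z", c("treatment", "assay"),
                                  alpha = alpha)
  ros_letters <- stats::setNames(lapply(c("FOX1", "DCF"), function(a) {
    anova_tukey_kramer(ros_long[ros_long$assay == a, , drop = FALSE],
                       "value", "treatment", alpha = alpha)$letters
  }), c("FOX1", "DCF"))

  feat_cols <- c(index_columns, "FOX1_rooh_uM", "DCF_rfu")
  usable <- feat_cols[vapply(feat_cols, function(cl)
    sum(stats::complete.cases(features[[cl]])) >= 3 &&
      stats::sd(features[[cl]], na.rm = TRUE) > 0, logical(1))]
  correlation <- pearson_matrix(features, usable)
  pca <- pca_features(features, usable)

  run <- structure(list(
    replicate_indices = idx, summaries = summaries,
    summary_table = summary_table, calibration = calibration,
    fox = fox, dcf = dcf, expression = expression, features = features,
    ros_anova = ros_anova, ros_letters = ros_letters,
    correlation = correlation, pca = pca, log = log,
    config = list(control = control, reference_genes = reference_genes,
                  alpha = alpha, dispersion = dispersion,
                  efficiency = efficiency)
  ), class = "seedvigor_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.seedvigor_run <- function(x, ...) {
  cat("seedvigor pipeline run\n")
  cat("  treatments:", paste(names(x$summaries), collapse = ", "), "\n")
  cat("\nGermination summary (mean ± SD; * = p <", x$config$alpha,
      "vs", x$config$control, "):\n")
  print(x$summary_table, quote = FALSE)
  cat(sprintf("\nFOX-1 calibration R^2 = %.4f; %d sample(s) quantified\n",
              x$calibration$r_squared, nrow(x$fox)))
  if (!is.null(x$expression))
    cat("Expression:", length(unique(x$expression$gene)), "gene(s) across",
        length(unique(x$expression$treatment)), "treatment(s)\n")
  cat("PC1/PC2 explained variance:",
      paste(round(100 * x$pca$var_explained[1:2], 1), collapse = "% / "),
      "%\n")
  invisible(x)
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                       row.names = FALSE)
  w(run$replicate_indices, "replicate_indices.csv")
  st <- data.frame(index = rownames(run$summary_table), run$summary_table,
                   check.names = FALSE)
  w(st, "treatment_summary.csv")
  w(data.frame(slope = run$calibration$slope,
               intercept = run$calibration$intercept,
               r_squared = run$calibration$r_squared,
               n_points = run$calibration$n_points), "calibration.csv")
  w(run$fox, "fox1_rooh.csv")
  w(run$dcf, "dcf_rfu.csv")
  if (!is.null(run$expression)) w(run$expression, "expression.csv")
  w(run$features, "features.csv")
  w(run$ros_anova$anova_table, "ros_anova.csv")
  w(run$ros_anova$comparisons, "ros_tukey.csv")
  w(do.call(rbind, lapply(names(run$ros_letters), function(a)
    cbind(assay = a, run$ros_letters[[a]]))), "ros_letters.csv")
  w(as.data.frame(run$correlation$r), "correlation_r.csv")
  w(as.data.frame(run$correlation$p), "correlation_p.csv")
  w(as.data.frame(run$pca$scores), "pca_scores.csv")
  w(as.data.frame(run$pca$loadings), "pca_loadings.csv")
  w(data.frame(component = seq_along(run$pca$var_explained),
               var_explained = run$pca$var_explained), "pca_variance.csv")
  manifest <- list(
    package = "seedvigor",
    version = as.character(utils::packageVersion("seedvigor")),
    config = run$config, log = run$log,
    outputs = sort(list.files(out_dir, pattern = "\\.csv$")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
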