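#' Convert a threshold cycle to a starting-quantity estimate (X0 method)
#'
#' qPCR threshold cycles (Ct) relate exponentially to the amount of
#' starting template: each cycle multiplies the template by
#' `1 + E`, where `E` is the amplification efficiency (1 = perfect
#' doubling). The X0 method linearises Ct values before any averaging
#' or normalisation by converting them to relative starting quantities
#'
#'   `X0 = (1 + E) ^ (-Ct)`
#'
#' up to an arbitrary threshold-fluorescence constant that cancels in
#' every relative quantity downstream.
#'
#' @param ct Numeric vector of threshold cycles (positive, finite).
#' @param efficiency Amplification efficiency in `(0, 1]` (default 1).
#' @return Numeric vector of starting quantities (arbitrary units),
#'   strictly decreasing in `ct`.
#' @examples
#' ct_to_x0(20) / ct_to_x0(21)  # one cycle earlier = twice the template
#' @export
ct_to_x0 <- function(ct, efficiency = 1) {
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      efficiency <= 0 || efficiency > 1)
    stop("`efficiency` must be in (0, 1]", call. = FALSE)
  if (!is.numeric(ct) || any(!is.finite(ct)) || any(ct < 0))
    stop("`ct` must be non-negative and finite", call. = FALSE)
  (1 + efficiency)^(-ct)
}

#' Normalise a target starting quantity against reference genes
#'
#' Divides a target gene's X0 by the geometric mean of the X0 values of
#' one or more reference genes measured in the same sample (the
#' standard multi-reference combination; with a single reference this
#' reduces to a plain ratio).
#'
#' @param target_x0 Positive numeric scalar or vector of target
#'   starting quantities.
#' @param ref_x0 Positive numeric vector of reference-gene starting
#'   quantities for the same sample.
#' @return `target_x0 / geometric mean(ref_x0)`.
#' @examples
#' normalize_expression(2, c(4, 1))  # geometric mean of refs is 2
#' @export
normalize_expression <- function(target_x0, ref_x0) {
  if (length(ref_x0) < 1)
    stop("need at least one reference gene", call. = FALSE)
  if (any(target_x0 <= 0) || any(ref_x0 <= 0) ||
      anyNA(target_x0) || anyNA(ref_x0))
    stop("starting quantities must be positive", call. = FALSE)
  target_x0 / geometric_mean(ref_x0)
}

#' Relative expression versus a control group
#'
#' Full X0-method workflow for a table of raw Ct values: technical
#' replicates are averaged (on the Ct scale by default), Ct values are
#' converted to starting quantities, each target is normalised by the
#' geometric mean of the reference genes within its sample, and each
#' gene x treatment mean is expressed relative to the control-group
#' mean (so the control is 1 by construction). A two-sided Student
#' t-test on the normalised per-sample values flags treatments that
#' differ from the control at `alpha`.
#'
#' Samples with a missing (undetermined) Ct for a gene are dropped for
#' that gene with a warning, never imputed.
#'
#' @param ct_data Data frame with columns `sample`, `treatment`,
#'   `gene`, `tech_replicate`, `ct`.
#' @param reference_genes Character vector of reference gene labels
#'   present in `ct_data` (e.g. `c("CYP", "RP40S")`).
#' @param control Control treatment label (default `"CTRL"`).
#' @param efficiency Named numeric vector of per-gene amplification
#'   efficiencies, or a single value for all genes (default 1).
#' @param tech_average `"ct"` (default) averages technical replicates
#'   on the cycle scale before conversion; `"x0"` converts first and
#'   averages starting quantities.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with columns `gene`, `treatment`,
#'   `rel_expression`, `sd`, `n`, `p_value`, `sig_vs_control`. The
#'   per-sample control-relative values behind the tests are attached
#'   as attribute `"per_sample"` (columns `sample`, `treatment`,
#'   `gene`, `rel`).
#' @examples
#' ct <- expand.grid(sample = paste0("s", 1:6), gene = c("CAT1", "CYP"),
#'                   tech_replicate = 1:2)
#' ct$treatment <- ifelse(ct$sample %in% paste0("s", 1:3), "CTRL", "HP4")
#' ct$ct <- ifelse(ct$gene == "CYP", 22,
#'                 ifelse(ct$treatment == "CTRL", 25, 24))
#' relative_to_control(ct, reference_genes = "CYP")
#' @export
relative_to_control <- function(ct_data, reference_genes,
                                control = "CTRL", efficiency = 1,
                                tech_average = c("ct", "x0"), alpha = 0.05) {
  tech_average <- match.arg(tech_average)
  need <- c("sample", "treatment", "gene", "ct")
  if (!is.data.frame(ct_data) || !all(need %in% names(ct_data)))
    stop("`ct_data` needs columns sample, treatment, gene, ct", call. = FALSE)
  if (!control %in% ct_data$treatment)
    stop("control group `", control, "` not found in `ct_data`",
         call. = FALSE)
  genes <- unique(as.character(ct_data$gene))
  if (!all(reference_genes %in% genes))
    stop("reference gene(s) missing from `ct_data`: ",
         paste(setdiff(reference_genes, genes), collapse = ", "),
         call. = FALSE)
  eff_of <- function(g) {
    if (length(efficiency) == 1L && is.null(names(efficiency)))
      return(efficiency)
    if (!g %in% names(efficiency))
      stop("no efficiency given for gene ", g, call. = FALSE)
    efficiency[[g]]
  }

  if (anyNA(ct_data$ct)) {
    bad <- is.na(ct_data$ct)
    warning(sum(bad), " undetermined Ct value(s) dropped", call. = FALSE)
    ct_data <- ct_data[!bad, , drop = FALSE]
  }

  # per sample x gene starting quantity
  key <- interaction(ct_data$sample, ct_data$gene, drop = TRUE)
  per_well <- split(ct_data, key)
  x0_tab <- do.call(rbind, lapply(per_well, function(d) {
    e <- eff_of(as.character(d$gene[1]))
    x0 <- if (tech_average == "ct") ct_to_x0(mean(d$ct), e)
          else mean(ct_to_x0(d$ct, e))
    data.frame(sample = as.character(d$sample[1]),
               treatment = as.character(d$treatment[1]),
               gene = as.character(d$gene[1]), x0 = x0,
               stringsAsFactors = FALSE)
  }))

  targets <- setdiff(genes, reference_genes)
  wide_refs <- split(x0_tab[x0_tab$gene %in% reference_genes, ],
                     x0_tab$sample[x0_tab$gene %in% reference_genes])
  ref_gm <- vapply(wide_refs, function(d) {
    if (!all(reference_genes %in% d$gene)) return(NA_real_)
    geometric_mean(d$x0[match(reference_genes, d$gene)])
  }, numeric(1))

  out <- list()
  per_sample <- list()
  for (g in targets) {
    dg <- x0_tab[x0_tab$gene == g, , drop = FALSE]
    dg$norm <- dg$x0 / ref_gm[dg$sample]
    if (anyNA(dg$norm)) {
      warning("sample(s) without complete reference measurements dropped for ",
              g, call. = FALSE)
      dg <- dg[!is.na(dg$norm), , drop = FALSE]
    }
    ctrl <- dg$norm[dg$treatment == control]
    if (length(ctrl) < 1)
      stop("no control samples left for gene ", g, call. = FALSE)
    ctrl_mean <- mean(ctrl)
    per_sample[[g]] <- data.frame(sample = dg$sample, treatment = dg$treatment,
                                  gene = g, rel = dg$norm / ctrl_mean,
                                  stringsAsFactors = FALSE)
    for (tr in unique(dg$treatment)) {
      v <- dg$norm[dg$treatment == tr]
      p <- if (tr == control || length(v) < 2 || length(ctrl) < 2) NA_real_
           else safe_t_test(v, ctrl)
      out[[length(out) + 1L]] <- data.frame(
        gene = g, treatment = tr,
        rel_expression = mean(v) / ctrl_mean,
        sd = if (length(v) > 1) stats::sd(v) / ctrl_mean else NA_real_,
        n = length(v), p_value = p,
        sig_vs_control = !is.na(p) & p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "per_sample") <- do.call(rbind, unname(per_sample))
  res
}
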