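# All simulator randomness flows through one seeded generator per
# scenario; the caller's .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Germination simulation scenario
#'
#' Describes one treatment group of a germination test: each sown seed
#' germinates independently with probability `p_germ`, and a
#' germinating seed's day is drawn from a discretized gamma
#' distribution with mean `mgt_true` days and standard deviation
#' `dispersion` (gamma chosen as a standard unimodal positive-support
#' family; any unimodal family would serve). Draws falling after the
#' monitoring window are censored -- exactly as in the real assay, such
#' seeds are simply never observed to germinate. `dispersion = 0`
#' degenerates to all germination on `round(mgt_true)`.
#'
#' @param p_germ Final germination probability in `[0, 1]`.
#' @param mgt_true True mean germination day, in `(0, monitoring_days]`.
#' @param dispersion Standard deviation (days) of the germination-day
#'   distribution; `>= 0`.
#' @param n_seeds Seeds sown per replicate (default 20).
#' @param n_replicates Petri dishes per treatment (default 3).
#' @param monitoring_days Length of the daily monitoring window
#'   (3 for soybean, 5 for wheat, 6 for tomato).
#' @param treatment,species Labels stamped on the output.
#' @param rng_seed Integer seed; identical scenarios reproduce output
#'   bit for bit.
#' @return A list of class `germination_scenario`.
#' @seealso [simulate_germination()], [expected_mgt()]
#' @export
germination_scenario <- function(p_germ, mgt_true, dispersion = 0.5,
                                 n_seeds = 20L, n_replicates = 3L,
                                 monitoring_days = 3L, treatment = "CTRL",
                                 species = "Glycine max", rng_seed = 1L) {
  if (p_germ < 0 || p_germ > 1) stop("`p_germ` must be in [0, 1]", call. = FALSE)
  if (p_germ > 0 && (mgt_true <= 0 || mgt_true > monitoring_days))
    stop("`mgt_true` must lie within (0, monitoring_days]", call. = FALSE)
  if (dispersion < 0) stop("`dispersion` must be >= 0", call. = FALSE)
  structure(list(p_germ = p_germ, mgt_true = mgt_true,
                 dispersion = dispersion, n_seeds = as.integer(n_seeds),
                 n_replicates = as.integer(n_replicates),
                 monitoring_days = as.integer(monitoring_days),
                 treatment = treatment, species = species,
                 rng_seed = as.integer(rng_seed)),
            class = "germination_scenario")
}

# day on the daily grid for continuous germination times; times below
# day 1 are scored at the first daily inspection
discretize_day <- function(x) pmax(round(x), 1)

draw_germination_day <- function(n, mgt, dispersion) {
  if (dispersion == 0) return(rep(discretize_day(mgt), n))
  shape <- (mgt / dispersion)^2
  rate <- mgt / dispersion^2
  discretize_day(stats::rgamma(n, shape = shape, rate = rate))
}

#' Simulate germination time courses for one scenario
#'
#' @param scenario A [germination_scenario()].
#' @return A list of `n_replicates` [germination_time_course()] objects.
#' @examples
#' sc <- germination_scenario(p_germ = 0.9, mgt_true = 1.4, rng_seed = 42)
#' sapply(simulate_germination(sc), germinability)
#' @export
simulate_germination <- function(scenario) {
  stopifnot(inherits(scenario, "germination_scenario"))
  s <- scenario
  with_seed(s$rng_seed, {
    lapply(seq_len(s$n_replicates), function(r) {
      n_germ <- stats::rbinom(1, s$n_seeds, s$p_germ)
      counts <- integer(s$monitoring_days)
      if (n_germ > 0) {
        days <- draw_germination_day(n_germ, s$mgt_true, s$dispersion)
        days <- days[days <= s$monitoring_days]  # censored past the window
        if (length(days))
          counts <- tabulate(days, nbins = s$monitoring_days)
      }
      germination_time_course(counts, total_seeds = s$n_seeds,
                              species = s$species, treatment = s$treatment,
                              replicate = as.character(r))
    })
  })
}

#' Censoring-adjusted true mean germination time of a scenario
#'
#' The analytic mean observation day implied by a scenario's
#' discretized gamma distribution, conditional on germination being
#' observed within the monitoring window. This is the quantity the
#' per-replicate MGT estimates converge to as replication grows (the
#' unconditional `mgt_true` is not, because late germination is
#' censored and continuous days are scored on a daily grid).
#'
#' @param scenario A [germination_scenario()].
#' @return Expected MGT in days.
#' @export
expected_mgt <- function(scenario) {
  s <- scenario
  d <- seq_len(s$monitoring_days)
  if (s$dispersion == 0) {
    day <- discretize_day(s$mgt_true)
    if (day > s$monitoring_days) return(NA_real_)
    return(day)
  }
  shape <- (s$mgt_true / s$dispersion)^2
  rate <- s$mgt_true / s$dispersion^2
  upper <- stats::pgamma(d + 0.5, shape, rate)
  lower <- c(0, stats::pgamma(d[-length(d)] + 0.5, shape, rate))
  p <- upper - lower  # day 1 absorbs all mass below 1.5
  sum(d * p) / sum(p)
}

#' ROS assay simulation scenario
#'
#' Per-treatment true means for the two ROS readouts, with lognormal
#' biological scatter of coefficient of variation `cv` around them:
#' `rooh_uM` feeds the FOX-1 branch (sample absorbance is generated
#' from the true concentration through the calibration truth plus
#' instrument noise) and `rfu` feeds the DCFH-DA branch (raw RFU is the
#' blank level plus the scattered net signal). Calibration standards at
#' 0, 1.25, 2.50 and 5 uM H2O2 are emitted alongside the samples.
#'
#' @param rooh_uM Named numeric vector of true peroxide concentrations
#'   per treatment (uM).
#' @param rfu Named numeric vector of true net DCF fluorescence per
#'   treatment (RFU); names must match `rooh_uM`.
#' @param cv Biological coefficient of variation (default 0.1).
#' @param slope,intercept,noise_sd Calibration truth: AU/uM, AU, and
#'   instrument noise SD in AU (defaults 0.1, 0.05, 0.005).
#' @param blank_rfu True dye-only fluorescence level (default 200 RFU).
#' @param n_per_treatment Seeds assayed per treatment (default 5, one
#'   seed per assay well).
#' @param standard_concs Standard concentrations (uM).
#' @param rng_seed Integer seed.
#' @return A list of class `assay_scenario`.
#' @export
assay_scenario <- function(rooh_uM, rfu, cv = 0.1, slope = 0.1,
                           intercept = 0.05, noise_sd = 0.005,
                           blank_rfu = 200, n_per_treatment = 5L,
                           standard_concs = c(0, 1.25, 2.5, 5),
                           rng_seed = 1L) {
  if (is.null(names(rooh_uM)) || is.null(names(rfu)) ||
      !identical(sort(names(rooh_uM)), sort(names(rfu))))
    stop("`rooh_uM` and `rfu` must be named by the same treatments",
         call. = FALSE)
  if (any(rooh_uM < 0) || any(rfu < 0) || cv < 0 || noise_sd < 0)
    stop("means, cv and noise_sd must be non-negative", call. = FALSE)
  structure(list(rooh_uM = rooh_uM, rfu = rfu, cv = cv, slope = slope,
                 intercept = intercept, noise_sd = noise_sd,
                 blank_rfu = blank_rfu,
                 n_per_treatment = as.integer(n_per_treatment),
                 standard_concs = standard_concs,
                 rng_seed = as.integer(rng_seed)),
            class = "assay_scenario")
}

#' Simulate plate-reader measurements for both ROS assays
#'
#' @param scenario An [assay_scenario()].
#' @return A data frame in the assay-input schema: columns `sample`,
#'   `treatment`, `assay` (`"FOX1"` or `"DCF"`), `value` (A560 in AU or
#'   raw RFU), `is_standard`, `standard_conc_uM`. Includes the FOX-1
#'   calibration standards and a dye-only DCF blank (sample
#'   `"DCF_blank"`).
#' @examples
#' sc <- assay_scenario(rooh_uM = c(CTRL = 2.5, HS = 4),
#'                      rfu = c(CTRL = 3500, HS = 5000), rng_seed = 7)
#' head(simulate_assays(sc))
#' @export
simulate_assays <- function(scenario) {
  stopifnot(inherits(scenario, "assay_scenario"))
  s <- scenario
  sdlog <- if (s$cv > 0) sqrt(log(1 + s$cv^2)) else 0
  scatter <- function(n, mean) {
    if (mean == 0) return(rep(0, n))
    if (sdlog == 0) return(rep(mean, n))
    mean * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  }
  with_seed(s$rng_seed, {
    std <- data.frame(
      sample = paste0("STD_", seq_along(s$standard_concs)),
      treatment = NA_character_, assay = "FOX1",
      value = s$intercept + s$slope * s$standard_concs +
        stats::rnorm(length(s$standard_concs), 0, s$noise_sd),
      is_standard = TRUE, standard_conc_uM = s$standard_concs,
      stringsAsFactors = FALSE)
    rows <- lapply(names(s$rooh_uM), function(tr) {
      n <- s$n_per_treatment
      rooh <- scatter(n, s$rooh_uM[[tr]])
      a560 <- s$intercept + s$slope * rooh + stats::rnorm(n, 0, s$noise_sd)
      rfu <- s$blank_rfu + scatter(n, s$rfu[[tr]])
      rbind(
        data.frame(sample = paste0(tr, "_fox_", seq_len(n)), treatment = tr,
                   assay = "FOX1", value = a560, is_standard = FALSE,
                   standard_conc_uM = NA_real_, stringsAsFactors = FALSE),
        data.frame(sample = paste0(tr, "_dcf_", seq_len(n)), treatment = tr,
                   assay = "DCF", value = rfu, is_standard = FALSE,
                   standard_conc_uM = NA_real_, stringsAsFactors = FALSE))
    })
    blank <- data.frame(sample = "DCF_blank", treatment = NA_character_,
                        assay = "DCF",
                        value = s$blank_rfu + stats::rnorm(1, 0, s$noise_sd),
                        is_standard = TRUE, standard_conc_uM = NA_real_,
                        stringsAsFactors = FALSE)
    out <- rbind(std, do.call(rbind, rows), blank)
    rownames(out) <- NULL
    out
  })
}

#' qPCR simulation scenario
#'
#' True per-gene fold changes by treatment drive the target threshold
#' cycles: a control sample amplifies gene `g` at its baseline Ct, and
#' a treatment sample with fold `f` amplifies `log(f) / log(1 + E)`
#' cycles earlier. Reference genes stay at their baselines up to a
#' per-sample stability jitter, and every well receives independent
#' technical noise.
#'
#' @param fold_changes Named list: one named numeric vector of per-gene
#'   fold changes per non-control treatment.
#' @param baseline_ct Named numeric vector of baseline cycles for every
#'   gene (targets and references). Unnamed scalar = common baseline.
#' @param reference_genes Character vector of reference gene labels
#'   (default `c("CYP", "RP40S")`).
#' @param ref_stability_sd Per-sample SD of reference-gene cycles
#'   (default 0.1).
#' @param tech_sd Technical replicate SD in cycles (default 0.15).
#' @param efficiency Amplification efficiency in `(0, 1]` (default 1).
#' @param n_biological Biological replicates per treatment (default 3).
#' @param n_tech Technical replicates per well (default 3).
#' @param control Control label (default `"CTRL"`).
#' @param rng_seed Integer seed.
#' @return A list of class `qpcr_scenario`.
#' @export
qpcr_scenario <- function(fold_changes, baseline_ct = 25,
                          reference_genes = c("CYP", "RP40S"),
                          ref_stability_sd = 0.1, tech_sd = 0.15,
                          efficiency = 1, n_biological = 3L, n_tech = 3L,
                          control = "CTRL", rng_seed = 1L) {
  if (!is.list(fold_changes) || is.null(names(fold_changes)))
    stop("`fold_changes` must be a named list (one vector per treatment)",
         call. = FALSE)
  if (any(unlist(fold_changes) <= 0))
    stop("fold changes must be positive", call. = FALSE)
  if (ref_stability_sd < 0 || tech_sd < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  genes <- unique(unlist(lapply(fold_changes, names)))
  if (is.null(genes) || any(!nzchar(genes)))
    stop("fold-change vectors must be named by gene", call. = FALSE)
  all_genes <- c(genes, reference_genes)
  if (length(baseline_ct) == 1L && is.null(names(baseline_ct)))
    baseline_ct <- stats::setNames(rep(baseline_ct, length(all_genes)),
                                   all_genes)
  if (!all(all_genes %in% names(baseline_ct)))
    stop("`baseline_ct` must cover every gene", call. = FALSE)
  structure(list(fold_changes = fold_changes, baseline_ct = baseline_ct,
                 reference_genes = reference_genes,
                 ref_stability_sd = ref_stability_sd, tech_sd = tech_sd,
                 efficiency = efficiency,
                 n_biological = as.integer(n_biological),
                 n_tech = as.integer(n_tech), control = control,
                 target_genes = genes, rng_seed = as.integer(rng_seed)),
            class = "qpcr_scenario")
}

#' Simulate a table of raw qPCR threshold cycles
#'
#' @param scenario A [qpcr_scenario()].
#' @return A data frame in the Ct-input schema: columns `sample`,
#'   `treatment`, `gene`, `tech_replicate`, `ct`.
#' @examples
#' sc <- qpcr_scenario(list(HP4 = c(CAT1 = 2)), tech_sd = 0, rng_seed = 3)
#' relative_to_control(simulate_ct(sc), reference_genes = c("CYP", "RP40S"))
#' @export
simulate_ct <- function(scenario) {
  stopifnot(inherits(scenario, "qpcr_scenario"))
  s <- scenario
  treatments <- c(s$control, names(s$fold_changes))
  with_seed(s$rng_seed, {
    rows <- list()
    for (tr in treatments) {
      for (b in seq_len(s$n_biological)) {
        smp <- paste0(tr, "_", b)
        jitter <- stats::rnorm(1, 0, s$ref_stability_sd)
        for (g in c(s$target_genes, s$reference_genes)) {
          base <- s$baseline_ct[[g]]
          ct_true <- if (g %in% s$reference_genes) {
            base + jitter
          } else {
            fold <- if (tr == s$control) 1 else s$fold_changes[[tr]][[g]] %||% 1
            base - log(fold) / log(1 + s$efficiency)
          }
          ct <- ct_true + stats::rnorm(s$n_tech, 0, s$tech_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = smp, treatment = tr, gene = g,
            tech_replicate = seq_len(s$n_tech), ct = ct,
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Study-like simulation template
#'
#' Bundles the three scenario types into a complete synthetic study of
#' hydroprimed (HP), heat-shocked (HS) and control (CTRL) seed lots:
#' 20 seeds x 3 replicates monitored daily (3 days for soybean, 5 for
#' wheat, 6 for tomato); HS germinates no seed; hydropriming speeds and
#' synchronises germination with an optimum at the intermediate
#' imbibition time; ROS group means are ordered HS > CTRL > HP for both
#' assays; and ROS-turnover genes are upregulated after imbibition and
#' after dry-back. Effect sizes are phenomenological defaults of
#' realistic magnitude, not measured values.
#'
#' @param species `"soybean"`, `"wheat"` or `"tomato"` (sets the
#'   monitoring window and imbibition durations).
#' @param seed Integer master seed; sub-scenarios derive distinct seeds
#'   from it.
#' @return A list of class `study_template` with elements
#'   `germination` (named list of [germination_scenario()]s), `assays`
#'   (an [assay_scenario()]) and `qpcr` (a [qpcr_scenario()]).
#' @seealso [simulate_study()]
#' @export
study_template <- function(species = c("soybean", "wheat", "tomato"),
                                seed = 1L) {
  species <- match.arg(species)
  cfg <- switch(species,
    soybean = list(days = 3L, hp = c("HP2", "HP4", "HP8"),
                   name = "Glycine max"),
    wheat = list(days = 5L, hp = c("HP2", "HP4", "HP6"),
                 name = "Triticum aestivum"),
    tomato = list(days = 6L, hp = c("HP2", "HP8", "HP24"),
                  name = "Solanum lycopersicum"))
  seed <- as.integer(seed)
  day_scale <- cfg$days / 3  # stretch soybean-shaped kinetics to the window
  germ_par <- list(
    CTRL = c(p = 0.70, mgt = 2.2, disp = 0.60),
    hp_slow = c(p = 0.85, mgt = 1.45, disp = 0.50),
    hp_best = c(p = 0.95, mgt = 1.25, disp = 0.35),
    hp_late = c(p = 0.90, mgt = 1.35, disp = 0.45),
    HS = c(p = 0, mgt = 1, disp = 0))
  trt_names <- c("CTRL", cfg$hp, "HS")
  germ_keys <- c("CTRL", "hp_slow", "hp_best", "hp_late", "HS")
  germination <- stats::setNames(lapply(seq_along(trt_names), function(i) {
    gp <- germ_par[[germ_keys[i]]]
    germination_scenario(
      p_germ = gp[["p"]], mgt_true = min(gp[["mgt"]] * day_scale, cfg$days),
      dispersion = gp[["disp"]] * day_scale, monitoring_days = cfg$days,
      treatment = trt_names[i], species = cfg$name,
      rng_seed = seed + 101L + i)
  }), trt_names)

  hp_rooh <- stats::setNames(c(1.2, 1.0, 1.1), cfg$hp)
  hp_rfu <- stats::setNames(c(1700, 1500, 1600), cfg$hp)
  assays <- assay_scenario(
    rooh_uM = c(CTRL = 2.5, hp_rooh, `HP-DB` = 1.6, HS = 4.2),
    rfu = c(CTRL = 3500, hp_rfu, `HP-DB` = 2200, HS = 5200),
    cv = 0.1, rng_seed = seed + 201L)

  qpcr <- qpcr_scenario(
    fold_changes = list(
      HP4 = c(MnSOD = 1.15, SOD1 = 2.2, CAT1 = 4.5, CAT5 = 3.8,
              APX2 = 2.6, RbohE2 = 1.6, RbohC2 = 1.9),
      HP4DB = c(MnSOD = 1.9, SOD1 = 2.0, CAT1 = 4.0, CAT5 = 3.4,
                APX2 = 1.05, RbohE2 = 1.5, RbohC2 = 1.8)),
    baseline_ct = c(MnSOD = 26, SOD1 = 25, CAT1 = 24, CAT5 = 24.5,
                    APX2 = 25.5, RbohE2 = 28, RbohC2 = 27.5,
                    CYP = 22, RP40S = 21),
    rng_seed = seed + 301L)

  structure(list(species = species, germination = germination,
                 assays = assays, qpcr = qpcr, seed = seed),
            class = "study_template")
}

#' Simulate a full study and (optionally) write its three input files
#'
#' Runs all scenarios of a [study_template()] and returns the
#' three tables the pipeline ingests; with `dir` given they are also
#' written as `germination_counts.csv`, `assay_readings.csv` and
#' `qpcr_ct.csv`.
#'
#' @param template A `study_template`.
#' @param dir Optional output directory.
#' @return Invisibly, a list with data frames `counts`, `assays`, `ct`.
#' @export
simulate_study <- function(template, dir = NULL) {
  stopifnot(inherits(template, "study_template"))
  counts <- do.call(rbind, lapply(template$germination, function(sc) {
    tcs <- simulate_germination(sc)
    do.call(rbind, lapply(tcs, function(tc) {
      data.frame(species = tc$species, treatment = tc$treatment,
                 replicate = tc$replicate, day = tc$times,
                 new_germinated = tc$counts, total_seeds = tc$total_seeds,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(counts) <- NULL
  assays <- simulate_assays(template$assays)
  ct <- simulate_ct(template$qpcr)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(counts, file.path(dir, "germination_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(assays, file.path(dir, "assay_readings.csv"),
                     row.names = FALSE)
    utils::write.csv(ct, file.path(dir, "qpcr_ct.csv"), row.names = FALSE)
  }
  invisible(list(counts = counts, assays = assays, ct = ct))
}
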