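# End-to-end orchestration: invert the measurement tables into per-
# microcosm pools, build the per-treatment growth decomposition, run the
# robust statistics, and write a reproducible result bundle.

CFE_COLS <- c("microcosm_id", "treatment", "timepoint_h", "doc_unfum",
              "doc_fum", "bq_unfum", "bq_fum", "dn_unfum")
GAS_COLS <- c("microcosm_id", "treatment", "timepoint_h", "t_start", "t_end",
              "co2_c", "delta13c")
STORAGE_COLS <- c("microcosm_id", "treatment", "timepoint_h", "compound",
                  "biomarker_class", "amount", "ap13c_derivative")
DNA_COLS <- c("microcosm_id", "treatment", "timepoint_h", "dna_mass",
              "o_total", "ap18o_measured")
DESIGN_COLS <- c("treatment", "glucose_c", "nutrients")

CONTROL_TREATMENT <- "C0"  # zero-C, no-nutrient background endmember group

check_schema <- function(df, cols, table) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    sg_stop(sprintf("table '%s' lacks required column(s): %s", table,
                    paste(missing_cols, collapse = ", ")), "sg_schema_error")
  }
  invisible(df)
}

design_table <- function(ms) {
  d <- unique(ms$ground_truth[c("glucose_c", "nutrients")])
  data.frame(treatment = treatment_label(d$glucose_c, d$nutrients),
             glucose_c = d$glucose_c, nutrients = d$nutrients,
             stringsAsFactors = FALSE)
}

#' Default pipeline constants
#'
#' The configurable physical constants of the analysis with their default
#' values: isotope reference ratios, the derivatization reagent delta13C,
#' the 18O natural abundance, the water-derived fraction of new-DNA oxygen,
#' and the mixing-fraction clamp tolerance. All are serialized into the run
#' log for provenance.
#'
#' @return Named list of constants.
#' @export
pipeline_constants <- function() {
  list(r13c_vpdb = iso_standards$carbon13$ratio,
       r18o_vsmow = iso_standards$oxygen18$ratio,
       reagent_delta13c = NATURAL_DELTA13C,
       ap18o_natural = AP18O_NATURAL_DEFAULT,
       f_water = F_WATER_DEFAULT,
       dna_o_fraction = DNA_O_FRACTION,
       phb_c_fraction = PHB_C_FRACTION,
       mixing_tol = 0.02)
}

#' Per-microcosm pool accounting
#'
#' Inverts the CFE, storage and gas tables into carbon pools and fluxes:
#' extractable MBC and its glucose-derived share (14C), PHB and TAG carbon
#' and their glucose-derived shares (13C after derivatization correction),
#' CO2 efflux rates and glucose-derived fractions. The unlabelled
#' background endmember for every 13C partition is the zero-C, no-nutrient
#' treatment measured on the same material at the same timepoint (for gas:
#' the same sampling interval).
#'
#' @param ms a `measurement_set` (from [generate_experiment()] or
#'   [read_measurement_set()]).
#' @param constants list from [pipeline_constants()].
#' @return List with data frames `pools` (one row per microcosm) and `co2`
#'   (one row per microcosm x interval).
#' @export
account_pools <- function(ms, constants = pipeline_constants()) {
  check_schema(ms$cfe, CFE_COLS, "cfe")
  check_schema(ms$storage, STORAGE_COLS, "storage")
  check_schema(ms$gas, GAS_COLS, "gas")
  design <- if (!is.null(ms$design)) ms$design else design_table(ms)
  check_schema(design, DESIGN_COLS, "design")
  tol <- constants$mixing_tol
  reagent_ap <- delta_to_atpercent(constants$reagent_delta13c)
  specs <- lapply(seq_len(nrow(design)), function(i) {
    treatment_spec(design$glucose_c[i], design$nutrients[i])
  })
  names(specs) <- design$treatment

  # ---- CFE pools
  cfe <- ms$cfe
  mbc <- cfe_biomass(cfe$doc_fum, cfe$doc_unfum)
  glucose_c <- design$glucose_c[match(cfe$treatment, design$treatment)]
  if (anyNA(glucose_c)) {
    sg_stop("cfe table contains treatments absent from the design",
            "sg_schema_error")
  }
  glucose_mbc <- rep(NA_real_, nrow(cfe))
  for (lab in design$treatment[design$glucose_c > 0]) {
    sel <- cfe$treatment == lab
    glucose_mbc[sel] <- glucose_derived_mbc_14c(
      cfe$bq_fum[sel], cfe$bq_unfum[sel], specific_activity(specs[[lab]]))
  }

  # ---- storage pools; background at% per timepoint x compound from C0
  sto <- ms$storage
  dv <- storage_derivatization(sto$compound)
  ap_analyte <- correct_derivatization(sto$ap13c_derivative, dv$n_analyte,
                                       dv$n_added, ap_added = reagent_ap)
  sto$pool_c <- ifelse(sto$compound == "PHB", phb_carbon(sto$amount),
                       sto$amount)
  ctrl <- sto$treatment == CONTROL_TREATMENT
  if (!any(ctrl)) {
    sg_stop("no zero-C, no-nutrient background rows in the storage table",
            "sg_missing_background")
  }
  bg_key <- paste(sto$timepoint_h, sto$compound)
  bg <- tapply(ap_analyte[ctrl], bg_key[ctrl], mean)
  sto$background_ap <- as.numeric(bg[bg_key])
  if (anyNA(sto$background_ap)) {
    sg_stop("missing background storage at% for some timepoint x compound",
            "sg_missing_background")
  }
  sto$glucose_c <- rep(NA_real_, nrow(sto))
  for (lab in design$treatment) {
    sel <- sto$treatment == lab
    if (design$glucose_c[match(lab, design$treatment)] > 0) {
      f <- mixing_fraction(ap_analyte[sel], specs[[lab]]$glucose_ap13c,
                           sto$background_ap[sel], tol = tol)
      sto$glucose_c[sel] <- sto$pool_c[sel] * f
    } else {
      sto$glucose_c[sel] <- 0
    }
  }
  key <- paste(sto$microcosm_id, sto$timepoint_h)
  is_phb <- sto$compound == "PHB"
  agg <- function(x, sel) {
    out <- tapply(x[sel], key[sel], sum)
    as.numeric(out[paste(cfe$microcosm_id, cfe$timepoint_h)])
  }
  pools <- data.frame(
    microcosm_id = cfe$microcosm_id, treatment = cfe$treatment,
    timepoint_h = cfe$timepoint_h,
    mbc = mbc, glucose_mbc = glucose_mbc,
    doc = cfe$doc_unfum, dn = cfe$dn_unfum,
    phb_c = agg(sto$pool_c, is_phb),
    glucose_phb_c = agg(sto$glucose_c, is_phb),
    tag_c = agg(sto$pool_c, !is_phb),
    glucose_tag_c = agg(sto$glucose_c, !is_phb),
    stringsAsFactors = FALSE)
  pools$storage_c <- pools$phb_c + pools$tag_c
  pools$glucose_storage_c <- pools$glucose_phb_c + pools$glucose_tag_c

  # ---- CO2 efflux and partition; background per interval from C0
  gas <- ms$gas
  rt <- co2_rate(gas$t_start, gas$t_end, gas$co2_c)
  gas$t_mid <- rt$t_mid
  gas$rate <- rt$rate
  ap_co2 <- delta_to_atpercent(gas$delta13c)
  gctrl <- gas$treatment == CONTROL_TREATMENT
  gkey <- paste(gas$timepoint_h, gas$t_start, gas$t_end)
  gbg <- tapply(ap_co2[gctrl], gkey[gctrl], mean)
  gas$background_ap <- as.numeric(gbg[gkey])
  if (anyNA(gas$background_ap)) {
    sg_stop("missing background CO2 at% for some sampling interval",
            "sg_missing_background")
  }
  gas$glucose_frac <- NA_real_
  for (lab in design$treatment) {
    sel <- gas$treatment == lab
    if (design$glucose_c[match(lab, design$treatment)] > 0) {
      gas$glucose_frac[sel] <- co2_glucose_fraction(
        gas$delta13c[sel], specs[[lab]], gas$background_ap[sel], tol = tol)
    } else {
      gas$glucose_frac[sel] <- 0
    }
  }
  gas$glucose_co2_c <- gas$co2_c * gas$glucose_frac
  co2 <- gas[c("microcosm_id", "treatment", "timepoint_h", "t_start",
               "t_end", "t_mid", "rate", "glucose_frac", "glucose_co2_c")]
  list(pools = pools, co2 = co2)
}

#' Per-treatment growth decomposition
#'
#' Builds the machine-readable growth summary: DNA-based replicative growth
#' (18O), labelled storage synthesis (glucose-derived PHB + TAG), their
#' total and derived comparison metrics, per treatment x timepoint.
#' DNA-based growth pairs treatment-level means (the 18O microcosms are
#' physically distinct from the CFE microcosms); the storage:MBC ratio is
#' formed per sample (same microcosm) before summarizing. Endurance is the
#' treatment's stored C divided by the basal respiration rate (zero-C,
#' no-nutrient efflux over the final sampling interval of the cohort).
#'
#' @param accounts output of [account_pools()].
#' @param dna the DNA capsule table of the measurement set.
#' @param constants list from [pipeline_constants()].
#' @return Data frame with one row per treatment x timepoint; `*_sd`
#'   columns carry the propagated standard deviations.
#' @export
account_growth <- function(accounts, dna, constants = pipeline_constants()) {
  check_schema(dna, DNA_COLS, "dna")
  pools <- accounts$pools
  co2 <- accounts$co2
  ap_dna <- kit_background_correct(dna$dna_mass, dna$o_total,
                                   dna$ap18o_measured,
                                   ap_natural = constants$ap18o_natural)
  dna$f_new <- fraction_new_dna(ap_dna,
                                ap_water = 4.2,
                                f_water = constants$f_water,
                                ap_natural = constants$ap18o_natural)

  cells <- unique(pools[c("treatment", "timepoint_h")])
  cells <- cells[order(cells$timepoint_h, cells$treatment), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    lab <- cells$treatment[i]; tp <- cells$timepoint_h[i]
    p <- pools[pools$treatment == lab & pools$timepoint_h == tp, ]
    d <- dna[dna$treatment == lab & dna$timepoint_h == tp, ]
    if (!nrow(d)) {
      sg_stop(sprintf("no DNA rows for treatment %s at %g h", lab, tp),
              "sg_schema_error")
    }
    f_new <- summarize_treatment(d$f_new, units = "fraction")
    mbc <- summarize_treatment(p$mbc, units = "ug C/g")
    growth <- dna_growth_c(f_new, mbc)
    storage <- summarize_treatment(p$glucose_storage_c, units = "ug C/g")
    total <- total_growth(growth, storage)
    extra <- if (growth$value > 0) extra_growth_pct(storage, growth) else
      mean_sd(NA_real_, 0, units = "%")
    ratio <- storage_to_mbc_ratio(p$phb_c, p$tag_c, p$mbc)
    basal <- co2[co2$treatment == CONTROL_TREATMENT &
                   co2$timepoint_h == tp, ]
    basal <- basal[basal$t_end == max(basal$t_end), ]
    endurance <- endurance_hours(mean(p$storage_c), mean(basal$rate))
    data.frame(
      treatment = lab, timepoint_h = tp, n = nrow(p),
      mbc = mbc$value, mbc_sd = mbc$sd,
      f_new = f_new$value, f_new_sd = f_new$sd,
      dna_growth_c = growth$value, dna_growth_sd = growth$sd,
      labelled_storage_c = storage$value, labelled_storage_sd = storage$sd,
      total_growth_c = total$value, total_growth_sd = total$sd,
      extra_growth_pct = extra$value, extra_growth_pct_sd = extra$sd,
      storage_c = mean(p$storage_c),
      storage_mbc_ratio = ratio$value, storage_mbc_ratio_sd = ratio$sd,
      endurance_h = endurance, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Robust pairwise statistics per response panel
#'
#' Runs the percentile-bootstrap pairwise comparison of medians across all
#' treatments of one timepoint for a chosen per-microcosm response (the
#' family for Benjamini-Hochberg adjustment is all pairs within one
#' response x timepoint panel), plus Hodges-Lehmann intervals and Cohen's d
#' for each pair, and a compact letter display.
#'
#' @param pools per-microcosm pools from [account_pools()].
#' @param response column of `pools` to compare (default `"storage_c"`).
#' @param timepoint timepoint in hours.
#' @param B,seed,conf bootstrap parameters, see [bootstrap_median_pairs()].
#' @return List with `comparisons` (data frame) and `letters` (named
#'   character vector).
#' @export
panel_statistics <- function(pools, response = "storage_c", timepoint,
                             B = 2000, seed, conf = 0.95) {
  p <- pools[pools$timepoint_h == timepoint, ]
  if (!nrow(p)) sg_stop("no rows at that timepoint", "sg_empty_group")
  groups <- split(p[[response]], p$treatment)
  cmp <- bootstrap_median_pairs(groups, B = B, seed = seed, conf = conf)
  hl <- do.call(rbind, lapply(seq_len(nrow(cmp)), function(i) {
    h <- hodges_lehmann(groups[[cmp$group1[i]]], groups[[cmp$group2[i]]],
                        conf = conf, labels = c(cmp$group1[i], cmp$group2[i]))
    h$cohens_d <- cohens_d(groups[[cmp$group1[i]]], groups[[cmp$group2[i]]])
    h
  }))
  cmp$hl_estimate <- hl$estimate
  cmp$hl_ci_low <- hl$ci_low
  cmp$hl_ci_high <- hl$ci_high
  cmp$cohens_d <- hl$cohens_d
  cmp$response <- response
  cmp$timepoint_h <- timepoint
  list(comparisons = cmp, letters = significance_letters(cmp))
}

#' Write and read a measurement set as plain CSV tables
#'
#' The on-disk interface of the pipeline: long-format CSV files
#' `cfe.csv`, `gas.csv`, `storage.csv`, `dna.csv`, `design.csv` (and
#' `ground_truth.csv` when the set came from the generator). Reading
#' validates each table's required columns and reports the offending file
#' and columns on failure.
#'
#' @param ms a `measurement_set`.
#' @param dir directory to write to / read from (created if needed).
#' @return `read_measurement_set()` returns a `measurement_set`;
#'   `write_measurement_set()` returns `dir` invisibly.
#' @export
write_measurement_set <- function(ms, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                         row.names = FALSE)
  wr(ms$cfe, "cfe.csv"); wr(ms$gas, "gas.csv")
  wr(ms$storage, "storage.csv"); wr(ms$dna, "dna.csv")
  design <- if (!is.null(ms$design)) ms$design else design_table(ms)
  wr(design, "design.csv")
  if (!is.null(ms$ground_truth)) wr(ms$ground_truth, "ground_truth.csv")
  invisible(dir)
}

#' @rdname write_measurement_set
#' @export
read_measurement_set <- function(dir) {
  rd <- function(f, cols) {
    path <- file.path(dir, f)
    if (!file.exists(path)) {
      sg_stop(sprintf("missing input table: %s", path), "sg_schema_error")
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    check_schema(df, cols, f)
    df
  }
  gt_path <- file.path(dir, "ground_truth.csv")
  structure(list(
    cfe = rd("cfe.csv", CFE_COLS), gas = rd("gas.csv", GAS_COLS),
    storage = rd("storage.csv", STORAGE_COLS), dna = rd("dna.csv", DNA_COLS),
    design = rd("design.csv", DESIGN_COLS),
    ground_truth = if (file.exists(gt_path))
      utils::read.csv(gt_path, stringsAsFactors = FALSE)
  ), class = "measurement_set")
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a measurement set, account pools, build the growth
#' decomposition, run the robust statistics and write a reproducible
#' result bundle: `pools.csv`, `co2.csv`, `growth_summary.csv`,
#' `comparisons.csv`, `letters.csv`, `qc_report.txt` and `run_log.txt`
#' (package version, constants, seed). Identical config and seed give an
#' identical bundle.
#'
#' @param scenario a [scenario_config] to simulate from, or `NULL` to read
#'   `input_dir`.
#' @param input_dir directory of measurement CSVs (used when `scenario` is
#'   `NULL`).
#' @param output_dir directory for the result bundle, or `NULL` to skip
#'   writing.
#' @param seed integer seed for simulation and bootstrap.
#' @param B bootstrap replicates.
#' @param conf confidence level.
#' @param stat_response per-microcosm column compared across treatments
#'   (default total storage C).
#' @param constants list from [pipeline_constants()].
#' @return Invisibly, a list with `pools`, `co2`, `growth`, `comparisons`,
#'   `letters`, `qc`, and (when simulating) `ground_truth`.
#' @export
run_pipeline <- function(scenario = default_paper_scenario(),
                         input_dir = NULL, output_dir = NULL, seed = 1,
                         B = 2000, conf = 0.95, stat_response = "storage_c",
                         constants = pipeline_constants()) {
  ms <- if (is.null(scenario)) read_measurement_set(input_dir) else
    generate_experiment(scenario, seed = seed)
  res <- collect_qc({
    accounts <- account_pools(ms, constants)
    growth <- account_growth(accounts, ms$dna, constants)
    tps <- sort(unique(accounts$pools$timepoint_h))
    stats_l <- lapply(tps, function(tp) {
      panel_statistics(accounts$pools, response = stat_response,
                       timepoint = tp, B = B, seed = seed + tp, conf = conf)
    })
    comparisons <- do.call(rbind, lapply(stats_l, `[[`, "comparisons"))
    letters_df <- do.call(rbind, lapply(seq_along(tps), function(i) {
      data.frame(timepoint_h = tps[i],
                 treatment = names(stats_l[[i]]$letters),
                 letters = unname(stats_l[[i]]$letters),
                 stringsAsFactors = FALSE)
    }))
    list(pools = accounts$pools, co2 = accounts$co2, growth = growth,
         comparisons = comparisons, letters = letters_df)
  })
  bundle <- res$value
  bundle$qc <- res$qc
  if (!is.null(ms$ground_truth)) bundle$ground_truth <- ms$ground_truth

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, f) utils::write.csv(df, file.path(output_dir, f),
                                           row.names = FALSE)
    wr(bundle$pools, "pools.csv"); wr(bundle$co2, "co2.csv")
    wr(bundle$growth, "growth_summary.csv")
    wr(bundle$comparisons, "comparisons.csv")
    wr(bundle$letters, "letters.csv")
    if (!is.null(bundle$ground_truth)) wr(bundle$ground_truth,
                                          "ground_truth.csv")
    qc_lines <- if (nrow(bundle$qc)) {
      sprintf("[%s] %s", bundle$qc$what, bundle$qc$message)
    } else "clean run: no QC flags"
    writeLines(qc_lines, file.path(output_dir, "qc_report.txt"))
    writeLines(c(
      sprintf("storgrowth %s",
              as.character(utils::packageVersion("storgrowth"))),
      sprintf("seed: %d  B: %d  conf: %g  response: %s", seed, B, conf,
              stat_response),
      sprintf("constants: %s",
              paste(sprintf("%s=%g", names(constants),
                            unlist(constants)), collapse = ", "))
    ), file.path(output_dir, "run_log.txt"))
  }
  invisible(bundle)
}
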