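# Synthetic microcosm experiments with known ground truth. The generator
# forward-simulates exactly the measurement model that the accounting
# modules invert: pool at% by two-pool mixing from the true glucose-derived
# fraction, derivative at% by forward derivatization dilution, DNA capsule
# at% by forward kit-oxygen mixing, 14C activity from the specific activity
# of the dose. Noise is multiplicative lognormal (mean-preserving) on
# amounts and additive normal on atom percent.

# delta13C assumed for all unlabelled (natural abundance) carbon
NATURAL_DELTA13C <- -27

# fatty acids making up the TAG pool, with biomarker class and C share
TAG_FA_SPLIT <- data.frame(
  compound = c("16:0", "16:1w7", "18:2w6"),
  biomarker_class = c("general", "bacterial", "fungal"),
  share = c(0.50, 0.35, 0.15),
  stringsAsFactors = FALSE
)

treatment_label <- function(glucose_c, nutrients) {
  paste0("C", glucose_c, ifelse(nutrients, "+ntr", ""))
}

#' Scenario configuration for the synthetic generator
#'
#' Bundles the per-treatment true values, the CO2 efflux timecourse, the
#' replicate count and the noise model, and validates isotopic mass
#' balance: for every treatment and harvest, glucose-derived CO2 plus
#' glucose-derived MBC, storage and DOC may not exceed the glucose dose.
#'
#' @param treatments data frame with one row per treatment x timepoint:
#'   `glucose_c`, `nutrients`, `timepoint_h`, `true_mbc`, `true_f_new`,
#'   `true_phb_c`, `true_tag_c`, `gf_mbc`, `gf_phb`, `gf_tag` (glucose-
#'   derived fractions), `true_doc`, `gf_doc`, `true_dn` (all amounts in
#'   ug C (or N) per g dry soil).
#' @param gas data frame with the CO2 timecourse per treatment:
#'   `glucose_c`, `nutrients`, `t_start`, `t_end`, `rate` (ug C/g/h),
#'   `glucose_frac`.
#' @param n_reps replicates per treatment x timepoint (default 4).
#' @param cv_amount lognormal coefficient of variation on amounts
#'   (default 0.10).
#' @param sd_atpercent additive sd on measured atom percent (default 0.02).
#' @param true_dna_mass ug DNA per capsule aliquot (default 2).
#' @param true_kit_o ug non-DNA (kit) oxygen per capsule (default 0.62,
#'   i.e. roughly equal to the DNA oxygen).
#' @param fungal_hotspot if `TRUE`, one 24 h replicate of the high-C
#'   nutrient treatment receives a 10x spike of the fungal fatty acid
#'   18:2w6, emulating a local hotspot of fungal activity.
#' @param spec_template a [treatment_spec] carrying label levels and soil
#'   masses shared by all cells.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(treatments, gas, n_reps = 4, cv_amount = 0.10,
                            sd_atpercent = 0.02, true_dna_mass = 2,
                            true_kit_o = 0.62, fungal_hotspot = FALSE,
                            spec_template = treatment_spec(0)) {
  req <- c("glucose_c", "nutrients", "timepoint_h", "true_mbc", "true_f_new",
           "true_phb_c", "true_tag_c", "gf_mbc", "gf_phb", "gf_tag",
           "true_doc", "gf_doc", "true_dn")
  missing_cols <- setdiff(req, names(treatments))
  if (length(missing_cols)) {
    sg_stop(sprintf("treatments table lacks column(s): %s",
                    paste(missing_cols, collapse = ", ")), "sg_schema_error")
  }
  fr <- as.matrix(treatments[c("true_f_new", "gf_mbc", "gf_phb", "gf_tag",
                               "gf_doc")])
  if (any(fr < 0 | fr > 1)) {
    sg_stop("fractions must lie in [0, 1]", "sg_invalid_config")
  }
  if (cv_amount < 0 || sd_atpercent < 0) {
    sg_stop("noise parameters must be >= 0", "sg_invalid_config")
  }
  zero_c <- treatments$glucose_c == 0
  if (any(zero_c & apply(fr[, -1, drop = FALSE], 1, max) > 0)) {
    sg_stop("zero-C treatments cannot have glucose-derived fractions > 0",
            "sg_invalid_config")
  }
  cfg <- structure(list(treatments = treatments, gas = gas,
                        n_reps = as.integer(n_reps), cv_amount = cv_amount,
                        sd_atpercent = sd_atpercent,
                        true_dna_mass = true_dna_mass, true_kit_o = true_kit_o,
                        fungal_hotspot = isTRUE(fungal_hotspot),
                        spec_template = spec_template),
                   class = "scenario_config")
  bal <- mass_balance(cfg)
  if (any(bal$glucose_recovered > bal$glucose_c + 1e-9 & bal$glucose_c > 0)) {
    sg_stop("mass balance violated: glucose-derived pools + CO2 exceed dose",
            "sg_mass_balance")
  }
  cfg
}

# glucose-derived C recovered in CO2 + pools per treatment x timepoint
mass_balance <- function(cfg) {
  tr <- cfg$treatments
  co2 <- vapply(seq_len(nrow(tr)), function(i) {
    g <- gas_rows(cfg$gas, tr$glucose_c[i], tr$nutrients[i], tr$timepoint_h[i])
    sum(g$rate * (g$t_end - g$t_start) * g$glucose_frac)
  }, numeric(1))
  data.frame(
    treatment = treatment_label(tr$glucose_c, tr$nutrients),
    timepoint_h = tr$timepoint_h, glucose_c = tr$glucose_c,
    glucose_recovered = co2 + tr$gf_mbc * tr$true_mbc +
      tr$gf_phb * tr$true_phb_c + tr$gf_tag * tr$true_tag_c +
      tr$gf_doc * tr$true_doc
  )
}

gas_rows <- function(gas, glucose_c, nutrients, timepoint_h) {
  g <- gas[gas$glucose_c == glucose_c & gas$nutrients == nutrients &
             gas$t_end <= timepoint_h + 1e-9, , drop = FALSE]
  g[order(g$t_start), , drop = FALSE]
}

#' Reference scenario: the full 3 x 2 x 2 design
#'
#' Returns the fully crossed design — glucose at 0, 90 and 400 ug C per g
#' soil, with and without mineral nutrients, harvested at 24 and 96 h, n =
#' 4 — populated with true values chosen once to reproduce the qualitative
#' treatment orderings of the system under study: PHB behaves as surplus
#' storage (strongly glucose-responsive, suppressed by nutrients, degraded
#' after the high-C nutrient treatment re-enters C limitation), TAG as
#' reserve storage (modest, tracking replicative growth, not suppressed by
#' nutrients), and replicative growth (fraction of new DNA) increases with
#' C and nutrient supply. Zero-C treatments carry zero glucose-derived
#' fractions by construction.
#'
#' @param ... overrides passed on to [scenario_config()] (e.g. `n_reps`,
#'   `cv_amount`, `fungal_hotspot`).
#' @return A `scenario_config`.
#' @export
default_paper_scenario <- function(...) {
  cell <- function(glucose_c, nutrients, tp, mbc, f_new, phb, tag,
                   gf_mbc, gf_phb, gf_tag, doc, gf_doc, dn) {
    data.frame(glucose_c = glucose_c, nutrients = nutrients,
               timepoint_h = tp, true_mbc = mbc, true_f_new = f_new,
               true_phb_c = phb, true_tag_c = tag, gf_mbc = gf_mbc,
               gf_phb = gf_phb, gf_tag = gf_tag, true_doc = doc,
               gf_doc = gf_doc, true_dn = dn)
  }
  treatments <- rbind(
    #    gluc  ntr    tp  mbc  f_new phb  tag  gfMBC gfPHB gfTAG doc gfDOC dn
    cell(0,   FALSE,  24, 100, 0.030, 13,  9.0, 0,    0,    0,    40, 0,    10.0),
    cell(0,   FALSE,  96, 100, 0.060, 13,  9.0, 0,    0,    0,    40, 0,    10.5),
    cell(0,   TRUE,   24, 100, 0.035, 10, 10.0, 0,    0,    0,    40, 0,    22.0),
    cell(0,   TRUE,   96, 103, 0.070,  9, 12.0, 0,    0,    0,    40, 0,    20.0),
    cell(90,  FALSE,  24, 110, 0.080, 15, 10.0, 0.30, 0.25, 0.04, 42, 0.10,  9.0),
    cell(90,  FALSE,  96, 118, 0.150, 17, 11.0, 0.35, 0.30, 0.05, 40, 0.05,  9.5),
    cell(90,  TRUE,   24, 113, 0.100, 13, 12.0, 0.30, 0.25, 0.04, 42, 0.10, 21.0),
    cell(90,  TRUE,   96, 125, 0.200, 14, 11.5, 0.35, 0.30, 0.05, 40, 0.05, 19.0),
    cell(400, FALSE,  24, 115, 0.100, 32, 11.0, 0.45, 0.55, 0.16, 118, 0.66, 5.0),
    cell(400, FALSE,  96, 133, 0.140, 53, 13.0, 0.50, 0.55, 0.20, 60, 0.30,  4.5),
    cell(400, TRUE,   24, 122, 0.180, 28, 14.0, 0.45, 0.50, 0.15, 45, 0.10, 15.0),
    cell(400, TRUE,   96, 140, 0.300, 22, 13.5, 0.50, 0.50, 0.15, 45, 0.10, 12.0)
  )
  gcell <- function(glucose_c, nutrients, rates, gfracs) {
    bounds <- c(0, 6, 12, 24, 48, 72, 96)
    data.frame(glucose_c = glucose_c, nutrients = nutrients,
               t_start = bounds[-7], t_end = bounds[-1],
               rate = rates, glucose_frac = gfracs)
  }
  gas <- rbind(
    gcell(0,   FALSE, rep(0.19, 6), rep(0, 6)),
    gcell(0,   TRUE,  rep(0.19, 6), rep(0, 6)),
    gcell(90,  FALSE, c(1.20, 1.00, 0.50, 0.30, 0.25, 0.22),
                      c(0.70, 0.65, 0.50, 0.30, 0.20, 0.15)),
    gcell(90,  TRUE,  c(1.30, 1.10, 0.55, 0.28, 0.24, 0.20),
                      c(0.70, 0.65, 0.50, 0.30, 0.20, 0.15)),
    gcell(400, FALSE, c(2.50, 3.00, 1.80, 0.90, 0.60, 0.45),
                      c(0.85, 0.90, 0.80, 0.60, 0.50, 0.40)),
    gcell(400, TRUE,  c(2.50, 3.50, 3.00, 0.50, 0.40, 0.35),
                      c(0.85, 0.90, 0.85, 0.50, 0.35, 0.30))
  )
  scenario_config(treatments, gas, ...)
}

#' Nutrient dose for complete utilisation of the carbon addition
#'
#' Nitrogen and phosphorus required to assimilate a carbon dose given a
#' carbon-use efficiency and a microbial biomass C:N:P ratio (mass basis;
#' default 38:5:1 with CUE 0.5, the sizing rule of the reference design).
#'
#' @param c_added carbon dose, ug C per g soil.
#' @param cue carbon-use efficiency in (0, 1].
#' @param cnp length-3 C:N:P mass ratio.
#' @return Data frame with `n_ug`, `n_umol`, `p_ug`, `p_umol` (per g soil).
#' @examples
#' compute_nutrient_dose(400) # N 26.3 ug = 1.88 umol; P 5.26 ug = 0.17 umol
#' @export
compute_nutrient_dose <- function(c_added, cue = 0.5, cnp = c(38, 5, 1)) {
  if (cue <= 0 || cue > 1) sg_stop("cue must lie in (0, 1]", "sg_invalid_config")
  if (length(cnp) != 3 || any(cnp <= 0)) {
    sg_stop("cnp must be three positive numbers", "sg_invalid_config")
  }
  assimilated <- c_added * cue
  n_ug <- assimilated * cnp[2] / cnp[1]
  p_ug <- assimilated * cnp[3] / cnp[1]
  data.frame(n_ug = n_ug, n_umol = n_ug / 14.007,
             p_ug = p_ug, p_umol = p_ug / 30.974)
}

# mean-preserving lognormal multiplicative noise
rlnorm_mean <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, length.out = n))
  sdlog <- sqrt(log1p(cv^2))
  out <- stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  out[mean == 0] <- 0
  out
}

#' Generate a complete synthetic experiment
#'
#' Forward-simulates all four measurement tables (headspace gas, CFE
#' extracts, storage compounds, DNA capsules) for every treatment x
#' timepoint x replicate of the scenario, together with the ground truth
#' needed to score recovery. Deterministic given `seed`.
#'
#' @param cfg a [scenario_config].
#' @param seed integer seed (required).
#' @return An object of class `measurement_set`: a list with data frames
#'   `gas`, `cfe`, `storage`, `dna`, `ground_truth` and the generating
#'   `scenario`.
#' @examples
#' ms <- generate_experiment(default_paper_scenario(), seed = 1)
#' head(ms$cfe)
#' @export
generate_experiment <- function(cfg, seed) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (missing(seed)) sg_stop("a seed is required", "sg_seed_required")
  set.seed(as.integer(seed))
  tr <- cfg$treatments
  n <- cfg$n_reps
  cv <- cfg$cv_amount
  sda <- cfg$sd_atpercent
  sp <- cfg$spec_template
  ap_nat13 <- delta_to_atpercent(NATURAL_DELTA13C)
  ap_glu <- sp$glucose_ap13c
  reagent_ap <- delta_to_atpercent(NATURAL_DELTA13C)
  ap_nat18 <- AP18O_NATURAL_DEFAULT
  ap_new <- F_WATER_DEFAULT * sp$water_ap18o + (1 - F_WATER_DEFAULT) * ap_nat18

  gas_l <- list(); cfe_l <- list(); sto_l <- list(); dna_l <- list()
  for (i in seq_len(nrow(tr))) {
    t <- tr[i, ]
    lab <- treatment_label(t$glucose_c, t$nutrients)
    ids <- sprintf("%s_t%d_r%d", lab, t$timepoint_h, seq_len(n))
    sa <- if (t$glucose_c > 0)
      sp$activity_14c / (t$glucose_c * sp$soil_mass) else 0

    # --- CFE: independent fumigated/unfumigated subsamples
    doc_unfum <- rlnorm_mean(n, t$true_doc, cv)
    doc_in_fum <- rlnorm_mean(n, t$true_doc, cv)
    mbc <- rlnorm_mean(n, t$true_mbc, cv)
    bq_unfum <- sa * t$gf_doc * doc_unfum
    bq_fum <- sa * (t$gf_doc * doc_in_fum + t$gf_mbc * mbc)
    cfe_l[[i]] <- data.frame(
      microcosm_id = ids, treatment = lab, timepoint_h = t$timepoint_h,
      doc_unfum = doc_unfum, doc_fum = doc_in_fum + mbc,
      bq_unfum = bq_unfum, bq_fum = bq_fum,
      dn_unfum = rlnorm_mean(n, t$true_dn, cv), stringsAsFactors = FALSE)

    # --- storage: PHB (ug PHB) + TAG fatty acids (ug C)
    ap_phb <- ap_nat13 + t$gf_phb * (ap_glu - ap_nat13)
    ap_phb_deriv <- (4 * ap_phb + PHB_ESTER_ADDED_C * reagent_ap) /
      (4 + PHB_ESTER_ADDED_C)
    phb <- data.frame(
      microcosm_id = ids, treatment = lab, timepoint_h = t$timepoint_h,
      compound = "PHB", biomarker_class = "bacterial",
      amount = rlnorm_mean(n, t$true_phb_c / PHB_C_FRACTION, cv),
      ap13c_derivative = ap_phb_deriv + stats::rnorm(n, 0, sda),
      stringsAsFactors = FALSE)
    ap_tag <- ap_nat13 + t$gf_tag * (ap_glu - ap_nat13)
    fa <- do.call(rbind, lapply(seq_len(nrow(TAG_FA_SPLIT)), function(k) {
      f <- TAG_FA_SPLIT[k, ]
      nc <- fatty_acid_c_count(f$compound)
      deriv <- (nc * ap_tag + FAME_ADDED_C * reagent_ap) / (nc + FAME_ADDED_C)
      data.frame(
        microcosm_id = ids, treatment = lab, timepoint_h = t$timepoint_h,
        compound = f$compound, biomarker_class = f$biomarker_class,
        amount = rlnorm_mean(n, t$true_tag_c * f$share, cv),
        ap13c_derivative = deriv + stats::rnorm(n, 0, sda),
        stringsAsFactors = FALSE)
    }))
    sto_l[[i]] <- rbind(phb, fa)

    # --- headspace gas per sampling interval
    g <- gas_rows(cfg$gas, t$glucose_c, t$nutrients, t$timepoint_h)
    gi <- g[rep(seq_len(nrow(g)), each = n), , drop = FALSE]
    co2_true <- gi$rate * (gi$t_end - gi$t_start)
    ap_co2 <- ap_nat13 + gi$glucose_frac * (ap_glu - ap_nat13) +
      stats::rnorm(nrow(gi), 0, sda)
    gas_l[[i]] <- data.frame(
      microcosm_id = rep(ids, times = nrow(g)), treatment = lab,
      timepoint_h = t$timepoint_h, t_start = gi$t_start, t_end = gi$t_end,
      co2_c = rlnorm_mean(nrow(gi), 1, cv) * co2_true,
      delta13c = atpercent_to_delta(ap_co2), stringsAsFactors = FALSE)

    # --- DNA capsules (parallel 0.5 g microcosms)
    dna_mass <- rlnorm_mean(n, cfg$true_dna_mass, cv)
    kit_o <- rlnorm_mean(n, cfg$true_kit_o, cv)
    o_dna <- DNA_O_FRACTION * dna_mass
    o_total <- o_dna + kit_o
    ap_dna <- ap_nat18 + t$true_f_new * (ap_new - ap_nat18)
    ap_capsule <- (o_dna * ap_dna + kit_o * ap_nat18) / o_total +
      stats::rnorm(n, 0, sda)
    dna_l[[i]] <- data.frame(
      microcosm_id = ids, treatment = lab, timepoint_h = t$timepoint_h,
      dna_mass = dna_mass, o_total = o_total, ap18o_measured = ap_capsule,
      a260_280 = stats::rnorm(n, 1.8, 0.02), a260_230 = stats::rnorm(n, 2.0, 0.05),
      stringsAsFactors = FALSE)
  }

  storage <- do.call(rbind, sto_l)
  if (cfg$fungal_hotspot) {
    hot <- which(storage$compound == "18:2w6" & storage$timepoint_h == 24 &
                   storage$treatment == treatment_label(400, TRUE))
    if (length(hot)) {
      storage$amount[hot[1]] <- storage$amount[hot[1]] * 10
    }
  }

  gt <- tr
  gt$treatment <- treatment_label(tr$glucose_c, tr$nutrients)
  gt$true_dna_growth_c <- tr$true_f_new * tr$true_mbc
  gt$true_labelled_storage_c <- tr$gf_phb * tr$true_phb_c +
    tr$gf_tag * tr$true_tag_c
  gt$true_total_growth_c <- gt$true_dna_growth_c + gt$true_labelled_storage_c

  design <- unique(data.frame(
    treatment = treatment_label(tr$glucose_c, tr$nutrients),
    glucose_c = tr$glucose_c, nutrients = tr$nutrients,
    stringsAsFactors = FALSE))
  structure(list(gas = do.call(rbind, gas_l), cfe = do.call(rbind, cfe_l),
                 storage = storage, dna = do.call(rbind, dna_l),
                 design = design, ground_truth = gt, scenario = cfg),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf(paste0("<measurement_set> %d treatments x timepoints, ",
                     "%d CFE rows, %d storage rows, %d gas rows, %d DNA rows\n"),
              nrow(x$ground_truth), nrow(x$cfe), nrow(x$storage),
              nrow(x$gas), nrow(x$dna)))
  invisible(x)
}
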