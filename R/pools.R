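# Per-microcosm carbon pool and flux accounting: CFE biomass, 14C-traced
# glucose incorporation, CO2 efflux and its glucose-derived share, and the
# storage compounds PHB (as ethyl 3-hydroxybutyrate) and TAG (as neutral
# lipid fatty acid methyl esters).

# C mass fraction of the PHB monomer unit C4H6O2: 4*12.011 / 86.090
PHB_C_FRACTION <- 4 * 12.011 / 86.090

# derivatization C added per analyte molecule
PHB_ESTER_ADDED_C <- 2L   # ethyl ester of the C4 monomer
FAME_ADDED_C <- 1L        # methyl ester of the fatty acid

#' Treatment specification for one experimental cell
#'
#' Captures the label levels and microcosm geometry of one cell of the
#' design: glucose dose, nutrient flag, soil mass, the 13C enrichment of
#' the added glucose, the 14C activity per microcosm and the realized 18O
#' enrichment of the soil solution in the parallel small microcosms.
#'
#' @param glucose_c glucose addition, ug C per g dry soil (0, 90 or 400 in
#'   the reference design).
#' @param nutrients logical; mineral nutrient supplementation (N, P, K, S).
#' @param soil_mass g dry soil per microcosm (25 g main; the 18O microcosms
#'   hold 0.5 g).
#' @param glucose_ap13c 13C enrichment of the glucose, atom percent
#'   (default 3).
#' @param activity_14c 14C activity added per microcosm, Bq (default 190,
#'   i.e. 0.19 kBq).
#' @param water_ap18o realized 18O enrichment of the soil solution, atom
#'   percent (default 4.2).
#' @param timepoints harvest times in hours.
#' @return An object of class `treatment_spec`.
#' @export
treatment_spec <- function(glucose_c, nutrients = FALSE, soil_mass = 25,
                           glucose_ap13c = 3, activity_14c = 190,
                           water_ap18o = 4.2, timepoints = c(24, 96)) {
  stopifnot(glucose_c >= 0, soil_mass > 0, activity_14c >= 0)
  structure(list(glucose_c = glucose_c, nutrients = isTRUE(nutrients),
                 soil_mass = soil_mass, glucose_ap13c = glucose_ap13c,
                 activity_14c = activity_14c, water_ap18o = water_ap18o,
                 timepoints = timepoints),
            class = "treatment_spec")
}

#' Extractable microbial biomass carbon by fumigation-extraction
#'
#' MBC as the difference in dissolved organic carbon between the
#' chloroform-fumigated and unfumigated extracts of paired subsamples,
#' reported as *extractable* biomass without a kec extraction-efficiency
#' conversion. A negative difference (extraction noise) is retained but QC
#' flagged.
#'
#' @param doc_fum,doc_unfum DOC of the fumigated and unfumigated extracts,
#'   ug C per g dry soil (vectorised).
#' @return Extractable MBC, ug C per g soil.
#' @export
cfe_biomass <- function(doc_fum, doc_unfum) {
  mbc <- doc_fum - doc_unfum
  if (any(mbc < 0)) {
    sg_qc_flag(sprintf("%d negative CFE biomass value(s) retained",
                       sum(mbc < 0)),
               what = "negative_cfe_biomass", n = sum(mbc < 0))
  }
  mbc
}

#' Specific 14C activity of the added glucose
#'
#' Activity per unit glucose carbon, the conversion factor from extract
#' radioactivity to glucose-derived C.
#'
#' @param spec a [treatment_spec] with `glucose_c > 0`.
#' @return Bq per ug glucose C.
#' @examples
#' specific_activity(treatment_spec(400)) # 190 / (400 * 25) = 0.019
#' @export
specific_activity <- function(spec) {
  stopifnot(inherits(spec, "treatment_spec"))
  if (spec$glucose_c <= 0) {
    sg_stop("specific activity undefined for a zero-C treatment",
            "sg_undefined_specific_activity")
  }
  spec$activity_14c / (spec$glucose_c * spec$soil_mass)
}

#' Glucose-derived microbial biomass from 14C
#'
#' Difference in extract radioactivity between fumigated and unfumigated
#' subsamples divided by the specific activity of the glucose. Negative
#' differences are clamped to zero with a QC flag.
#'
#' @param bq_fum,bq_unfum extract activity, Bq per g soil (vectorised).
#' @param sa specific activity, Bq per ug glucose C (> 0).
#' @return Glucose-derived MBC, ug C per g soil.
#' @export
glucose_derived_mbc_14c <- function(bq_fum, bq_unfum, sa) {
  if (!is.numeric(sa) || sa <= 0) {
    sg_stop("specific activity must be > 0", "sg_undefined_specific_activity")
  }
  g <- (bq_fum - bq_unfum) / sa
  if (any(g < 0)) {
    sg_qc_flag(sprintf("%d negative glucose-derived MBC value(s) clamped to 0",
                       sum(g < 0)),
               what = "negative_14c_mbc_clamped", n = sum(g < 0))
    g[g < 0] <- 0
  }
  g
}

#' CO2 efflux rate at the interval midpoint
#'
#' Average rate over each headspace sampling interval, reported at the
#' interval midpoint.
#'
#' @param t_start,t_end interval bounds in hours (vectorised).
#' @param co2_c CO2-C accumulated in the headspace over the interval, ug C
#'   per g soil.
#' @return Data frame with columns `t_mid` (h) and `rate`
#'   (ug C per g per h).
#' @export
co2_rate <- function(t_start, t_end, co2_c) {
  if (any(t_end <= t_start)) {
    sg_stop("sampling interval must have positive length", "sg_bad_interval")
  }
  if (any(co2_c < 0)) sg_stop("negative CO2 amount", "sg_bad_interval")
  data.frame(t_mid = (t_start + t_end) / 2, rate = co2_c / (t_end - t_start))
}

#' Glucose-derived fraction of CO2 efflux
#'
#' Two-pool mixing of the headspace CO2 delta13C between the glucose
#' endmember and an unlabelled background endmember (in the reference
#' design: the mean CO2 at% of the zero-C, no-nutrient treatment over the
#' matching interval).
#'
#' @param delta13c measured CO2 delta13C, per mil (vectorised).
#' @param spec a [treatment_spec] with `glucose_c > 0`.
#' @param background_ap background CO2 atom percent for the matching
#'   interval.
#' @param tol clamp tolerance passed to [mixing_fraction()].
#' @return Fraction of CO2 derived from the added glucose.
#' @export
co2_glucose_fraction <- function(delta13c, spec, background_ap, tol = 0.02) {
  stopifnot(inherits(spec, "treatment_spec"))
  if (spec$glucose_c <= 0) {
    sg_stop("glucose-derived CO2 undefined for a zero-C treatment",
            "sg_zero_c_partition")
  }
  mixing_fraction(delta_to_atpercent(delta13c), spec$glucose_ap13c,
                  background_ap, tol = tol)
}

#' Carbon content of storage compound pools
#'
#' `phb_carbon()` converts a PHB amount to carbon units using the C mass
#' fraction of the C4H6O2 monomer (0.5581). `tag_carbon()` sums fatty-acid
#' carbon over the neutral-lipid fatty acids of a microcosm; the glycerol
#' backbone is deliberately not added because it is not measured.
#'
#' @param amount_phb PHB amount, ug per g soil (vectorised).
#' @param fa_amount_c fatty-acid amounts, ug C per g soil.
#' @return ug C per g soil.
#' @examples
#' phb_carbon(100) # 55.81
#' tag_carbon(c(`16:0` = 2, `18:2w6` = 1)) # 3
#' @export
phb_carbon <- function(amount_phb) {
  stopifnot(all(amount_phb >= 0))
  amount_phb * PHB_C_FRACTION
}

#' @rdname phb_carbon
#' @export
tag_carbon <- function(fa_amount_c) {
  if (!length(fa_amount_c)) return(0)
  stopifnot(all(fa_amount_c >= 0))
  sum(fa_amount_c)
}

# analyte C count and added derivatization C for a storage compound name
storage_derivatization <- function(compound) {
  is_phb <- compound == "PHB"
  n_analyte <- integer(length(compound))
  n_analyte[is_phb] <- 4L
  if (any(!is_phb)) n_analyte[!is_phb] <- fatty_acid_c_count(compound[!is_phb])
  n_added <- ifelse(is_phb, PHB_ESTER_ADDED_C, FAME_ADDED_C)
  list(n_analyte = n_analyte, n_added = as.integer(n_added))
}

#' Glucose-derived carbon in a storage compound
#'
#' Corrects the measured derivative at% for derivatization carbon, then
#' partitions the analyte between the glucose endmember and the unlabelled
#' background endmember (the treatment-matched zero-C, no-nutrient storage
#' at% at the same timepoint), and multiplies by the pool size.
#'
#' @param amount_c pool size, ug C per g soil (vectorised).
#' @param ap13c_derivative measured derivative atom percent.
#' @param compound `"PHB"` or a fatty-acid name such as `"16:1w7"` (decides
#'   the derivatization C counts: 4 + 2 for the PHB ethyl ester, Cn + 1 for
#'   a FAME).
#' @param spec a [treatment_spec].
#' @param background_ap background (unlabelled) analyte atom percent.
#' @param reagent_ap at% of the derivatization carbon; defaults to natural
#'   abundance at delta13C = -27 per mil.
#' @param tol clamp tolerance passed to [mixing_fraction()].
#' @return Glucose-derived C, ug per g soil.
#' @export
glucose_derived_storage <- function(amount_c, ap13c_derivative, compound,
                                    spec, background_ap,
                                    reagent_ap = delta_to_atpercent(-27),
                                    tol = 0.02) {
  stopifnot(inherits(spec, "treatment_spec"))
  dv <- storage_derivatization(compound)
  ap_analyte <- correct_derivatization(ap13c_derivative, dv$n_analyte,
                                       dv$n_added, ap_added = reagent_ap)
  f <- mixing_fraction(ap_analyte, spec$glucose_ap13c, background_ap,
                       tol = tol)
  amount_c * f
}
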