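# Isotope arithmetic. All mixing is done in atom-fraction (at%) space;
# delta notation is accepted only at the I/O boundary, because at tracer
# enrichments (3 at% 13C, 4.2 at% 18O) linear mixing of delta values is
# wrong.

#' Isotope reference standards
#'
#' Constructor and registry of the isotope ratio standards used to convert
#' between delta notation and atom percent. The conventional reference
#' ratios are 13C/12C (VPDB) = 0.0111802 and 18O/16O (VSMOW) = 0.0020052;
#' both are configurable by constructing your own standard.
#'
#' @param name label for the scale.
#' @param ratio heavy/light isotope abundance ratio of the reference
#'   material (dimensionless, > 0).
#' @return An object of class `iso_standard`.
#' @examples
#' iso_standard("VPDB (13C)", 0.0111802)
#' iso_standards$carbon13
#' @export
iso_standard <- function(name, ratio) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) ||
      ratio <= 0) {
    sg_stop("'ratio' must be a single positive number", "sg_invalid_standard")
  }
  structure(list(name = name, ratio = ratio), class = "iso_standard")
}

#' @rdname iso_standard
#' @format `iso_standards` is a list with elements `carbon13` (VPDB) and
#'   `oxygen18` (VSMOW).
#' @export
iso_standards <- list(
  carbon13 = structure(list(name = "VPDB (13C/12C)", ratio = 0.0111802),
                       class = "iso_standard"),
  oxygen18 = structure(list(name = "VSMOW (18O/16O)", ratio = 0.0020052),
                       class = "iso_standard")
)

#' @export
print.iso_standard <- function(x, ...) {
  cat(sprintf("<iso_standard> %s, R = %.7g\n", x$name, x$ratio))
  invisible(x)
}

#' Convert between delta notation and atom percent
#'
#' `delta_to_atpercent()` maps a per-mil delta value to atom percent of the
#' heavy isotope via `R = R_std * (delta/1000 + 1)` and
#' `at% = 100 * R / (1 + R)`. `atpercent_to_delta()` is its exact inverse.
#'
#' @param delta delta value in per mil (must be > -1000).
#' @param ap atom percent of the heavy isotope, strictly between 0 and 100.
#' @param standard an [iso_standard]; defaults to the VPDB 13C scale.
#' @return Numeric vector: atom percent, or per-mil delta.
#' @examples
#' delta_to_atpercent(0)                      # 1.10566 at% (VPDB)
#' atpercent_to_delta(delta_to_atpercent(42)) # 42
#' @export
delta_to_atpercent <- function(delta, standard = iso_standards$carbon13) {
  stopifnot(inherits(standard, "iso_standard"))
  if (any(!is.finite(delta)) || any(delta <= -1000)) {
    sg_stop("delta values must be finite and > -1000 per mil",
            "sg_invalid_isotope_value")
  }
  r <- standard$ratio * (delta / 1000 + 1)
  100 * r / (1 + r)
}

#' @rdname delta_to_atpercent
#' @export
atpercent_to_delta <- function(ap, standard = iso_standards$carbon13) {
  stopifnot(inherits(standard, "iso_standard"))
  if (any(!is.finite(ap)) || any(ap <= 0) || any(ap >= 100)) {
    sg_stop("atom percent must lie strictly between 0 and 100",
            "sg_undefined_ratio")
  }
  r <- ap / (100 - ap)
  1000 * (r / standard$ratio - 1)
}

#' Two-pool isotope mixing fraction
#'
#' Linear partition of a measured atom-percent value between two endmembers:
#' `f = (ap_sample - ap_background) / (ap_source - ap_background)`. Used for
#' the 13C source partitioning of CO2, PHB, TAG fatty acids and extractable
#' biomass, and for the 18O-DNA growth model. Mixing is always performed in
#' atom-fraction space.
#'
#' Values that fall outside `[0, 1]` by at most `tol` (measurement noise
#' around a pure endmember) are clamped to the boundary with a QC flag;
#' larger excursions are clamped too but indicate an endmember
#' misspecification and are flagged as such.
#'
#' @param ap_sample,ap_source,ap_background atom percent of the mixture, the
#'   labelled source and the unlabelled background. Vectorised over
#'   `ap_sample`.
#' @param tol clamp tolerance on the mixing fraction (default 0.02).
#' @return Mixing fraction(s) in `[0, 1]`.
#' @examples
#' mixing_fraction(2, 3, 1) # 0.5
#' @export
mixing_fraction <- function(ap_sample, ap_source, ap_background, tol = 0.02) {
  span <- ap_source - ap_background
  if (any(abs(span) < .Machine$double.eps * 100)) {
    sg_stop("source and background endmembers are equal: mixing is degenerate",
            "sg_degenerate_mixing")
  }
  f <- (ap_sample - ap_background) / span
  low <- f < 0
  high <- f > 1
  if (any(low | high)) {
    outside_tol <- f < -tol | f > 1 + tol
    sg_qc_flag(
      sprintf("%d mixing fraction(s) outside [0, 1] clamped%s",
              sum(low | high),
              if (any(outside_tol))
                sprintf(" (%d beyond tolerance %.3g)", sum(outside_tol), tol)
              else ""),
      what = "mixing_fraction_clamped",
      n = sum(low | high), n_beyond_tol = sum(outside_tol)
    )
    f[low] <- 0
    f[high] <- 1
  }
  f
}

#' Correct a derivative's isotope composition for derivatization carbon
#'
#' Transesterification (PHB to its ethyl ester) and methylation (fatty acids
#' to FAMEs) add reagent carbon of known isotopic composition to the
#' analyte. The measured at% of the derivative is a C-weighted mixture; this
#' inverts it to recover the analyte at%:
#' `ap_analyte = ((n_a + n_d) * ap_measured - n_d * ap_added) / n_a`.
#'
#' For the PHB ethyl ester `n_analyte_c = 4`, `n_added_c = 2`; for FAMEs
#' `n_added_c = 1` and `n_analyte_c` is the fatty-acid carbon count.
#'
#' @param ap_measured measured derivative atom percent (vectorised).
#' @param n_analyte_c carbon atoms in the analyte (>= 1).
#' @param n_added_c carbon atoms added by derivatization (>= 0).
#' @param ap_added atom percent of the added carbon; defaults to natural
#'   abundance at delta13C = -27 per mil.
#' @return Atom percent of the underivatized analyte.
#' @examples
#' # forward mixture (4*3.0 + 2*1.08)/6 = 2.36; correction recovers 3.0
#' correct_derivatization(2.36, 4, 2, ap_added = 1.08)
#' @export
correct_derivatization <- function(ap_measured, n_analyte_c, n_added_c,
                                   ap_added = delta_to_atpercent(-27)) {
  stopifnot(n_analyte_c >= 1, n_added_c >= 0)
  ap <- ((n_analyte_c + n_added_c) * ap_measured - n_added_c * ap_added) /
    n_analyte_c
  if (any(ap < 0 | ap > 100)) {
    sg_stop(paste("derivatization correction left atom percent outside",
                  "[0, 100]: check reagent at% and carbon counts"),
            "sg_correction_out_of_range")
  }
  ap
}

# Fatty-acid C counts from names like "16:0", "16:1w7", "18:2w6" (omega
# accepted as the Greek letter too).
fatty_acid_c_count <- function(name) {
  m <- regmatches(name, regexpr("^[0-9]+", name))
  bad <- lengths(regmatches(name, gregexpr("^[0-9]+:[0-9]+", name))) == 0
  if (any(bad) || length(m) != length(name)) {
    sg_stop(sprintf("cannot resolve carbon count from fatty-acid name(s): %s",
                    paste(unique(name[bad]), collapse = ", ")),
            "sg_unknown_fatty_acid")
  }
  as.integer(m)
}
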