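# MeanWithSD: the propagation currency of the pipeline. First-order
# (delta-method) propagation with independence assumed throughout; no
# covariance information is available because the pools come from distinct
# analytical procedures.

#' Value with standard deviation
#'
#' Lightweight container for a treatment-level mean with its standard
#' deviation, replicate count and units; all error-propagation operations
#' consume and return this class.
#'
#' @param value numeric mean.
#' @param sd standard deviation (>= 0).
#' @param n replicate count (>= 1).
#' @param units unit string, used to guard sums against unit mismatch.
#' @return An object of class `mean_sd`.
#' @examples
#' mean_sd(30, 4.2, n = 4, units = "ug C/g")
#' @export
mean_sd <- function(value, sd = 0, n = 1L, units = "") {
  stopifnot(is.numeric(value), length(value) == 1L,
            is.numeric(sd), length(sd) == 1L)
  if (!is.finite(sd) || sd < 0) sg_stop("sd must be >= 0", "sg_invalid_sd")
  if (n < 1) sg_stop("n must be >= 1", "sg_invalid_n")
  structure(list(value = value, sd = sd, n = as.integer(n), units = units),
            class = "mean_sd")
}

#' @export
print.mean_sd <- function(x, ...) {
  cat(sprintf("%.6g ± %.6g %s (n = %d)\n", x$value, x$sd, x$units, x$n))
  invisible(x)
}

#' @export
format.mean_sd <- function(x, ...) {
  sprintf("%.6g ± %.6g %s", x$value, x$sd, x$units)
}

#' Summarize replicate values as mean and standard deviation
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) over
#' per-microcosm values; this is how every treatment-level quantity is
#' reported. A singleton gets sd 0 with a QC flag.
#'
#' @param values numeric vector of per-microcosm values (NA dropped).
#' @param units unit string carried into the result.
#' @return A [mean_sd].
#' @examples
#' summarize_treatment(c(1, 2, 3)) # 2 +/- 1, n = 3
#' @export
summarize_treatment <- function(values, units = "") {
  values <- values[!is.na(values)]
  if (!length(values)) sg_stop("no values to summarize", "sg_empty_group")
  if (length(values) == 1L) {
    sg_qc_flag("treatment summarized from a single replicate (sd set to 0)",
               what = "singleton_treatment")
    return(mean_sd(values, 0, n = 1L, units = units))
  }
  mean_sd(mean(values), stats::sd(values), n = length(values), units = units)
}

check_mean_sd <- function(x) {
  if (!inherits(x, "mean_sd"))
    sg_stop("expected a 'mean_sd' object", "sg_type_error")
  x
}

#' Error propagation for sums, products and ratios
#'
#' Standard first-order propagation assuming independent errors:
#' sums add sds in quadrature; products and ratios add *relative* sds in
#' quadrature. Replicate count of the result is the smaller of the two
#' inputs' counts (the limiting information).
#'
#' @param a,b [mean_sd] objects. `propagate_sum()` requires matching units.
#' @param units units of the result for product/ratio (they cannot be
#'   derived reliably from the operand unit strings).
#' @return A [mean_sd].
#' @examples
#' propagate_sum(mean_sd(10, 1), mean_sd(5, 1))     # 15 +/- sqrt(2)
#' propagate_ratio(mean_sd(50, 5), mean_sd(100, 10)) # 0.5 +/- 0.0707
#' @export
propagate_sum <- function(a, b) {
  check_mean_sd(a); check_mean_sd(b)
  if (!identical(a$units, b$units)) {
    sg_stop(sprintf("unit mismatch in sum: '%s' vs '%s'", a$units, b$units),
            "sg_unit_mismatch")
  }
  mean_sd(a$value + b$value, sqrt(a$sd^2 + b$sd^2),
          n = min(a$n, b$n), units = a$units)
}

#' @rdname propagate_sum
#' @export
propagate_product <- function(a, b, units = "") {
  check_mean_sd(a); check_mean_sd(b)
  v <- a$value * b$value
  rel <- sqrt(rel_sd(a)^2 + rel_sd(b)^2)
  mean_sd(v, abs(v) * rel, n = min(a$n, b$n), units = units)
}

#' @rdname propagate_sum
#' @export
propagate_ratio <- function(a, b, units = "") {
  check_mean_sd(a); check_mean_sd(b)
  if (b$value == 0) sg_stop("division by a zero-mean quantity",
                            "sg_degenerate_ratio")
  v <- a$value / b$value
  rel <- sqrt(rel_sd(a)^2 + rel_sd(b)^2)
  mean_sd(v, abs(v) * rel, n = min(a$n, b$n), units = units)
}

rel_sd <- function(x) if (x$value == 0) 0 else x$sd / abs(x$value)

scale_mean_sd <- function(x, k, units = x$units) {
  mean_sd(x$value * k, x$sd * abs(k), n = x$n, units = units)
}
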