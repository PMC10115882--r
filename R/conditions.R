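#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the pipeline's QC log) can react to
# specific failure modes instead of matching on message text.

sg_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "storgrowth_error"), call = call))
}

# A QC flag is a classed warning carrying structured fields; the pipeline
# collects them into its QC report, interactive use just sees a warning.
sg_qc_flag <- function(msg, what, ...) {
  warning(warningCondition(
    msg,
    class = c("storgrowth_qc", "storgrowth_condition"),
    what = what, info = list(...)
  ))
  invisible(NULL)
}

#' Evaluate an expression while collecting QC flags
#'
#' Runs `expr`, intercepting the classed QC warnings raised by accounting
#' operations (negative CFE biomass, clamped mixing fractions, dropped
#' samples, ...) instead of letting them surface as ordinary warnings.
#'
#' @param expr expression to evaluate.
#' @return A list with elements `value` (the result of `expr`) and `qc`
#'   (a data frame with columns `what` and `message`, zero rows if clean).
#' @export
collect_qc <- function(expr) {
  flags <- list()
  value <- withCallingHandlers(
    expr,
    storgrowth_qc = function(w) {
      flags[[length(flags) + 1L]] <<- data.frame(
        what = w$what, message = conditionMessage(w),
        stringsAsFactors = FALSE
      )
      invokeRestart("muffleWarning")
    }
  )
  qc <- if (length(flags)) do.call(rbind, flags) else
    data.frame(what = character(), message = character())
  list(value = value, qc = qc)
}
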