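#' @useDynLib dtcqc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Quiet R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".", ".N", "chrom", "pos", "rsid", "allele1", "allele2", "nocall",
  "ref", "alt", "af_all", "af_eur", "k", "n", "prevalence", "base",
  "build", "key_", "genotype", "reason"
))

#' Raise a file-level rejection
#'
#' Rejections are classed conditions so the pipeline driver can catch them
#' and turn them into a QC-report entry instead of a stack trace.
#'
#' @param reason short machine-readable reason string
#' @param detail optional human-readable detail
#' @keywords internal
reject <- function(reason, detail = NULL) {
  msg <- if (is.null(detail)) reason else paste0(reason, ": ", detail)
  cond <- structure(
    class = c("dtcqc_rejected", "error", "condition"),
    list(message = paste0("rejected file (", msg, ")"), call = sys.call(-1),
         reason = reason, detail = detail)
  )
  stop(cond)
}

#' Construct a rejection value
#'
#' Some checks report rejection as a return value rather than a condition
#' (the caller is expected to inspect it). `is_rejection()` tests for it.
#'
#' @param reason short machine-readable reason string
#' @param stage pipeline stage that produced the rejection
#' @param detail optional human-readable detail
#' @return an object of class `dtcqc_rejection`
#' @export
rejection <- function(reason, stage = NA_character_, detail = NULL) {
  structure(list(reason = reason, stage = stage, detail = detail),
            class = "dtcqc_rejection")
}

#' @rdname rejection
#' @param x object to test
#' @export
is_rejection <- function(x) inherits(x, "dtcqc_rejection")

#' @export
print.dtcqc_rejection <- function(x, ...) {
  cat("<rejected", if (!is.na(x$stage)) paste0("at ", x$stage), "-",
      x$reason, ">\n")
  invisible(x)
}

# Run an expression, converting a dtcqc_rejected condition into a
# dtcqc_rejection value tagged with the stage name.
capture_rejection <- function(expr, stage) {
  tryCatch(expr, dtcqc_rejected = function(e) {
    rejection(e$reason, stage = stage, detail = e$detail)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
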