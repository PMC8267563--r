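# QC report serialization and validation.

#' @export
print.dtc_qc_report <- function(x, ...) {
  cat("QC report:", x$file, "\n")
  cat(sprintf("  source=%s build=%s kind=%s cluster=%s\n",
              x$source, x$build, x$data_kind, x$cluster))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-16s %s%s\n", nm, st$status,
                if (!is.null(st$detail)) paste0(" (", st$detail, ")") else ""))
  }
  cat(if (isTRUE(x$passed)) "  PASSED\n"
      else sprintf("  REJECTED at %s: %s\n", x$rejection_stage,
                   x$rejection_reason))
  invisible(x)
}

#' Serialize a QC report
#'
#' @param report a `dtc_qc_report` from [run_single()]
#' @param path output file; `NULL` returns the serialized text
#' @param format `"json"` or `"text"`
#' @return the text invisibly (and writes `path` when given)
#' @export
write_qc_report <- function(report, path = NULL, format = c("json", "text")) {
  format <- match.arg(format)
  txt <- if (format == "json") {
    jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                     pretty = TRUE, null = "null", na = "null")
  } else {
    paste(utils::capture.output(print(report)), collapse = "\n")
  }
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Validate a QC report against the packaged schema
#'
#' Checks the presence and type of every required field listed in the
#' packaged schema (a JSON description of the report layout).
#'
#' @param report a `dtc_qc_report`, or a path to a report JSON file
#' @return `TRUE` invisibly; errors describe the first violation
#' @export
validate_qc_report <- function(report) {
  if (is.character(report)) {
    report <- jsonlite::fromJSON(report, simplifyVector = FALSE)
  }
  schema <- jsonlite::fromJSON(
    system.file("extdata", "qc_report_schema.json", package = "dtcqc"),
    simplifyVector = FALSE
  )
  for (field in names(schema$required)) {
    if (!(field %in% names(report))) {
      stop("QC report missing required field: ", field)
    }
  }
  if (!is.list(report$stages)) stop("QC report 'stages' must be an object")
  for (nm in names(report$stages)) {
    st <- report$stages[[nm]]
    if (is.null(st$status) ||
        !(st$status %in% c("pass", "fail"))) {
      stop("stage '", nm, "' must carry status pass/fail")
    }
  }
  if (isFALSE(report$passed) &&
      (is.null(report$rejection_reason) ||
         is.na(report$rejection_reason) ||
         !nzchar(report$rejection_reason))) {
    stop("rejected report must carry exactly one rejection reason")
  }
  invisible(TRUE)
}
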