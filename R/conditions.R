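#' Structured errors
#'
#' All errors raised by the package carry a stable machine-readable `code`
#' (e.g. `XREF_UNRESOLVED`, `IMPORT_UNKNOWN_COLUMN`) alongside the human
#' message, so callers and the REST layer can react programmatically.
#'
#' @param code stable machine code string (upper snake case)
#' @param message human-readable message
#' @param ... extra fields attached to the condition
#' @return does not return; signals a condition of class
#'   `c(code, "genapp_error", "error", "condition")`
#' @keywords internal
ga_stop <- function(code, message, ...) {
  cond <- structure(
    class = c(code, "genapp_error", "error", "condition"),
    list(message = sprintf("[%s] %s", code, message),
         call = sys.call(-1), code = code, ...)
  )
  stop(cond)
}

#' Extract the machine code from a caught genapp error
#' @param cond a condition object
#' @return the code string, or `NA_character_` for foreign conditions
#' @export
error_code <- function(cond) {
  if (!is.null(cond$code)) cond$code else NA_character_
}

# closed enumeration of validation issue codes; validate() and the
# documentation both draw from this single table
GA_ISSUE_CODES <- c(
  "MODEL_DUPLICATE_ENTITY",
  "MODEL_INHERITANCE_CYCLE",
  "MODEL_XREF_CYCLE",
  "NAME_INVALID",
  "FIELD_REDECLARED",
  "FIELD_BAD_TYPE",
  "FIELD_BAD_LENGTH",
  "XREF_INCOMPLETE",
  "XREF_ATTRS_UNEXPECTED",
  "XREF_TARGET_MISSING",
  "XREF_TARGET_NOT_UNIQUE",
  "XREF_TO_XREF",
  "XREF_SELF_NOT_NILLABLE",
  "ENTITY_NO_KEY",
  "UI_ENTITY_MISSING",
  "UI_DUPLICATE_NAME",
  "UI_NO_LINK",
  "UI_AMBIGUOUS_LINK",
  "UI_BAD_LINK_FIELD",
  "EXTRACT_TYPE_UNMAPPED",
  "EXTRACT_UNIQUE_PROMOTED",
  "EXTRACT_FK_COMPOSITE",
  "EXTRACT_FK_DEGRADED"
)

# construct one validation issue row
ga_issue <- function(severity, code, locus, message) {
  stopifnot(code %in% GA_ISSUE_CODES)
  data.frame(severity = severity, code = code, locus = locus,
             message = message, stringsAsFactors = FALSE)
}

ga_no_issues <- function() {
  data.frame(severity = character(), code = character(),
             locus = character(), message = character(),
             stringsAsFactors = FALSE)
}
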