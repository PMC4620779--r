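# Internal condition helpers. All package errors/warnings carry a subclass so
# callers (and the pipeline runner) can react to specific failure modes.

stop_grsbmi <- function(msg, class) {
  cond <- structure(
    class = c(class, "grsbmi_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

warn_grsbmi <- function(msg, class) {
  cond <- structure(
    class = c(class, "grsbmi_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  )
  warning(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse booleans the way questionnaire exports encode them.
parse_bool <- function(x, column, subject_id = NULL) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "yes", "true", "t")] <- TRUE
  out[v %in% c("0", "no", "false", "f")] <- FALSE
  bad <- !is.na(v) & v != "" & is.na(out)
  if (any(bad)) {
    who <- if (!is.null(subject_id)) {
      sprintf(" (subject %s)", paste(subject_id[bad], collapse = ", "))
    } else ""
    stop_grsbmi(
      sprintf("column '%s' has non-boolean values: %s%s",
              column, paste(unique(v[bad]), collapse = ", "), who),
      "grsbmi_format_error"
    )
  }
  out
}
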