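# internal validation helpers; all user-facing errors route through these so
# messages consistently name the offending field

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("odorisk_validation_error", "error")))
}

check_number <- function(x, name, lower = -Inf, strict = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x))) {
    stop_validation("'", name, "' must be a finite numeric of length ", len)
  }
  bad <- if (strict) any(x <= lower) else any(x < lower)
  if (bad) {
    stop_validation("'", name, "' must be ", if (strict) "> " else ">= ",
                    lower, " (got ", paste(signif(x, 6), collapse = ", "), ")")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
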