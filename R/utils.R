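`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    stop(sprintf("`%s` must be a single %s number", name,
                 if (strict) "strictly positive" else "non-negative"),
         call. = FALSE)
  }
  invisible(x)
}

# strict list-constructor helper: all of `args` must be known fields
check_known_fields <- function(args, known, where) {
  bad <- setdiff(names(args), known)
  if (length(bad)) {
    stop(sprintf("unknown %s field(s): %s", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(args)
}
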