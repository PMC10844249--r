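# Internal helpers: error classes, logging, small validators.

os_error <- function(msg, class) {
  stop(structure(
    class = c(class, "orthoscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

config_error     <- function(msg) os_error(msg, "orthoscreen_config_error")
validation_error <- function(msg) os_error(msg, "orthoscreen_validation_error")
parse_error      <- function(msg) os_error(msg, "orthoscreen_parse_error")
degenerate_error <- function(msg) os_error(msg, "orthoscreen_degenerate_error")
io_error         <- function(msg) os_error(msg, "orthoscreen_io_error")

# All diagnostics go to stderr so result files stay clean.
os_log <- function(...) {
  message("[orthoscreen] ", sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    validation_error(sprintf("'%s' must be a single finite number", name))
  if (x < lower || x > upper || (strict_lower && x <= lower))
    validation_error(sprintf("'%s' = %g out of range", name, x))
  invisible(x)
}

# Fixed-format numeric rendering for deterministic, precision-preserving TSV
# output (round-trips doubles exactly via %.17g; integers stay integers).
fmt_num <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- "NA"
  ok <- !is.na(x)
  out[ok] <- formatC(x[ok], format = "g", digits = 17)
  out
}

write_tsv_deterministic <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  is_num <- vapply(df, is.double, logical(1))
  for (j in which(is_num)) df[[j]] <- fmt_num(df[[j]])
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    io_error(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e))))
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(df), sep = "\t")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
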