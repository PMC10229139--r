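# Internal helpers shared across modules.

abort <- function(..., class = "sccausal_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

validation_error <- function(...) abort(..., class = "sccausal_validation_error")
parse_error <- function(...) abort(..., class = "sccausal_parse_error")
state_error <- function(...) abort(..., class = "sccausal_state_error")

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    validation_error(name, " must be a finite scalar")
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok)
    validation_error(name, " = ", x, " is outside the allowed range")
  invisible(x)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic per-call sub-seed (kept well below 2^31).
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 31 + (as.numeric(p) %% 1e6)) %% 2147480000
  as.integer(s)
}

# Canonical unordered-pair key, used for sepsets and per-pair annotations.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

pair_key_split <- function(key) strsplit(key, "\r", fixed = TRUE)

# Content hash of an R object via its serialized form (for config fingerprints).
object_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeBin(serialize(x, NULL, version = 2L), tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
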