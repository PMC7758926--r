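# Structured error conditions. Every error raised by the package carries the
# class "pges_error" plus one of the subclasses below; the command-line
# wrapper maps subclasses to distinct exit codes.

pges_stop <- function(subclass, msg, call. = FALSE) {
  stop(structure(
    class = c(subclass, "pges_error", "error", "condition"),
    list(message = msg, call = NULL)))
}

stop_argument <- function(msg) pges_stop("pges_argument_error", msg)
stop_schema <- function(msg) pges_stop("pges_schema_error", msg)
stop_format <- function(msg) pges_stop("pges_format_error", msg)
stop_montage <- function(msg) pges_stop(c("pges_montage_error",
                                          "pges_schema_error"), msg)
stop_io <- function(msg) pges_stop("pges_io_error", msg)
stop_persistence <- function(msg) pges_stop(c("pges_persistence_error",
                                              "pges_io_error"), msg)
stop_metric <- function(msg) pges_stop(c("pges_metric_error",
                                         "pges_argument_error"), msg)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate an expression under a fixed RNG seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-condition seed derived from a master seed and a label,
# kept inside the 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 1000003
  as.integer((as.numeric(seed) * 1009 + h * 97 + 17) %% .Machine$integer.max)
}
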