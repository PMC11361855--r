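# internal helpers shared across modules

# Deterministic 31-bit FNV-1a hash over the string rendering of its
# arguments.  Must stay in lock-step with stable_hash() in
# inst/python/chem_backend.py: replica seeds are derived from it on both
# sides of the bridge.  All arithmetic is exact in doubles (< 2^53).
stable_hash <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1)), collapse = "|")
  h <- 2166136261
  xor32 <- function(a, b) {
    bitwXor(a %% 65536L, b %% 65536L) +
      bitwXor(a %/% 65536L, b %/% 65536L) * 65536
  }
  p <- 16777619
  for (code in utf8ToInt(s)) {
    h <- xor32(h, code)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  h %% 2147483647
}

# classed error constructors so callers can distinguish failure modes
pepperm_error <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "pepperm_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

input_error <- function(msg) pepperm_error("pepperm_input_error", msg)
size_error <- function(msg) pepperm_error("pepperm_size_error", msg)
chem_error <- function(msg) pepperm_error("pepperm_chem_error", msg)
backend_error <- function(msg) pepperm_error("pepperm_backend_error", msg)

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce jsonlite's row-list / vector forms to an n x 3 numeric matrix
as_coord_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.numeric(x) && length(x) == 3) return(matrix(x, nrow = 1))
  do.call(rbind, lapply(x, as.numeric))
}
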