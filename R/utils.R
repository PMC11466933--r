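`%||%` <- function(x, y) if (is.null(x)) y else x

# FNV-1a 32-bit over UTF-8 bytes; used for short, stable InfoTree digests.
fnv1a32 <- function(txt) {
  bytes <- utf8ToInt(enc2utf8(txt))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256), keeping h a plain double
    lowb <- h %% 256
    h <- h - lowb + bitwXor(as.integer(lowb), as.integer(b))
    # 32-bit multiply by 16777619 without overflow: split into 16-bit halves
    lo <- h %% 65536
    hi <- (h %/% 65536) %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer((h %/% 65536) %% 65536), as.integer(h %% 65536))
}

# Run code with a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.ops_state <- new.env(parent = emptyenv())
.ops_state$next_id <- 0L

# Monotone identifiers for mutable objects, used by the execution history.
new_obj_id <- function() {
  .ops_state$next_id <- .ops_state$next_id + 1L
  sprintf("obj-%d", .ops_state$next_id)
}

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

ops_log <- function(env, level, msg) {
  lvl <- .log_levels[[level]]
  thr <- .log_levels[[env$log_level %||% "warn"]]
  if (lvl >= thr) message(sprintf("[%s] %s", level, msg))
  invisible(NULL)
}
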