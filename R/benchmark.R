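#' Dispatch-overhead micro-benchmark
#'
#' Times the `benchmark.increment` op through each execution pathway:
#' direct implementation call, engine matching (cache disabled), engine with
#' the match cache, engine with shape adaptation \[A\] (requested as a
#' function op), engine with parameter conversion \[C\] (requested with a
#' real-sequence argument), and their composition \[A+C\].  Only relative
#' statements are meaningful (cached < uncached; direct < any engine
#' pathway; A+C >= max(A, C)); absolute times are hardware-dependent.
#'
#' @param env an [op_environment()] holding `benchmark.increment`; defaults
#'   to [default_ops_env()].
#' @param reps repetitions per pathway.
#' @return data.frame with columns `pathway`, `mean_us`, `min_us`,
#'   `max_us`, `reps` (per-call times in microseconds; min/max over 10
#'   blocks of reps/10 calls).
#' @export
ops_benchmark <- function(env = default_ops_env(), reps = 1000L) {
  reps <- max(10L, as.integer(reps))
  bs <- byte_seq(rep(0, 16))
  rs <- real_seq(rep(0, 16))
  impl <- resolve_impl(env, "opsmatch::.op_benchmark_increment")

  req_inplace <- op_request("benchmark.increment", "inplace",
                            input_types = "byte-seq", mutable_pos = 1L)
  req_adapt <- op_request("benchmark.increment", "function",
                          input_types = "byte-seq")
  req_conv <- op_request("benchmark.increment", "inplace",
                         input_types = "real-seq", mutable_pos = 1L)
  req_both <- op_request("benchmark.increment", "function",
                         input_types = "real-seq")

  time_path <- function(fn) {
    blocks <- 10L
    per <- reps %/% blocks
    means <- numeric(blocks)
    for (b in seq_len(blocks)) {
      t0 <- proc.time()[["elapsed"]]
      for (i in seq_len(per)) fn()
      means[b] <- (proc.time()[["elapsed"]] - t0) / per * 1e6
    }
    c(mean = mean(means), min = min(means), max = max(means))
  }

  engine_run <- function(req, arg, cached) {
    old <- env$cache_enabled
    env$cache_enabled <- cached
    on.exit(env$cache_enabled <- old)
    if (cached) op_match_cached(env, req)   # warm once
    time_path(function() {
      tree <- if (cached) op_match_cached(env, req) else op_match(env, req)
      do.call(tree_executable(env, tree), list(arg))
    })
  }

  rows <- list(
    direct = time_path(function() impl(bs)),
    engine_direct = engine_run(req_inplace, bs, cached = FALSE),
    engine_cached = engine_run(req_inplace, bs, cached = TRUE),
    engine_adaptation = engine_run(req_adapt, bs, cached = FALSE),
    engine_conversion = engine_run(req_conv, rs, cached = FALSE),
    engine_adaptation_conversion = engine_run(req_both, rs, cached = FALSE))

  data.frame(pathway = names(rows),
             mean_us = vapply(rows, `[[`, numeric(1), "mean"),
             min_us = vapply(rows, `[[`, numeric(1), "min"),
             max_us = vapply(rows, `[[`, numeric(1), "max"),
             reps = reps, row.names = NULL, stringsAsFactors = FALSE)
}
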