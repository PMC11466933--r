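# Independent oracles.  The brute-force matcher enumerates every
# (op, adapter, per-position converter) combination flat, checks validity
# from first principles, and ranks with the documented rule; it shares no
# code with the engine's candidate generation.

bf_assignable <- function(reg, from, to) {
  # transitive closure by fixed-point iteration over the edge list
  if (from == to) return(TRUE)
  edges <- do.call(rbind, lapply(names(reg$parents), function(ch)
    if (length(reg$parents[[ch]])) cbind(ch, reg$parents[[ch]])))
  if (is.null(edges)) return(FALSE)
  reach <- from
  repeat {
    nxt <- unique(c(reach, edges[edges[, 1] %in% reach, 2]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  to %in% reach
}

# signature of `op` seen through `ad` (NULL / shape adapter) in req's shape;
# returns list(types, ios, out) or NULL
bf_signature <- function(op, ad, req) {
  ptype <- vapply(op$parameters, `[[`, character(1), "type")
  pio <- vapply(op$parameters, `[[`, character(1), "io")
  if (is.null(ad)) {
    if (op$shape != req$shape) return(NULL)
    if (op$shape == "function")
      return(list(types = ptype[pio == "input"], ios = pio[pio == "input"],
                  out = ptype[pio == "output"]))
    if (op$shape == "computer")
      return(list(types = ptype, ios = pio, out = ptype[pio == "container"]))
    return(list(types = ptype, ios = ifelse(pio == "mutable", "mutable", "input"),
                out = ptype[pio == "mutable"]))
  }
  a <- ad$adapter
  if (a$kind != "shape" || a$from != op$shape || a$to != req$shape) return(NULL)
  tf <- paste(a$from, a$to)
  if (tf == "computer function")
    return(list(types = ptype[pio == "input"], ios = pio[pio == "input"],
                out = ptype[pio == "container"], need = c("create")))
  if (tf == "inplace function")
    return(list(types = ptype, ios = rep("input", length(ptype)),
                out = ptype[pio == "mutable"], need = c("create", "copy")))
  if (tf == "function computer")
    return(list(types = c(ptype[pio == "input"], ptype[pio == "output"]),
                ios = c(pio[pio == "input"], "container"),
                out = ptype[pio == "output"], need = "copy"))
  if (tf == "inplace computer")
    return(list(types = c(ptype, ptype[pio == "mutable"]),
                ios = c(rep("input", length(ptype)), "container"),
                out = ptype[pio == "mutable"], need = "copy"))
  if (tf == "computer inplace") {
    ct <- ptype[pio == "container"]
    ins <- which(pio == "input")
    hit <- ins[ptype[ins] == ct]
    if (!length(hit)) return(NULL)
    ios <- rep("input", length(ins)); ios[match(hit[1], ins)] <- "mutable"
    return(list(types = ptype[ins], ios = ios, out = ct, need = c("create", "copy")))
  }
  NULL
}

bf_pick <- function(ops) {
  if (!length(ops)) return(NULL)
  df <- data.frame(p = vapply(ops, `[[`, numeric(1), "priority"),
                   s = vapply(ops, `[[`, character(1), "source"))
  ops[[order(-df$p, df$s, method = "radix")[1]]]
}

bf_converter <- function(env, from, to, loose_from = FALSE) {
  cands <- Filter(function(o) {
    if (o$shape != "function" || length(o$parameters) != 2L) return(FALSE)
    if (!any(o$names == "engine.convert" |
             startsWith(o$names, "engine.convert."))) return(FALSE)
    ti <- vapply(o$parameters, `[[`, character(1), "type")
    io <- vapply(o$parameters, `[[`, character(1), "io")
    cin <- ti[io == "input"]; cout <- ti[io == "output"]
    ok_in <- bf_assignable(env$types, from, cin) ||
      (loose_from && bf_assignable(env$types, cin, from))
    ok_in && bf_assignable(env$types, cout, to)
  }, env$ops)
  bf_pick(cands)
}

bf_engine_op <- function(env, family, type) {
  cands <- Filter(function(o) {
    if (!any(o$names == family | startsWith(o$names, paste0(family, ".")))) return(FALSE)
    ti <- vapply(o$parameters, `[[`, character(1), "type")
    if (family == "engine.create")
      o$shape == "function" && length(ti) == 2L &&
        bf_assignable(env$types, type, ti[1]) && bf_assignable(env$types, ti[2], type)
    else
      o$shape == "computer" && length(ti) == 2L &&
        bf_assignable(env$types, type, ti[1]) && bf_assignable(env$types, type, ti[2])
  }, env$ops)
  bf_pick(cands)
}

# Full brute-force match.  Returns a summary comparable to tree_summary(),
# or NULL when no routine yields a candidate.
brute_force_match <- function(env, req) {
  adapters <- Filter(function(o) !is.null(o$adapter), env$ops)
  plain <- Filter(function(o) is.null(o$adapter), env$ops)
  routines <- list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))
  for (fl in routines) {
    allow_ad <- fl[1]; allow_cv <- fl[2]
    combos <- list()
    for (cand_op in plain) {
      if (!(req$name %in% cand_op$names)) next
      ads <- if (allow_ad) adapters else list(NULL)
      for (ad in ads) {
        sig <- bf_signature(cand_op, ad, req)
        if (is.null(sig)) next
        if (allow_ad && is.null(ad)) next
        # adapter engine needs
        if (!is.null(sig$need)) {
          miss <- FALSE
          for (nd in sig$need)
            if (is.null(bf_engine_op(env, paste0("engine.", nd), sig$out))) miss <- TRUE
          if (miss) next
        }
        if (is.null(req$input_types)) {
          combos[[length(combos) + 1L]] <- list(op = cand_op, adapter = ad,
                                                convs = list(), outconv = NULL)
          next
        }
        if (length(sig$types) != length(req$input_types)) next
        if (req$shape == "computer" &&
            which(sig$ios == "container") != req$container_pos) next
        if (req$shape == "inplace" &&
            which(sig$ios == "mutable") != req$mutable_pos) next
        convs <- list(); ok <- TRUE
        for (i in seq_along(sig$types)) {
          if (bf_assignable(env$types, req$input_types[i], sig$types[i])) next
          if (!allow_cv) { ok <- FALSE; break }
          fwd <- bf_converter(env, req$input_types[i], sig$types[i])
          if (is.null(fwd)) { ok <- FALSE; break }
          if (sig$ios[i] %in% c("container", "mutable")) {
            back <- bf_converter(env, sig$types[i], req$input_types[i],
                                 loose_from = TRUE)
            cpy <- bf_engine_op(env, "engine.copy", req$input_types[i])
            if (is.null(back) || is.null(cpy)) { ok <- FALSE; break }
          }
          convs[[as.character(i)]] <- fwd
        }
        if (!ok) next
        outconv <- NULL
        if (!is.null(req$output_type) && req$shape == "function" &&
            !bf_assignable(env$types, sig$out, req$output_type)) {
          if (!allow_cv) next
          outconv <- bf_converter(env, sig$out, req$output_type)
          if (is.null(outconv)) next
        }
        n_wrap_conv <- length(convs) + (if (is.null(outconv)) 0L else 1L)
        if (allow_cv && n_wrap_conv == 0L) next
        combos[[length(combos) + 1L]] <- list(op = cand_op, adapter = ad,
                                              convs = convs, outconv = outconv)
      }
    }
    if (length(combos)) {
      key <- vapply(combos, function(cb) paste(
        c(cb$op$source, if (!is.null(cb$adapter)) cb$adapter$source,
          unlist(lapply(cb$convs, `[[`, "source")),
          if (!is.null(cb$outconv)) cb$outconv$source), collapse = ""),
        character(1))
      wrap <- vapply(combos, function(cb)
        length(cb$convs) + (if (is.null(cb$outconv)) 0L else 1L) +
          (if (is.null(cb$adapter)) 0L else 1L), integer(1))
      prio <- vapply(combos, function(cb) cb$op$priority, numeric(1))
      best <- combos[[order(-prio, wrap, key, method = "radix")[1]]]
      return(list(root = best$op$source, arity = length(best$op$parameters),
                  adapter = if (is.null(best$adapter)) NA_character_
                            else best$adapter$source,
                  convs = lapply(best$convs, `[[`, "source"),
                  outconv = if (is.null(best$outconv)) NA_character_
                            else best$outconv$source))
    }
  }
  NULL
}

# --- numeric oracles -------------------------------------------------------

# Dense (non-separable) 2-D Gaussian convolution with mirror borders.
dense_gauss_oracle <- function(values, sigma) {
  hw <- ceiling(4 * sigma)
  off <- seq(-hw, hw)
  k1 <- exp(-off^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  d <- dim(values)
  refl <- function(i, n) {
    if (n == 1L) return(rep(1L, length(i)))
    per <- 2L * n - 2L
    j <- (i - 1L) %% per
    ifelse(j >= n, per - j, j) + 1L
  }
  out <- array(0, dim = d)
  for (a in seq_along(off)) for (b in seq_along(off)) {
    ri <- refl(seq_len(d[1]) + off[a], d[1])
    ci <- refl(seq_len(d[2]) + off[b], d[2])
    out <- out + K[a, b] * values[ri, ci]
  }
  out
}

# Exhaustive Otsu: try all 255 split points on the 256-bin histogram.
otsu_oracle <- function(values, kind = "uint8") {
  v <- as.vector(values)
  if (kind == "uint8") { lo <- 0; hi <- 256 } else { lo <- min(v); hi <- max(v) }
  width <- (hi - lo) / 256
  idx <- pmin(floor((v - lo) / width), 255)
  counts <- tabulate(idx + 1L, nbins = 256)
  centers <- lo + width * (0:255 + 0.5)
  total <- length(v)
  vars <- vapply(1:255, function(t) {
    n0 <- sum(counts[1:t]); n1 <- total - n0
    if (n0 == 0 || n1 == 0) return(-Inf)
    mu0 <- sum(counts[1:t] * centers[1:t]) / n0
    mu1 <- sum(counts[(t + 1):256] * centers[(t + 1):256]) / n1
    (n0 / total) * (n1 / total) * (mu0 - mu1)^2
  }, numeric(1))
  t <- which.max(vars)
  if (kind == "uint8") t - 1 else lo + width * t
}

# Standard normal CDF by numeric integration of the density.
pnorm_oracle <- function(x) {
  vapply(x, function(z)
    stats::integrate(function(u) exp(-u^2 / 2) / sqrt(2 * pi), -Inf, z,
                     rel.tol = 1e-10)$value, numeric(1))
}

# Counting-loop histogram oracle.
hist_oracle <- function(values, lo, hi, bins) {
  counts <- integer(bins)
  width <- (hi - lo) / bins
  for (v in as.vector(values)) {
    i <- floor((v - lo) / width)
    if (i >= bins) i <- bins - 1
    counts[i + 1L] <- counts[i + 1L] + 1L
  }
  counts
}
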