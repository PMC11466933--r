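# Fixture builders shared across the suite.  Everything is generated in
# code; seeds are fixed per call site.

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_img <- function(shape, seed, kind = "float64") {
  with_seed(seed, {
    v <- if (kind == "uint8") array(sample(0:255, prod(shape), TRUE), dim = shape)
    else array(stats::rnorm(prod(shape), 50, 20), dim = shape)
    dense_image(v, kind)
  })
}

# A 5-op fixture descriptor exercising every shape, optionals, aliases and
# dependencies; used by the YAML round-trip tests.
fixture_descriptor_infos <- function() {
  list(
    op_info("copy.array", "computer",
            list(param_spec("input", "byte-seq"),
                 param_spec("output", "byte-seq", io = "container")),
            source = "fixmod:copy_array",
            description = "byte-wise array copy"),
    op_info(c("math.add", "math.plus"), "function",
            list(param_spec("a", "real"), param_spec("b", "real"),
                 param_spec("sum", "real", io = "output")),
            priority = 2.5, source = "fixmod:add2"),
    op_info("filter.fft", "function",
            list(param_spec("input", "dense-image"),
                 param_spec("fftType", "text"),
                 param_spec("borderSize", "integer", optional = TRUE, default = 0L),
                 param_spec("fast", "boolean", optional = TRUE, default = TRUE),
                 param_spec("output", "complex-grid", io = "output")),
            source = "fixmod:fft"),
    op_info("touch.first", "inplace",
            list(param_spec("data", "byte-seq", io = "mutable")),
            source = "fixmod:touch", priority = -1),
    op_info("filter.dog", "function",
            list(param_spec("input", "dense-image"),
                 param_spec("sigma1", "real"), param_spec("sigma2", "real"),
                 param_spec("output", "dense-image", io = "output")),
            source = "fixmod:dog",
            dependencies = list(
              dep_spec("gauss1", "filter.gauss", "function",
                       input_types = c("dense-image", "real"),
                       output_type = "dense-image"),
              dep_spec("sub", "math.sub", "function"))))
}

# Minimal registry for matcher tests: abstract top, two image-ish types, two
# scalar types with an edge.
tiny_registry <- function() {
  reg <- type_registry()
  register_type(reg, "top")
  for (t in c("t1", "t2", "t3", "t4")) register_type(reg, t, parent = "top")
  register_type(reg, "t1sub", parent = "t1")
  reg
}

dummy_impl <- function(...) NULL

# Random matcher environment of <= 10 ops over a random type DAG, plus a
# random subset of engine ops (shape adapters, converters, create, copy).
# Returns list(env, request) -- impls are dummies; matching only.
make_random_env <- function(seed) {
  with_seed(seed, {
    reg <- type_registry()
    ntype <- sample(4:6, 1)
    tnames <- paste0("T", seq_len(ntype))
    for (i in seq_len(ntype)) {
      parents <- if (i == 1L) NULL else {
        cand <- tnames[seq_len(i - 1L)]
        cand[stats::runif(length(cand)) < 0.4]
      }
      register_type(reg, tnames[i], parent = parents)
    }
    env <- op_environment(types = reg)
    pool <- c("alpha.op", "beta.op")
    shapes <- c("function", "computer", "inplace")
    n_plain <- sample(2:5, 1)
    for (i in seq_len(n_plain)) {
      shape <- sample(shapes, 1)
      arity <- sample(1:2, 1)
      ins <- sample(tnames, arity, replace = TRUE)
      params <- lapply(seq_along(ins), function(k)
        param_spec(paste0("p", k), ins[k]))
      if (shape == "function")
        params <- c(params, list(param_spec("out", sample(tnames, 1), io = "output")))
      if (shape == "computer")
        params <- c(params, list(param_spec("cont", sample(tnames, 1), io = "container")))
      if (shape == "inplace") params[[1]]$io <- "mutable"
      info <- op_info(sample(pool, 1), shape, params,
                      priority = sample(c(0, 0, 1, 10), 1),
                      source = sprintf("rnd%03d:op%d", seed %% 1000, i))
      register_op(env, info, impl = dummy_impl)
    }
    # engine helpers
    adapter_defs <- list(
      list(nm = "engine.adapt.c2f", from = "computer", to = "function"),
      list(nm = "engine.adapt.f2c", from = "function", to = "computer"),
      list(nm = "engine.adapt.i2f", from = "inplace", to = "function"),
      list(nm = "engine.adapt.i2c", from = "inplace", to = "computer"),
      list(nm = "engine.adapt.c2i", from = "computer", to = "inplace"))
    for (ad in adapter_defs[stats::runif(5) < 0.7]) {
      info <- op_info(c("engine.adapt", ad$nm), "function",
                      list(param_spec("op", "T1"),
                           param_spec("adapted", "T1", io = "output")),
                      source = paste0("rnd:", ad$nm),
                      adapter = list(from = ad$from, to = ad$to, kind = "shape"))
      register_op(env, info, impl = dummy_impl)
    }
    n_conv <- sample(0:3, 1)
    for (i in seq_len(n_conv)) {
      ft <- sample(tnames, 2)
      info <- op_info(c("engine.convert", sprintf("engine.convert.c%d", i)),
                      "function",
                      list(param_spec("input", ft[1]),
                           param_spec("output", ft[2], io = "output")),
                      source = sprintf("rnd:conv%d", i))
      register_op(env, info, impl = dummy_impl)
    }
    for (t in tnames[stats::runif(ntype) < 0.5]) {
      register_op(env, op_info(
        c("engine.create", "engine.create.like"), "function",
        list(param_spec("reference", t), param_spec("output", t, io = "output")),
        source = paste0("rnd:create_", t)), impl = dummy_impl)
    }
    for (t in tnames[stats::runif(ntype) < 0.5]) {
      register_op(env, op_info(
        "engine.copy", "computer",
        list(param_spec("source", t), param_spec("target", t, io = "container")),
        source = paste0("rnd:copy_", t)), impl = dummy_impl)
    }
    shape <- sample(shapes, 1)
    arity <- sample(1:2, 1)
    req <- op_request(sample(pool, 1), shape,
                      input_types = sample(tnames, arity, replace = TRUE),
                      output_type = if (shape == "function" &&
                                        stats::runif(1) < 0.5) sample(tnames, 1),
                      container_pos = if (shape == "computer") arity,
                      mutable_pos = if (shape == "inplace") 1L)
    list(env = env, request = req)
  })
}

# Flat summary of a resolved tree for oracle comparison.
tree_summary <- function(tree) {
  list(root = tree$root$source,
       arity = length(tree$root$parameters),
       adapter = if (is.null(tree$adapter)) NA_character_ else tree$adapter$source,
       convs = lapply(tree$conversions, function(cv) cv$forward$root$source),
       outconv = if (is.null(tree$output_conversion)) NA_character_
                 else tree$output_conversion$root$source)
}
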