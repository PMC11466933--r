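test_that("assignability is reflexive, follows edges, and matches a closure oracle", {
  reg <- tiny_registry()
  expect_true(assignable(reg, "t1", "t1"))
  expect_true(assignable(reg, "t1sub", "t1"))
  expect_true(assignable(reg, "t1sub", "top"))
  expect_false(assignable(reg, "t1", "t2"))
  expect_error(assignable(reg, "nope", "t1"), "unregistered type")

  # random 30-type DAG vs Floyd-Warshall closure
  with_seed(42, {
    reg2 <- type_registry()
    nms <- sprintf("n%02d", 1:30)
    A <- matrix(FALSE, 30, 30, dimnames = list(nms, nms))
    for (i in 1:30) {
      parents <- if (i > 1) nms[seq_len(i - 1)][stats::runif(i - 1) < 0.1]
      register_type(reg2, nms[i], parent = parents)
      A[nms[i], parents] <- TRUE
    }
    C <- A | diag(TRUE, 30)
    for (k in 1:30) C <- C | (C[, k] %o% C[k, ])   # Floyd-Warshall closure
    for (i in 1:30) for (j in 1:30)
      if (assignable(reg2, nms[i], nms[j]) != C[i, j])
        fail(sprintf("disagreement at %s -> %s", nms[i], nms[j]))
    succeed()
  })
})

test_that("direct matching respects name, shape and types; single candidate wins", {
  reg <- tiny_registry()
  env <- op_environment(types = reg)
  info <- op_info("math.add", "function",
                  list(param_spec("a", "t1"), param_spec("b", "t1"),
                       param_spec("out", "t1", io = "output")),
                  source = "m:add")
  register_op(env, info, impl = function(a, b) NULL)
  tree <- op_match(env, op_request("math.add", "function", c("t1", "t1"), "t1"))
  expect_s3_class(tree, "info_tree")
  expect_equal(tree$root$source, "m:add")
  expect_null(tree$adapter)
  expect_length(tree$conversions, 0)
  # subtype arguments are accepted directly
  t2 <- op_match(env, op_request("math.add", "function", c("t1sub", "t1")))
  expect_equal(t2$root$source, "m:add")
  # mismatches fail with a routine-by-routine near-miss report
  expect_error(op_match(env, op_request("math.add", "function", c("t2", "t1"))),
               "match failure.*near misses.*not assignable")
  expect_error(op_match(env, op_request("math.mul", "function", c("t1", "t1"))),
               "match failure")
})

test_that("dependency trees are resolved recursively through the engine", {
  env <- default_ops_env()
  tree <- op_match(env, op_request("filter.dog", "function",
                                   c("dense-image", "real", "real"),
                                   "dense-image"))
  expect_equal(sort(names(tree$dependencies)), c("gauss1", "gauss2", "sub"))
  # two gauss nodes reached through computer->function adaptation
  g <- tree$dependencies$gauss1
  expect_true("filter.gauss" %in% g$root$names)
  expect_equal(g$adapter$adapter$from, "computer")
  # the sub dependency is the scalar op lifted element-wise
  s <- tree$dependencies$sub
  expect_true("math.sub" %in% s$root$names)
  expect_equal(s$adapter$adapter$kind, "lift")
  expect_equal(opsmatch:::info_tree_count(tree, "filter.gauss"), 2L)
  expect_equal(opsmatch:::info_tree_count(tree, "math.sub"), 1L)
})

test_that("routine precedence: a direct candidate beats any adapted or converted one", {
  env <- default_ops_env()
  # only an element-wise scalar math.sub exists: image request adapts (lift)
  tree <- op_match(env, op_request("math.sub", "function",
                                   c("dense-image", "dense-image")))
  expect_equal(tree$adapter$adapter$kind, "lift")
  # register a native image subtraction: direct now wins despite priority 0
  register_op(env, op_info(
    "math.sub", "function",
    list(param_spec("a", "dense-image"), param_spec("b", "dense-image"),
         param_spec("out", "dense-image", io = "output")),
    source = "native:subimg"),
    impl = function(a, b) {
      out <- dense_image(img_values(a) - img_values(b), img_kind(a)); out
    })
  tree2 <- op_match(env, op_request("math.sub", "function",
                                    c("dense-image", "dense-image")))
  expect_null(tree2$adapter)
  expect_equal(tree2$root$source, "native:subimg")
})

test_that("ranking: priority, then wrapper count, then source; permutation invariant", {
  mk <- function(p, w, s) list(priority = p, wrappers = as.integer(w),
                               source_key = s)
  cands <- list(mk(100, 2, "zzz"), mk(0, 0, "aaa"))
  expect_equal(rank_candidates(cands)[[1]]$priority, 100)
  cands <- list(mk(0, 2, "aaa"), mk(0, 0, "zzz"))
  expect_equal(rank_candidates(cands)[[1]]$wrappers, 0L)
  with_seed(7, {
    pool <- lapply(1:20, function(i)
      mk(sample(c(0, 1, 10), 1), sample(0:3, 1), sprintf("s%02d", i)))
    ranked <- rank_candidates(pool)
    for (k in 1:5) {
      perm <- sample(pool)
      expect_identical(rank_candidates(perm), ranked)
    }
  })
})

test_that("matching agrees with the brute-force enumeration oracle", {
  agree <- 0L
  for (seed in 1:60) {
    fx <- make_random_env(seed)
    got <- tryCatch(tree_summary(op_match(fx$env, fx$request)),
                    error = function(e) NULL)
    want <- brute_force_match(fx$env, fx$request)
    expect_identical(got, want,
                     info = sprintf("random environment seed %d", seed))
    agree <- agree + 1L
  }
  expect_equal(agree, 60L)
})

test_that("matching is deterministic under registration-order shuffles", {
  fx <- make_random_env(101)
  baseline <- tryCatch(info_tree_format(op_match(fx$env, fx$request)),
                       error = function(e) paste("ERR", conditionMessage(e)))
  ops <- fx$env$ops
  for (k in 1:5) {
    with_seed(2000 + k, {
      env2 <- op_environment(types = fx$env$types)
      for (o in sample(Filter(function(x) is.null(x$reduced_from), ops)))
        register_op(env2, o, impl = dummy_impl)
      got <- tryCatch(info_tree_format(op_match(env2, fx$request)),
                      error = function(e) paste("ERR", conditionMessage(e)))
      expect_identical(got, baseline, info = sprintf("shuffle %d", k))
    })
  }
})

test_that("the match cache is transparent and invalidated by mutation", {
  env <- default_ops_env()
  req <- op_request("math.add", "function", c("integer", "integer"))
  t1 <- op_match_cached(env, req)
  t2 <- op_match_cached(env, req)
  expect_identical(info_tree_format(t1), info_tree_format(t2))
  expect_true(exists(request_key(req), envir = env$cache))
  # registering a higher-priority implementation invalidates and rebinds
  register_op(env, op_info(
    "math.add", "function",
    list(param_spec("a", "real"), param_spec("b", "real"),
         param_spec("out", "real", io = "output")),
    priority = 100, source = "fast:add"), impl = function(a, b) a + b)
  t3 <- op_match_cached(env, req)
  expect_equal(t3$root$source, "fast:add")

  # cold/warm equivalence over random requests interleaved with mutations
  envA <- default_ops_env(cache_enabled = TRUE)
  envB <- default_ops_env(cache_enabled = FALSE)
  reqs <- list(
    op_request("filter.gauss", "computer",
               c("dense-image", "real", "dense-image"), container_pos = 3L),
    op_request("math.mul", "function", c("real", "real")),
    op_request("filter.dog", "function", c("dense-image", "real", "real")),
    op_request("benchmark.increment", "inplace", "byte-seq", mutable_pos = 1L))
  spice <- op_info("math.mul", "function",
                   list(param_spec("a", "real"), param_spec("b", "real"),
                        param_spec("out", "real", io = "output")),
                   priority = 50, source = "fast:mul")
  for (step in 1:12) {
    r <- reqs[[(step - 1L) %% length(reqs) + 1L]]
    fa <- info_tree_format(op_match_cached(envA, r))
    fb <- info_tree_format(op_match_cached(envB, r))
    expect_identical(fa, fb, info = sprintf("step %d", step))
    if (step == 6L) {
      register_op(envA, spice, impl = function(a, b) a * b)
      register_op(envB, spice, impl = function(a, b) a * b)
    }
  }
})

test_that("dependency cycles and depth overruns are reported", {
  reg <- tiny_registry()
  env <- op_environment(types = reg)
  mk <- function(name, dep, src) op_info(
    name, "function",
    list(param_spec("x", "t1"), param_spec("out", "t1", io = "output")),
    source = src,
    dependencies = list(dep_spec("d", dep, "function")))
  register_op(env, mk("a.x", "b.y", "m:ax"), impl = dummy_impl)
  register_op(env, mk("b.y", "a.x", "m:by"), impl = dummy_impl)
  expect_error(op_match(env, op_request("a.x", "function", "t1")),
               "cycle error.*m:ax.*m:by")

  env2 <- op_environment(types = reg)
  # self-dependency is the smallest cycle
  register_op(env2, mk("c.z", "c.z", "m:cz"), impl = dummy_impl)
  expect_error(op_match(env2, op_request("c.z", "function", "t1")),
               "cycle error")
})

test_that("wildcard requests resolve dependencies by name and shape alone", {
  reg <- tiny_registry()
  env <- op_environment(types = reg)
  register_op(env, op_info("helper.h", "function",
                           list(param_spec("x", "t2"),
                                param_spec("out", "t2", io = "output")),
                           source = "m:h1"), impl = dummy_impl)
  register_op(env, op_info("helper.h", "function",
                           list(param_spec("x", "t3"),
                                param_spec("out", "t3", io = "output")),
                           priority = 5, source = "m:h2"), impl = dummy_impl)
  register_op(env, op_info(
    "main.op", "function",
    list(param_spec("x", "t1"), param_spec("out", "t1", io = "output")),
    source = "m:main",
    dependencies = list(dep_spec("h", "helper.h", "function"))),
    impl = dummy_impl)
  tree <- op_match(env, op_request("main.op", "function", "t1"))
  # wildcard dependency: priority decides among same-name candidates
  expect_equal(tree$dependencies$h$root$source, "m:h2")
})
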