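test_that("descriptor parsing builds OpInfos with defaults applied", {
  txt <- '
version: "1"
ops:
  - names: [copy.array]
    type: computer
    source: "fixmod:copy_array"
    parameters:
      - {name: input, type: byte-seq, io: input}
      - {name: output, type: byte-seq, io: container}
'
  infos <- parse_descriptor(txt)
  expect_length(infos, 1)
  info <- infos[[1]]
  expect_equal(info$names, "copy.array")
  expect_equal(info$shape, "computer")
  expect_equal(info$priority, 0)
  expect_equal(vapply(info$parameters, `[[`, character(1), "io"),
               c("input", "container"))
  expect_false(info$parameters[[1]]$optional)

  expect_length(parse_descriptor('version: "1"\nops: []'), 0)
})

test_that("descriptor schema errors name the offending entry and key", {
  expect_error(parse_descriptor("ops:\n  - {names: [a.b], type: function}"),
               "missing mandatory key 'source'.*a\\.b")
  expect_error(parse_descriptor("ops:\n  - {type: function}"),
               "missing mandatory key 'names'.*entry 1")
  expect_error(parse_descriptor("ops:\n  - bad: ["), "YAML parse error")
  expect_warning(
    parse_descriptor('
ops:
  - names: [a.b]
    type: inplace
    source: "m:f"
    wibble: 1
    parameters:
      - {name: x, type: byte-seq, io: mutable}
'), "unknown keys.*wibble")
})

test_that("emit/parse round-trip reproduces the OpInfo list field-by-field", {
  infos <- fixture_descriptor_infos()
  txt <- emit_descriptor(infos)
  expect_match(txt, "type: function")
  back <- parse_descriptor(txt)
  expect_length(back, length(infos))
  for (i in seq_along(infos)) {
    expect_true(opsmatch:::op_info_equal(infos[[i]], back[[i]]),
                info = sprintf("fixture op %d round-trips", i))
  }
  # emitting zero infos still yields a parseable empty descriptor
  expect_length(parse_descriptor(emit_descriptor(list())), 0)
})

test_that("round-trip holds for randomly generated OpInfos", {
  shapes <- c("function", "computer", "inplace")
  types <- c("real", "integer", "dense-image", "byte-seq", "text")
  gen_info <- function(i) {
    with_seed(1000 + i, {
      shape <- sample(shapes, 1)
      arity <- sample(1:3, 1)
      params <- lapply(seq_len(arity), function(k)
        param_spec(paste0("p", k), sample(types, 1),
                   description = sample(c("", "doc"), 1)))
      params <- switch(shape,
        "function" = c(params, list(param_spec("out", sample(types, 1),
                                               io = "output"))),
        "computer" = c(params, list(param_spec("cont", sample(types, 1),
                                               io = "container"))),
        "inplace" = { params[[1]]$io <- "mutable"; params })
      op_info(paste0("ns.op", i), shape, params,
              priority = sample(c(-1, 0, 2.5, 100), 1),
              source = sprintf("mod%d:fn%d", i, i))
    })
  }
  infos <- lapply(1:10, gen_info)
  back <- parse_descriptor(emit_descriptor(infos))
  for (i in 1:10)
    expect_true(opsmatch:::op_info_equal(infos[[i]], back[[i]]),
                info = sprintf("random op %d", i))
})

test_that("OpInfo invariants are enforced", {
  # function op needs exactly one output
  expect_error(op_info("a.b", "function",
                       list(param_spec("x", "real")), source = "m:f"),
               "wrong io roles")
  # computer may not declare an output
  expect_error(op_info("a.b", "computer",
                       list(param_spec("x", "real", io = "output"),
                            param_spec("c", "real", io = "container")),
               source = "m:f"), "wrong io roles")
  # duplicate parameter names
  expect_error(op_info("a.b", "inplace",
                       list(param_spec("x", "real", io = "mutable"),
                            param_spec("x", "real")), source = "m:f"),
               "duplicate parameter names")
  # optional only on inputs
  expect_error(op_info("a.b", "computer",
                       list(param_spec("x", "real"),
                            param_spec("c", "real", io = "container",
                                       optional = TRUE)), source = "m:f"),
               "optional only allowed on inputs")
})

test_that("annotation indexing reproduces a hand-written descriptor", {
  src <- '
#\' Copies a byte array element-wise.
#\' @param input (byte-seq) source array
#\' @container output (byte-seq) destination array
#\' @implNote op names="copy.array" type=computer
copy_array <- function(input, output) NULL

# untagged helper, must be ignored
plain <- function(x) x

#\' Adds two numbers.
#\' @param a (real) first addend
#\' @param b (real) second addend
#\' @return (real) the sum
#\' @implNote op names="math.add,math.plus" type=function priority=2.5
add2 <- function(a, b) a + b

#\' Blurs with an optional width.
#\' @param img (dense-image) input
#\' @param sigma (real, optional=2) kernel width
#\' @return (dense-image) blurred
#\' @implNote op names="filter.blur" type=function
blur <- function(img, sigma = 2) img
'
  yaml_out <- index_annotations(list(fixmod = src))
  infos <- parse_descriptor(yaml_out)
  expect_length(infos, 3)
  expect_equal(infos[[1]]$names, "copy.array")
  expect_equal(infos[[1]]$shape, "computer")
  expect_equal(infos[[1]]$source, "fixmod:copy_array")
  expect_equal(vapply(infos[[1]]$parameters, `[[`, character(1), "io"),
               c("input", "container"))
  expect_equal(infos[[2]]$names, c("math.add", "math.plus"))
  expect_equal(infos[[2]]$priority, 2.5)
  expect_true(infos[[3]]$parameters[[2]]$optional)
  expect_equal(infos[[3]]$parameters[[2]]$default, 2)

  # manual transcription oracle: hand-written op_info equals the indexed one
  manual <- op_info(c("math.add", "math.plus"), "function",
                    list(param_spec("a", "real", description = "first addend"),
                         param_spec("b", "real", description = "second addend"),
                         param_spec("output", "real", io = "output",
                                    description = "the sum")),
                    priority = 2.5, source = "fixmod:add2",
                    description = "Adds two numbers.")
  expect_true(opsmatch:::op_info_equal(manual, infos[[2]]))

  # idempotence: indexing the same sources twice yields identical YAML text
  expect_identical(yaml_out, index_annotations(list(fixmod = src)))
  # no tags -> empty descriptor
  expect_length(parse_descriptor(index_annotations("x <- function(i) i")), 0)
})

test_that("indexer reports unparseable annotations and duplicate names", {
  bad <- '
#\' @param a () broken
#\' @implNote op names="x.y" type=function
f <- function(a) a
'
  expect_error(index_annotations(bad), "indexing error.*'f'")
  dup <- '
#\' @param a (real) in
#\' @return (real) out
#\' @implNote op names="x.y" type=function
f <- function(a) a

#\' @param a (real) in
#\' @return (real) out
#\' @implNote op names="x.y" type=function
g <- function(a) a
'
  expect_warning(yaml_out <- index_annotations(dup), "duplicate op names.*x\\.y")
  expect_length(parse_descriptor(yaml_out), 2)
})

test_that("optional-parameter reduction drops trailing optionals right to left", {
  fft <- fixture_descriptor_infos()[[3]]
  forms <- reduce_optional(fft)
  expect_length(forms, 3)
  expect_identical(forms[[1]], fft)
  arities <- vapply(forms, function(f)
    sum(vapply(f$parameters, function(p) p$io == "input", logical(1))),
    integer(1))
  expect_equal(arities, c(4L, 3L, 2L))
  nm2 <- vapply(forms[[2]]$parameters, `[[`, character(1), "name")
  expect_equal(nm2, c("input", "fftType", "borderSize", "output"))
  expect_true(opsmatch:::op_info_equal(forms[[2]]$reduced_from, fft))
  expect_equal(vapply(forms[[3]]$dropped, `[[`, integer(1), "position"), 3:4)
  # reduced signatures inherit priority unchanged
  expect_equal(unique(vapply(forms, `[[`, numeric(1), "priority")), fft$priority)

  # no optionals -> just the op itself
  add <- fixture_descriptor_infos()[[2]]
  expect_length(reduce_optional(add), 1)
})

test_that("reduction matches brute-force prefix enumeration and skips stranded optionals", {
  # 3 trailing optionals -> 4 signatures, equal to enumerating right-to-left
  # prefixes by hand
  info <- op_info("x.y", "function",
                  list(param_spec("a", "real"),
                       param_spec("o1", "real", optional = TRUE, default = 1),
                       param_spec("o2", "real", optional = TRUE, default = 2),
                       param_spec("o3", "real", optional = TRUE, default = 3),
                       param_spec("out", "real", io = "output")),
                  source = "m:f")
  forms <- reduce_optional(info)
  prefix_names <- lapply(0:3, function(k)
    c("a", if (k < 3) paste0("o", seq_len(3 - k))))
  got_names <- lapply(forms, function(f)
    setdiff(vapply(f$parameters, `[[`, character(1), "name"), "out"))
  expect_equal(got_names, prefix_names)

  # an optional followed by a required one is never dropped
  stranded <- op_info("x.z", "function",
                      list(param_spec("o1", "real", optional = TRUE, default = 1),
                           param_spec("b", "real"),
                           param_spec("out", "real", io = "output")),
                      source = "m:g")
  expect_length(reduce_optional(stranded), 1)

  # droppable optional without default is a validation error
  expect_error(reduce_optional(
    op_info("x.w", "function",
            list(param_spec("a", "real"),
                 param_spec("o", "real", optional = TRUE),
                 param_spec("out", "real", io = "output")),
            source = "m:h")),
    "without default")
})
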