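# Implementations behind the engine-support op collection.  Every one of
# these is registered through the same YAML descriptor mechanism as any
# other op (inst/ops/base-ops.yaml); the engine discovers create/copy/
# convert/adapt helpers from the environment, never from hard-coded links.

# engine.create.like -- new object, same shape/kind, all zero, no storage
# shared with the reference.
.op_create_like_dense <- function(reference) {
  dense_image(array(0, dim = img_shape(reference)), img_kind(reference))
}

.op_create_like_planar <- function(reference) {
  planar_image(lapply(reference$planes, function(p) array(0, dim = dim(p))),
               reference$element_kind)
}

.op_create_like_byte <- function(reference) byte_seq(rep(0, length(reference$values)))

.op_create_like_real <- function(reference) real_seq(rep(0, length(reference$values)))

# engine.copy -- target elements overwritten with source's; source untouched.
.op_copy_dense <- function(source, target) {
  if (!identical(img_shape(source), img_shape(target)))
    stop("dimension error: copy shapes ",
         paste(img_shape(source), collapse = "x"), " vs ",
         paste(img_shape(target), collapse = "x"))
  img_set_values(target, img_values(source))
  invisible(target)
}

.op_copy_planar <- function(source, target) {
  if (!identical(source$plane_shape, target$plane_shape) ||
      length(source$planes) != length(target$planes))
    stop("dimension error: planar copy shape mismatch")
  target$planes <- lapply(source$planes, function(p)
    cast_kind(p, target$element_kind))
  invisible(target)
}

.op_copy_byte <- function(source, target) {
  if (length(source$values) != length(target$values))
    stop("dimension error: sequence lengths ", length(source$values), " vs ",
         length(target$values))
  target$values <- pmin(255, pmax(0, floor(source$values + 0.5)))
  invisible(target)
}

.op_copy_real <- function(source, target) {
  if (length(source$values) != length(target$values))
    stop("dimension error: sequence lengths ", length(source$values), " vs ",
         length(target$values))
  target$values <- as.double(source$values)
  invisible(target)
}

# engine.convert -- single-hop parameter converters.
.op_convert_planar_dense <- function(x) dense_from_planar(x)
.op_convert_dense_planar <- function(x) planar_from_dense(x)
.op_convert_byte_real <- function(x) real_seq(x$values)
.op_convert_real_byte <- function(x) byte_seq(pmin(255, pmax(0, floor(x$values + 0.5))))

# scalar math ops; exact arithmetic in the widest argument kind
.op_math_add <- function(a, b) a + b
.op_math_sub <- function(a, b) a - b
.op_math_mul <- function(a, b) a * b
.op_math_div <- function(a, b) {
  if (b == 0) stop("arithmetic error: division by zero")
  a / b
}

# benchmark.increment -- first element incremented modulo 256 (unsigned
# byte wraparound), everything else untouched.
.op_benchmark_increment <- function(data) {
  if (!length(data$values)) stop("precondition error: empty sequence")
  data$values[1] <- (data$values[1] + 1) %% 256
  invisible(data)
}

# engine.describe -- pure lookups mapping type names to simple names
.op_describe_image <- function(type_name) "image"
.op_describe_number <- function(type_name) "number"
.op_describe_sequence <- function(type_name) "sequence"
.op_describe_text <- function(type_name) "text"
.op_describe_boolean <- function(type_name) "boolean"
.op_describe_grid <- function(type_name) "frequency grid"
.op_describe_histogram <- function(type_name) "histogram"
.op_describe_threshold <- function(type_name) "threshold result"
.op_describe_intvec <- function(type_name) "integer list"

# engine.adapt -- the wrapping logic lives in the engine executor; these
# entries exist so adapters are ordinary, discoverable, removable ops.
.op_adapt_marker <- function(op) {
  stop("engine.adapt ops are applied by the matching engine, not called directly")
}

#' Default type registry
#'
#' Registers the semantic types the shipped op collections use: scalar
#' numbers (`integer` < `real` < `number`), booleans and text, the two image
#' representations (`dense-image` and `planar-image` under `image`, with
#' `volume` the 3-D dense subtype), mutable byte/real sequences, and the
#' result containers (histogram, threshold result, frequency grid).
#' Recognizers map runtime values to the most specific type; element types
#' drive element-wise lifting.
#'
#' @return a [type_registry()].
#' @export
default_type_registry <- function() {
  reg <- type_registry()
  is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L &&
    is.null(dim(x)) && !is.environment(x)
  register_type(reg, "number", description = "number",
                recognizer = is_scalar_num)
  register_type(reg, "real", parent = "number", description = "number",
                recognizer = is_scalar_num)
  register_type(reg, "integer", parent = "real", description = "number",
                recognizer = function(x) is_scalar_num(x) && is.finite(x) &&
                  x == floor(x))
  register_type(reg, "boolean", description = "boolean",
                recognizer = function(x) is.logical(x) && length(x) == 1L)
  register_type(reg, "text", description = "text",
                recognizer = function(x) is.character(x) && length(x) == 1L)
  register_type(reg, "int-vector", description = "integer list",
                recognizer = function(x) is.numeric(x) && length(x) > 1L &&
                  is.null(dim(x)) && all(x == floor(x)))
  register_type(reg, "image", description = "image")
  register_type(reg, "dense-image", parent = "image", description = "image",
                recognizer = function(x) inherits(x, "dense_image"),
                element_type = "real")
  register_type(reg, "volume", parent = "dense-image", description = "image",
                recognizer = function(x) inherits(x, "dense_image") &&
                  length(dim(x$values)) == 3L,
                element_type = "real")
  register_type(reg, "planar-image", parent = "image", description = "image",
                recognizer = function(x) inherits(x, "planar_image"),
                element_type = "real")
  register_type(reg, "sequence", description = "sequence")
  register_type(reg, "byte-seq", parent = "sequence", description = "sequence",
                recognizer = function(x) inherits(x, "byte_seq"),
                element_type = "integer")
  register_type(reg, "real-seq", parent = "sequence", description = "sequence",
                recognizer = function(x) inherits(x, "real_seq"),
                element_type = "real")
  register_type(reg, "op-executable", description = "op")
  register_type(reg, "complex-grid", description = "frequency grid",
                recognizer = function(x) is.complex(x) && !is.null(dim(x)))
  register_type(reg, "histogram", description = "histogram",
                recognizer = function(x) inherits(x, "ops_histogram"))
  register_type(reg, "threshold-result", description = "threshold result",
                recognizer = function(x) inherits(x, "ops_threshold"))
  reg
}

#' Default op environment
#'
#' An [op_environment()] with the default type registry and the two shipped
#' descriptor files registered: the engine-support collection
#' (`base-ops.yaml`: create/copy/convert/adapt/describe helpers, scalar
#' math, `benchmark.increment`) and the image-processing collection
#' (`image-ops.yaml`: Gaussian and Difference-of-Gaussians filtering,
#' histogram, Otsu threshold, FFT, normal CDF, significance mask, synthetic
#' fixture generator).
#'
#' @param cache_enabled should the match cache be consulted?
#' @param log_level logging threshold.
#' @return an `op_environment`.
#' @export
default_ops_env <- function(cache_enabled = TRUE, log_level = "warn") {
  env <- op_environment(types = default_type_registry(),
                        cache_enabled = cache_enabled, log_level = log_level)
  for (f in c("base-ops.yaml", "image-ops.yaml")) {
    path <- system.file("ops", f, package = "opsmatch")
    if (!nzchar(path)) stop("descriptor not found: ", f)
    register_descriptor(env, paste(readLines(path), collapse = "\n"))
  }
  env
}
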