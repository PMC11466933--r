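# --- Gaussian filtering ----------------------------------------------------

# Normalized discrete Gaussian, half-width ceil(4*sigma).
gauss_kernel <- function(sigma) {
  hw <- ceiling(4 * sigma)
  x <- seq(-hw, hw)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# 0-based mirror reflection (no edge duplication): ... 2 1 0 1 2 ... n-2 n-1 n-2 ...
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  period <- 2L * n - 2L
  j <- i %% period
  ifelse(j >= n, period - j, j)
}

# n x n convolution matrix for one axis with mirror boundary.
conv_matrix <- function(n, kernel) {
  hw <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (t in seq_along(kernel)) {
    off <- t - hw - 1L
    src <- mirror_index(seq_len(n) - 1L + off, n) + 1L
    for (out in seq_len(n)) M[out, src[out]] <- M[out, src[out]] + kernel[t]
  }
  M
}

# Apply a convolution matrix along one axis of an n-d array.
apply_axis <- function(arr, axis, M) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  dm <- dim(a)
  mat <- matrix(a, nrow = dm[1])
  res <- M %*% mat
  dim(res) <- dm
  aperm(res, order(perm))
}

#' Separable Gaussian blur
#'
#' Convolves each axis with a normalized discrete Gaussian kernel of
#' half-width `ceil(4 * sigma)` using mirror boundary handling.  All
#' accumulation happens in float64; the result is cast to the output's
#' element kind at the end (uint8 rounds half-up and clamps).
#'
#' Registered as the `filter.gauss` computer op; `image_gauss()` is the
#' allocating convenience form.
#'
#' @param input a [dense_image()].
#' @param sigma positive standard deviation, either one value (isotropic)
#'   or one per axis.
#' @param output pre-allocated container of the same shape.
#' @return the container (`.op_gauss`) / a new image (`image_gauss`).
#' @export
image_gauss <- function(input, sigma) {
  out <- .op_create_like_dense(input)
  .op_gauss(input, sigma, out)
  out
}

.op_gauss <- function(input, sigma, output) {
  if (any(sigma <= 0)) stop("parameter error: sigma must be positive")
  v <- img_values(input)
  d <- dim(v)
  if (!identical(d, img_shape(output)))
    stop("dimension error: input and container shapes differ")
  sig <- if (length(sigma) == 1L) rep(sigma, length(d)) else sigma
  if (length(sig) != length(d))
    stop("parameter error: sigma must be scalar or one per axis")
  for (ax in seq_along(d)) {
    v <- apply_axis(v, ax, conv_matrix(d[ax], gauss_kernel(sig[ax])))
  }
  img_set_values(output, v)
  invisible(output)
}

# Difference of Gaussians; all three steps are engine-resolved dependencies,
# never hard-linked.
.op_dog <- function(input, sigma1, sigma2, .deps) {
  a <- .deps$gauss1(input, sigma1)
  b <- .deps$gauss2(input, sigma2)
  .deps$sub(a, b)
}

# --- histogram and Otsu ----------------------------------------------------

#' Intensity histogram
#'
#' uint8 images bin over the fixed range \[0, 256); float images over
#' `[min, max]` with the last bin right-closed.  Bin assignment is
#' `floor((v - lo) / width)`; counts always sum to the element count.
#'
#' @param input a [dense_image()].
#' @param bins number of bins (>= 2); default 256.
#' @return an `ops_histogram`: `bin_edges` (length `bins + 1`) and `counts`.
#' @export
image_histogram <- function(input, bins = 256L) {
  if (bins < 2) stop("parameter error: bins must be >= 2")
  bins <- as.integer(bins)
  v <- as.vector(img_values(input))
  if (img_kind(input) == "uint8") { lo <- 0; hi <- 256 }
  else { lo <- min(v); hi <- max(v) }
  if (hi == lo) hi <- lo + 1           # constant float image: single-value bin
  width <- (hi - lo) / bins
  idx <- floor((v - lo) / width)
  idx[idx >= bins] <- bins - 1         # right-closed last bin
  counts <- tabulate(idx + 1L, nbins = bins)
  structure(list(bin_edges = lo + width * (0:bins), counts = counts),
            class = "ops_histogram")
}

.op_histogram <- function(input, bins = 256L) image_histogram(input, bins)

#' Otsu threshold
#'
#' Maximizes the between-class variance over the 256-bin histogram of the
#' image; ties are broken by the lowest maximizing threshold.  The mask is
#' `input > threshold`.  A constant image is a degenerate input.
#'
#' @param input a [dense_image()] with at least 2 distinct values.
#' @return an `ops_threshold`: `threshold` (value in image units) and
#'   `mask` (logical array of the image's shape).
#' @export
threshold_otsu <- function(input) {
  v <- img_values(input)
  if (length(unique(as.vector(v))) < 2L)
    stop("degenerate-input error: constant image has no threshold")
  h <- image_histogram(input, 256L)
  counts <- h$counts
  edges <- h$bin_edges
  total <- sum(counts)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  best_t <- NA_integer_
  best_var <- -Inf
  cum_n <- cumsum(counts)
  cum_s <- cumsum(counts * centers)
  mu_all <- cum_s[256] / total
  for (t in 1:255) {                   # split: bins 1..t vs t+1..256
    w0 <- cum_n[t] / total
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- cum_s[t] / cum_n[t]
    mu1 <- (cum_s[256] - cum_s[t]) / (total - cum_n[t])
    bc <- w0 * w1 * (mu0 - mu1)^2
    if (bc > best_var) { best_var <- bc; best_t <- t }   # strict: lowest t wins ties
  }
  thr <- if (img_kind(input) == "uint8") best_t - 1 else edges[best_t + 1]
  structure(list(threshold = thr, mask = v > thr), class = "ops_threshold")
}

.op_otsu <- function(input) threshold_otsu(input)

# --- FFT -------------------------------------------------------------------

# Smallest integer >= n whose prime factors are all in {2,3,5,7}.
next_smooth <- function(n) {
  is_smooth <- function(m) {
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    m == 1L
  }
  m <- max(1L, as.integer(n))
  while (!is_smooth(m)) m <- m + 1L
  m
}

#' Discrete Fourier transform with mirror padding
#'
#' Pads the image by `border_size` per axis (mirror boundary, both sides);
#' with `fast = TRUE` each padded axis length is rounded up to the next size
#' factorable into \{2, 3, 5, 7\} (extra samples are appended by continuing
#' the mirror).  The transform itself is the standard n-dimensional DFT.
#'
#' @param input a float [dense_image()].
#' @param fft_type only `"real_to_complex"` is defined.
#' @param border_size non-negative padding per axis (scalar recycled).
#' @param fast round padded lengths up to 7-smooth sizes?
#' @return complex array; attribute `"pad_offset"` records where the
#'   original image starts in the padded grid (0-based per axis).
#' @export
image_fft <- function(input, fft_type = "real_to_complex", border_size = 0L,
                      fast = TRUE) {
  if (!identical(fft_type, "real_to_complex"))
    stop("parameter error: unknown fftType '", fft_type, "'")
  if (any(border_size < 0)) stop("parameter error: borderSize must be >= 0")
  v <- img_values(input)
  d <- dim(v)
  p <- as.integer(if (length(border_size) == 1L) rep(border_size, length(d))
                  else border_size)
  L <- d + 2L * p
  if (isTRUE(fast)) L <- vapply(L, next_smooth, integer(1))
  idx <- lapply(seq_along(d), function(ax)
    mirror_index(seq_len(L[ax]) - 1L - p[ax], d[ax]) + 1L)
  padded <- do.call(`[`, c(list(v), idx, list(drop = FALSE)))
  out <- stats::fft(padded)
  attr(out, "pad_offset") <- p
  out
}

.op_fft <- function(input, fftType, borderSize = 0L, fast = TRUE) {
  image_fft(input, fftType, borderSize, fast)
}

#' @rdname image_fft
#' @param grid complex array from [image_fft()].
#' @param shape original image shape; when given, the result is cropped back
#'   to the unpadded region using the grid's `"pad_offset"` attribute.
#' @return real array (inverse transform).
#' @export
image_ifft <- function(grid, shape = NULL) {
  res <- Re(stats::fft(grid, inverse = TRUE)) / length(grid)
  if (!is.null(shape)) {
    p <- attr(grid, "pad_offset") %||% rep(0L, length(shape))
    idx <- lapply(seq_along(shape), function(ax) p[ax] + seq_len(shape[ax]))
    res <- do.call(`[`, c(list(res), idx, list(drop = FALSE)))
  }
  res
}

# --- normal CDF and significance mask --------------------------------------

.op_pnorm_scalar <- function(x) stats::pnorm(x)

# One-sided upper-tail significance mask on a z-score image; the pixel-wise
# normal CDF is an engine-resolved stats.pnorm dependency.
.op_sigmask <- function(zscores, alpha = 0.05, .deps) {
  if (alpha <= 0 || alpha >= 1)
    stop("parameter error: alpha must be in (0, 1)")
  p_img <- .deps$pnorm(zscores)
  mask <- (1 - img_values(p_img)) < alpha
  dense_image(array(as.numeric(mask), dim = img_shape(zscores)), "uint8")
}

# --- synthetic fixtures ----------------------------------------------------

#' Seeded synthetic spot image
#'
#' Emulates a fluorescence micrograph as a sum of isotropic Gaussian spots
#' (amplitude 100) at seeded-uniform positions plus seeded Gaussian noise.
#' The same seed always yields a bit-identical float64 image.
#'
#' @param shape integer vector, slowest axis first.
#' @param n_spots number of spots.
#' @param spot_sigma spot standard deviation in pixels.
#' @param noise_sd standard deviation of the additive noise.
#' @param seed integer fixing the random stream.
#' @return a float64 [dense_image()].
#' @export
synthetic_image <- function(shape = c(64L, 64L), n_spots = 20L,
                            spot_sigma = 2, noise_sd = 5, seed = 1L) {
  shape <- as.integer(shape)
  arr <- with_seed(seed, {
    a <- array(0, dim = shape)
    grids <- lapply(shape, seq_len)
    if (n_spots > 0) {
      centers <- matrix(stats::runif(n_spots * length(shape), 1,
                                     rep(shape, each = n_spots)),
                        nrow = n_spots)
      for (s in seq_len(n_spots)) {
        comps <- lapply(seq_along(shape), function(ax)
          exp(-(grids[[ax]] - centers[s, ax])^2 / (2 * spot_sigma^2)))
        bump <- Reduce(`%o%`, comps)
        a <- a + 100 * bump
      }
    }
    if (noise_sd > 0) a <- a + array(stats::rnorm(length(a), 0, noise_sd),
                                     dim = shape)
    a
  })
  dense_image(arr, "float64")
}

.op_synthetic_image <- function(shape, n_spots, spot_sigma, noise_sd, seed) {
  synthetic_image(shape, n_spots, spot_sigma, noise_sd, seed)
}
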