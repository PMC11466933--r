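#' Read and write images as TIFF or PNG
#'
#' Grids are written in the declared axis order (slowest axis first,
#' 0-based data-model indices): a multi-page TIFF maps pages to the leading
#' (planar) axis of a 3-D dense image; PNG holds a single 2-D uint8 plane.
#' Pixel values use the \[0, 255\] intensity scale (stored scaled to
#' \[0, 1\] as both formats require, so float images must stay in range).
#'
#' @param path file path; format chosen by extension (`.tif`/`.tiff`/`.png`).
#' @return `read_image`: a [dense_image()] (2-D, or 3-D for a multi-page
#'   TIFF).  `write_image`: `path`, invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]   # drop extra channels
      p * 255
    })
    if (length(pages) == 1L) dense_image(pages[[1]])
    else dense_from_planar(planar_image(pages))
  } else if (ext == "png") {
    p <- png::readPNG(path)
    if (length(dim(p)) == 3L) p <- p[, , 1]
    dense_image(p * 255, "uint8")
  } else stop("I/O error: unsupported image extension: ", ext)
}

#' @rdname read_image
#' @param img a `dense_image` with values in \[0, 255\].
#' @export
write_image <- function(img, path) {
  v <- img_values(img) / 255
  d <- dim(v)
  v <- pmin(1, pmax(0, v))
  dim(v) <- d              # pmin drops the dim attribute
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    d <- dim(v)
    if (length(d) == 2L) tiff::writeTIFF(v, path, bits.per.sample = 16)
    else if (length(d) == 3L) {
      planes <- lapply(seq_len(d[1]), function(p) {
        m <- v[p, , , drop = TRUE]; dim(m) <- d[2:3]; m
      })
      tiff::writeTIFF(planes, path, bits.per.sample = 16)
    } else stop("I/O error: TIFF supports 2-D or 3-D images")
  } else if (ext == "png") {
    if (length(dim(v)) != 2L) stop("I/O error: PNG supports 2-D images only")
    png::writePNG(v, path)
  } else stop("I/O error: unsupported image extension: ", ext)
  invisible(path)
}
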