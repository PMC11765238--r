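#' Construct an RGB image
#'
#' An `rgb_image` is an H x W x 3 numeric array of integer-valued channel
#' intensities in `[0, 255]`, channel order R, G, B, row-major with origin at
#' the top-left corner (x rightward, y downward).
#'
#' @param pixels numeric array of dimension H x W x 3 with values in
#'   `[0, 255]`.
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(pixels) {
  pixels <- validate_raster(pixels, max_h = 255)
  structure(pixels, class = "rgb_image")
}

#' Construct an HSV image
#'
#' An `hsv_image` is an H x W x 3 numeric array with hue in `[0, 180)`
#' (half-degree units, possibly fractional), saturation and value integer
#' scaled to `[0, 255]`. An optional logical sentinel mask of the same H x W
#' marks background pixels excluded from analysis (suppressed lips, teeth,
#' out-of-range colors).
#'
#' @param pixels numeric array H x W x 3 (hue, saturation, value).
#' @param sentinel optional H x W logical matrix; `TRUE` marks excluded
#'   pixels. Defaults to all-`FALSE`.
#' @return an object of class `hsv_image`.
#' @export
hsv_image <- function(pixels, sentinel = NULL) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  h <- pixels[, , 1]; s <- pixels[, , 2]; v <- pixels[, , 3]
  if (any(h < 0 | h >= 180)) stop("hue values must lie in [0, 180)")
  if (any(s < 0 | s > 255) || any(v < 0 | v > 255))
    stop("saturation and value must lie in [0, 255]")
  if (is.null(sentinel)) {
    sentinel <- matrix(FALSE, nrow = dim(pixels)[1], ncol = dim(pixels)[2])
  }
  stopifnot(is.logical(sentinel),
            all(dim(sentinel) == dim(pixels)[1:2]))
  structure(pixels, sentinel = sentinel, class = "hsv_image")
}

validate_raster <- function(pixels, max_h) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have positive height and width")
  if (any(pixels < 0) || any(pixels > 255))
    stop("channel values must lie in [0, 255]")
  pixels
}

#' @export
dim.rgb_image <- function(x) dim(unclass(x))

#' Sentinel mask of an HSV image
#' @param img an `hsv_image`.
#' @return H x W logical matrix (`TRUE` = excluded background pixel).
#' @export
sentinel_mask <- function(img) {
  stopifnot(inherits(img, "hsv_image"))
  attr(img, "sentinel")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, channels R,G,B in [0,255]>\n", d[1], d[2]))
  invisible(x)
}

#' @export
print.hsv_image <- function(x, ...) {
  d <- dim(unclass(x))
  cat(sprintf("<hsv_image %d x %d, H in [0,180), S,V in [0,255], %d sentinel px>\n",
              d[1], d[2], sum(attr(x, "sentinel"))))
  invisible(x)
}

#' An image with acquisition metadata
#'
#' Bundles an image with its occlusion view (frontal, left or right bite
#' view), capture device and subject identifiers.
#'
#' @param image an `rgb_image`.
#' @param view one of `"frontal"`, `"left"`, `"right"`.
#' @param device_id,subject_id character scalars.
#' @return an object of class `image_record`.
#' @export
image_record <- function(image, view = c("frontal", "left", "right"),
                         device_id = "", subject_id = "") {
  stopifnot(inherits(image, "rgb_image"))
  view <- match.arg(view)
  structure(list(image = image, view = view,
                 device_id = as.character(device_id),
                 subject_id = as.character(subject_id)),
            class = "image_record")
}

#' Convert RGB to HSV
#'
#' Per-pixel hexcone conversion. Hue is returned in half-degree units
#' (`[0, 180)`), kept at floating-point precision so that the inverse
#' conversion reproduces the input to within one intensity level per
#' channel; saturation and value are rounded to integers in `[0, 255]`
#' (value equals `max(R, G, B)` exactly).
#'
#' @param img an `rgb_image`.
#' @return an `hsv_image`.
#' @export
rgb_to_hsv <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  px <- unclass(img)
  d <- dim(px)
  m <- grDevices::rgb2hsv(r = as.vector(px[, , 1]),
                          g = as.vector(px[, , 2]),
                          b = as.vector(px[, , 3]),
                          maxColorValue = 255)
  out <- array(0, dim = d)
  out[, , 1] <- m["h", ] * 180           # h in [0,1) -> half-degrees
  out[, , 2] <- round(m["s", ] * 255)
  out[, , 3] <- round(m["v", ] * 255)
  out[, , 1][out[, , 1] >= 180] <- 0
  hsv_image(out)
}

#' Convert HSV to RGB
#'
#' Inverse of [rgb_to_hsv()] up to integer rounding. Sentinel pixels render
#' as black.
#'
#' @param img an `hsv_image`.
#' @return an `rgb_image`.
#' @export
hsv_to_rgb <- function(img) {
  stopifnot(inherits(img, "hsv_image"))
  px <- unclass(img)
  d <- dim(px)
  h6 <- as.vector(px[, , 1]) / 30        # hue sector in [0, 6)
  s <- as.vector(px[, , 2]) / 255
  v <- as.vector(px[, , 3])
  c <- v * s
  x <- c * (1 - abs(h6 %% 2 - 1))
  m <- v - c
  sec <- floor(h6) %% 6
  r <- c * (sec == 0 | sec == 5) + x * (sec == 1 | sec == 4)
  g <- c * (sec == 1 | sec == 2) + x * (sec == 0 | sec == 3)
  b <- c * (sec == 3 | sec == 4) + x * (sec == 2 | sec == 5)
  out <- array(0, dim = d)
  out[, , 1] <- round(r + m)
  out[, , 2] <- round(g + m)
  out[, , 3] <- round(b + m)
  bg <- attr(img, "sentinel")
  if (any(bg)) for (k in 1:3) out[, , k][bg] <- 0
  rgb_image(pmin(pmax(out, 0), 255))
}

#' Load an oral photograph
#'
#' Reads a PNG or JPEG file into an `rgb_image`. Non-square inputs are
#' letterboxed (padded with black) to a square before any rescaling so
#' aspect ratio is preserved; images larger than `working_size` are rescaled
#' down to `working_size` x `working_size` (block averaging for integer
#' downscale factors, bilinear otherwise).
#'
#' @param path path to a PNG or JPEG file.
#' @param working_size maximum square side length in pixels (default 1280,
#'   the lowest capture resolution among mid/low-range mobile devices).
#' @return an `rgb_image`.
#' @export
load_image <- function(path, working_size = 1280) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch({
    if (ext == "png") {
      a <- png::readPNG(path)
      if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
      if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
      a
    } else {
      e <- EBImage::readImage(path)
      a <- EBImage::imageData(e)
      if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
      if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
      aperm(a, c(2, 1, 3))               # EBImage stores (x, y, channel)
    }
  }, error = function(e) {
    stop("failed to decode image file '", path, "': ", conditionMessage(e))
  })
  img <- rgb_image(round(px * 255))
  d <- dim(img)
  if (d[1] != d[2]) img <- letterbox_square(img)
  if (dim(img)[1] > working_size) img <- resize_image(img, working_size, working_size)
  img
}

#' Save an image as PNG
#'
#' Lossless 8-bit PNG; a load/save round-trip is bit-exact.
#'
#' @param img an `rgb_image`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

letterbox_square <- function(img) {
  px <- unclass(img)
  d <- dim(px)
  side <- max(d[1], d[2])
  out <- array(0, dim = c(side, side, 3))
  r0 <- (side - d[1]) %/% 2
  c0 <- (side - d[2]) %/% 2
  out[r0 + seq_len(d[1]), c0 + seq_len(d[2]), ] <- px
  rgb_image(out)
}

#' Resize an RGB image
#'
#' Deterministic resizing: exact block averaging when both dimensions shrink
#' by an integer factor, bilinear interpolation otherwise.
#'
#' @param img an `rgb_image`.
#' @param height,width target size in pixels.
#' @return an `rgb_image` of the requested size.
#' @export
resize_image <- function(img, height, width) {
  stopifnot(inherits(img, "rgb_image"), height >= 1, width >= 1)
  px <- unclass(img)
  d <- dim(px)
  if (d[1] == height && d[2] == width) return(img)
  if (d[1] %% height == 0 && d[2] %% width == 0 && d[1] >= height && d[2] >= width) {
    fr <- d[1] %/% height; fc <- d[2] %/% width
    out <- array(0, dim = c(height, width, 3))
    for (k in 1:3) {
      m <- px[, , k]
      # average fr x fc blocks
      m <- rowsum(m, rep(seq_len(height), each = fr)) / fr
      m <- t(rowsum(t(m), rep(seq_len(width), each = fc)) / fc)
      out[, , k] <- m
    }
    return(rgb_image(round(out)))
  }
  e <- EBImage::Image(aperm(px / 255, c(2, 1, 3)), colormode = "Color")
  r <- EBImage::resize(e, w = width, h = height, filter = "bilinear")
  rgb_image(pmin(pmax(round(aperm(EBImage::imageData(r), c(2, 1, 3)) * 255), 0), 255))
}
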