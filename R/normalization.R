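PLAQUE_CLASSES <- c("NEW", "MATURE", "OVER_MATURE")

#' Canonical normalized palette
#'
#' The fixed HSV triples every in-range plaque (and white) pixel is mapped to
#' during color normalization: new plaque (pink stain) (120, 200, 200),
#' mature plaque (purple) (125, 200, 200), over-mature plaque (blue)
#' (100, 200, 200) and white tooth surface (0, 0, 255).
#'
#' @return named list of HSV triples, read-only constants.
#' @export
normalized_palette <- function() {
  list(NEW         = c(120, 200, 200),
       MATURE      = c(125, 200, 200),
       OVER_MATURE = c(100, 200, 200),
       WHITE       = c(0, 0, 255))
}

#' An HSV color range
#'
#' Lower/upper HSV bounds delimiting one stain class. Hue intervals are
#' stored non-wrapping (the plaque hue band 95-130 and white never straddle
#' the hue origin); bounds are inclusive on all three channels.
#'
#' @param lower,upper numeric HSV triples, `lower <= upper` component-wise.
#' @param class_label one of `"NEW"`, `"MATURE"`, `"OVER_MATURE"`, `"WHITE"`.
#' @return an object of class `color_range`.
#' @export
color_range <- function(lower, upper, class_label) {
  stopifnot(length(lower) == 3L, length(upper) == 3L,
            class_label %in% c(PLAQUE_CLASSES, "WHITE"))
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (any(lower > upper))
    stop("color_range: lower bound exceeds upper bound")
  structure(list(lower = lower, upper = upper, class_label = class_label),
            class = "color_range")
}

#' A dataset-level normalization profile
#'
#' Holds the global white statistics (mean saturation and value of white
#' tooth pixels, with their spreads), the averaged lower/upper HSV range per
#' plaque class, and the brightness cap `T`. White pixels are recognised by
#' `S <= s_cut` and `V >= v_cut`; the cuts default to
#' `s_avg + k_s * s_sd` and `v_avg - k_v * v_sd` but can be set explicitly.
#'
#' @param s_avg,v_avg mean saturation / value of white pixels, `[0, 255]`.
#' @param ranges named list of `color_range`, one per plaque class.
#' @param brightness_threshold brightness cap `T` (default 230).
#' @param s_sd,v_sd spread of white saturation / value (default 0).
#' @param k_s,k_v multipliers for the white decision cuts (default 1).
#' @param s_cut,v_cut explicit white cuts overriding the derived ones.
#' @return an object of class `normalization_profile`.
#' @export
normalization_profile <- function(s_avg, v_avg, ranges,
                                  brightness_threshold = 230,
                                  s_sd = 0, v_sd = 0, k_s = 1, k_v = 1,
                                  s_cut = NULL, v_cut = NULL) {
  if (brightness_threshold < 0 || brightness_threshold > 255)
    stop("brightness_threshold must lie in [0, 255]")
  stopifnot(s_avg >= 0, s_avg <= 255, v_avg >= 0, v_avg <= 255)
  missing <- setdiff(PLAQUE_CLASSES, names(ranges))
  if (length(missing))
    stop("profile is missing ranges for classes: ", paste(missing, collapse = ", "))
  for (cl in PLAQUE_CLASSES) stopifnot(inherits(ranges[[cl]], "color_range"))
  if (is.null(s_cut)) s_cut <- s_avg + k_s * s_sd
  if (is.null(v_cut)) v_cut <- v_avg - k_v * v_sd
  structure(list(s_avg = s_avg, v_avg = v_avg, s_sd = s_sd, v_sd = v_sd,
                 ranges = ranges[PLAQUE_CLASSES],
                 brightness_threshold = brightness_threshold,
                 s_cut = s_cut, v_cut = v_cut),
            class = "normalization_profile")
}

#' @export
print.normalization_profile <- function(x, ...) {
  cat(sprintf("<normalization_profile T=%g, white: S<=%.1f & V>=%.1f (s_avg=%.1f, v_avg=%.1f)>\n",
              x$brightness_threshold, x$s_cut, x$v_cut, x$s_avg, x$v_avg))
  for (cl in names(x$ranges)) {
    r <- x$ranges[[cl]]
    cat(sprintf("  %-12s [%s] .. [%s]\n", cl,
                paste(round(r$lower, 1), collapse = ","),
                paste(round(r$upper, 1), collapse = ",")))
  }
  invisible(x)
}

#' Default normalization profile
#'
#' Reference HSV ranges for the three stain classes centred on the canonical
#' palette hues (new 120, mature 125, over-mature 100), with saturation and
#' value bands wide enough to absorb device-to-device illumination
#' variation after the brightness cap, plus white cuts for tooth
#' suppression.
#'
#' @return a `normalization_profile`.
#' @export
default_profile <- function() {
  normalization_profile(
    s_avg = 12, v_avg = 230,
    ranges = list(
      NEW         = color_range(c(118, 140, 140), c(122, 230, 230), "NEW"),
      MATURE      = color_range(c(123, 140, 140), c(127, 230, 230), "MATURE"),
      OVER_MATURE = color_range(c(95, 140, 140), c(105, 230, 230), "OVER_MATURE")),
    brightness_threshold = 230,
    s_cut = 30, v_cut = 225)
}

#' Cap excessive brightness
#'
#' Clamps the value channel at the pre-computed threshold `T`: pixels with
#' `V > T` are reduced to `T`; hue and saturation are untouched. Clamping is
#' idempotent and never increases any value.
#'
#' @param img an `hsv_image`.
#' @param threshold brightness cap `T` in `[0, 255]` (default 230).
#' @return an `hsv_image`.
#' @export
reduce_brightness <- function(img, threshold = 230) {
  stopifnot(inherits(img, "hsv_image"))
  if (threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]")
  px <- unclass(img)
  px[, , 3] <- pmin(px[, , 3], threshold)
  hsv_image(px, sentinel = attr(img, "sentinel"))
}

#' Global white saturation/value averages
#'
#' Arithmetic means of saturation and value over a collection of white
#' pixels, the dataset-level statistics driving white suppression.
#'
#' @param white_pixels N x 2 numeric matrix (columns S, V) or a data.frame
#'   with columns `s` and `v`.
#' @return named numeric vector `c(s_avg, v_avg)`.
#' @export
compute_global_sv_averages <- function(white_pixels) {
  if (is.data.frame(white_pixels))
    white_pixels <- cbind(white_pixels$s, white_pixels$v)
  white_pixels <- as.matrix(white_pixels)
  if (nrow(white_pixels) < 1L)
    stop("at least one white pixel is required (mean over zero pixels is undefined)")
  stopifnot(ncol(white_pixels) == 2L)
  c(s_avg = mean(white_pixels[, 1]), v_avg = mean(white_pixels[, 2]))
}

#' Average lower/upper limits over sampled color ranges
#'
#' Component-wise means of the lower bounds and of the upper bounds over a
#' collection of per-image `color_range` samples of one class, producing the
#' dataset-level reference range for that class.
#'
#' @param samples list of `color_range`, all of `class_label`.
#' @param class_label the expected class.
#' @return a `color_range` with the averaged bounds.
#' @export
compute_range_averages <- function(samples, class_label) {
  if (length(samples) < 1L) stop("at least one range sample is required")
  labels <- vapply(samples, function(r) r$class_label, "")
  if (any(labels != class_label))
    stop("mixed class labels in range samples: expected ", class_label,
         ", got ", paste(unique(labels), collapse = ", "))
  lo <- colMeans(do.call(rbind, lapply(samples, `[[`, "lower")))
  up <- colMeans(do.call(rbind, lapply(samples, `[[`, "upper")))
  color_range(lo, up, class_label)
}

white_predicate <- function(s, v, profile) {
  s <= profile$s_cut & v >= profile$v_cut
}

in_range_predicate <- function(h, s, v, range) {
  h >= range$lower[1] & h <= range$upper[1] &
    s >= range$lower[2] & s <= range$upper[2] &
    v >= range$lower[3] & v <= range$upper[3]
}

#' Suppress white tooth areas
#'
#' Pixels classified as white (`S <= s_cut` and `V >= v_cut`, cuts taken
#' from the profile) are marked as background sentinel; their stored value
#' becomes the canonical white palette triple so a later pixel census sees
#' only palette values. All other pixels are unchanged.
#'
#' @param img an `hsv_image` (brightness-reduced).
#' @param profile a `normalization_profile`.
#' @return an `hsv_image` with white pixels masked.
#' @export
suppress_white <- function(img, profile) {
  stopifnot(inherits(img, "hsv_image"), inherits(profile, "normalization_profile"))
  px <- unclass(img)
  bg <- attr(img, "sentinel")
  w <- white_predicate(px[, , 2], px[, , 3], profile) & !bg
  if (any(w)) {
    pal <- normalized_palette()$WHITE
    px[, , 1][w] <- pal[1]; px[, , 2][w] <- pal[2]; px[, , 3][w] <- pal[3]
    bg <- bg | w
  }
  hsv_image(px, sentinel = bg)
}

#' Normalize stain colors to the canonical palette
#'
#' Every pixel inside a class's averaged `[L_avg, U_avg]` range (inclusive
#' on all channels) is replaced by that class's canonical palette triple;
#' pixels matching the white test become canonical white and are masked as
#' background; pixels in no range become black sentinel. Overlapping class
#' ranges are resolved by a fixed clinical-severity priority (over-mature >
#' mature > new by default). The output contains at most four distinct
#' non-sentinel values and the operation is idempotent on its own output.
#'
#' @param img an `hsv_image`, already brightness-reduced (white suppression
#'   may or may not have been applied; it is repeated here).
#' @param profile a `normalization_profile`.
#' @param palette palette constants, see [normalized_palette()].
#' @param priority class priority for overlapping ranges, highest first.
#' @return an `hsv_image` containing only palette values and sentinel.
#' @export
normalize_colors <- function(img, profile, palette = normalized_palette(),
                             priority = c("OVER_MATURE", "MATURE", "NEW")) {
  stopifnot(inherits(img, "hsv_image"), inherits(profile, "normalization_profile"))
  stopifnot(setequal(priority, PLAQUE_CLASSES))
  px <- unclass(img)
  bg <- attr(img, "sentinel")
  d <- dim(px)
  h <- matrix(px[, , 1], d[1], d[2])
  s <- matrix(px[, , 2], d[1], d[2])
  v <- matrix(px[, , 3], d[1], d[2])
  live <- !bg
  assigned <- matrix(FALSE, nrow = d[1], ncol = d[2])

  wh <- live & white_predicate(s, v, profile)
  set_px <- function(px, sel, triple) {
    px[, , 1][sel] <- triple[1]; px[, , 2][sel] <- triple[2]; px[, , 3][sel] <- triple[3]
    px
  }
  px <- set_px(px, wh, palette$WHITE)
  assigned <- assigned | wh

  for (cl in priority) {
    sel <- live & !assigned & in_range_predicate(h, s, v, profile$ranges[[cl]])
    px <- set_px(px, sel, palette[[cl]])
    assigned <- assigned | sel
  }
  rest <- live & !assigned
  px <- set_px(px, rest, c(0, 0, 0))
  hsv_image(px, sentinel = bg | wh | rest)
}

#' Build a normalization profile from an annotated dataset
#'
#' Pools the annotated white pixels of every image to compute the global
#' saturation/value averages (and spreads), and averages the per-image
#' lower/upper range samples of each plaque class. By default statistics are
#' pooled at pixel level; `level = "image"` averages per-image means
#' instead (both readings of an N-of-pixels-or-samples average are
#' supported).
#'
#' @param dataset list of samples; each sample is a list with elements
#'   `image` (an `hsv_image`), `white` (H x W logical matrix of annotated
#'   white pixels) and `ranges` (list of `color_range` samples).
#' @param brightness_threshold brightness cap stored in the profile.
#' @param level `"pixel"` (default) or `"image"`.
#' @param ... further arguments passed to [normalization_profile()].
#' @return a `normalization_profile`.
#' @export
build_profile <- function(dataset, brightness_threshold = 230,
                          level = c("pixel", "image"), ...) {
  level <- match.arg(level)
  if (length(dataset) < 1L) stop("dataset must contain at least one image")
  sv <- lapply(dataset, function(d) {
    stopifnot(inherits(d$image, "hsv_image"), is.logical(d$white))
    px <- unclass(d$image)
    cbind(px[, , 2][d$white], px[, , 3][d$white])
  })
  nwhite <- vapply(sv, nrow, 0L)
  if (all(nwhite == 0L)) stop("dataset contains no annotated white pixels")
  if (level == "pixel") {
    pooled <- do.call(rbind, sv)
  } else {
    pooled <- do.call(rbind, lapply(sv[nwhite > 0], colMeans))
  }
  avg <- compute_global_sv_averages(pooled)
  s_sd <- stats::sd(pooled[, 1]); v_sd <- stats::sd(pooled[, 2])
  if (is.na(s_sd)) s_sd <- 0
  if (is.na(v_sd)) v_sd <- 0

  all_ranges <- unlist(lapply(dataset, `[[`, "ranges"), recursive = FALSE)
  labels <- vapply(all_ranges, function(r) r$class_label, "")
  missing <- setdiff(PLAQUE_CLASSES, labels)
  if (length(missing))
    stop("dataset has no range samples for classes: ",
         paste(missing, collapse = ", "))
  ranges <- lapply(PLAQUE_CLASSES, function(cl)
    compute_range_averages(all_ranges[labels == cl], cl))
  names(ranges) <- PLAQUE_CLASSES
  normalization_profile(avg[["s_avg"]], avg[["v_avg"]], ranges,
                        brightness_threshold = brightness_threshold,
                        s_sd = s_sd, v_sd = v_sd, ...)
}

#' Write a normalization profile to a plain-text file
#'
#' Serialized as YAML key/value pairs (`s_avg`, `v_avg`, `s_sd`, `v_sd`,
#' `s_cut`, `v_cut`, `brightness_threshold`, and per-class `lower`/`upper`
#' triples under `ranges`); [read_profile()] restores it exactly.
#'
#' @param profile a `normalization_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "normalization_profile"))
  obj <- list(
    s_avg = profile$s_avg, v_avg = profile$v_avg,
    s_sd = profile$s_sd, v_sd = profile$v_sd,
    s_cut = profile$s_cut, v_cut = profile$v_cut,
    brightness_threshold = profile$brightness_threshold,
    ranges = lapply(profile$ranges, function(r)
      list(lower = r$lower, upper = r$upper)))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  obj <- yaml::read_yaml(path)
  ranges <- lapply(names(obj$ranges), function(cl)
    color_range(unlist(obj$ranges[[cl]]$lower),
                unlist(obj$ranges[[cl]]$upper), cl))
  names(ranges) <- names(obj$ranges)
  normalization_profile(obj$s_avg, obj$v_avg, ranges,
                        brightness_threshold = obj$brightness_threshold,
                        s_sd = obj$s_sd, v_sd = obj$v_sd,
                        s_cut = obj$s_cut, v_cut = obj$v_cut)
}
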