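#' Per-class plaque mask
#'
#' @param mask H x W logical matrix.
#' @param class_label one of `"NEW"`, `"MATURE"`, `"OVER_MATURE"`.
#' @return an object of class `plaque_mask`.
#' @export
plaque_mask <- function(mask, class_label) {
  stopifnot(is.logical(mask), is.matrix(mask),
            class_label %in% PLAQUE_CLASSES)
  structure(list(mask = mask, class_label = class_label),
            class = "plaque_mask")
}

#' Connected-component extraction parameters
#'
#' @param min_area_px drop components smaller than this many pixels
#'   (default 25 at the 1280 x 1280 working size, below any annotatable
#'   plaque patch).
#' @param connectivity 4 or 8 (default 8).
#' @return an object of class `component_params`.
#' @export
component_params <- function(min_area_px = 25, connectivity = 8) {
  stopifnot(min_area_px >= 0, connectivity %in% c(4L, 8L))
  structure(list(min_area_px = as.integer(min_area_px),
                 connectivity = as.integer(connectivity)),
            class = "component_params")
}

# Run-based two-pass labeling: per-column runs of TRUE pixels are merged
# with overlapping runs of the previous column via union-find. Efficient
# when foreground consists of blobs (few runs), which is the regime here.
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), is.matrix(mask), connectivity %in% c(4, 8))
  H <- nrow(mask); W <- ncol(mask)
  runs <- vector("list", W)
  nseg <- 0L
  for (j in seq_len(W)) {
    col <- mask[, j]
    if (!any(col)) next
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) next
    s <- starts[keep]; e <- ends[keep]
    id <- nseg + seq_along(s)
    nseg <- nseg + length(s)
    runs[[j]] <- list(s = s, e = e, id = id)
  }
  if (nseg == 0L) return(matrix(0L, H, W))
  parent <- seq_len(nseg)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  slack <- if (connectivity == 8) 1L else 0L
  for (j in 2:max(2L, W)) {
    if (j > W) break
    a <- runs[[j - 1L]]; b <- runs[[j]]
    if (is.null(a) || is.null(b)) next
    for (k in seq_along(b$s)) {
      ov <- which(a$s <= b$e[k] + slack & a$e >= b$s[k] - slack)
      for (m in ov) union(a$id[m], b$id[k])
    }
  }
  root <- vapply(seq_len(nseg), find, 0L)
  relab <- match(root, sort(unique(root)))
  out <- matrix(0L, H, W)
  for (j in seq_len(W)) {
    r <- runs[[j]]
    if (is.null(r)) next
    for (k in seq_along(r$s))
      out[r$s[k]:r$e[k], j] <- relab[r$id[k]]
  }
  out
}

#' Default lip color range
#'
#' Reddish low-hue band typical of lips and gel residue on lips; well
#' separated from the plaque stain hues (95-130).
#'
#' @return a `color_range` with label `"LIP"`.
#' @export
default_lip_range <- function() {
  structure(list(lower = c(0, 60, 60), upper = c(20, 255, 240),
                 class_label = "LIP"),
            class = "color_range")
}

#' Suppress lip regions
#'
#' Marks as background sentinel (1) every pixel inside the configured lip
#' color range and (2) every connected component of the lip mask dilated by
#' `fringe` pixels (restricted to non-plaque pixels) that touches the image
#' border and is predominantly lip-colored (fraction >= `border_lip_frac`);
#' this removes lip bands together with a jittered fringe that falls just
#' outside the color range. Pixels whose color lies in any plaque class
#' range are never removed.
#'
#' @param img an `hsv_image`.
#' @param lip_range a `color_range` for lip color.
#' @param plaque_ranges named list of plaque `color_range`s used as the
#'   do-not-remove guard (defaults to [default_profile()] ranges).
#' @param border_lip_frac majority threshold for border components.
#' @param fringe dilation radius in pixels for the border-component rule.
#' @return an `hsv_image` with lip pixels masked (values set to 0).
#' @export
suppress_lips <- function(img, lip_range = default_lip_range(),
                          plaque_ranges = default_profile()$ranges,
                          border_lip_frac = 0.5, fringe = 2) {
  stopifnot(inherits(img, "hsv_image"))
  px <- unclass(img)
  bg <- attr(img, "sentinel")
  h <- px[, , 1]; s <- px[, , 2]; v <- px[, , 3]
  plaque <- Reduce(`|`, lapply(plaque_ranges, function(r)
    in_range_predicate(h, s, v, r)))
  lip <- in_range_predicate(h, s, v, lip_range) & !plaque & !bg

  kill <- lip
  if (any(lip) && fringe > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(fringe) + 1L, shape = "box")
    cand <- EBImage::imageData(EBImage::dilate(
      EBImage::Image(lip * 1), brush)) > 0
    cand <- cand & !plaque & !bg
    lab <- label_components(cand, connectivity = 8)
    H <- nrow(lab); W <- ncol(lab)
    border_ids <- setdiff(unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W])), 0L)
    for (id in border_ids) {
      comp <- lab == id
      if (mean(lip[comp]) >= border_lip_frac) kill <- kill | comp
    }
  }
  if (any(kill)) {
    for (k in 1:3) px[, , k][kill] <- 0
    bg <- bg | kill
  }
  hsv_image(px, sentinel = bg)
}

#' Extract per-class plaque masks from a normalized image
#'
#' One mask per plaque class; a pixel belongs to a class's mask iff it
#' carries exactly that class's canonical palette triple. Masks are pairwise
#' disjoint by construction.
#'
#' @param img a normalized `hsv_image` (only palette values and sentinel).
#' @param palette palette constants.
#' @return named list of `plaque_mask`, one per class.
#' @export
extract_class_masks <- function(img, palette = normalized_palette()) {
  stopifnot(inherits(img, "hsv_image"))
  px <- unclass(img)
  bg <- attr(img, "sentinel")
  h <- px[, , 1]; s <- px[, , 2]; v <- px[, , 3]
  masks <- lapply(PLAQUE_CLASSES, function(cl) {
    p <- palette[[cl]]
    plaque_mask(h == p[1] & s == p[2] & v == p[3] & !bg, cl)
  })
  names(masks) <- PLAQUE_CLASSES
  covered <- Reduce(`|`, lapply(masks, `[[`, "mask")) | bg
  pw <- palette$WHITE
  covered <- covered | (h == pw[1] & s == pw[2] & v == pw[3]) |
    (h == 0 & s == 0 & v == 0)
  if (!all(covered))
    stop("image contains non-palette pixels; run normalize_colors() first")
  masks
}

#' Bounding boxes of mask components
#'
#' One axis-aligned tight box per connected component with area at least
#' `min_area_px`, emitted in normalized YOLO center-size coordinates
#' (pixel extents of width `max - min + 1` divided by image size).
#'
#' @param mask a `plaque_mask`.
#' @param params a `component_params`.
#' @return data.frame with columns `class_id`, `cx`, `cy`, `w`, `h`
#'   (and `conf`, all `NA`).
#' @export
masks_to_boxes <- function(mask, params = component_params()) {
  stopifnot(inherits(mask, "plaque_mask"), inherits(params, "component_params"))
  m <- mask$mask
  H <- nrow(m); W <- ncol(m)
  lab <- label_components(m, connectivity = params$connectivity)
  n <- max(lab)
  if (n == 0L) return(empty_boxes())
  rows <- row(lab)[lab > 0]; cols <- col(lab)[lab > 0]; ids <- lab[lab > 0]
  out <- lapply(seq_len(n), function(id) {
    sel <- ids == id
    if (sum(sel) < params$min_area_px) return(NULL)
    r <- rows[sel]; cc <- cols[sel]
    px_extent_to_yolo(min(r), max(r), min(cc), max(cc), H, W,
                      class_id = class_label_to_id(mask$class_label))
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty_boxes())
  do.call(rbind, out)
}

class_label_to_id <- function(label) match(label, PLAQUE_CLASSES) - 1L

class_id_to_label <- function(id) PLAQUE_CLASSES[id + 1L]

empty_boxes <- function() {
  data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
             w = numeric(), h = numeric(), conf = numeric())
}

# inclusive 1-based pixel extents -> normalized YOLO center/size box
px_extent_to_yolo <- function(rmin, rmax, cmin, cmax, H, W, class_id,
                              conf = NA_real_) {
  data.frame(class_id = as.integer(class_id),
             cx = (cmin + cmax - 1) / (2 * W),
             cy = (rmin + rmax - 1) / (2 * H),
             w = (cmax - cmin + 1) / W,
             h = (rmax - rmin + 1) / H,
             conf = conf)
}

#' Write a mask as a single-channel PNG (0/255)
#'
#' @param mask a `plaque_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "plaque_mask"))
  png::writePNG(mask$mask * 1.0, path)
  invisible(path)
}
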