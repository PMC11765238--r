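#' Default scene colors of the synthetic stained-mouth generator
#'
#' HSV triples used when rendering: near-white teeth, reddish lip bands,
#' dark mouth background, and per-class stain hue centers matching the
#' canonical palette (new/pink 120, mature/purple 125, over-mature/blue
#' 100).
#'
#' @return named list of HSV triples and hue centers.
#' @export
scene_colors <- function() {
  list(tooth = c(0, 12, 248),
       lip = c(8, 150, 150),
       background = c(0, 0, 40),
       hue_center = c(NEW = 120, MATURE = 125, OVER_MATURE = 100))
}

#' Specification of one synthetic stained-mouth scene
#'
#' Fully determines a rendered sample: image size, tooth grid (via
#' [default_tooth_layout()] parameters), lip band height, elliptical plaque
#' blobs (class, center, semi-axes, hue/saturation/value), per-image
#' illumination gain, additive RGB noise, view and device tags, and the
#' seed that fixes every random draw.
#'
#' @param width,height image size (default 1280 x 1280, the working
#'   resolution of the acquisition protocol).
#' @param n_teeth,rows tooth grid shape (default 12 teeth in 2 arches).
#' @param lip_height lip band height in pixels (top and bottom bands).
#' @param blobs data.frame with columns `class_label`, `surface_tooth`,
#'   `surface`, `x`, `y` (ellipse center, continuous pixel coordinates),
#'   `a`, `b` (semi-axes), `hue`, `s`, `v`.
#' @param gain multiplicative illumination gain applied to the value
#'   channel (> 0).
#' @param noise_sd standard deviation of additive Gaussian RGB noise.
#' @param view,device_id,subject_id metadata tags.
#' @param seed integer seed fixing all random draws during rendering.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(width = 1280, height = 1280, n_teeth = 12, rows = 2,
                       lip_height = 120, blobs = NULL, gain = 1,
                       noise_sd = 0, view = "frontal", device_id = "dev0",
                       subject_id = "subj0", seed = 1L) {
  stopifnot(gain > 0, noise_sd >= 0, width >= 64, height >= 64)
  layout <- default_tooth_layout(width, height, n_teeth = n_teeth,
                                 rows = rows,
                                 margin_x = max(8L, width %/% 21),
                                 margin_y = max(lip_height + 8L, height %/% 8),
                                 gap = max(4L, width %/% 107))
  if (is.null(blobs))
    blobs <- data.frame(class_label = character(), surface_tooth = character(),
                        surface = character(), x = numeric(), y = numeric(),
                        a = numeric(), b = numeric(), hue = numeric(),
                        s = numeric(), v = numeric())
  if (nrow(blobs)) {
    if (any(blobs$x - blobs$a < 0 | blobs$x + blobs$a > width |
            blobs$y - blobs$b < 0 | blobs$y + blobs$b > height))
      stop("blob extends outside the image")
    stopifnot(all(blobs$class_label %in% PLAQUE_CLASSES))
  }
  structure(list(width = width, height = height, n_teeth = n_teeth,
                 rows = rows, lip_height = lip_height, layout = layout,
                 blobs = blobs, gain = gain, noise_sd = noise_sd,
                 view = view, device_id = device_id,
                 subject_id = subject_id, seed = as.integer(seed)),
            class = "scene_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# pixel-center column extents of an ellipse per raster row (analytic)
ellipse_row_extents <- function(x0, y0, a, b, H, W) {
  rows <- which(abs(seq_len(H) - 0.5 - y0) <= b)
  if (!length(rows)) return(NULL)
  yc <- rows - 0.5
  hw <- a * sqrt(pmax(1 - ((yc - y0) / b)^2, 0))
  cmin <- pmax(ceiling(x0 - hw + 0.5), 1L)
  cmax <- pmin(floor(x0 + hw + 0.5), W)
  keep <- cmin <= cmax
  if (!any(keep)) return(NULL)
  data.frame(row = rows[keep], cmin = cmin[keep], cmax = cmax[keep])
}

#' Render a synthetic stained-mouth sample
#'
#' Deterministic given the spec's seed. Teeth are rendered near-white, lip
#' bands in lip color, plaque blobs as ellipses whose HSV colors lie inside
#' their class's reference range; the value channel is scaled by the
#' per-image illumination gain and Gaussian noise is added in RGB. Ground
#' truth (boxes, surface chart, true O'Leary index) is derived analytically
#' from the spec, never from rendered pixels.
#'
#' @param spec a `scene_spec`.
#' @return a `generated_sample`: list with `image` (`rgb_image`),
#'   `gt_boxes`, `chart`, `truth` (`oleary_result`), `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  W <- spec$width; H <- spec$height
  col <- scene_colors()
  hm <- matrix(col$background[1], H, W)
  sm <- matrix(col$background[2], H, W)
  vm <- matrix(col$background[3], H, W)
  # lip bands top and bottom
  if (spec$lip_height > 0) {
    rows <- c(seq_len(spec$lip_height), H - seq_len(spec$lip_height) + 1L)
    hm[rows, ] <- col$lip[1]; sm[rows, ] <- col$lip[2]; vm[rows, ] <- col$lip[3]
  }
  # teeth
  for (i in seq_len(nrow(spec$layout))) {
    z <- spec$layout[i, ]
    hm[z$y0:z$y1, z$x0:z$x1] <- col$tooth[1]
    sm[z$y0:z$y1, z$x0:z$x1] <- col$tooth[2]
    vm[z$y0:z$y1, z$x0:z$x1] <- col$tooth[3]
  }
  # plaque blobs
  gt <- list()
  bl <- spec$blobs
  for (i in seq_len(nrow(bl))) {
    ex <- ellipse_row_extents(bl$x[i], bl$y[i], bl$a[i], bl$b[i], H, W)
    if (is.null(ex)) stop("blob ", i, " rasterizes to no pixels")
    for (k in seq_len(nrow(ex))) {
      r <- ex$row[k]
      hm[r, ex$cmin[k]:ex$cmax[k]] <- bl$hue[i]
      sm[r, ex$cmin[k]:ex$cmax[k]] <- bl$s[i]
      vm[r, ex$cmin[k]:ex$cmax[k]] <- bl$v[i]
    }
    gt[[i]] <- px_extent_to_yolo(min(ex$row), max(ex$row),
                                 min(ex$cmin), max(ex$cmax), H, W,
                                 class_id = class_label_to_id(bl$class_label[i]))
  }
  gt_boxes <- if (length(gt)) do.call(rbind, gt) else empty_boxes()

  vm <- pmin(vm * spec$gain, 255)
  px <- array(0, dim = c(H, W, 3))
  px[, , 1] <- hm; px[, , 2] <- sm; px[, , 3] <- vm
  img <- hsv_to_rgb(hsv_image(px))
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed, {
      noisy <- unclass(img) + stats::rnorm(length(img), sd = spec$noise_sd)
      rgb_image(pmin(pmax(round(noisy), 0), 255))
    })
  }

  teeth <- unique(spec$layout$tooth_id)
  pres <- matrix(FALSE, length(teeth), 4L)
  if (nrow(bl)) {
    for (i in seq_len(nrow(bl))) {
      pres[match(bl$surface_tooth[i], teeth),
           match(bl$surface[i], SURFACES)] <- TRUE
    }
  }
  chart <- surface_chart(teeth, pres)
  structure(list(image = img, gt_boxes = gt_boxes, chart = chart,
                 truth = compute_index(chart), spec = spec),
            class = "generated_sample")
}

#' @export
print.generated_sample <- function(x, ...) {
  cat(sprintf("<generated_sample %dx%d, %d boxes, O'Leary %.2f%% (%s), seed %d>\n",
              x$spec$height, x$spec$width, nrow(x$gt_boxes),
              x$truth$index, x$truth$category, x$spec$seed))
  invisible(x)
}

#' Randomly specified scene with a chosen plaque burden
#'
#' Picks `k_affected` of the chart's surfaces at random and places one
#' elliptical blob of a random stain class fully inside each chosen zone
#' (with a safety margin, and large enough to exceed the chart coverage
#' threshold), so the true chart and O'Leary index are known by
#' construction.
#'
#' @param seed integer seed.
#' @param k_affected number of affected surfaces, `0..n_teeth*4`.
#' @param min_coverage coverage fraction each blob must guarantee within
#'   its zone (matches [chart_from_masks()]'s default).
#' @param gain,noise_sd,width,height,n_teeth,rows passed to [scene_spec()].
#' @param view,device_id,subject_id metadata tags.
#' @return a `scene_spec`.
#' @export
random_scene_spec <- function(seed, k_affected = NULL, min_coverage = 0.05,
                              gain = 1, noise_sd = 0,
                              width = 1280, height = 1280, n_teeth = 12,
                              rows = 2, view = "frontal",
                              device_id = "dev0", subject_id = "subj0") {
  base <- scene_spec(width = width, height = height, n_teeth = n_teeth,
                     rows = rows, gain = gain, noise_sd = noise_sd,
                     lip_height = max(16L, height %/% 11),
                     view = view, device_id = device_id,
                     subject_id = subject_id, seed = seed)
  layout <- base$layout
  n_zones <- nrow(layout)
  with_seed(seed, {
    if (is.null(k_affected)) k_affected <- sample.int(n_zones + 1L, 1L) - 1L
    stopifnot(k_affected >= 0, k_affected <= n_zones)
    picks <- if (k_affected > 0) sample.int(n_zones, k_affected) else integer()
    hc <- scene_colors()$hue_center
    blobs <- lapply(picks, function(i) {
      z <- layout[i, ]
      zw <- z$x1 - z$x0 + 1L; zh <- z$y1 - z$y0 + 1L
      m_a <- min(3, 0.2 * zw); m_b <- min(3, 0.2 * zh)
      a_max <- zw / 2 - m_a; b_max <- zh / 2 - m_b
      # area >= min_coverage * zone area, with rasterization headroom
      need <- 1.6 * min_coverage * zw * zh / pi
      b <- stats::runif(1, 0.55 * b_max, b_max)
      a_lo <- min(max(need / b, 0.45 * a_max), 0.999 * a_max)
      a <- stats::runif(1, a_lo, a_max)
      cx0 <- (z$x0 + z$x1) / 2; cy0 <- (z$y0 + z$y1) / 2
      x <- cx0 + stats::runif(1, -(a_max - a), a_max - a)
      y <- cy0 + stats::runif(1, -(b_max - b), b_max - b)
      # snap to pixel centers so every blob rasterizes to >= 1 pixel
      x <- floor(x) + 0.5; y <- floor(y) + 0.5
      cl <- sample(PLAQUE_CLASSES, 1L)
      data.frame(class_label = cl, surface_tooth = z$tooth_id,
                 surface = z$surface, x = x, y = y, a = a, b = b,
                 hue = hc[[cl]] + stats::runif(1, -1.5, 1.5),
                 s = stats::runif(1, 160, 220),
                 v = stats::runif(1, 160, 220))
    })
    blobs <- if (length(blobs)) do.call(rbind, blobs) else NULL
    scene_spec(width = width, height = height, n_teeth = n_teeth,
               rows = rows, lip_height = base$lip_height, blobs = blobs,
               gain = gain, noise_sd = noise_sd, view = view,
               device_id = device_id, subject_id = subject_id, seed = seed)
  })
}

#' Generate a cohort with a target severity mix
#'
#' Draws each sample's severity category from `severity_mix`, picks a
#' surface count inside that category's O'Leary band (Mild 0-12 of 48
#' surfaces, Moderate 13-24, Severe 25-48 for the default 12-tooth chart),
#' and renders the scene. Fully deterministic given `seed`.
#'
#' @param n cohort size (> 0).
#' @param severity_mix named proportions over `MILD`, `MODERATE`, `SEVERE`
#'   summing to 1.
#' @param seed integer seed.
#' @param ... passed to [random_scene_spec()] (e.g. `width`, `noise_sd`).
#' @return list of `generated_sample`.
#' @export
generate_cohort <- function(n, severity_mix = c(MILD = 1/3, MODERATE = 1/3,
                                                SEVERE = 1/3),
                            seed = 1L, ...) {
  if (n <= 0) stop("cohort size must be positive")
  if (abs(sum(severity_mix) - 1) > 1e-8)
    stop("severity_mix proportions must sum to 1")
  stopifnot(setequal(names(severity_mix), c("MILD", "MODERATE", "SEVERE")))
  extra <- list(...)
  n_teeth <- if (!is.null(extra$n_teeth)) extra$n_teeth else 12L
  n_zones <- n_teeth * 4L
  mild_max <- as.integer(floor(0.25 * n_zones))
  mod_max <- as.integer(floor(0.50 * n_zones))
  with_seed(seed, {
    cats <- sample(c("MILD", "MODERATE", "SEVERE"), n, replace = TRUE,
                   prob = severity_mix[c("MILD", "MODERATE", "SEVERE")])
    ks <- vapply(cats, function(cat) switch(cat,
      MILD = sample.int(mild_max + 1L, 1L) - 1L,
      MODERATE = mild_max + sample.int(mod_max - mild_max, 1L),
      SEVERE = mod_max + sample.int(n_zones - mod_max, 1L)), 0L)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      sp <- random_scene_spec(seed = seeds[i], k_affected = ks[i],
                              subject_id = sprintf("subj%03d", i), ...)
      generate_scene(sp)
    })
  })
}

#' MixUp augmentation
#'
#' Per-pixel convex combination `lambda * a + (1 - lambda) * b`, rounded to
#' integer intensities. Symmetric: `mixup(a, b, l)` equals
#' `mixup(b, a, 1 - l)` up to rounding.
#'
#' @param a,b `rgb_image`s of identical size.
#' @param lambda mixing weight in `[0, 1]`.
#' @return an `rgb_image`.
#' @export
mixup <- function(a, b, lambda) {
  stopifnot(inherits(a, "rgb_image"), inherits(b, "rgb_image"),
            lambda >= 0, lambda <= 1)
  if (!all(dim(a) == dim(b))) stop("mixup: image sizes differ")
  mixed <- round(lambda * unclass(a) + (1 - lambda) * unclass(b))
  storage.mode(mixed) <- "integer"
  rgb_image(mixed)
}

#' CutMix augmentation with label bookkeeping
#'
#' Replaces a rectangular patch of `a` with the corresponding pixels of
#' `b`. Labels: `a`'s boxes are clipped away from the patch when the patch
#' spans them in one axis, dropped when more than `drop_frac` of their area
#' is covered, and kept unchanged otherwise; `b`'s boxes are clipped to the
#' patch (dropped when empty).
#'
#' @param a,b `rgb_image`s of identical size.
#' @param patch integer rectangle `c(x0, y0, x1, y1)` in 1-based inclusive
#'   pixel coordinates (zero-area patch: pass `NULL`).
#' @param labels_a,labels_b box data.frames (normalized coordinates).
#' @param drop_frac coverage fraction above which an occluded `a` box is
#'   dropped (default 0.8).
#' @return list with `image` (`rgb_image`) and `labels` (box data.frame).
#' @export
cutmix <- function(a, b, patch, labels_a = empty_boxes(),
                   labels_b = empty_boxes(), drop_frac = 0.8) {
  stopifnot(inherits(a, "rgb_image"), inherits(b, "rgb_image"))
  if (!all(dim(a) == dim(b))) stop("cutmix: image sizes differ")
  d <- dim(a); H <- d[1]; W <- d[2]
  labels_a <- normalize_box_df(labels_a); labels_b <- normalize_box_df(labels_b)
  if (is.null(patch))
    return(list(image = a, labels = labels_a))
  stopifnot(length(patch) == 4L, patch[1] >= 1, patch[2] >= 1,
            patch[3] <= W, patch[4] <= H, patch[1] <= patch[3],
            patch[2] <= patch[4])
  px <- unclass(a)
  px[patch[2]:patch[4], patch[1]:patch[3], ] <-
    unclass(b)[patch[2]:patch[4], patch[1]:patch[3], ]
  # normalized patch rectangle
  pn <- c((patch[1] - 1) / W, (patch[2] - 1) / H, patch[3] / W, patch[4] / H)
  keep_a <- lapply(seq_len(nrow(labels_a)), function(i) {
    bb <- labels_a[i, ]
    x1 <- bb$cx - bb$w / 2; x2 <- bb$cx + bb$w / 2
    y1 <- bb$cy - bb$h / 2; y2 <- bb$cy + bb$h / 2
    iw <- max(min(x2, pn[3]) - max(x1, pn[1]), 0)
    ih <- max(min(y2, pn[4]) - max(y1, pn[2]), 0)
    cov <- iw * ih / (bb$w * bb$h)
    if (cov >= 1 || cov > drop_frac) return(NULL)
    if (cov == 0) return(bb)
    spans_y <- pn[2] <= y1 && pn[4] >= y2
    spans_x <- pn[1] <= x1 && pn[3] >= x2
    if (spans_y && !spans_x) {
      # clip in x to the side outside the patch
      if (pn[1] > x1) x2 <- min(x2, pn[1]) else x1 <- max(x1, pn[3])
      bb$cx <- (x1 + x2) / 2; bb$w <- x2 - x1
    } else if (spans_x && !spans_y) {
      if (pn[2] > y1) y2 <- min(y2, pn[2]) else y1 <- max(y1, pn[4])
      bb$cy <- (y1 + y2) / 2; bb$h <- y2 - y1
    }
    bb
  })
  keep_b <- lapply(seq_len(nrow(labels_b)), function(i) {
    bb <- labels_b[i, ]
    x1 <- max(bb$cx - bb$w / 2, pn[1]); x2 <- min(bb$cx + bb$w / 2, pn[3])
    y1 <- max(bb$cy - bb$h / 2, pn[2]); y2 <- min(bb$cy + bb$h / 2, pn[4])
    if (x2 <= x1 || y2 <= y1) return(NULL)
    bb$cx <- (x1 + x2) / 2; bb$w <- x2 - x1
    bb$cy <- (y1 + y2) / 2; bb$h <- y2 - y1
    bb
  })
  lab <- do.call(rbind, c(keep_a[!vapply(keep_a, is.null, TRUE)],
                          keep_b[!vapply(keep_b, is.null, TRUE)]))
  if (is.null(lab)) lab <- empty_boxes()
  list(image = rgb_image(px), labels = lab)
}

#' Write a generated dataset to disk
#'
#' YOLO-style layout: `images/<stem>.png` and `labels/<stem>.txt` with
#' matching stems, plus `charts.csv` (long per-sample surface charts),
#' `truth.csv` (true index, category, NAPC/NTAE, seed per sample) and a
#' JSON `manifest.json` listing every file with the sample seed and a hash
#' of its scene spec. Existing files are never silently overwritten.
#'
#' @param samples list of `generated_sample`.
#' @param root output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_dataset <- function(samples, root) {
  dir.create(file.path(root, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "labels"), recursive = TRUE, showWarnings = FALSE)
  stems <- sprintf("sample_%04d", seq_along(samples))
  entries <- list()
  charts <- list()
  truth <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    stopifnot(inherits(s, "generated_sample"))
    ipath <- file.path(root, "images", paste0(stems[i], ".png"))
    lpath <- file.path(root, "labels", paste0(stems[i], ".txt"))
    if (file.exists(ipath) || file.exists(lpath))
      stop("refusing to overwrite existing files for stem ", stems[i])
    save_image(s$image, ipath)
    gt <- s$gt_boxes; gt$conf <- NA_real_
    write_yolo(gt, lpath)
    charts[[i]] <- data.frame(
      sample = stems[i],
      tooth_id = rep(s$chart$teeth, each = 4L),
      surface = rep(SURFACES, times = length(s$chart$teeth)),
      affected = as.integer(t(s$chart$presence)))
    truth[[i]] <- data.frame(sample = stems[i], index = s$truth$index,
                             category = s$truth$category,
                             napc = s$truth$napc, ntae = s$truth$ntae,
                             seed = s$spec$seed)
    entries[[i]] <- list(stem = stems[i],
                         image = file.path("images", paste0(stems[i], ".png")),
                         labels = file.path("labels", paste0(stems[i], ".txt")),
                         seed = s$spec$seed,
                         spec_hash = rlang::hash(s$spec))
  }
  utils::write.csv(do.call(rbind, charts), file.path(root, "charts.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, truth), file.path(root, "truth.csv"),
                   row.names = FALSE)
  manifest <- list(n_samples = length(samples), samples = entries)
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
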