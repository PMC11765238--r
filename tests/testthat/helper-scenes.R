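# Shared fixture builders: everything is generated in code at test time.

# small test scene; defaults keep unit tests fast
test_scene <- function(seed = 1, k = 6, size = 256, ...) {
  generate_scene(random_scene_spec(seed = seed, k_affected = k,
                                   width = size, height = size, ...))
}

run_preprocess <- function(img, profile = default_profile()) {
  hsv <- rgb_to_hsv(img)
  hsv <- suppress_lips(hsv, plaque_ranges = profile$ranges)
  hsv <- reduce_brightness(hsv, profile$brightness_threshold)
  hsv <- suppress_white(hsv, profile)
  normalize_colors(hsv, profile)
}

# analytic per-class truth masks for a generated sample
truth_masks <- function(sample) {
  sp <- sample$spec
  bl <- sp$blobs
  out <- lapply(c("NEW", "MATURE", "OVER_MATURE"), function(cl) {
    m <- matrix(FALSE, sp$height, sp$width)
    for (i in which(bl$class_label == cl)) {
      ex <- plaquekit:::ellipse_row_extents(bl$x[i], bl$y[i], bl$a[i],
                                            bl$b[i], sp$height, sp$width)
      for (k in seq_len(nrow(ex))) m[ex$row[k], ex$cmin[k]:ex$cmax[k]] <- TRUE
    }
    m
  })
  names(out) <- c("NEW", "MATURE", "OVER_MATURE")
  out
}

box_key <- function(b, digits = 9) {
  paste(b$class_id, round(b$cx, digits), round(b$cy, digits),
        round(b$w, digits), round(b$h, digits))
}

# constant-color HSV image
flat_hsv <- function(h, s, v, H = 8, W = 8) {
  px <- array(0, dim = c(H, W, 3))
  px[, , 1] <- h; px[, , 2] <- s; px[, , 3] <- v
  hsv_image(px)
}
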