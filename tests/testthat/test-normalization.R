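test_that("brightness reduction clamps only values above the threshold", {
  img <- flat_hsv(90, 200, 230, 1, 1)
  expect_equal(unclass(reduce_brightness(img, 230)), unclass(img))
  bright <- flat_hsv(90, 200, 255, 1, 1)
  expect_equal(as.vector(unclass(reduce_brightness(bright, 230))),
               c(90, 200, 230))
  zero <- flat_hsv(0, 0, 0)
  expect_equal(unclass(reduce_brightness(zero, 230)), unclass(zero))
  expect_error(reduce_brightness(img, 300), "\\[0, 255\\]")
})

test_that("brightness reduction is idempotent, monotone and matches a per-pixel min oracle", {
  set.seed(5)
  px <- array(c(runif(64, 0, 179), runif(64, 0, 255), runif(64, 0, 255)),
              dim = c(8, 8, 3))
  img <- hsv_image(px)
  once <- reduce_brightness(img, 230)
  twice <- reduce_brightness(once, 230)
  expect_identical(unclass(once), unclass(twice))
  expect_equal(unclass(once)[, , 3], pmin(px[, , 3], 230))
  expect_true(all(unclass(once)[, , 3] <= px[, , 3]))
  expect_identical(unclass(once)[, , 1:2], px[, , 1:2])
})

test_that("global S/V averages equal direct summation", {
  expect_equal(compute_global_sv_averages(cbind(rep(100, 5), rep(100, 5))),
               c(s_avg = 100, v_avg = 100))
  expect_equal(compute_global_sv_averages(rbind(c(0, 0), c(255, 255))),
               c(s_avg = 127.5, v_avg = 127.5))
  set.seed(9)
  m <- cbind(runif(1000, 0, 255), runif(1000, 0, 255))
  got <- compute_global_sv_averages(m)
  expect_equal(got[["s_avg"]], sum(m[, 1]) / 1000, tolerance = 1e-9)
  expect_equal(got[["v_avg"]], sum(m[, 2]) / 1000, tolerance = 1e-9)
  expect_error(compute_global_sv_averages(matrix(0, 0, 2)), "at least one")
})

test_that("range averaging is the component-wise mean of bounds", {
  r <- color_range(c(90, 100, 100), c(110, 200, 200), "NEW")
  expect_equal(compute_range_averages(list(r, r, r), "NEW")$lower, r$lower)
  a <- color_range(c(90, 100, 100), c(110, 200, 200), "NEW")
  b <- color_range(c(110, 120, 120), c(130, 220, 220), "NEW")
  avg <- compute_range_averages(list(a, b), "NEW")
  expect_equal(avg$lower, c(100, 110, 110))
  expect_equal(avg$upper, c(120, 210, 210))

  set.seed(13)
  samples <- lapply(1:50, function(i) {
    lo <- c(runif(1, 90, 110), runif(1, 80, 120), runif(1, 80, 120))
    color_range(lo, lo + runif(3, 0, 40), "MATURE")
  })
  avg <- compute_range_averages(samples, "MATURE")
  expect_equal(avg$lower,
               colMeans(do.call(rbind, lapply(samples, `[[`, "lower"))),
               tolerance = 1e-9)
  expect_error(compute_range_averages(list(), "NEW"), "at least one")
  expect_error(compute_range_averages(list(a, color_range(1:3, 4:6, "MATURE")),
                                      "NEW"), "mixed")
})

test_that("white suppression follows the S-cut/V-cut predicate", {
  prof <- normalization_profile(
    s_avg = 20, v_avg = 240, s_sd = 0, v_sd = 0,
    ranges = default_profile()$ranges, s_cut = 20, v_cut = 240)
  img <- flat_hsv(0, 10, 250, 2, 2)
  out <- suppress_white(img, prof)
  expect_true(all(sentinel_mask(out)))
  pink <- flat_hsv(150, 200, 200, 2, 2)
  expect_false(any(sentinel_mask(suppress_white(pink, prof))))
  expect_identical(unclass(suppress_white(pink, prof)), unclass(pink))

  # random pixels agree with a scalar predicate oracle
  set.seed(17)
  px <- array(c(runif(64, 0, 179), runif(64, 0, 255), runif(64, 0, 255)),
              dim = c(8, 8, 3))
  out <- suppress_white(hsv_image(px), prof)
  oracle <- px[, , 2] <= 20 & px[, , 3] >= 240
  expect_equal(sentinel_mask(out), oracle)
})

test_that("color normalization maps in-range pixels to the canonical palette", {
  prof <- default_profile()
  pal <- normalized_palette()
  near_new <- flat_hsv(119, 180, 210, 2, 2)
  out <- normalize_colors(near_new, prof)
  expect_equal(as.vector(unclass(out)[1, 1, ]), pal$NEW)
  expect_equal(pal$NEW, c(120, 200, 200))
  near_over <- flat_hsv(97, 160, 170, 2, 2)
  expect_equal(as.vector(unclass(normalize_colors(near_over, prof))[1, 1, ]),
               pal$OVER_MATURE)
  expect_equal(pal$OVER_MATURE, c(100, 200, 200))
  nowhere <- flat_hsv(60, 200, 200, 2, 2)
  out <- normalize_colors(nowhere, prof)
  expect_true(all(sentinel_mask(out)))
  expect_true(all(unclass(out) == 0))
})

test_that("normalization output census holds only palette values and sentinel", {
  s <- test_scene(seed = 31, k = 8, size = 192)
  norm <- run_preprocess(s$image)
  px <- unclass(norm)
  vals <- unique(paste(px[, , 1], px[, , 2], px[, , 3]))
  pal <- normalized_palette()
  allowed <- c(vapply(pal, function(p) paste(p[1], p[2], p[3]), ""), "0 0 0")
  expect_true(all(vals %in% allowed))
  expect_lte(length(setdiff(vals, "0 0 0")), 4)
})

test_that("color normalization is idempotent and never raises V", {
  s <- test_scene(seed = 33, k = 5, size = 160)
  hsv <- rgb_to_hsv(s$image)
  prof <- default_profile()
  v0 <- unclass(hsv)[, , 3]
  step1 <- reduce_brightness(hsv, prof$brightness_threshold)
  norm <- normalize_colors(step1, prof)
  again <- normalize_colors(norm, prof)
  expect_identical(unclass(norm), unclass(again))
  expect_identical(sentinel_mask(norm), sentinel_mask(again))
  # V through the brightness stage never increases
  expect_true(all(unclass(step1)[, , 3] <= v0))
})

test_that("overlapping ranges resolve by clinical severity priority", {
  ranges <- list(
    NEW = color_range(c(100, 100, 100), c(130, 255, 255), "NEW"),
    MATURE = color_range(c(100, 100, 100), c(130, 255, 255), "MATURE"),
    OVER_MATURE = color_range(c(100, 100, 100), c(130, 255, 255), "OVER_MATURE"))
  prof <- normalization_profile(s_avg = 5, v_avg = 250, ranges = ranges,
                                s_cut = 5, v_cut = 250)
  img <- flat_hsv(110, 150, 150, 1, 1)
  out <- normalize_colors(img, prof)
  expect_equal(as.vector(unclass(out)), normalized_palette()$OVER_MATURE)
  out2 <- normalize_colors(img, prof,
                           priority = c("NEW", "MATURE", "OVER_MATURE"))
  expect_equal(as.vector(unclass(out2)), normalized_palette()$NEW)
})

test_that("profile building pools annotations and is duplication/permutation invariant", {
  mk_sample <- function(seed) {
    set.seed(seed)
    px <- array(c(runif(48, 0, 179), runif(48, 0, 255), runif(48, 0, 255)),
                dim = c(4, 12, 3))
    white <- matrix(runif(48) < 0.4, 4, 12)
    ranges <- lapply(c("NEW", "MATURE", "OVER_MATURE"), function(cl) {
      lo <- c(runif(1, 95, 120), runif(1, 120, 160), runif(1, 120, 160))
      color_range(lo, lo + 20, cl)
    })
    list(image = hsv_image(px), white = white, ranges = ranges)
  }
  ds <- lapply(1:6, mk_sample)
  p1 <- build_profile(ds)
  p_dup <- build_profile(c(ds, ds))
  p_perm <- build_profile(rev(ds))
  expect_equal(p1$s_avg, p_dup$s_avg, tolerance = 1e-12)
  expect_equal(p1$v_avg, p_perm$v_avg, tolerance = 1e-12)
  for (cl in c("NEW", "MATURE", "OVER_MATURE")) {
    expect_equal(p1$ranges[[cl]]$lower, p_dup$ranges[[cl]]$lower,
                 tolerance = 1e-12)
    expect_equal(p1$ranges[[cl]]$upper, p_perm$ranges[[cl]]$upper,
                 tolerance = 1e-12)
  }

  # flat summation oracle for the pooled white statistics
  sv <- do.call(rbind, lapply(ds, function(d) {
    px <- unclass(d$image)
    cbind(px[, , 2][d$white], px[, , 3][d$white])
  }))
  expect_equal(p1$s_avg, sum(sv[, 1]) / nrow(sv), tolerance = 1e-12)
  expect_equal(p1$v_avg, sum(sv[, 2]) / nrow(sv), tolerance = 1e-12)

  # constant single-image dataset reproduces its constants
  const <- list(image = flat_hsv(0, 10, 240, 4, 4),
                white = matrix(TRUE, 4, 4),
                ranges = lapply(c("NEW", "MATURE", "OVER_MATURE"), function(cl)
                  color_range(c(100, 150, 150), c(120, 220, 220), cl)))
  pc <- build_profile(list(const))
  expect_equal(pc$s_avg, 10)
  expect_equal(pc$v_avg, 240)
  expect_equal(pc$ranges$NEW$lower, c(100, 150, 150))

  # missing class errors and names the class
  bad <- list(list(image = const$image, white = const$white,
                   ranges = const$ranges[1:2]))
  expect_error(build_profile(bad), "OVER_MATURE")
})

test_that("profile serialization round-trips through the text format", {
  prof <- build_profile(list(list(
    image = flat_hsv(0, 12.5, 241.25, 4, 4),
    white = matrix(TRUE, 4, 4),
    ranges = lapply(c("NEW", "MATURE", "OVER_MATURE"), function(cl)
      color_range(c(101.5, 150, 150), c(121.25, 220, 220), cl)))))
  f <- withr::local_tempfile(fileext = ".yml")
  write_profile(prof, f)
  back <- read_profile(f)
  expect_equal(back$s_avg, prof$s_avg)
  expect_equal(back$v_cut, prof$v_cut)
  expect_equal(back$ranges$NEW$upper, prof$ranges$NEW$upper)
  expect_equal(back$brightness_threshold, prof$brightness_threshold)
})
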