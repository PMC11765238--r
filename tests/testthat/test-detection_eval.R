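test_that("iou handles identity, disjoint, partial overlap and degenerate boxes", {
  a <- c(0.5, 0.5, 0.2, 0.2)
  expect_equal(iou(a, a), 1.0)
  expect_equal(iou(a, c(0.1, 0.1, 0.1, 0.1)), 0.0)
  # unit-width boxes offset by half a width: overlap/union = 1/3
  b1 <- c(0.4, 0.5, 0.2, 0.2); b2 <- c(0.5, 0.5, 0.2, 0.2)
  expect_equal(iou(b1, b2), 1 / 3, tolerance = 1e-12)
  expect_warning(v <- iou(a, c(0.5, 0.5, 0, 0)), "degenerate")
  expect_equal(v, 0)
  expect_warning(v2 <- iou(c(0.5, 0.5, 0, 0.2), a), "degenerate")
  expect_equal(v2, 0)
})

test_that("iou agrees with a pixel-rasterization oracle", {
  set.seed(61)
  for (i in 1:8) {
    a <- as.numeric(random_boxes(1)[1, c("cx", "cy", "w", "h")])
    b <- as.numeric(random_boxes(1)[1, c("cx", "cy", "w", "h")])
    expect_equal(iou(a, b), raster_iou(a, b), tolerance = 5e-3)
  }
})

test_that("matching handles perfect, empty and double-detection cases", {
  gts <- boxes(0, 0.5, 0.5, 0.2, 0.2)
  dets <- gts; dets$conf <- 0.9
  t <- match_detections(dets, gts)
  expect_equal(t$tp, 1L); expect_equal(t$fp, 0L); expect_equal(t$fn, 0L)

  t0 <- match_detections(plaquekit:::empty_boxes(), gts)
  expect_equal(t0$fn, 1L); expect_equal(sum(t0$tp) + sum(t0$fp), 0L)

  # two detections over one gt: greedy gives one TP, one FP
  dets2 <- boxes(c(0, 0), c(0.5, 0.52), c(0.5, 0.5), c(0.2, 0.2),
                 c(0.2, 0.2), conf = c(0.9, 0.8))
  t2 <- match_detections(dets2, gts)
  expect_equal(t2$tp, 1L); expect_equal(t2$fp, 1L); expect_equal(t2$fn, 0L)

  expect_error(match_detections(dets, gts, iou_thr = 0), "\\(0, 1\\]")
  expect_error(match_detections(dets, gts, iou_thr = 1.2), "\\(0, 1\\]")
})

test_that("matching is class-aware", {
  gts <- boxes(1, 0.5, 0.5, 0.2, 0.2)
  dets <- boxes(0, 0.5, 0.5, 0.2, 0.2, conf = 0.99)
  t <- match_detections(dets, gts)
  expect_equal(sum(t$tp), 0L)
  expect_equal(sum(t$fp), 1L)
  expect_equal(sum(t$fn), 1L)
})

test_that("matcher agrees with an independent greedy oracle on many small instances", {
  set.seed(67)
  for (i in 1:300) {
    dets <- random_boxes(sample(0:4, 1))
    gts <- random_boxes(sample(0:4, 1), with_conf = FALSE)
    got <- match_detections(dets, gts)
    want <- greedy_match_oracle(dets, gts)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(as.data.frame(got)[order(got$class_id), ],
                   want[order(want$class_id), ], ignore_attr = TRUE)
    }
  }
})

test_that("tally conservation holds on random evaluations", {
  set.seed(71)
  for (i in 1:40) {
    dets <- random_boxes(sample(0:6, 1))
    gts <- random_boxes(sample(0:6, 1), with_conf = FALSE)
    t <- match_detections(dets, gts, iou_thr = runif(1, 0.05, 0.95))
    for (cl in t$class_id) {
      r <- t[t$class_id == cl, ]
      expect_equal(r$tp + r$fn, sum(gts$class_id == cl))
      expect_equal(r$tp + r$fp, sum(dets$class_id == cl))
    }
  }
})

test_that("raising the IoU threshold never increases true positives", {
  set.seed(73)
  for (i in 1:20) {
    dets <- random_boxes(5)
    gts <- random_boxes(5, with_conf = FALSE)
    tps <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(thr)
      sum(match_detections(dets, gts, thr)$tp), 0L)
    expect_true(all(diff(tps) <= 0))
  }
})

test_that("precision and recall follow their ratio definitions and edge conventions", {
  t <- structure(data.frame(class_id = 0L, tp = 3L, fp = 1L, fn = 0L),
                 class = c("match_tally", "data.frame"))
  expect_equal(precision(t), 0.75)
  t$tp <- 0L; t$fp <- 5L
  expect_equal(precision(t), 0.0)
  t$fp <- 0L
  expect_equal(precision(t), 1.0)          # zero predictions
  t2 <- structure(data.frame(class_id = 0L, tp = 5L, fp = 0L, fn = 0L),
                  class = c("match_tally", "data.frame"))
  expect_equal(recall(t2), 1.0)
  t2$tp <- 2L; t2$fn <- 2L
  expect_equal(recall(t2), 0.5)
  t2$tp <- 0L; t2$fn <- 0L
  expect_warning(r <- recall(t2), "no ground-truth")
  expect_equal(r, 0.0)
})

test_that("PR curve matches a brute-force re-matching sweep and recall is monotone", {
  gts <- boxes(0, 0.5, 0.5, 0.2, 0.2)
  dets <- gts; dets$conf <- 0.7
  cv <- pr_curve(list(dets), list(gts), class_id = 0)
  expect_equal(cv$recall, 1.0)
  expect_equal(cv$precision, 1.0)

  spurious <- boxes(0, c(0.1, 0.9), c(0.1, 0.9), c(0.05, 0.05),
                    c(0.05, 0.05), conf = c(0.8, 0.6))
  cv2 <- pr_curve(list(spurious), list(gts), class_id = 0)
  expect_true(all(cv2$precision == 0))

  set.seed(79)
  for (i in 1:10) {
    dets_list <- lapply(1:3, function(j) random_boxes(sample(2:5, 1)))
    gts_list <- lapply(1:3, function(j) random_boxes(sample(1:4, 1),
                                                     with_conf = FALSE))
    for (cl in 0:2) {
      got <- pr_curve(dets_list, gts_list, class_id = cl)
      want <- pr_sweep_oracle(dets_list, gts_list, cl)
      if (is.null(want) || !nrow(want)) {
        expect_equal(got$recall, 0); expect_equal(got$precision, 1.0)
      } else {
        expect_equal(got$recall, want$recall, tolerance = 1e-12)
        expect_equal(got$precision, want$precision, tolerance = 1e-12)
      }
      expect_true(all(diff(got$recall) >= 0))
    }
  }
})

test_that("average precision integrates the interpolated envelope", {
  perfect <- data.frame(recall = 1.0, precision = 1.0)
  expect_equal(average_precision(perfect), 1.0)
  dead <- data.frame(recall = c(0.2, 0.4), precision = c(0, 0))
  expect_equal(average_precision(dead), 0.0)
  expect_equal(average_precision(NULL), 0.0)

  # hand-built curve, integrated by hand:
  # envelope: p=1.0 up to r=0.25, 0.8 up to 0.5, 0.5 up to 0.75
  curve <- data.frame(recall = c(0.25, 0.5, 0.5, 0.75),
                      precision = c(1.0, 0.6, 0.8, 0.5))
  hand <- 0.25 * 1.0 + 0.25 * 0.8 + 0.25 * 0.5
  expect_equal(average_precision(curve), hand, tolerance = 1e-12)

  set.seed(83)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    r <- sort(runif(n)); p <- runif(n)
    curve <- data.frame(recall = r, precision = p)
    expect_equal(average_precision(curve), ap_step_oracle(curve),
                 tolerance = 1e-9)
    ap <- average_precision(curve)
    expect_gte(ap, 0); expect_lte(ap, 1)
  }
})

test_that("AP is invariant under order-preserving confidence rescaling", {
  set.seed(89)
  dets <- random_boxes(8)
  gts <- random_boxes(5, with_conf = FALSE)
  ap1 <- average_precision(pr_curve(list(dets), list(gts), 0))
  dets2 <- dets; dets2$conf <- dets$conf * 0.5
  ap2 <- average_precision(pr_curve(list(dets2), list(gts), 0))
  expect_equal(ap1, ap2, tolerance = 1e-12)
})

test_that("mAP averages only classes present in the ground truth", {
  expect_equal(map50(c(0.5, 1.0)), 0.75)
  expect_equal(map50(c(0.3, 0.3, 0.3)), 0.3)
  expect_equal(map50(c(0.5, 1.0, 0.0), has_gt = c(TRUE, TRUE, FALSE)), 0.75)
  expect_error(map50(c(0.1), has_gt = FALSE), "no class")

  # constructed two-class instance: class 1 never appears in ground truth
  gts <- boxes(0, 0.5, 0.5, 0.2, 0.2)
  dets <- rbind(boxes(0, 0.5, 0.5, 0.2, 0.2, conf = 0.9),
                boxes(1, 0.2, 0.2, 0.1, 0.1, conf = 0.8))
  rep <- evaluate_detections(list(dets), list(gts))
  expect_equal(rep$map50, 1.0)
})

test_that("full evaluation report is internally consistent", {
  set.seed(97)
  dets_list <- lapply(1:4, function(i) random_boxes(6))
  gts_list <- lapply(1:4, function(i) random_boxes(4, with_conf = FALSE))
  rep <- evaluate_detections(dets_list, gts_list, conf_cut = 0.3)
  expect_true(all(rep$per_class$ap >= 0 & rep$per_class$ap <= 1))
  expect_gte(rep$map50, 0); expect_lte(rep$map50, 1)
  expect_equal(rep$map50,
               mean(rep$per_class$ap[rep$per_class$n_gt > 0]))
  expect_gte(rep$precision, 0); expect_lte(rep$recall, 1)
})

test_that("box size summaries match sort-based order statistics", {
  b1 <- boxes(0, 0.5, 0.5, 0.2, 0.3)
  st <- box_size_stats(b1)
  w <- st[st$dim == "w", ]
  expect_true(all(w[, c("min", "q1", "median", "q3", "max")] == 0.2))

  widths <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  b2 <- boxes(rep(0, 5), rep(0.5, 5), rep(0.5, 5), widths, rep(0.2, 5))
  st2 <- box_size_stats(b2)
  expect_equal(st2[st2$dim == "w", "median"], 0.3)

  set.seed(101)
  b3 <- random_boxes(200)
  st3 <- box_size_stats(b3)
  for (cl in unique(b3$class_id)) {
    ws <- sort(b3$w[b3$class_id == cl])
    r <- st3[st3$class_id == cl & st3$dim == "w", ]
    expect_equal(r$min, ws[1]); expect_equal(r$max, ws[length(ws)])
    expect_equal(r$median, unname(stats::quantile(ws, 0.5)), tolerance = 1e-12)
  }
})

test_that("YOLO text files round-trip and malformed lines are located", {
  d <- withr::local_tempdir()
  gt <- boxes(c(0, 2), c(0.25, 0.75), c(0.25, 0.75), c(0.1, 0.2),
              c(0.1, 0.2))
  pr <- gt; pr$conf <- c(0.9, 0.4)
  write_yolo(gt, file.path(d, "img1.txt"))
  write_yolo(pr, file.path(d, "img2.txt"))
  back_gt <- read_yolo(file.path(d, "img1.txt"))
  back_pr <- read_yolo(file.path(d, "img2.txt"))
  expect_equal(back_gt$cx, gt$cx, tolerance = 1e-6)
  expect_true(all(is.na(back_gt$conf)))
  expect_equal(back_pr$conf, pr$conf, tolerance = 1e-6)
  all_files <- read_yolo_dir(d)
  expect_named(all_files, c("img1", "img2"))

  bad <- file.path(d, "bad.txt")
  writeLines(c("0 0.5 0.5 0.1 0.1", "0 0.5 0.5"), bad)
  expect_error(read_yolo(bad), "bad.txt:2")
})

test_that("evaluation reports serialize to CSV with the documented header", {
  gts <- boxes(0, 0.5, 0.5, 0.2, 0.2)
  dets <- gts; dets$conf <- 0.9
  rep <- evaluate_detections(list(dets), list(gts))
  f <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(rep, f)
  df <- read.csv(f)
  expect_equal(names(df), c("class_id", "class_label", "n_gt", "ap",
                            "precision", "recall", "map50"))
  expect_equal(df$map50[df$class_id == "all"], 1.0)
})
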