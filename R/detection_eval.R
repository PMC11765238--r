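#' Construct a set of bounding boxes
#'
#' Boxes use the YOLO convention: normalized center coordinates and sizes in
#' `[0, 1]`; class ids 0 = new, 1 = mature, 2 = over-mature. Ground-truth
#' boxes carry `conf = NA`.
#'
#' @param class_id integer vector.
#' @param cx,cy,w,h numeric vectors of normalized coordinates.
#' @param conf confidence scores in `[0, 1]`, or `NA` for ground truth.
#' @return data.frame with columns `class_id`, `cx`, `cy`, `w`, `h`, `conf`.
#' @export
boxes <- function(class_id, cx, cy, w, h, conf = NA_real_) {
  df <- data.frame(class_id = as.integer(class_id),
                   cx = cx, cy = cy, w = w, h = h, conf = conf)
  if (nrow(df)) {
    stopifnot(all(df$cx >= 0 & df$cx <= 1), all(df$cy >= 0 & df$cy <= 1),
              all(df$w > 0 & df$w <= 1), all(df$h > 0 & df$h <= 1))
    cf <- df$conf[!is.na(df$conf)]
    stopifnot(all(cf >= 0 & cf <= 1))
  }
  df
}

box_corners <- function(b) {
  # clip extents to the unit square
  x1 <- pmax(b$cx - b$w / 2, 0); x2 <- pmin(b$cx + b$w / 2, 1)
  y1 <- pmax(b$cy - b$h / 2, 0); y2 <- pmin(b$cy + b$h / 2, 1)
  cbind(x1, y1, x2, y2)
}

#' Intersection over union of two boxes
#'
#' @param a,b boxes: either numeric `c(cx, cy, w, h)` or one-row data.frames
#'   with those columns.
#' @return IoU in `[0, 1]`; 0 for disjoint boxes; 0 with a warning when
#'   either box has zero area after clipping to the unit square.
#' @export
iou <- function(a, b) {
  a <- as_box_row(a); b <- as_box_row(b)
  ca <- box_corners(a); cb <- box_corners(b)
  area_a <- (ca[3] - ca[1]) * (ca[4] - ca[2])
  area_b <- (cb[3] - cb[1]) * (cb[4] - cb[2])
  if (area_a <= 0 || area_b <= 0) {
    warning("degenerate (zero-area) box; IoU defined as 0")
    return(0)
  }
  iw <- min(ca[3], cb[3]) - max(ca[1], cb[1])
  ih <- min(ca[4], cb[4]) - max(ca[2], cb[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (area_a + area_b - inter)
}

as_box_row <- function(b) {
  if (is.numeric(b) && length(b) >= 4)
    return(data.frame(cx = b[1], cy = b[2], w = b[3], h = b[4]))
  stopifnot(is.data.frame(b), nrow(b) == 1L)
  b
}

# dets x gts IoU matrix (no degeneracy warnings; zero-area -> 0)
iou_matrix <- function(dets, gts) {
  nd <- nrow(dets); ng <- nrow(gts)
  out <- matrix(0, nd, ng)
  if (nd == 0L || ng == 0L) return(out)
  cd <- box_corners(dets); cg <- box_corners(gts)
  ad <- (cd[, 3] - cd[, 1]) * (cd[, 4] - cd[, 2])
  ag <- (cg[, 3] - cg[, 1]) * (cg[, 4] - cg[, 2])
  for (i in seq_len(nd)) {
    iw <- pmin(cd[i, 3], cg[, 3]) - pmax(cd[i, 1], cg[, 1])
    ih <- pmin(cd[i, 4], cg[, 4]) - pmax(cd[i, 2], cg[, 2])
    inter <- pmax(iw, 0) * pmax(ih, 0)
    u <- ad[i] + ag - inter
    out[i, ] <- ifelse(u > 0, inter / u, 0)
  }
  out
}

#' Match detections to ground truth
#'
#' Class-aware greedy matching within one image: detections are taken in
#' order of descending confidence; each claims its highest-IoU unmatched
#' same-class ground-truth box provided IoU >= `iou_thr` (inclusive, the
#' usual mAP\@50 convention). Matched pairs count as true positives,
#' unmatched detections as false positives, unmatched ground-truth boxes as
#' false negatives. IoU ties are broken by ground-truth index order;
#' confidence ties by detection index order.
#'
#' @param dets data.frame of predicted boxes (with `conf`).
#' @param gts data.frame of ground-truth boxes.
#' @param iou_thr IoU threshold in `(0, 1]` (default 0.5).
#' @return a `match_tally`: data.frame with one row per class present,
#'   columns `class_id`, `tp`, `fp`, `fn`.
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  if (iou_thr <= 0 || iou_thr > 1)
    stop("iou_thr must lie in (0, 1]")
  dets <- normalize_box_df(dets); gts <- normalize_box_df(gts)
  classes <- sort(unique(c(dets$class_id, gts$class_id)))
  rows <- lapply(classes, function(cl) {
    d <- dets[dets$class_id == cl, , drop = FALSE]
    g <- gts[gts$class_id == cl, , drop = FALSE]
    ord <- order(-replace(d$conf, is.na(d$conf), 1),
                 seq_len(nrow(d)))
    d <- d[ord, , drop = FALSE]
    M <- iou_matrix(d, g)
    taken <- rep(FALSE, nrow(g))
    tp <- 0L
    for (i in seq_len(nrow(d))) {
      if (!nrow(g)) break
      cand <- which(!taken & M[i, ] >= iou_thr)
      if (!length(cand)) next
      best <- cand[which.max(M[i, cand])]   # first max -> lowest gt index on ties
      taken[best] <- TRUE
      tp <- tp + 1L
    }
    data.frame(class_id = cl, tp = tp,
               fp = nrow(d) - tp, fn = nrow(g) - tp)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class_id = integer(), tp = integer(), fp = integer(),
               fn = integer())
  structure(out, class = c("match_tally", "data.frame"))
}

normalize_box_df <- function(df) {
  if (is.null(df) || !nrow(df))
    return(empty_boxes())
  if (!"conf" %in% names(df)) df$conf <- NA_real_
  df[c("class_id", "cx", "cy", "w", "h", "conf")]
}

#' Combine match tallies
#'
#' Sums per-class counts across images.
#'
#' @param ... `match_tally` objects (or a single list of them).
#' @return a `match_tally`.
#' @export
combine_tallies <- function(...) {
  ts <- list(...)
  if (length(ts) == 1L && !inherits(ts[[1]], "match_tally")) ts <- ts[[1]]
  all <- do.call(rbind, lapply(ts, as.data.frame))
  if (is.null(all) || !nrow(all))
    return(structure(data.frame(class_id = integer(), tp = integer(),
                                fp = integer(), fn = integer()),
                     class = c("match_tally", "data.frame")))
  agg <- stats::aggregate(cbind(tp, fp, fn) ~ class_id, data = all, FUN = sum)
  structure(agg[order(agg$class_id), ], class = c("match_tally", "data.frame"))
}

tally_counts <- function(t, class_id = NULL) {
  if (!is.null(class_id)) t <- t[t$class_id %in% class_id, , drop = FALSE]
  c(tp = sum(t$tp), fp = sum(t$fp), fn = sum(t$fn))
}

#' Precision of a match tally
#'
#' `TP / (TP + FP)`. With zero predictions the ratio is defined as 1.0 (no
#' prediction is wrong; the convention that anchors a precision-recall
#' sweep).
#'
#' @param tally a `match_tally`.
#' @param class_id optional class restriction; default aggregates all rows.
#' @return precision in `[0, 1]`.
#' @export
precision <- function(tally, class_id = NULL) {
  n <- tally_counts(tally, class_id)
  if (n[["tp"]] + n[["fp"]] == 0) return(1.0)
  unname(n[["tp"]] / (n[["tp"]] + n[["fp"]]))
}

#' Recall of a match tally
#'
#' `TP / (TP + FN)`. With no ground-truth boxes the ratio is defined as 0.0
#' and a warning is raised.
#'
#' @inheritParams precision
#' @return recall in `[0, 1]`.
#' @export
recall <- function(tally, class_id = NULL) {
  n <- tally_counts(tally, class_id)
  if (n[["tp"]] + n[["fn"]] == 0) {
    warning("no ground-truth boxes for this class; recall defined as 0")
    return(0.0)
  }
  unname(n[["tp"]] / (n[["tp"]] + n[["fn"]]))
}

#' Precision-recall curve for one class
#'
#' Sweeps the confidence threshold over every distinct detection confidence
#' (descending); at each threshold, detections with confidence >= threshold
#' are re-matched from scratch image by image and the aggregate
#' (recall, precision) point is emitted. Recall is non-decreasing along the
#' sweep.
#'
#' @param dets_by_image list of per-image detection data.frames.
#' @param gts_by_image list of per-image ground-truth data.frames (same
#'   length/order).
#' @param class_id class to evaluate.
#' @param iou_thr IoU threshold (default 0.5).
#' @return a `pr_curve`: data.frame with columns `threshold`, `recall`,
#'   `precision`, plus attribute `class_id`.
#' @export
pr_curve <- function(dets_by_image, gts_by_image, class_id, iou_thr = 0.5) {
  stopifnot(length(dets_by_image) == length(gts_by_image))
  dets_by_image <- lapply(dets_by_image, function(d) {
    d <- normalize_box_df(d); d <- d[d$class_id == class_id, , drop = FALSE]
    # deterministic detectors emit no scores; treat as full confidence,
    # consistent with match_detections()
    d$conf[is.na(d$conf)] <- 1.0
    d
  })
  gts_by_image <- lapply(gts_by_image, function(g) {
    g <- normalize_box_df(g); g[g$class_id == class_id, , drop = FALSE]
  })
  confs <- sort(unique(unlist(lapply(dets_by_image, `[[`, "conf"))),
                decreasing = TRUE)
  n_gt <- sum(vapply(gts_by_image, nrow, 0L))
  if (!length(confs)) {
    out <- data.frame(threshold = NA_real_, recall = 0, precision = 1.0)
    attr(out, "class_id") <- class_id
    class(out) <- c("pr_curve", "data.frame")
    return(out)
  }
  pts <- lapply(confs, function(thr) {
    tallies <- mapply(function(d, g) {
      match_detections(d[!is.na(d$conf) & d$conf >= thr, , drop = FALSE],
                       g, iou_thr = iou_thr)
    }, dets_by_image, gts_by_image, SIMPLIFY = FALSE)
    t <- combine_tallies(tallies)
    n <- tally_counts(t)
    data.frame(threshold = thr,
               recall = if (n_gt > 0) n[["tp"]] / n_gt else 0,
               precision = if (n[["tp"]] + n[["fp"]] > 0)
                 n[["tp"]] / (n[["tp"]] + n[["fp"]]) else 1.0)
  })
  out <- do.call(rbind, pts)
  attr(out, "class_id") <- class_id
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Average precision (area under the PR curve)
#'
#' All-point interpolated area:
#' `AP = sum over i of (r_i - r_(i-1)) * p_interp(r_i)` with
#' `p_interp(r) = max(precision at recall >= r)`. Set
#' `interpolation = "101-point"` for the COCO-style fixed-grid variant.
#'
#' @param curve a `pr_curve` (or data.frame with `recall`, `precision`).
#' @param interpolation `"all-point"` (default) or `"101-point"`.
#' @return AP in `[0, 1]`; 0 for an empty curve.
#' @export
average_precision <- function(curve, interpolation = c("all-point", "101-point")) {
  interpolation <- match.arg(interpolation)
  if (is.null(curve) || !nrow(curve)) return(0.0)
  r <- curve$recall; p <- curve$precision
  ord <- order(r, -p)
  r <- r[ord]; p <- p[ord]
  # envelope: max precision at recall >= r
  penv <- rev(cummax(rev(p)))
  if (interpolation == "101-point") {
    grid <- seq(0, 1, by = 0.01)
    pi_g <- vapply(grid, function(g) {
      k <- which(r >= g)
      if (length(k)) penv[k[1]] else 0
    }, 0)
    return(mean(pi_g))
  }
  keep <- !duplicated(r)   # first point per recall carries the full envelope
  r <- r[keep]; penv <- penv[keep]
  sum(diff(c(0, r)) * penv)
}

#' Mean average precision over classes
#'
#' Unweighted mean of per-class APs, restricted to classes with at least one
#' ground-truth box.
#'
#' @param aps named or plain numeric vector of per-class APs.
#' @param has_gt logical vector: does the class occur in the ground truth?
#'   Defaults to all `TRUE`.
#' @return mAP in `[0, 1]`.
#' @export
map50 <- function(aps, has_gt = rep(TRUE, length(aps))) {
  stopifnot(length(aps) == length(has_gt))
  if (!any(has_gt)) stop("no class has ground-truth boxes; mAP undefined")
  mean(aps[has_gt])
}

#' Evaluate detections against ground truth
#'
#' Runs the full mAP\@50 protocol: per-class PR curves (threshold sweep with
#' greedy IoU matching), per-class AP, their mean over classes present in
#' the ground truth, and aggregate precision/recall at a stated confidence
#' cut.
#'
#' @inheritParams pr_curve
#' @param conf_cut confidence threshold for the reported aggregate
#'   precision/recall point (default 0.25).
#' @param interpolation passed to [average_precision()].
#' @return an `eval_report`: list with `per_class` data.frame (`class_id`,
#'   `n_gt`, `ap`, `precision`, `recall`), `map50`, `precision`, `recall`,
#'   `conf_cut`, `iou_thr`.
#' @export
evaluate_detections <- function(dets_by_image, gts_by_image, iou_thr = 0.5,
                                conf_cut = 0.25,
                                interpolation = "all-point") {
  stopifnot(length(dets_by_image) == length(gts_by_image))
  dets_by_image <- lapply(dets_by_image, normalize_box_df)
  gts_by_image <- lapply(gts_by_image, normalize_box_df)
  classes <- sort(unique(c(unlist(lapply(dets_by_image, `[[`, "class_id")),
                           unlist(lapply(gts_by_image, `[[`, "class_id")))))
  n_gt <- vapply(classes, function(cl)
    sum(vapply(gts_by_image, function(g) sum(g$class_id == cl), 0L)), 0L)
  aps <- vapply(classes, function(cl)
    average_precision(pr_curve(dets_by_image, gts_by_image, cl, iou_thr),
                      interpolation = interpolation), 0)
  cut_tally <- combine_tallies(mapply(function(d, g) {
    match_detections(d[is.na(d$conf) | d$conf >= conf_cut, , drop = FALSE],
                     g, iou_thr = iou_thr)
  }, dets_by_image, gts_by_image, SIMPLIFY = FALSE))
  per_class <- data.frame(class_id = classes, n_gt = n_gt, ap = aps)
  per_class$precision <- vapply(classes, function(cl)
    precision(cut_tally, cl), 0)
  per_class$recall <- vapply(classes, function(cl)
    suppressWarnings(recall(cut_tally, cl)), 0)
  structure(list(per_class = per_class,
                 map50 = map50(aps, n_gt > 0),
                 precision = precision(cut_tally),
                 recall = suppressWarnings(recall(cut_tally)),
                 conf_cut = conf_cut, iou_thr = iou_thr),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report mAP@%.0f = %.4f, P = %.4f, R = %.4f at conf >= %.2f>\n",
              100 * x$iou_thr, x$map50, x$precision, x$recall, x$conf_cut))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Five-number summaries of normalized box sizes
#'
#' Min, lower quartile, median, upper quartile and max of normalized widths
#' and heights, per class. Quartiles use linear interpolation
#' (`stats::quantile` type 7). Classes without boxes are omitted with a
#' message.
#'
#' @param box_df data.frame of boxes.
#' @return data.frame: `class_id`, `dim` (`"w"`/`"h"`), `min`, `q1`,
#'   `median`, `q3`, `max`.
#' @export
box_size_stats <- function(box_df) {
  box_df <- normalize_box_df(box_df)
  if (!nrow(box_df)) stop("no boxes supplied")
  rows <- lapply(sort(unique(box_df$class_id)), function(cl) {
    b <- box_df[box_df$class_id == cl, ]
    do.call(rbind, lapply(c("w", "h"), function(dm) {
      q <- stats::quantile(b[[dm]], c(0, .25, .5, .75, 1), type = 7,
                           names = FALSE)
      data.frame(class_id = cl, dim = dm, min = q[1], q1 = q[2],
                 median = q[3], q3 = q[4], max = q[5])
    }))
  })
  do.call(rbind, rows)
}

#' Read / write YOLO-format label files
#'
#' One text file per image; each line is `class cx cy w h` (ground truth)
#' or `class cx cy w h conf` (predictions), whitespace-separated with '.'
#' decimal marks. Malformed lines raise an error naming the file and line
#' number.
#'
#' @param path a label file.
#' @return data.frame of boxes (`conf` is `NA` for 5-field lines).
#' @export
read_yolo <- function(path) {
  if (!file.exists(path)) stop("no such label file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_boxes())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!(length(f) %in% c(5L, 6L)))
      stop(sprintf("malformed YOLO line (%d fields) at %s:%d",
                   length(f), path, i))
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v)))
      stop(sprintf("non-numeric field in YOLO line at %s:%d", path, i))
    data.frame(class_id = as.integer(v[1]), cx = v[2], cy = v[3],
               w = v[4], h = v[5],
               conf = if (length(v) == 6L) v[6] else NA_real_)
  })
  do.call(rbind, rows)
}

#' @rdname read_yolo
#' @param dir directory of `.txt` label files.
#' @return for `read_yolo_dir`: named list of box data.frames keyed by file
#'   stem.
#' @export
read_yolo_dir <- function(dir) {
  if (!dir.exists(dir)) stop("no such label directory: ", dir)
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  out <- lapply(files, read_yolo)
  names(out) <- tools::file_path_sans_ext(basename(files))
  out
}

#' @rdname read_yolo
#' @param box_df data.frame of boxes to write.
#' @export
write_yolo <- function(box_df, path) {
  box_df <- normalize_box_df(box_df)
  fmt <- function(r) {
    base <- sprintf("%d %.6f %.6f %.6f %.6f", r$class_id, r$cx, r$cy, r$w, r$h)
    if (!is.na(r$conf)) paste(base, sprintf("%.6f", r$conf)) else base
  }
  lines <- if (nrow(box_df))
    vapply(seq_len(nrow(box_df)), function(i) fmt(box_df[i, ]), "")
  else character()
  writeLines(lines, path)
  invisible(path)
}

#' Write an evaluation report as CSV
#'
#' Fixed header `class_id,class_label,n_gt,ap,precision,recall,map50`; one
#' row per class plus an `all` summary row carrying the aggregate
#' precision/recall and the mAP.
#'
#' @param report an `eval_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  pc <- report$per_class
  df <- data.frame(class_id = as.character(pc$class_id),
                   class_label = class_id_to_label(pc$class_id),
                   n_gt = pc$n_gt, ap = pc$ap,
                   precision = pc$precision, recall = pc$recall,
                   map50 = NA_real_)
  df <- rbind(df, data.frame(class_id = "all", class_label = "all",
                             n_gt = sum(pc$n_gt), ap = NA_real_,
                             precision = report$precision,
                             recall = report$recall,
                             map50 = report$map50))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
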