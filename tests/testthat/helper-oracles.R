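# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: scalar closed forms, brute-force sweeps,
# rasterization.

# scalar hexcone RGB -> HSV (H in degrees, S and V in [0,1])
hexcone_hsv <- function(r, g, b) {
  mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
  v <- mx / 255
  s <- if (mx == 0) 0 else d / mx
  h <- if (d == 0) 0
  else if (mx == r) 60 * (((g - b) / d) %% 6)
  else if (mx == g) 60 * ((b - r) / d + 2)
  else 60 * ((r - g) / d + 4)
  c(h = h, s = s, v = v)
}

# IoU by rasterizing both boxes on a fine grid over the unit square
raster_iou <- function(a, b, res = 2000) {
  centers <- (seq_len(res) - 0.5) / res
  inside <- function(bx) {
    x <- centers >= bx[1] - bx[3] / 2 & centers <= bx[1] + bx[3] / 2
    y <- centers >= bx[2] - bx[4] / 2 & centers <= bx[2] + bx[4] / 2
    outer(y, x)
  }
  A <- inside(a); B <- inside(b)
  sum(A & B) / sum(A | B)
}

# independent greedy matcher: plain loops, corner arithmetic written from
# scratch; considers every ground truth at every step
greedy_match_oracle <- function(dets, gts, iou_thr = 0.5) {
  iou1 <- function(p, q) {
    ax1 <- p["cx"] - p["w"] / 2; ax2 <- p["cx"] + p["w"] / 2
    ay1 <- p["cy"] - p["h"] / 2; ay2 <- p["cy"] + p["h"] / 2
    bx1 <- q["cx"] - q["w"] / 2; bx2 <- q["cx"] + q["w"] / 2
    by1 <- q["cy"] - q["h"] / 2; by2 <- q["cy"] + q["h"] / 2
    iw <- min(ax2, bx2) - max(ax1, bx1)
    ih <- min(ay2, by2) - max(ay1, by1)
    if (iw <= 0 || ih <= 0) return(0)
    inter <- iw * ih
    inter / ((ax2 - ax1) * (ay2 - ay1) + (bx2 - bx1) * (by2 - by1) - inter)
  }
  classes <- sort(unique(c(dets$class_id, gts$class_id)))
  res <- NULL
  for (cl in classes) {
    d <- dets[dets$class_id == cl, , drop = FALSE]
    g <- gts[gts$class_id == cl, , drop = FALSE]
    d <- d[order(-d$conf, seq_len(nrow(d))), , drop = FALSE]
    used <- rep(FALSE, nrow(g))
    tp <- 0L
    for (i in seq_len(nrow(d))) {
      best <- 0; best_j <- 0L
      for (j in seq_len(nrow(g))) {
        if (used[j]) next
        v <- iou1(unlist(d[i, c("cx", "cy", "w", "h")]),
                  unlist(g[j, c("cx", "cy", "w", "h")]))
        if (v >= iou_thr && v > best) { best <- v; best_j <- j }
      }
      if (best_j > 0L) { used[best_j] <- TRUE; tp <- tp + 1L }
    }
    res <- rbind(res, data.frame(class_id = cl, tp = tp,
                                 fp = nrow(d) - tp, fn = nrow(g) - tp))
  }
  res
}

# brute-force PR sweep for one class over a single pool of images
pr_sweep_oracle <- function(dets_by_image, gts_by_image, class_id,
                            iou_thr = 0.5) {
  dets_by_image <- lapply(dets_by_image, function(d)
    d[d$class_id == class_id, , drop = FALSE])
  gts_by_image <- lapply(gts_by_image, function(g)
    g[g$class_id == class_id, , drop = FALSE])
  confs <- sort(unique(unlist(lapply(dets_by_image, `[[`, "conf"))),
                decreasing = TRUE)
  n_gt <- sum(vapply(gts_by_image, nrow, 0L))
  do.call(rbind, lapply(confs, function(thr) {
    tp <- 0L; fp <- 0L
    for (i in seq_along(dets_by_image)) {
      d <- dets_by_image[[i]]
      t <- greedy_match_oracle(d[d$conf >= thr, , drop = FALSE],
                               gts_by_image[[i]], iou_thr)
      if (!is.null(t)) { tp <- tp + sum(t$tp); fp <- fp + sum(t$fp) }
    }
    data.frame(threshold = thr,
               recall = if (n_gt) tp / n_gt else 0,
               precision = if (tp + fp) tp / (tp + fp) else 1)
  }))
}

# step integration of the interpolated PR envelope on a dense recall grid
ap_step_oracle <- function(curve, n_grid = 200000) {
  p_interp <- function(r) {
    sel <- curve$recall >= r
    if (!any(sel)) 0 else max(curve$precision[sel])
  }
  rs <- sort(unique(curve$recall))
  total <- 0
  prev <- 0
  for (r in rs) {
    total <- total + (r - prev) * p_interp(r)
    prev <- r
  }
  total
}

random_boxes <- function(n, classes = 0:2, with_conf = TRUE) {
  if (n == 0) return(plaquekit:::empty_boxes())
  w <- runif(n, 0.05, 0.4); h <- runif(n, 0.05, 0.4)
  data.frame(class_id = sample(classes, n, replace = TRUE),
             cx = runif(n, w / 2, 1 - w / 2),
             cy = runif(n, h / 2, 1 - h / 2),
             w = w, h = h,
             conf = if (with_conf) round(runif(n), 3) else NA_real_)
}
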