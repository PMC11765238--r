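SURFACES <- c("cervical", "middle", "incisal_occlusal", "lingual_vestibular")

#' Per-tooth four-surface plaque chart
#'
#' Each tooth is scored on four areas: cervical, middle, incisal/occlusal
#' and lingual/vestibular. The chart records plaque presence per cell; the
#' number of affected cells is NAPC and the total number of cells NTAE in
#' the O'Leary index.
#'
#' @param teeth character vector of tooth identifiers.
#' @param presence logical matrix, `length(teeth)` x 4, or missing for an
#'   all-clean chart.
#' @return an object of class `surface_chart`.
#' @export
surface_chart <- function(teeth, presence = NULL) {
  teeth <- as.character(teeth)
  if (length(teeth) < 1L) stop("a chart needs at least one tooth")
  if (is.null(presence))
    presence <- matrix(FALSE, length(teeth), 4L)
  presence <- as.matrix(presence)
  stopifnot(is.logical(presence), nrow(presence) == length(teeth),
            ncol(presence) == 4L)
  dimnames(presence) <- list(teeth, SURFACES)
  structure(list(teeth = teeth, presence = presence),
            class = "surface_chart")
}

#' @export
print.surface_chart <- function(x, ...) {
  cat(sprintf("<surface_chart %d teeth x 4 surfaces, %d/%d affected>\n",
              length(x$teeth), sum(x$presence), length(x$presence)))
  invisible(x)
}

#' O'Leary plaque index of a chart
#'
#' `index = 100 * NAPC / NTAE`, where NAPC is the number of tooth areas
#' affected by plaque and NTAE the total number of areas examined. The
#' severity category is attached via [categorize_oleary()].
#'
#' @param chart a `surface_chart`.
#' @return an `oleary_result`: list with `index` (percent), `category`,
#'   `napc`, `ntae`.
#' @export
compute_index <- function(chart) {
  stopifnot(inherits(chart, "surface_chart"))
  ntae <- length(chart$presence)
  if (ntae == 0L) stop("chart has no examined areas; index undefined")
  napc <- sum(chart$presence)
  index <- 100 * napc / ntae
  structure(list(index = index, category = categorize_oleary(index),
                 napc = as.integer(napc), ntae = as.integer(ntae)),
            class = "oleary_result")
}

#' @export
print.oleary_result <- function(x, ...) {
  cat(sprintf("<oleary_result %.2f%% (%d/%d areas) -> %s>\n",
              x$index, x$napc, x$ntae, x$category))
  invisible(x)
}

#' Severity category of an O'Leary index
#'
#' Mild for indices up to 25%, Moderate above 25 up to 50%, Severe above
#' 50% (the continuous totalization of the printed integer bins Mild 0-25,
#' Moderate 26-50, Severe >50).
#'
#' @param index percentage in `[0, 100]`.
#' @return `"MILD"`, `"MODERATE"` or `"SEVERE"` (vectorized).
#' @export
categorize_oleary <- function(index) {
  if (any(index < 0 | index > 100))
    stop("index must lie in [0, 100]")
  ifelse(index <= 25, "MILD", ifelse(index <= 50, "MODERATE", "SEVERE"))
}

#' Rectangular tooth layout
#'
#' Maps image pixels to chart cells: a grid of upright tooth rectangles,
#' each split into four horizontal bands (cervical, middle,
#' incisal/occlusal, lingual/vestibular, top to bottom with equal heights).
#' Clinical layouts can be supplied as any data.frame with the same columns.
#'
#' @param width,height image size in pixels.
#' @param n_teeth number of teeth (default 12).
#' @param rows number of tooth rows (default 2: upper and lower arch of a
#'   bite view).
#' @param margin_x,margin_y pixels left free at the borders (lip bands).
#' @param gap horizontal gap between adjacent teeth in pixels.
#' @return a `tooth_layout`: data.frame with columns `tooth_id`, `surface`,
#'   `x0`, `x1`, `y0`, `y1` (inclusive 1-based pixel bounds).
#' @export
default_tooth_layout <- function(width = 1280, height = 1280, n_teeth = 12,
                                 rows = 2, margin_x = 60, margin_y = 160,
                                 gap = 12) {
  stopifnot(n_teeth %% rows == 0)
  per_row <- n_teeth %/% rows
  tw <- (width - 2 * margin_x - (per_row - 1) * gap) %/% per_row
  th <- (height - 2 * margin_y - (rows - 1) * gap) %/% rows
  band <- th %/% 4
  stopifnot(tw >= 8, band >= 4)
  out <- list()
  t <- 0L
  for (r in seq_len(rows)) {
    y_top <- margin_y + (r - 1) * (th + gap)
    for (k in seq_len(per_row)) {
      t <- t + 1L
      x0 <- margin_x + (k - 1) * (tw + gap) + 1L
      for (s in seq_along(SURFACES)) {
        out[[length(out) + 1L]] <- data.frame(
          tooth_id = sprintf("T%02d", t), surface = SURFACES[s],
          x0 = x0, x1 = x0 + tw - 1L,
          y0 = y_top + (s - 1L) * band + 1L,
          y1 = y_top + s * band)
      }
    }
  }
  layout <- do.call(rbind, out)
  class(layout) <- c("tooth_layout", "data.frame")
  layout
}

#' Build a surface chart from plaque masks
#'
#' A chart cell is marked affected iff the union of the plaque masks (all
#' three stain classes pooled: the index predates staging) covers at least
#' `min_coverage` of the cell's zone pixels. Per-class charts are available
#' via `by_class = TRUE`.
#'
#' @param masks named list of `plaque_mask` (as from
#'   [extract_class_masks()]).
#' @param layout a `tooth_layout` (pixel bounds within the mask raster).
#' @param min_coverage minimum covered fraction of a zone (default 0.05,
#'   so isolated noise pixels cannot mark a surface).
#' @param by_class if `TRUE`, return a named list of per-class charts
#'   alongside the pooled one.
#' @return a `surface_chart`, or a list `(pooled, per_class)` when
#'   `by_class = TRUE`.
#' @export
chart_from_masks <- function(masks, layout, min_coverage = 0.05,
                             by_class = FALSE) {
  if (is.null(layout) || !nrow(layout)) stop("empty tooth layout")
  union_mask <- Reduce(`|`, lapply(masks, `[[`, "mask"))
  teeth <- unique(layout$tooth_id)
  fill_chart <- function(m) {
    pres <- matrix(FALSE, length(teeth), 4L)
    for (i in seq_len(nrow(layout))) {
      z <- layout[i, ]
      zone <- m[z$y0:z$y1, z$x0:z$x1]
      cov <- mean(zone)
      if (cov >= min_coverage) {
        pres[match(z$tooth_id, teeth), match(z$surface, SURFACES)] <- TRUE
      }
    }
    surface_chart(teeth, pres)
  }
  pooled <- fill_chart(union_mask)
  if (!by_class) return(pooled)
  per_class <- lapply(masks, function(m) fill_chart(m$mask))
  list(pooled = pooled, per_class = per_class)
}

#' Summarize a cohort of O'Leary results
#'
#' Histogram of indices over fixed-width bins spanning `[0, 100]` plus
#' per-severity-category counts (which always sum to the cohort size).
#' Bins are left-closed `[low, high)`, with the final bin closed at 100.
#'
#' @param results list of `oleary_result` (or numeric vector of indices).
#' @param bin_width histogram bin width in percent (default 10).
#' @return list with `histogram` (data.frame `bin_low`, `bin_high`,
#'   `count`) and `categories` (data.frame `category`, `count`).
#' @export
cohort_summary <- function(results, bin_width = 10) {
  if (is.list(results) && length(results) &&
      inherits(results[[1]], "oleary_result")) {
    idx <- vapply(results, `[[`, 0, "index")
  } else {
    idx <- as.numeric(results)
  }
  if (!length(idx)) stop("empty cohort")
  stopifnot(bin_width > 0, all(idx >= 0 & idx <= 100))
  lows <- seq(0, 100 - bin_width, by = bin_width)
  highs <- pmin(lows + bin_width, 100)
  count <- vapply(seq_along(lows), function(i) {
    if (i == length(lows)) sum(idx >= lows[i] & idx <= highs[i])
    else sum(idx >= lows[i] & idx < highs[i])
  }, 0L)
  cats <- factor(categorize_oleary(idx),
                 levels = c("MILD", "MODERATE", "SEVERE"))
  list(histogram = data.frame(bin_low = lows, bin_high = highs,
                              count = count),
       categories = data.frame(category = levels(cats),
                               count = as.integer(table(cats))))
}

#' Read / write surface charts as CSV
#'
#' Long format with header `tooth_id,surface,affected` and `affected` in
#' `{0, 1}`.
#'
#' @param chart a `surface_chart`.
#' @param path CSV path.
#' @return `path` invisibly for write; a `surface_chart` for read.
#' @export
write_chart <- function(chart, path) {
  stopifnot(inherits(chart, "surface_chart"))
  df <- data.frame(
    tooth_id = rep(chart$teeth, each = 4L),
    surface = rep(SURFACES, times = length(chart$teeth)),
    affected = as.integer(t(chart$presence)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chart
#' @export
read_chart <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tooth_id", "surface", "affected") %in% names(df)))
  teeth <- unique(df$tooth_id)
  pres <- matrix(FALSE, length(teeth), 4L)
  for (i in seq_len(nrow(df))) {
    pres[match(df$tooth_id[i], teeth), match(df$surface[i], SURFACES)] <-
      df$affected[i] != 0
  }
  surface_chart(teeth, pres)
}
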