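#' Pixel area of a region
#'
#' The area trait is the actual number of pixels belonging to the region
#' — no perimeter correction and no hole discount (holes are filled
#' earlier in the pipeline).
#'
#' @param region A logical matrix, a [binary_mask], or a two-column
#'   matrix of (row, col) pixel coordinates.
#' @return Integer pixel count.
#' @export
region_area <- function(region) {
  coords <- region_coords(region)
  if (nrow(coords) == 0L) stop("empty region", call. = FALSE)
  nrow(coords)
}

region_coords <- function(region) {
  if (is.matrix(region) && !is.logical(region) && ncol(region) == 2L &&
      !inherits(region, "binary_mask")) {
    return(region)
  }
  m <- as_plain(as.matrix(region))
  which(m > 0, arr.ind = TRUE)
}

#' Major axis of the moment-equivalent ellipse (PBL2)
#'
#' The primary-branch length proxy PBL2 is the major-axis length of the
#' ellipse that has the same normalized second central moments as the
#' region. With area-normalized central moments `uxx`, `uyy`, `uxy`
#' (x = column, y = row) the length is
#' `2 * sqrt(2) * sqrt(uxx + uyy + sqrt((uxx - uyy)^2 + 4 uxy^2))`.
#'
#' By default each diagonal moment is augmented by 1/12, the variance of
#' a unit pixel, which keeps single-pixel and one-pixel-thin regions
#' non-degenerate and reproduces the measurement convention of the
#' classical region-properties tools; set `pixel_correction = FALSE` for
#' the bare point-mass moments.
#'
#' @inheritParams region_area
#' @param pixel_correction Add the 1/12 per-pixel variance to the
#'   diagonal second moments (default `TRUE`).
#' @return Major-axis length in pixels (`> 0`).
#' @export
region_major_axis <- function(region, pixel_correction = TRUE) {
  region_ellipse_axes(region, pixel_correction)[["major"]]
}

region_ellipse_axes <- function(region, pixel_correction = TRUE) {
  coords <- region_coords(region)
  n <- nrow(coords)
  if (n == 0L) stop("empty region", call. = FALSE)
  y <- coords[, 1]; x <- coords[, 2]
  corr <- if (pixel_correction) 1 / 12 else 0
  uxx <- sum(x * x) / n - mean(x)^2 + corr
  uyy <- sum(y * y) / n - mean(y)^2 + corr
  uxy <- sum(x * y) / n - mean(x) * mean(y)
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  c(major = 2 * sqrt(2) * sqrt(uxx + uyy + common),
    minor = 2 * sqrt(2) * sqrt(max(uxx + uyy - common, 0)))
}

#' Per-region traits of a labeled mask
#'
#' Computes, for every labeled region, the pixel area, the
#' moment-equivalent-ellipse major and minor axis lengths and the
#' centroid, in one vectorized pass over the foreground pixels.
#'
#' @param lbl A [labeled_mask].
#' @param pixel_correction See [region_major_axis()].
#' @return A data frame with columns `label`, `area_px`, `pbl2_px`,
#'   `minor_px`, `centroid_row`, `centroid_col`.
#' @export
region_traits <- function(lbl, pixel_correction = TRUE) {
  stopifnot(inherits(lbl, "labeled_mask"))
  n <- n_regions(lbl)
  if (n == 0L)
    return(data.frame(label = integer(0), area_px = integer(0),
                      pbl2_px = numeric(0), minor_px = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  px <- as_plain(lbl)
  idx <- which(px > 0L)
  lab <- px[idx]
  h <- nrow(lbl)
  row <- ((idx - 1L) %% h) + 1L
  col <- ((idx - 1L) %/% h) + 1L
  area <- tabulate(lab, nbins = n)
  sx <- rowsum(as.numeric(col), lab)[, 1]
  sy <- rowsum(as.numeric(row), lab)[, 1]
  sxx <- rowsum(as.numeric(col) * col, lab)[, 1]
  syy <- rowsum(as.numeric(row) * row, lab)[, 1]
  sxy <- rowsum(as.numeric(col) * row, lab)[, 1]
  mx <- sx / area; my <- sy / area
  corr <- if (pixel_correction) 1 / 12 else 0
  uxx <- sxx / area - mx^2 + corr
  uyy <- syy / area - my^2 + corr
  uxy <- sxy / area - mx * my
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  data.frame(
    label = seq_len(n),
    area_px = area,
    pbl2_px = 2 * sqrt(2) * sqrt(uxx + uyy + common),
    minor_px = 2 * sqrt(2) * sqrt(pmax(uxx + uyy - common, 0)),
    centroid_row = my,
    centroid_col = mx
  )
}

#' Aggregate branch-region traits into a per-panicle measurement
#'
#' Sums the per-region traits over all labeled primary-branch regions:
#' `tlpb2_px` is the sum of the region major-axis lengths (the image
#' analogue of the total length of primary branches, TLPB2) and
#' `total_area_px` the summed pixel area. Lengths are also reported in
#' centimetres via the scan resolution, `cm = px * 2.54 / dpi`.
#'
#' @param lbl A [labeled_mask] with at least one region.
#' @param dpi Scan resolution; defaults to the mask's own dpi, else 72.
#' @param panicle_id,variety Identifiers carried into the output.
#' @param snpp_manual Optional manually counted spikelet number.
#' @param pal_cm,tlpb1_cm Optional manual ruler measurements (panicle
#'   axis length; total primary-branch length, method-1 endpoints).
#' @param pixel_correction See [region_major_axis()].
#' @return A `panicle_measurement` object: a list with the per-panicle
#'   aggregates and a `regions` data frame (see [region_traits()]).
#' @export
measure_panicle <- function(lbl, dpi = NULL, panicle_id = "panicle",
                            variety = NA_character_,
                            snpp_manual = NA_integer_,
                            pal_cm = NA_real_, tlpb1_cm = NA_real_,
                            pixel_correction = TRUE) {
  stopifnot(inherits(lbl, "labeled_mask"))
  if (n_regions(lbl) == 0L) stop("no regions to measure", call. = FALSE)
  if (is.null(dpi)) dpi <- img_dpi(lbl)
  if (!is.finite(dpi) || dpi <= 0) dpi <- 72
  if (!is.na(snpp_manual) && snpp_manual < 0)
    stop("snpp_manual must be non-negative", call. = FALSE)
  reg <- region_traits(lbl, pixel_correction)
  tlpb2_px <- sum(reg$pbl2_px)
  structure(list(
    panicle_id = as.character(panicle_id),
    variety = as.character(variety),
    n_regions = nrow(reg),
    total_area_px = sum(reg$area_px),
    tlpb2_px = tlpb2_px,
    tlpb2_cm = px_to_cm(tlpb2_px, dpi),
    dpi = dpi,
    snpp_manual = snpp_manual,
    pal_cm = pal_cm,
    tlpb1_cm = tlpb1_cm,
    regions = reg
  ), class = "panicle_measurement")
}

#' @export
print.panicle_measurement <- function(x, ...) {
  cat(sprintf("<panicle_measurement '%s': %d regions, area %d px, TLPB2 %.1f px (%.2f cm)>\n",
              x$panicle_id, x$n_regions, x$total_area_px, x$tlpb2_px, x$tlpb2_cm))
  invisible(x)
}

#' @export
as.data.frame.panicle_measurement <- function(x, ...) {
  data.frame(panicle_id = x$panicle_id, variety = x$variety,
             n_regions = x$n_regions, total_area_px = x$total_area_px,
             tlpb2_px = x$tlpb2_px, tlpb2_cm = x$tlpb2_cm,
             snpp_manual = x$snpp_manual, stringsAsFactors = FALSE)
}

#' Pixel/centimetre conversion
#'
#' @param px,cm Length in pixels / centimetres.
#' @param dpi Dots per inch of the scan.
#' @return Converted length.
#' @export
px_to_cm <- function(px, dpi) px * 2.54 / dpi

#' @rdname px_to_cm
#' @export
cm_to_px <- function(cm, dpi) cm * dpi / 2.54

shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

neighbor_shifts <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                        c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))

#' Skeletonize a mask and locate junction/terminal vertices
#'
#' Thins the mask to a one-pixel-wide skeleton (Zhang-Suen iterative
#' thinning) and classifies skeleton pixels by their number of
#' 8-connected skeleton neighbours: exactly one neighbour marks a
#' terminal (branch tip), three or more mark a junction (branching
#' point). This is a diagnostic of panicle architecture; it plays no
#' part in the spikelet-number estimate.
#'
#' @param mask A [binary_mask].
#' @return A list with `skeleton` (a [binary_mask]), `junctions` and
#'   `terminals` (two-column (row, col) coordinate matrices). An empty
#'   mask gives empty outputs.
#' @export
skeleton_vertices <- function(mask) {
  m <- (as_plain(as.matrix(mask)) > 0) * 1L
  h <- nrow(m); w <- ncol(m)
  if (sum(m) > 0L) {
    repeat {
      changed <- FALSE
      for (step in 1:2) {
        nb <- lapply(neighbor_shifts, function(s) shift_mat(m, s[1], s[2]))
        # nb order: P2(N), P3(NE), P4(E), P5(SE), P6(S), P7(SW), P8(W), P9(NW)
        B <- Reduce(`+`, nb)
        seq9 <- c(nb, nb[1])
        A <- matrix(0L, h, w)
        for (k in 1:8) A <- A + (seq9[[k]] == 0L & seq9[[k + 1L]] == 1L)
        if (step == 1L) {
          cond <- nb[[1]] * nb[[3]] * nb[[5]] == 0L &
                  nb[[3]] * nb[[5]] * nb[[7]] == 0L
        } else {
          cond <- nb[[1]] * nb[[3]] * nb[[7]] == 0L &
                  nb[[1]] * nb[[5]] * nb[[7]] == 0L
        }
        del <- m == 1L & B >= 2L & B <= 6L & A == 1L & cond
        if (any(del)) {
          m[del] <- 0L
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  skel <- m == 1L
  if (!any(skel)) {
    empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
    return(list(skeleton = binary_mask(skel, dpi = img_dpi(mask)),
                junctions = empty, terminals = empty))
  }
  nbcount <- Reduce(`+`, lapply(neighbor_shifts,
                                function(s) shift_mat(m, s[1], s[2])))
  term <- skel & nbcount == 1L
  junc <- skel & nbcount >= 3L
  coords <- function(x) {
    cc <- which(x, arr.ind = TRUE)
    colnames(cc) <- c("row", "col")
    cc
  }
  list(skeleton = binary_mask(skel, dpi = img_dpi(mask)),
       junctions = coords(junc), terminals = coords(term))
}
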