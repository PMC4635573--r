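#' Convert an RGB scan to grayscale by the channel mean
#'
#' Each output pixel is the unweighted arithmetic mean of the red, green
#' and blue channels, `(R + G + B) / 3`, rounded half-up to an integer.
#' The unweighted mean (rather than luminance weights) is deliberate: the
#' panicle/background contrast at scanner resolution is strong in all
#' three channels and the mean keeps the pipeline's arithmetic exactly
#' reproducible across tool chains.
#'
#' @param img An [rgb_image].
#' @return A [gray_image] of the same height and width.
#' @export
to_gray <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("not an RGB image", call. = FALSE)
  px <- as_plain(img)
  g <- floor((px[, , 1L] + px[, , 2L] + px[, , 3L]) / 3 + 0.5)
  gray_image(g, dpi = img_dpi(img))
}

#' Otsu's automatic threshold
#'
#' Finds the integer threshold `t` in 0..254 that maximises the
#' between-class variance of the 256-bin intensity histogram split into
#' the classes `{<= t}` and `{> t}`. Among tied maximisers the smallest
#' threshold is returned.
#'
#' @param img A [gray_image] (or plain matrix of intensities in 0-255)
#'   with at least two distinct values.
#' @return Integer threshold in `[0, 254]`.
#' @export
otsu_threshold <- function(img) {
  v <- as.integer(round(as_plain(as.matrix(img))))
  counts <- tabulate(v + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L)
    stop("degenerate histogram: image has a single intensity value",
         call. = FALSE)
  p <- counts / sum(counts)
  lev <- 0:255
  w0 <- cumsum(p)[1:255]          # P(class 0) for t = 0..254
  m0 <- cumsum(p * lev)[1:255]    # first moment of class 0
  mt <- sum(p * lev)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  # smallest threshold among (numerically) tied maximisers: thresholds in
  # a histogram gap share the same class split, so their variances are
  # equal up to rounding noise
  mx <- max(sigma_b)
  as.integer(which(sigma_b >= mx - 1e-9 * (1 + abs(mx)))[1] - 1L)
}

#' Binarize a gray image at a threshold
#'
#' @param img A [gray_image].
#' @param t Threshold in `[0, 255]`.
#' @param polarity `"dark_foreground"` marks pixels `<= t` as foreground
#'   (the default: scans are a dark panicle on a light scanner lid),
#'   `"light_foreground"` marks pixels `> t`, and `"auto"` picks whichever
#'   class has fewer pixels.
#' @return A [binary_mask].
#' @export
binarize <- function(img, t,
                     polarity = c("dark_foreground", "light_foreground", "auto")) {
  polarity <- match.arg(polarity)
  stopifnot(t >= 0, t <= 255)
  px <- as_plain(as.matrix(img))
  dark <- px <= t
  fg <- switch(polarity,
    dark_foreground  = dark,
    light_foreground = !dark,
    auto = if (sum(dark) <= length(dark) - sum(dark)) dark else !dark)
  binary_mask(fg, dpi = img_dpi(img))
}

# one erosion/dilation step by the 3x3 diamond (centre + 4-neighbours),
# vectorized as row/column shifts; outside the image counts as background
erode1 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  down <- rbind(FALSE, m[-h, , drop = FALSE])
  left <- cbind(m[, -1, drop = FALSE], FALSE)
  right <- cbind(FALSE, m[, -w, drop = FALSE])
  m & up & down & left & right
}

dilate1 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  down <- rbind(FALSE, m[-h, , drop = FALSE])
  left <- cbind(m[, -1, drop = FALSE], FALSE)
  right <- cbind(FALSE, m[, -w, drop = FALSE])
  m | up | down | left | right
}

#' Morphological opening with a disk structuring element
#'
#' Erosion followed by dilation with a disk of the given radius (the
#' default radius 1 is the 3x3 diamond: centre plus 4-neighbours). In the
#' panicle pipeline this removes the thin rachis and pedicels while the
#' spikelet-covered branch regions survive, which is what separates the
#' primary-branch regions from each other.
#'
#' The radius-`r` disk is the `r`-fold Minkowski sum of the radius-1
#' diamond, so erosion/dilation are applied as `r` passes of the
#' elementary operation — exact, and vectorized as four matrix shifts
#' per pass.
#'
#' @param mask A [binary_mask].
#' @param radius Disk radius in pixels, integer `>= 1`.
#' @return A [binary_mask]; always a subset of the input.
#' @export
morphological_open <- function(mask, radius = 1L) {
  if (length(radius) != 1L || !is.finite(radius) || radius < 1 ||
      radius != as.integer(radius))
    stop("radius must be an integer >= 1", call. = FALSE)
  m <- as_plain(as.matrix(mask)) > 0
  for (i in seq_len(radius)) m <- erode1(m)
  for (i in seq_len(radius)) m <- dilate1(m)
  binary_mask(m, dpi = img_dpi(mask))
}

#' Fill enclosed holes in a binary mask
#'
#' Every background component that is not 4-connected to the image border
#' becomes foreground: the complement of the mask is reconstructed from a
#' border marker (a geodesic flood from a one-pixel background frame) and
#' whatever the flood cannot reach is a hole. In panicle scans this
#' closes the gaps that awns and touching spikelets enclose inside a
#' branch region.
#'
#' @param mask A [binary_mask].
#' @return A [binary_mask]; always a superset of the input.
#' @export
fill_holes <- function(mask) {
  m <- as_plain(as.matrix(mask))
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m * 1
  flooded <- EBImage::floodFill(pad, c(1L, 1L), col = 2)
  out <- as.matrix(flooded)[2:(h + 1L), 2:(w + 1L)] != 2
  binary_mask(out, dpi = img_dpi(mask))
}

#' Remove small connected components
#'
#' Deletes every 8-connected foreground component with strictly fewer
#' than `min_pixels` pixels (dust, detached awn fragments); components at
#' or above the cutoff are kept unchanged. The default cutoff of 100
#' pixels is the pipeline's standard cleanup rule at 72 dpi.
#'
#' @param mask A [binary_mask].
#' @param min_pixels Minimum component size to keep, integer `>= 1`.
#' @return A [binary_mask].
#' @export
remove_small_objects <- function(mask, min_pixels = 100L) {
  if (length(min_pixels) != 1L || !is.finite(min_pixels) || min_pixels < 1)
    stop("min_pixels must be an integer >= 1", call. = FALSE)
  lbl <- label_components(mask)
  n <- n_regions(lbl)
  if (n == 0L) return(binary_mask(as_plain(as.matrix(mask)) & FALSE,
                                  dpi = img_dpi(mask)))
  sizes <- tabulate(as_plain(lbl)[as_plain(lbl) > 0L], nbins = n)
  keep <- c(FALSE, sizes >= min_pixels)  # index by label + 1
  out <- matrix(keep[as_plain(lbl) + 1L], nrow(lbl), ncol(lbl))
  binary_mask(out, dpi = img_dpi(mask))
}

#' Label 8-connected foreground components
#'
#' Components are labelled 1..n in raster-scan order (row-major from the
#' top-left) of their first-encountered pixel; background stays 0.
#' Foreground uses 8-connectivity, the dual of the 4-connectivity used
#' for background holes in [fill_holes()].
#'
#' Implemented as run-length connected-component labelling: foreground
#' runs are extracted per row and merged across adjacent rows with a
#' union-find, so cost scales with the number of runs rather than with
#' repeated image passes.
#'
#' @param mask A [binary_mask].
#' @return A [labeled_mask]; an empty mask yields `n_regions = 0`.
#' @export
label_components <- function(mask) {
  m <- as_plain(as.matrix(mask)) > 0
  h <- nrow(m); w <- ncol(m)
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  row_first <- integer(h + 1L)  # index of first run in each row (cumulative)
  nr <- 0L
  rows_list <- vector("list", h)
  for (r in seq_len(h)) {
    v <- m[r, ]
    if (any(v)) {
      rl <- rle(v)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      fg <- rl$values
      rows_list[[r]] <- cbind(starts[fg], ends[fg])
    }
  }
  counts <- vapply(rows_list, function(x) if (is.null(x)) 0L else nrow(x),
                   integer(1))
  total <- sum(counts)
  if (total == 0L) {
    return(labeled_mask(matrix(0L, h, w), dpi = img_dpi(mask)))
  }
  run_row <- rep.int(seq_len(h), counts)
  run_s <- unlist(lapply(rows_list, function(x) if (is.null(x)) integer(0) else x[, 1]))
  run_e <- unlist(lapply(rows_list, function(x) if (is.null(x)) integer(0) else x[, 2]))
  offset <- c(0L, cumsum(counts))  # runs of row r are offset[r]+1 .. offset[r+1]

  parent <- seq_len(total)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(h - 1L)) {
    i <- offset[r] + 1L; iend <- offset[r + 1L]
    j <- offset[r + 1L] + 1L; jend <- offset[r + 2L]
    while (i <= iend && j <= jend) {
      if (run_s[j] > run_e[i] + 1L) {
        i <- i + 1L
      } else if (run_s[i] > run_e[j] + 1L) {
        j <- j + 1L
      } else {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        if (run_e[i] <= run_e[j]) i <- i + 1L else j <- j + 1L
      }
    }
  }
  # assign labels in raster order of first pixel: runs are already stored
  # row by row, left to right
  root <- vapply(seq_len(total), find, integer(1))
  lab_of_root <- integer(total)
  nlab <- 0L
  labels <- integer(total)
  for (k in seq_len(total)) {
    rk <- root[k]
    if (lab_of_root[rk] == 0L) {
      nlab <- nlab + 1L
      lab_of_root[rk] <- nlab
    }
    labels[k] <- lab_of_root[rk]
  }
  out <- matrix(0L, h, w)
  for (k in seq_len(total)) out[run_row[k], run_s[k]:run_e[k]] <- labels[k]
  labeled_mask(out, dpi = img_dpi(mask))
}

#' Extract labeled primary-branch regions from a panicle scan
#'
#' Runs the full segmentation pipeline in the fixed order: channel-mean
#' grayscale, Otsu threshold, binarization, morphological opening (which
#' removes the thin rachis and pedicels so branch regions separate), hole
#' filling by reconstruction from the border, removal of components under
#' `min_pixels`, and 8-connected labelling.
#'
#' @param img An [rgb_image].
#' @param polarity Binarization polarity, see [binarize()].
#' @param radius Opening disk radius, see [morphological_open()].
#' @param min_pixels Small-component cutoff, see [remove_small_objects()].
#' @param debug If `TRUE`, the returned mask carries a `"stages"`
#'   attribute with every intermediate raster (`gray`, `binary`, `opened`,
#'   `filled`, `cleaned`) plus the extraction-check `overlay`
#'   `b - b * (-f)` comparing the raw binary image `b` against the final
#'   region mask `f` (i.e. the part of the initial segmentation that
#'   survived cleanup).
#' @return A [labeled_mask] with one label per primary-branch region.
#' @export
extract_branch_regions <- function(img,
                                   polarity = "dark_foreground",
                                   radius = 1L,
                                   min_pixels = 100L,
                                   debug = FALSE) {
  g <- to_gray(img)
  t <- tryCatch(otsu_threshold(g), error = function(e) {
    # a constant scan (e.g. an empty scanner bed) has nothing to segment
    stop("no panicle detected: ", conditionMessage(e), call. = FALSE)
  })
  b <- binarize(g, t, polarity)
  op <- morphological_open(b, radius)
  fl <- fill_holes(op)
  cl <- remove_small_objects(fl, min_pixels)
  lbl <- label_components(cl)
  if (n_regions(lbl) == 0L)
    stop("no panicle detected: no region survived segmentation cleanup",
         call. = FALSE)
  if (isTRUE(debug)) {
    f <- as_plain(lbl) > 0L
    overlay <- binary_mask(as_plain(b) & f, dpi = img_dpi(img))
    attr(lbl, "stages") <- list(gray = g, binary = b, opened = op,
                                filled = fl, cleaned = cl,
                                threshold = t, overlay = overlay)
  }
  lbl
}
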