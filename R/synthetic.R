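#' Specification for a synthetic panicle scan
#'
#' Describes one rendered panicle: a thin rachis with `n_branches`
#' primary branches attached, each branch a gently curved axis bearing
#' spikelets as filled ellipses at a per-branch linear density. The
#' defaults emulate a 72-dpi scan of a spread-out panicle: at that
#' resolution one pixel is ~0.35 mm, a rice spikelet (~7 x 3 mm grain)
#' is an ellipse with semi-axes of roughly 10 x 4.5 px, and primary
#' branches run ~100-400 px (3.5-14 cm).
#'
#' Spikelet size is held near-constant within a panicle (grain size and
#' filling are assumed approximately uniform within a variety — the
#' premise that makes branch-region area proportional to spikelet
#' count), while the per-branch density varies with coefficient of
#' variation `density_cv`.
#'
#' @param seed RNG seed; the render and its ground truth are
#'   bit-reproducible given the seed.
#' @param n_branches Number of primary branches (5-15); `NULL` samples
#'   uniformly from that range.
#' @param branch_length_px Range the branch lengths are drawn from, px.
#' @param branch_lengths Optional explicit branch lengths (overrides the
#'   range; lengths also fix `n_branches`).
#' @param spikelets_per_px Mean linear spikelet density along a branch
#'   (spikelets per pixel of branch length).
#' @param density_cv Coefficient of variation of the per-branch density.
#' @param spikelet_radius_px Range of the spikelet minor semi-axis, px
#'   (one value per panicle is drawn from it).
#' @param spikelet_aspect Major/minor semi-axis ratio of a spikelet.
#' @param rachis_width_px Width of the rachis stroke, 1-2 px (thin
#'   enough that the opening step removes it).
#' @param dpi Nominal scan resolution recorded in the image.
#' @param bg_intensity,fg_intensity Background / panicle gray levels.
#' @param noise_sd Standard deviation of additive Gaussian channel
#'   noise (0 gives an exactly two-valued render).
#' @return A `panicle_spec` list.
#' @export
panicle_spec <- function(seed = 1L,
                         n_branches = NULL,
                         branch_length_px = c(100, 400),
                         branch_lengths = NULL,
                         spikelets_per_px = 0.04,
                         density_cv = 0.07,
                         spikelet_radius_px = c(4.2, 5.0),
                         spikelet_aspect = 2.2,
                         rachis_width_px = 2L,
                         dpi = 72,
                         bg_intensity = 230,
                         fg_intensity = 60,
                         noise_sd = 6) {
  stopifnot(all(branch_length_px > 0), density_cv >= 0,
            all(spikelet_radius_px > 0), spikelets_per_px > 0,
            rachis_width_px >= 1, rachis_width_px <= 2)
  structure(as.list(environment()), class = "panicle_spec")
}

paint_ellipse <- function(mask, cy, cx, a, b, theta) {
  h <- nrow(mask); w <- ncol(mask)
  r0 <- max(1L, floor(cy - a)); r1 <- min(h, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(w, ceiling(cx + a))
  rows <- r0:r1; cols <- c0:c1
  dy <- rows - cy; dx <- cols - cx
  ct <- cos(theta); st <- sin(theta)
  # local ellipse frame: u along the branch tangent, v across it
  u <- outer(dy, dx, function(y, x) x * ct + y * st)
  v <- outer(dy, dx, function(y, x) -x * st + y * ct)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  mask[rows, cols] <- mask[rows, cols] | inside
  mask
}

#' Render a synthetic panicle scan with ground truth
#'
#' Draws the panicle described by a [panicle_spec()] into an RGB raster:
#' a thin, slightly curved rachis; one primary branch per lane, curved
#' by a low bump (branches on a scanned panicle cannot be straightened
#' perfectly); spikelets as filled ellipses centred on the branch axis,
#' oriented along the local tangent. The spikelet minor axis follows a
#' semi-elliptical width profile along the branch (widest mid-branch,
#' tapering to the tips), so a branch region's mass profile matches the
#' moment-equivalent-ellipse length convention used by the trait
#' measurements. A 3-px axis stroke bridges consecutive spikelets so
#' each branch stays one connected region through the opening step,
#' while the rachis (width `<= 2`) is removed by it. Branches sit in
#' disjoint lanes, so regions never touch.
#'
#' @param spec A [panicle_spec()].
#' @return A list with `image` (an [rgb_image]) and `truth`: per-branch
#'   `length_px` (true arc length) and `n_spikelets`, plus totals
#'   `snpp` (true spikelet number), `total_length_px`,
#'   `painted_area_px`, `n_branches`, and the originating `seed`.
#' @export
generate_panicle <- function(spec) {
  stopifnot(inherits(spec, "panicle_spec"))
  with_seed(spec$seed, generate_panicle_impl(spec))
}

generate_panicle_impl <- function(spec) {
  n <- if (!is.null(spec$branch_lengths)) length(spec$branch_lengths)
       else if (!is.null(spec$n_branches)) spec$n_branches
       else sample(5:15, 1L)
  lens <- if (!is.null(spec$branch_lengths)) as.numeric(spec$branch_lengths)
          else stats::runif(n, spec$branch_length_px[1], spec$branch_length_px[2])
  b_minor <- stats::runif(1, spec$spikelet_radius_px[1], spec$spikelet_radius_px[2])
  a_major <- spec$spikelet_aspect * b_minor
  if (any(lens <= 2 * a_major + 4))
    stop("layout failure: branch too short to carry spikelets", call. = FALSE)
  dens <- spec$spikelets_per_px * pmax(0.2, 1 + stats::rnorm(n, 0, spec$density_cv))
  counts <- pmax(1L, as.integer(round(dens * lens)))
  amp <- stats::runif(n, -3, 3)

  margin <- 12L
  lane_h <- as.integer(ceiling(2 * b_minor + 2 * 3 + 5))  # region + curve room + gap
  rachis_x <- 18L
  H <- 2L * margin + n * lane_h
  W <- as.integer(ceiling(rachis_x + max(lens) + a_major + 14))
  if (H > 6000L || W > 6000L)
    stop("layout failure: canvas exceeds bounds", call. = FALSE)
  mask <- matrix(FALSE, H, W)

  # rachis: near-vertical stroke of width rachis_width_px, gentle sway
  rr <- margin:(H - margin)
  xr <- rachis_x + round(2 * sin(pi * (rr - margin) / max(1, H - 2 * margin)))
  for (kx in seq_len(spec$rachis_width_px) - 1L)
    mask[cbind(rr, pmin(W, xr + kx))] <- TRUE

  branch_len_true <- numeric(n)
  for (b in seq_len(n)) {
    y0 <- margin + (b - 0.5) * lane_h
    Lx <- lens[b]
    x0 <- rachis_x
    xs <- x0:(x0 + as.integer(round(Lx)))
    tt <- (xs - x0) / max(1, (length(xs) - 1L))
    yc <- y0 + amp[b] * 4 * tt * (1 - tt)
    branch_len_true[b] <- sum(sqrt(1 + diff(yc)^2))
    yci <- round(yc)
    # spikelets: near-even spacing with jitter; size tapers towards the
    # branch tips following a semi-elliptic profile, so the region's
    # mass distribution matches the moment-ellipse length convention
    k <- counts[b]
    spacing <- Lx / k
    s <- (seq_len(k) - 0.5) * spacing +
      stats::runif(k, -0.15 * spacing, 0.15 * spacing)
    s <- pmin(pmax(s, a_major * 0.85), Lx - a_major * 0.85)
    # 3-px axis stroke bridging the spikelets
    ax_lo <- max(1L, as.integer(round(min(s) - 0.2 * a_major)))
    ax_hi <- min(length(xs), as.integer(round(max(s) + 0.2 * a_major)))
    for (dy in -1:1)
      mask[cbind(pmax(1L, pmin(H, yci[ax_lo:ax_hi] + dy)), xs[ax_lo:ax_hi])] <- TRUE
    # thin pedicel-like stem joining the branch to the rachis; the
    # opening step removes it, which is what separates the regions
    if (ax_lo > 1L)
      mask[cbind(pmax(1L, pmin(H, yci[1:ax_lo])), xs[1:ax_lo])] <- TRUE
    f <- s / Lx
    wf <- 0.2 + 0.8 * sqrt(pmax(0, 1 - (2 * f - 1)^2))
    for (i in seq_len(k)) {
      xi <- x0 + s[i]
      ti <- s[i] / Lx
      yi <- y0 + amp[b] * 4 * ti * (1 - ti)
      slope <- amp[b] * (4 - 8 * ti) / Lx
      mask <- paint_ellipse(mask, yi, xi,
                            a = a_major * (0.5 + 0.5 * wf[i]),
                            b = max(1.8, b_minor * wf[i]),
                            theta = atan(slope))
    }
  }

  painted <- sum(mask)
  base <- matrix(spec$bg_intensity, H, W)
  base[mask] <- spec$fg_intensity
  px <- array(0, c(H, W, 3L))
  for (ch in 1:3) {
    chan <- base
    if (spec$noise_sd > 0)
      chan <- chan + stats::rnorm(H * W, 0, spec$noise_sd)
    px[, , ch] <- pmin(255, pmax(0, floor(chan + 0.5)))
  }
  truth <- list(
    per_branch = data.frame(branch = seq_len(n),
                            length_px = branch_len_true,
                            n_spikelets = counts),
    snpp = sum(counts),
    total_length_px = sum(branch_len_true),
    painted_area_px = painted,
    n_branches = n,
    spikelet_minor_px = b_minor,
    seed = spec$seed
  )
  list(image = rgb_image(px, dpi = spec$dpi), truth = truth)
}

#' Generate a synthetic rice variety
#'
#' Draws `n_panicles` panicles whose true spikelet numbers are roughly
#' lognormal around `mean_snpp` (panicle size distributions are
#' right-skewed in the field). Within the variety the linear spikelet
#' density and spikelet size are held near-constant, so total branch
#' length scales with spikelet number — the physiological premise of
#' the linear trait-to-SNPP model. Per-panicle branch counts and
#' lengths are derived from the target spikelet number at the variety
#' density.
#'
#' @param n_panicles Number of panicles to generate.
#' @param mean_snpp Target mean spikelet number per panicle.
#' @param snpp_spread Lognormal sdlog of the spikelet number across
#'   panicles (default 0.18, i.e. ~18 percent CV).
#' @param seed Master seed; per-panicle seeds are drawn from it, so the
#'   whole variety is reproducible.
#' @param variety Variety label used in panicle ids.
#' @param ... Further arguments passed to [panicle_spec()] (e.g.
#'   `noise_sd`, `density_cv`, `spikelets_per_px`).
#' @return A list with `panicles` (list of `generate_panicle()` results)
#'   and `truth`, a data frame with one row per panicle: `panicle_id`,
#'   `variety`, `n_branches`, `true_snpp`, `true_total_length_px`,
#'   `painted_area_px`, `seed`.
#' @export
generate_variety <- function(n_panicles, mean_snpp, snpp_spread = 0.18,
                             seed = 1L, variety = "S", ...) {
  stopifnot(n_panicles >= 1, mean_snpp > 0)
  extra <- list(...)
  with_seed(seed, {
    dens <- if (!is.null(extra$spikelets_per_px)) extra$spikelets_per_px
            else eval(formals(panicle_spec)$spikelets_per_px)
    radius_range <- if (!is.null(extra$spikelet_radius_px)) extra$spikelet_radius_px
                    else eval(formals(panicle_spec)$spikelet_radius_px)
    # grain size is a varietal character: one spikelet radius per variety
    # (with a +/-1 percent per-panicle jitter), not per panicle — this is
    # the uniformity assumption that makes area proportional to count
    b_var <- stats::runif(1, min(radius_range), max(radius_range))
    extra$spikelet_radius_px <- b_var * c(0.99, 1.01)
    targets <- stats::rlnorm(n_panicles,
                             meanlog = log(mean_snpp) - snpp_spread^2 / 2,
                             sdlog = snpp_spread)
    seeds <- sample.int(2147483646L, n_panicles)
    panicles <- vector("list", n_panicles)
    for (i in seq_len(n_panicles)) {
      l_tot <- targets[i] / dens
      n_b <- min(15L, max(5L, as.integer(round(l_tot / 330))))
      w <- stats::runif(n_b, 0.75, 1.25)
      lens <- pmin(620, pmax(70, l_tot * w / sum(w)))
      args <- c(list(seed = seeds[i], branch_lengths = lens), extra)
      panicles[[i]] <- generate_panicle(do.call(panicle_spec, args))
    }
    truth <- data.frame(
      panicle_id = sprintf("%s_%03d", variety, seq_len(n_panicles)),
      variety = variety,
      n_branches = vapply(panicles, function(p) p$truth$n_branches, integer(1)),
      true_snpp = vapply(panicles, function(p) p$truth$snpp, integer(1)),
      true_total_length_px = vapply(panicles,
                                    function(p) p$truth$total_length_px,
                                    numeric(1)),
      painted_area_px = vapply(panicles,
                               function(p) p$truth$painted_area_px,
                               integer(1)),
      seed = seeds,
      stringsAsFactors = FALSE
    )
    list(panicles = panicles, truth = truth, variety = variety,
         mean_snpp = mean_snpp, seed = seed)
  })
}
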