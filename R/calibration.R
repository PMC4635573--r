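#' Choose calibration samples uniformly across the trait scale
#'
#' Picks `k` samples whose trait values cover the observed range evenly:
#' for each target value `min + j * (max - min) / (k - 1)`, `j = 0..k-1`,
#' the unused sample nearest the target is selected (ties go to the lower
#' trait value). The first and last targets are the range endpoints, so
#' the minimum and maximum samples are always included and the fitted
#' line never extrapolates over the training data.
#'
#' @param values Numeric trait values (area or TLPB2), one per sample.
#' @param ids Sample identifiers (default: names of `values`, else
#'   indices).
#' @param k Number of calibration points (default 5).
#' @param strategy `"value_uniform"` (even spacing of trait values, the
#'   default), `"rank_uniform"` (even spacing of order statistics) or
#'   `"random"` (simple random sample; honours the current RNG state).
#' @return Character vector of `k` distinct selected ids.
#' @export
select_calibration_points <- function(values, ids = NULL, k = 5L,
                                      strategy = c("value_uniform",
                                                   "rank_uniform",
                                                   "random")) {
  strategy <- match.arg(strategy)
  if (is.null(ids)) ids <- if (!is.null(names(values))) names(values) else
    as.character(seq_along(values))
  stopifnot(length(ids) == length(values))
  if (length(values) < k)
    stop("insufficient calibration spread: need at least ", k, " samples",
         call. = FALSE)
  rng <- range(values)
  if (diff(rng) <= 0)
    stop("insufficient calibration spread: trait range is zero",
         call. = FALSE)
  if (strategy == "random") return(as.character(sample(ids, k)))
  if (strategy == "rank_uniform") {
    ord <- order(values, ids)
    pick <- unique(round(seq(1L, length(values), length.out = k)))
    return(as.character(ids[ord[pick]]))
  }
  targets <- rng[1] + (seq_len(k) - 1L) * diff(rng) / (k - 1L)
  used <- rep(FALSE, length(values))
  sel <- integer(k)
  for (j in seq_len(k)) {
    d <- abs(values - targets[j])
    d[used] <- Inf
    best <- which(d == min(d))
    if (length(best) > 1L) best <- best[which.min(values[best])]
    sel[j] <- best
    used[best] <- TRUE
  }
  as.character(ids[sel])
}

#' Fit the linear trait-to-SNPP calibration model
#'
#' Ordinary least squares of spikelet number on a single image trait.
#' The linear form follows from panicle physiology: spikelets sit on the
#' primary branches at a roughly constant linear density and roughly
#' constant grain size, so both the summed branch length (TLPB2) and the
#' branch-region area scale proportionally with the spikelet number.
#'
#' @param x Trait values (pixel area or TLPB2) of the training samples.
#' @param y Manually counted spikelet numbers for the same samples.
#' @param trait Which trait `x` is: `"area"` or `"tlpb2"`.
#' @param training_ids Optional ids of the training samples, recorded so
#'   that evaluation can enforce a disjoint holdout.
#' @param dpi Optional pixel scale recorded with the model.
#' @return A `calibration_model`: list with `trait`, `slope` (spikelets
#'   per trait unit), `intercept` (spikelets), `r_squared`, `n_points`,
#'   `trait_range` and `training_ids`.
#' @export
fit_line <- function(x, y, trait = c("area", "tlpb2"), training_ids = NULL,
                     dpi = NA_real_) {
  trait <- match.arg(trait)
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  if (diff(range(x)) <= 0)
    stop("degenerate fit: trait values are constant", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = as.numeric(x),
                                            y = as.numeric(y)))
  ssres <- sum(stats::residuals(fit)^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - ssres / sstot else as.numeric(ssres <= 1e-12)
  structure(list(
    trait = trait,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    n_points = length(x),
    trait_range = range(x),
    training_ids = if (is.null(training_ids)) character(0)
                   else as.character(training_ids),
    pixel_scale_dpi = dpi
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model %s: SNPP = %.6g * %s %+.6g, R^2 = %.4f, n = %d>\n",
              x$trait, x$slope, x$trait, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Predict spikelet number from a trait value
#'
#' Applies `slope * x + intercept`, floored at zero (a panicle cannot
#' carry a negative spikelet number). Predictions are left real-valued:
#' the deviation statistics of mean spikelet numbers are computed from
#' unrounded means. Set `round` to get integer counts.
#'
#' @param model A `calibration_model` from [fit_line()].
#' @param x Trait value(s).
#' @param round Round predictions to whole spikelets (default `FALSE`).
#' @return Estimated spikelet number(s), `snpp_cal`.
#' @export
predict_snpp <- function(model, x, round = FALSE) {
  stopifnot(inherits(model, "calibration_model"))
  out_of_range <- x < model$trait_range[1] | x > model$trait_range[2]
  if (any(out_of_range))
    warning(sum(out_of_range),
            " trait value(s) outside the calibration range [",
            format(model$trait_range[1]), ", ",
            format(model$trait_range[2]), "]: extrapolating",
            call. = FALSE)
  y <- pmax(0, model$slope * x + model$intercept)
  if (isTRUE(round)) y <- base::round(y)
  y
}

#' Per-panicle estimation error
#'
#' Relative error of an estimated spikelet number against the manual
#' count, in percent:
#' `|SNPP(cal) - SNPP(manual)| / SNPP(manual) * 100`.
#'
#' @param snpp_manual Manually counted spikelet number(s), `> 0`.
#' @param snpp_cal Estimated spikelet number(s).
#' @return Absolute relative error in percent.
#' @export
estimation_error <- function(snpp_manual, snpp_cal) {
  if (any(snpp_manual <= 0))
    stop("undefined error: manual spikelet count must be positive",
         call. = FALSE)
  abs(snpp_cal - snpp_manual) / snpp_manual * 100
}

#' Fraction of samples within error thresholds
#'
#' For each threshold `T`, the percentage of samples whose estimation
#' error is strictly below `T` percent.
#'
#' @param errors Per-sample errors in percent (see [estimation_error()]).
#' @param thresholds Error thresholds in percent (default 5 and 10).
#' @return Named numeric vector of percentages, one per threshold.
#' @export
error_range_table <- function(errors, thresholds = c(5, 10)) {
  if (length(errors) == 0L) stop("no errors to summarise", call. = FALSE)
  out <- vapply(thresholds, function(t) 100 * mean(errors < t), numeric(1))
  names(out) <- paste0("within_", thresholds)
  out
}

#' Signed deviation of the mean spikelet number (SNPS)
#'
#' The spikelet number per square (SNPS) is the average SNPP over the
#' sampled panicles; its estimation deviation is the signed relative
#' difference of the estimated mean from the true (manually counted)
#' mean: `(mean(cal) - mean(true)) / mean(true) * 100`. Note this is a
#' ratio of means, not a mean of per-sample ratios.
#'
#' @param true_mean Mean of the manual counts, `> 0`.
#' @param cal_mean Mean of the estimated counts.
#' @return Signed deviation in percent.
#' @export
snps_deviation <- function(true_mean, cal_mean) {
  if (any(true_mean <= 0))
    stop("undefined deviation: true mean must be positive", call. = FALSE)
  (cal_mean - true_mean) / true_mean * 100
}

#' Fit a calibration model from a traits table
#'
#' Convenience wrapper over [select_calibration_points()] and
#' [fit_line()]: either the 5-point calibration (default) or a random
#' 80/20 split fit, on the trait column of a per-panicle traits table
#' (as produced by [measure_panicles()] or read back from its CSV).
#'
#' @param traits Data frame with columns `panicle_id`, `snpp_manual` and
#'   the trait column (`total_area_px` for `"area"`, `tlpb2_px` for
#'   `"tlpb2"`). Rows without a manual count are ignored.
#' @param trait `"area"` or `"tlpb2"`.
#' @param mode `"five_point"` or `"split_80_20"`.
#' @param k Number of calibration points in `"five_point"` mode.
#' @param seed RNG seed for the random split / random selection.
#' @param strategy Point-selection strategy, see
#'   [select_calibration_points()].
#' @return A `calibration_model` whose `training_ids` are the selected
#'   calibration (or 80 percent training) panicles.
#' @export
calibrate_snpp <- function(traits, trait = c("area", "tlpb2"),
                           mode = c("five_point", "split_80_20"),
                           k = 5L, seed = NULL,
                           strategy = "value_uniform") {
  trait <- match.arg(trait)
  mode <- match.arg(mode)
  col <- trait_column(trait)
  if (!col %in% names(traits))
    stop("traits table lacks column '", col, "'", call. = FALSE)
  lab <- traits[!is.na(traits$snpp_manual), , drop = FALSE]
  if (nrow(lab) < max(2L, if (mode == "five_point") k else 2L))
    stop("not enough rows with manual spikelet counts", call. = FALSE)
  run <- function() {
    if (mode == "five_point") {
      ids <- select_calibration_points(lab[[col]], lab$panicle_id, k = k,
                                       strategy = strategy)
    } else {
      n_train <- max(2L, floor(0.8 * nrow(lab)))
      ids <- as.character(sample(lab$panicle_id, n_train))
    }
    tr <- lab[lab$panicle_id %in% ids, , drop = FALSE]
    m <- fit_line(tr[[col]], tr$snpp_manual, trait = trait,
                  training_ids = ids,
                  dpi = if ("dpi" %in% names(tr)) tr$dpi[1] else NA_real_)
    m$mode <- mode
    m$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
    m
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

trait_column <- function(trait) {
  switch(trait, area = "total_area_px", tlpb2 = "tlpb2_px",
         stop("unknown trait: ", trait, call. = FALSE))
}

#' Evaluate a calibration model on held-out panicles
#'
#' Predicts the spikelet number for every holdout panicle, and summarises
#' the per-sample estimation errors and the deviation of the mean
#' (SNPS). The panicles used to fit the model must not appear in the
#' holdout — overlapping ids are an error, not silently dropped.
#'
#' @param model A `calibration_model`.
#' @param holdout Data frame with `panicle_id`, `snpp_manual` and the
#'   model's trait column.
#' @param thresholds Error thresholds in percent for the error-range
#'   table.
#' @return An `snpp_error_report`: list with `per_sample` (data frame:
#'   `panicle_id`, `snpp_manual`, `snpp_cal`, `error_pct`),
#'   `frac_within_5`, `frac_within_10` (or analogous for other
#'   thresholds), `snps_true`, `snps_cal` and `deviation_pct`.
#' @export
evaluate_model <- function(model, holdout, thresholds = c(5, 10)) {
  stopifnot(inherits(model, "calibration_model"))
  col <- trait_column(model$trait)
  if (!col %in% names(holdout))
    stop("holdout table lacks the model trait column '", col, "'",
         call. = FALSE)
  overlap <- intersect(as.character(holdout$panicle_id), model$training_ids)
  if (length(overlap) > 0L)
    stop("holdout overlaps the calibration samples: ",
         paste(utils::head(overlap, 5L), collapse = ", "), call. = FALSE)
  h <- holdout[!is.na(holdout$snpp_manual), , drop = FALSE]
  if (nrow(h) == 0L) stop("holdout has no manual counts", call. = FALSE)
  cal <- suppressWarnings(predict_snpp(model, h[[col]]))
  err <- estimation_error(h$snpp_manual, cal)
  ranges <- error_range_table(err, thresholds)
  snps_true <- mean(h$snpp_manual)
  snps_cal <- mean(cal)
  rep <- c(
    list(per_sample = data.frame(panicle_id = as.character(h$panicle_id),
                                 snpp_manual = h$snpp_manual,
                                 snpp_cal = cal, error_pct = err,
                                 stringsAsFactors = FALSE)),
    as.list(ranges),
    list(snps_true = snps_true, snps_cal = snps_cal,
         deviation_pct = snps_deviation(snps_true, snps_cal),
         trait = model$trait, n = nrow(h))
  )
  names(rep) <- sub("^within_", "frac_within_", names(rep))
  structure(rep, class = "snpp_error_report")
}

#' @export
print.snpp_error_report <- function(x, ...) {
  cat(sprintf("<snpp_error_report (%s): n = %d, within 5%% = %.2f%%, within 10%% = %.2f%%, SNPS deviation = %+.2f%%>\n",
              x$trait, x$n, x$frac_within_5, x$frac_within_10,
              x$deviation_pct))
  invisible(x)
}

#' Persist / restore a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path JSON file path.
#' @return `write_calibration_model` returns `path` invisibly;
#'   `read_calibration_model` returns the model.
#' @export
write_calibration_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_calibration_model
#' @export
read_calibration_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$trait_range <- as.numeric(m$trait_range)
  m$training_ids <- as.character(m$training_ids)
  structure(m, class = "calibration_model")
}

# evaluate under a temporary seed without clobbering the caller's RNG
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
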