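#' End-to-end synthetic evaluation study
#'
#' Runs the full method over synthetic varieties: render `n` panicle
#' scans per variety, segment every scan and measure its traits, fit a
#' per-variety calibration model (5-point by default) on the chosen
#' trait, predict the spikelet number of every non-calibration panicle,
#' and summarise the per-variety estimation errors and SNPS deviation.
#' The ground-truth spikelet counts play the role of the manual counts.
#'
#' The default study conditions are six varieties of 100 panicles at
#' 72 dpi with mean spikelet numbers 90, 110, 105, 90, 185 and 200 —
#' two japonica-sized, two intermediate and two large indica-sized
#' populations — under the generator's default 7 percent per-branch
#' density variation.
#'
#' @param mean_snpp Mean spikelet number of each variety.
#' @param n Panicles per variety.
#' @param seeds One seed per variety.
#' @param trait,mode,k Calibration settings, see [calibrate_snpp()].
#' @param ... Further generator settings passed to [generate_variety()].
#' @return A data frame with one row per variety: `variety`, `seed`,
#'   `mean_snpp`, `r_squared`, `n_holdout`, `frac_within_5`,
#'   `frac_within_10`, `snps_true`, `snps_cal`, `deviation_pct`.
#' @export
simulation_study <- function(mean_snpp = c(90, 110, 105, 90, 185, 200),
                             n = 100L,
                             seeds = seq_along(mean_snpp),
                             trait = "area", mode = "five_point", k = 5L,
                             ...) {
  stopifnot(length(seeds) == length(mean_snpp))
  rows <- vector("list", length(mean_snpp))
  for (v in seq_along(mean_snpp)) {
    vid <- LETTERS[((v - 1L) %% 26L) + 1L]
    gv <- generate_variety(n, mean_snpp[v], seed = seeds[v], variety = vid, ...)
    meas <- do.call(rbind, lapply(seq_len(n), function(i) {
      lbl <- extract_branch_regions(gv$panicles[[i]]$image)
      as.data.frame(measure_panicle(
        lbl, panicle_id = gv$truth$panicle_id[i], variety = vid,
        snpp_manual = gv$truth$true_snpp[i]))
    }))
    model <- calibrate_snpp(meas, trait = trait, mode = mode, k = k,
                            seed = seeds[v])
    holdout <- meas[!meas$panicle_id %in% model$training_ids, , drop = FALSE]
    rep <- evaluate_model(model, holdout)
    rows[[v]] <- data.frame(
      variety = vid, seed = seeds[v], mean_snpp = mean_snpp[v],
      r_squared = model$r_squared, n_holdout = rep$n,
      frac_within_5 = rep$frac_within_5,
      frac_within_10 = rep$frac_within_10,
      snps_true = rep$snps_true, snps_cal = rep$snps_cal,
      deviation_pct = rep$deviation_pct,
      stringsAsFactors = FALSE
    )
    rm(gv, meas)
  }
  do.call(rbind, rows)
}
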