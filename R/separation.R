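#' Separation efficiency from colony counts
#'
#' The separation efficiency of a magnetophoretic sorting run is the
#' collected share of the population flown through the device:
#' `collected / injected`. The integer percent report truncates (floor)
#' rather than rounds, which reproduces the customary "about NN%"
#' statements from raw counts (e.g. 2.3e8 of 3.3e8 collected -> 69%).
#'
#' @param collected Colony count recovered from the collection outlet
#'   (vectorized).
#' @param injected Cell count flown through the device (> 0).
#' @return data.frame with columns `fraction` and `percent` (integer).
#' @export
#' @examples
#' separation_efficiency(2.3e8, 3.3e8)  # fraction 0.697, percent 69
separation_efficiency <- function(collected, injected) {
  if (any(injected <= 0)) stop("injected count must be positive")
  if (any(collected < 0)) stop("collected count must be non-negative")
  if (any(collected > injected)) {
    warning("collected exceeds injected for some records (counting noise)")
  }
  fraction <- collected / injected
  data.frame(fraction = fraction,
             percent = as.integer(floor(fraction * 100)))
}

#' Fold ratio between two separation efficiencies
#'
#' Ratio of two efficiency fractions, rounded half-up to one decimal.
#' Unrounded fractions should be supplied; rounding happens only at the
#' report stage.
#'
#' @param eff_a,eff_b Efficiency fractions; `eff_b` must be positive.
#' @return Numeric ratio with one decimal.
#' @export
#' @examples
#' fold_ratio(2.3e8 / 3.3e8, 9.7e7 / 3.3e8)  # 2.4
fold_ratio <- function(eff_a, eff_b) {
  if (any(eff_b <= 0)) stop("reference efficiency must be positive")
  floor(eff_a / eff_b * 10 + 0.5) / 10
}

#' Read a colony-count table
#'
#' Expects a TSV with columns `strain`, `flow_rate`, `replicate`,
#' `collected`, `injected`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_separation_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "flow_rate", "replicate", "collected", "injected")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("colony-count table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Replicate summary of separation efficiencies
#'
#' Groups records by strain and flow rate and reports the mean and
#' sample standard deviation of the efficiency fractions (measurements
#' are typically taken in triplicate).
#'
#' @param records data.frame with columns `strain`, `flow_rate`,
#'   `collected`, `injected` (one row per replicate).
#' @return data.frame: `strain`, `flow_rate`, `n`, `mean_efficiency`,
#'   `sd_efficiency`.
#' @export
replicate_summary <- function(records) {
  eff <- separation_efficiency(records$collected, records$injected)$fraction
  df <- data.frame(strain = records$strain, flow_rate = records$flow_rate,
                   eff = eff)
  agg <- aggregate(eff ~ strain + flow_rate, data = df, FUN = function(x) {
    c(n = length(x), mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
  })
  out <- data.frame(strain = agg$strain, flow_rate = agg$flow_rate,
                    n = as.integer(agg$eff[, "n"]),
                    mean_efficiency = agg$eff[, "mean"],
                    sd_efficiency = agg$eff[, "sd"])
  out[order(out$strain, out$flow_rate), , drop = FALSE]
}
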