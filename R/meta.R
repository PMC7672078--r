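#' Warming effect size for one field observation
#'
#' Relative change of the soil organic carbon stock in the warmed plot
#' against its control, either as a percent change (the primary metric,
#' reported as mean +/- sd across studies) or as the log response ratio.
#'
#' @param control,warmed SOC stocks in the same units, both > 0
#'   (vectorized).
#' @param mode `"percent"` or `"lnRR"`.
#' @return Effect size(s): percent change or `ln(warmed/control)`.
#' @export
#' @examples
#' effect_size(100, 102)                  # +2 %
#' effect_size(100, 102, mode = "lnRR")
effect_size <- function(control, warmed, mode = c("percent", "lnRR")) {
  mode <- match.arg(mode)
  if (any(control <= 0) || any(warmed <= 0)) stop("SOC stocks must be > 0")
  if (mode == "percent") 100 * (warmed - control) / control
  else log(warmed / control)
}

#' Default duration bins (years): <1, 1-10, >10
#'
#' Boundary conventions follow the printed labels: exactly 1 year and
#' exactly 10 years both fall in the middle bin.
#' @noRd
.duration_bin <- function(duration_yr) {
  cut(duration_yr, breaks = c(0, 1, 10, Inf), right = FALSE,
      labels = c("<1", "1-10", ">10")) |>
    (\(b) {
      # right = FALSE puts exactly 10 in ">10"; the printed binning is
      # "1-10" inclusive, so move the boundary case back
      b[duration_yr == 10] <- "1-10"
      b
    })()
}

#' Summarize warming effect sizes by experimental duration
#'
#' Computes per-study effect sizes and their unweighted mean +/- sd within
#' duration groups (<1 year, 1-10 years, >10 years by default) and overall.
#' When per-arm sampling variances are available and `mode = "lnRR"`,
#' a fixed-effect inverse-variance weighted overall mean is reported
#' alongside the unweighted one.
#'
#' @param observations data.frame with columns `soc_control`, `soc_warmed`,
#'   `duration_yr` (and optionally `sd_control`, `sd_warmed`, `n_control`,
#'   `n_warmed`).
#' @param mode effect metric, `"percent"` (default) or `"lnRR"`.
#' @return List with `by_bin` (data.frame: `bin`, `mean`, `sd`, `n`) and
#'   `overall` (`mean`, `sd`, `n`, and `weighted_mean` when computable).
#' @export
summarize_effects <- function(observations, mode = c("percent", "lnRR")) {
  mode <- match.arg(mode)
  req <- c("soc_control", "soc_warmed", "duration_yr")
  miss <- setdiff(req, names(observations))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(observations$duration_yr <= 0)) stop("durations must be > 0")
  es <- effect_size(observations$soc_control, observations$soc_warmed, mode)
  bin <- .duration_bin(observations$duration_yr)
  by_bin <- do.call(rbind, lapply(levels(bin), function(b) {
    v <- es[bin == b]
    data.frame(bin = b, mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               n = length(v))
  }))
  overall <- list(mean = mean(es), sd = stats::sd(es), n = length(es))
  if (mode == "lnRR" &&
      all(c("sd_control", "sd_warmed", "n_control", "n_warmed") %in%
          names(observations))) {
    vi <- with(observations,
               sd_warmed^2 / (n_warmed * soc_warmed^2) +
                 sd_control^2 / (n_control * soc_control^2))
    overall$weighted_mean <- stats::weighted.mean(es, 1 / vi)
  }
  list(by_bin = by_bin, overall = overall, mode = mode)
}

#' Read a field-warming observation table
#'
#' Loads a CSV of field warming experiments (one row per independent
#' observation: control and warmed SOC stock, warming magnitude, duration)
#' into the column layout the meta-analysis expects.  Arbitrary source
#' layouts are absorbed by `column_map`, a named character vector mapping
#' the required names to the file's headers.
#'
#' @param path CSV file.
#' @param column_map named character vector; names are the target columns
#'   (`soc_control`, `soc_warmed`, `delta_t`, `duration_yr`, optionally
#'   `study`), values are the file's column names.  `NULL` means the file
#'   already uses the target names.
#' @return data.frame of observations.
#' @export
read_meta_csv <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    miss <- setdiff(unname(column_map), names(df))
    if (length(miss)) stop("mapped column(s) absent from file: ",
                           paste(miss, collapse = ", "))
    for (target in names(column_map)) {
      df[[target]] <- df[[column_map[[target]]]]
    }
  }
  req <- c("soc_control", "soc_warmed", "duration_yr")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df
}
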