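#' Percent change between replicate groups with a Mann-Whitney test
#'
#' Percent difference of group means,
#' `100 * (mean(treated) - mean(control)) / mean(control)`, reported with the
#' sign convention of the stated direction: with `direction = "decrease"` a
#' treated mean below control gives a positive "percent decrease". The
#' p-value is a two-sided Mann-Whitney U test (exact for small samples
#' without ties).
#'
#' @param control,treated Numeric replicate vectors (>= 3 each).
#' @param direction `"decrease"` or `"increase"`.
#' @return List: `percent`, `p`, `mean_control`, `mean_treated`, `U`.
#' @export
percent_change <- function(control, treated,
                           direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(control), is.numeric(treated))
  if (length(control) < 3L || length(treated) < 3L) {
    stop("need >= 3 replicates per group")
  }
  mc <- mean(control)
  mt <- mean(treated)
  if (mc == 0) stop("control mean is zero; percent change undefined")
  pct <- 100 * (mt - mc) / mc
  if (direction == "decrease") pct <- -pct
  wt <- suppressWarnings(stats::wilcox.test(treated, control,
                                            alternative = "two.sided"))
  list(percent = pct, p = wt$p.value, mean_control = mc, mean_treated = mt,
       U = unname(wt$statistic))
}

#' Per-cell glucose uptake
#'
#' Normalizes replicate luminescence readings by matched cell counts.
#'
#' @param luminescence Numeric replicate readings.
#' @param cell_counts Matched positive cell counts.
#' @return List: `per_cell` (replicate ratios), `mean`, `sd`.
#' @export
glucose_uptake_per_cell <- function(luminescence, cell_counts) {
  stopifnot(is.numeric(luminescence), is.numeric(cell_counts),
            length(luminescence) == length(cell_counts))
  if (any(cell_counts <= 0)) stop("cell counts must be positive")
  per <- luminescence / cell_counts
  list(per_cell = per, mean = mean(per), sd = stats::sd(per))
}
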