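#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `v(d) = bottom + (top - bottom) / (1 + (d/ic50)^hill)`
#' by Levenberg-Marquardt with a multistart grid over Hill slope and IC50.
#' The IC50 is fitted on the log scale; dose 0 enters the model exactly
#' (`0^hill = 0`), anchoring the zero-dose response on the top asymptote.
#' Box constraints keep `bottom` in [0, 1] and `top` in [0.5, 1.5]
#' (viabilities normalized to the untreated control).
#'
#' @param data data.frame with columns `dose` and `viability` (replicates as
#'   extra rows), or a numeric dose vector when `viability` is given.
#' @param viability Optional numeric vector when `data` is a dose vector.
#' @param hill_starts,ic50_quantiles Multistart grid: Hill slopes tried, and
#'   quantiles of the nonzero doses used as IC50 starting values.
#' @return Object of class `dose_response_fit`: `top`, `bottom`, `ic50`,
#'   `hill`, `rss`, `converged`, `identifiable`. A flat response (no
#'   detectable top-bottom separation) is returned with `identifiable =
#'   FALSE`, `ic50 = NA` and a warning instead of a spurious estimate.
#' @export
fit_4pl <- function(data, viability = NULL,
                    hill_starts = c(0.5, 1, 1.5, 2, 3),
                    ic50_quantiles = c(0.25, 0.5, 0.75)) {
  if (!is.data.frame(data)) {
    data <- data.frame(dose = data, viability = viability)
  }
  stopifnot(all(c("dose", "viability") %in% names(data)))
  data <- data[stats::complete.cases(data[c("dose", "viability")]), ]
  if (any(data$dose < 0)) stop("doses must be non-negative")
  if (length(unique(data$dose)) < 4L) {
    stop("need >= 4 distinct doses for an identifiable 4PL fit")
  }
  dose_means <- tapply(data$viability, data$dose, mean)
  if (diff(range(dose_means)) < 1e-3) {
    warning("flat dose-response (top = bottom): IC50 unidentifiable")
    return(structure(list(top = mean(data$viability),
                          bottom = mean(data$viability), ic50 = NA_real_,
                          hill = NA_real_, rss = sum((data$viability -
                                                        mean(data$viability))^2),
                          converged = TRUE, identifiable = FALSE),
                     class = "dose_response_fit"))
  }
  nz <- data$dose[data$dose > 0]
  d <- data$dose
  y <- data$viability
  top0 <- min(max(dose_means), 1.5)
  bottom0 <- max(min(dose_means), 0)
  starts <- expand.grid(hill = hill_starts,
                        lic50 = log(stats::quantile(nz, ic50_quantiles,
                                                    names = FALSE)))
  lower <- c(top = 0.5, bottom = 0, lic50 = log(min(nz) / 100), hill = 0.05)
  upper <- c(top = 1.5, bottom = 1, lic50 = log(max(data$dose) * 10),
             hill = 20)
  best <- NULL
  diagnostics <- character(0)
  for (i in seq_len(nrow(starts))) {
    # (d / ic50)^hill written via exp(lic50); 0^hill = 0 keeps the zero-dose
    # anchor exactly on the top asymptote
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + (d / exp(lic50))^hill),
        start = list(top = top0, bottom = bottom0,
                     lic50 = starts$lic50[i], hill = starts$hill[i]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-13,
                                             ptol = 1e-13)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
      next
    }
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(coef = stats::coef(fit), rss = rss)
    }
  }
  if (is.null(best)) {
    stop("4PL fit failed from all ", nrow(starts), " starts: ",
         paste(unique(diagnostics), collapse = "; "))
  }
  co <- best$coef
  structure(list(top = unname(co["top"]), bottom = unname(co["bottom"]),
                 ic50 = exp(unname(co["lic50"])), hill = unname(co["hill"]),
                 rss = best$rss, converged = TRUE, identifiable = TRUE),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("dose_response_fit: flat response, IC50 unidentifiable\n")
  } else {
    cat(sprintf("dose_response_fit: IC50 %.4g | hill %.3g | top %.3g | bottom %.3g | RSS %.3g\n",
                x$ic50, x$hill, x$top, x$bottom, x$rss))
  }
  invisible(x)
}
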