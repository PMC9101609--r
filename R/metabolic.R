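#' Extracellular-flux trace
#'
#' An OCR (pmol O2/min) or ECAR (mpH/min) time series segmented by injection
#' events. The canonical mitochondrial stress test has three injections —
#' oligomycin (ATP-synthase inhibitor), FCCP (uncoupler) and
#' rotenone/antimycin A (complex I/III inhibitors) — defining four segments:
#' baseline, post-oligomycin, post-FCCP and post-rotenone/antimycin.
#'
#' @param times Measurement times (minutes, strictly increasing).
#' @param values Measured rates, same length as `times`.
#' @param injections Named numeric vector of injection times (strictly
#'   increasing, within the time range); names are free but
#'   [respiration_params()] expects `oligomycin`, `fccp`,
#'   `rotenone_antimycin`.
#' @return Object of class `flux_trace`.
#' @export
flux_trace <- function(times, values, injections = numeric(0)) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (length(times) < 2L) stop("a trace needs at least 2 measurements")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (length(injections)) {
    if (is.null(names(injections)) || any(!nzchar(names(injections)))) {
      stop("injections must be named")
    }
    if (is.unsorted(injections, strictly = TRUE)) {
      stop("injection times must be strictly increasing")
    }
    if (min(injections) <= min(times) || max(injections) >= max(times)) {
      stop("injection times must lie strictly within the measurement range")
    }
  }
  seg <- findInterval(times, injections) + 1L
  n_seg <- length(injections) + 1L
  per_seg <- tabulate(seg, nbins = n_seg)
  if (any(per_seg < 3L) && length(injections)) {
    stop("need >= 3 measurements per segment; segment(s) ",
         paste(which(per_seg < 3L), collapse = ", "), " have ",
         paste(per_seg[per_seg < 3L], collapse = ", "))
  }
  structure(list(times = times, values = values, injections = injections,
                 segment = seg),
            class = "flux_trace")
}

#' @export
print.flux_trace <- function(x, ...) {
  cat("flux_trace:", length(x$times), "measurements,",
      length(x$injections), "injections (",
      paste(names(x$injections), collapse = ", "), ")\n")
  invisible(x)
}

# internal: mean value per segment, in order
.segment_levels <- function(trace) {
  vapply(split(trace$values, trace$segment), mean, 0)
}

#' Respiration parameters from a mitochondrial stress-test trace
#'
#' Derives the standard respiration parameters from the four segment levels:
#' non-mitochondrial respiration is the post-rotenone/antimycin level; basal
#' respiration is the baseline level minus non-mitochondrial; ATP-linked
#' respiration is the baseline level minus the post-oligomycin level; proton
#' leak is basal minus ATP-linked; maximal respiration is the post-FCCP
#' level minus non-mitochondrial; reserve capacity is maximal minus basal.
#'
#' @param trace A [flux_trace()] with injections `oligomycin`, `fccp`,
#'   `rotenone_antimycin` (in that order).
#' @param baseline `"mean"` (default): segment level = mean of its
#'   measurements; `"first"`: use the first baseline measurement for the
#'   baseline level, matching protocols that quote "the first OCR
#'   measurement".
#' @return Object of class `respiration_params` with fields `non_mito`,
#'   `basal`, `atp_linked`, `proton_leak`, `maximal`, `reserve` and the four
#'   segment `levels`. Negative `atp_linked` or `reserve` values are kept
#'   and flagged with a data-quality warning.
#' @export
respiration_params <- function(trace, baseline = c("mean", "first")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(trace, "flux_trace"))
  need <- c("oligomycin", "fccp", "rotenone_antimycin")
  missing <- setdiff(need, names(trace$injections))
  if (length(missing)) stop("missing injection(s): ", paste(missing, collapse = ", "))
  if (!identical(names(trace$injections), need)) {
    stop("injections must be ordered oligomycin, fccp, rotenone_antimycin")
  }
  lv <- unname(.segment_levels(trace))
  if (baseline == "first") lv[1L] <- trace$values[trace$segment == 1L][1L]
  non_mito <- lv[4L]
  basal <- lv[1L] - non_mito
  atp_linked <- lv[1L] - lv[2L]
  proton_leak <- basal - atp_linked
  maximal <- lv[3L] - non_mito
  reserve <- maximal - basal
  if (atp_linked < 0 || reserve < 0) {
    warning("negative ", paste(c("atp_linked", "reserve")[c(atp_linked, reserve) < 0],
                               collapse = " and "),
            " respiration: check trace quality")
  }
  structure(list(non_mito = non_mito, basal = basal, atp_linked = atp_linked,
                 proton_leak = proton_leak, maximal = maximal,
                 reserve = reserve,
                 levels = setNames(lv, c("baseline", "post_oligomycin",
                                         "post_fccp", "post_rotenone_antimycin"))),
            class = "respiration_params")
}

#' @export
print.respiration_params <- function(x, ...) {
  cat(sprintf(paste0("respiration_params: basal %.2f | ATP-linked %.2f | ",
                     "proton leak %.2f | maximal %.2f | reserve %.2f | ",
                     "non-mito %.2f\n"),
              x$basal, x$atp_linked, x$proton_leak, x$maximal, x$reserve,
              x$non_mito))
  invisible(x)
}

#' Minimal and maximal rate of a trace
#'
#' Minimum and maximum of the segment means (for a trace without injections,
#' both equal the overall mean). Used for ECAR summaries and for the
#' min/max OCR convention.
#'
#' @param trace A [flux_trace()].
#' @return Named numeric: `minimal`, `maximal`.
#' @export
ecar_minmax <- function(trace) {
  stopifnot(inherits(trace, "flux_trace"))
  lv <- .segment_levels(trace)
  c(minimal = min(lv), maximal = max(lv))
}
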