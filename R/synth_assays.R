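#' Planted respiration truth
#'
#' Helper building a consistent set of respiration parameters from the four
#' independent quantities; proton leak and reserve follow from the
#' additivity identities.
#'
#' @param non_mito,basal,atp_linked,maximal Respiration parameters (same
#'   units as the trace, e.g. pmol O2/min). `atp_linked <= basal` and
#'   `basal <= maximal` are not enforced — a reserve or leak can be negative
#'   in poor-quality data — but all four plateau levels implied by the
#'   parameters must be non-negative.
#' @return List of class `respiration_truth` with all six parameters and the
#'   implied plateau levels.
#' @export
respiration_truth <- function(non_mito, basal, atp_linked, maximal) {
  levels <- c(baseline = non_mito + basal,
              post_oligomycin = non_mito + basal - atp_linked,
              post_fccp = non_mito + maximal,
              post_rotenone_antimycin = non_mito)
  if (any(levels < 0)) {
    stop("parameters imply negative plateau level(s): ",
         paste(names(levels)[levels < 0], collapse = ", "))
  }
  structure(list(non_mito = non_mito, basal = basal, atp_linked = atp_linked,
                 proton_leak = basal - atp_linked, maximal = maximal,
                 reserve = maximal - basal, levels = levels),
            class = "respiration_truth")
}

#' Simulate a mitochondrial stress-test OCR trace
#'
#' Generates a four-segment trace (baseline, post-oligomycin, post-FCCP,
#' post-rotenone/antimycin) whose segment means equal the plateau levels
#' implied by the planted parameters, plus Gaussian noise.
#'
#' @param truth A [respiration_truth()].
#' @param noise_sd Gaussian noise standard deviation (same units as the
#'   trace; 0 gives an exact round trip through
#'   [respiration_params()]).
#' @param seed Integer seed.
#' @param n_per_segment Measurements per segment (>= 3, default 3).
#' @param dt Minutes between measurements (default 6.5).
#' @return A [flux_trace()].
#' @export
simulate_ocr_trace <- function(truth, noise_sd = 0, seed = 1L,
                               n_per_segment = 3L, dt = 6.5) {
  stopifnot(inherits(truth, "respiration_truth"))
  if (n_per_segment < 3L) stop("need >= 3 measurements per segment")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  withr::with_seed(.stream_seed(seed, "flux"), {
    n <- 4L * n_per_segment
    times <- dt * seq_len(n)
    mu <- rep(truth$levels, each = n_per_segment)
    values <- mu + rnorm(n, 0, noise_sd)
    inj <- times[n_per_segment * (1:3)] + dt / 2
    names(inj) <- c("oligomycin", "fccp", "rotenone_antimycin")
    flux_trace(times, values, inj)
  })
}

#' Simulate a four-parameter-logistic dose-response table
#'
#' Replicate viabilities (normalized to the untreated control, top asymptote
#' 1) from `v(d) = floor + (1 - floor) / (1 + (d / ic50)^hill)` with Gaussian
#' noise.
#'
#' @param ic50 Planted IC50 (same units as `doses`, conventionally µM);
#'   must be positive.
#' @param hill Hill slope (positive for decreasing viability).
#' @param floor Bottom asymptote as a proportion of control (default 0.05).
#' @param n_reps Replicates per dose (default 3).
#' @param doses Dose vector (>= 4 distinct values; default 8 doses spanning
#'   0-5 µM).
#' @param noise_sd Gaussian noise SD on the viability scale (default 0.05).
#' @param seed Integer seed.
#' @return data.frame: `dose`, `viability`, `replicate`.
#' @export
simulate_dose_response <- function(ic50, hill = 1.5, floor = 0.05, n_reps = 3L,
                                   doses = seq(0, 5, length.out = 8),
                                   noise_sd = 0.05, seed = 1L) {
  if (ic50 <= 0) stop("ic50 must be positive")
  if (any(doses < 0)) stop("doses must be non-negative")
  if (length(unique(doses)) < 4L) {
    stop("need >= 4 distinct doses for an identifiable 4PL fit")
  }
  if (floor < 0 || floor >= 1) stop("floor must be in [0, 1)")
  withr::with_seed(.stream_seed(seed, "dose"), {
    d <- rep(doses, times = n_reps)
    mu <- floor + (1 - floor) / (1 + (d / ic50)^hill)
    data.frame(dose = d,
               viability = mu + rnorm(length(d), 0, noise_sd),
               replicate = rep(seq_len(n_reps), each = length(doses)))
  })
}
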