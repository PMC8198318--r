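# Synthetic assay tables with known generating parameters: dose-response
# viability, exponential growth counts, gel lane profiles, wound mask pairs.

#' LL4 parameter set
#'
#' Four-parameter log-logistic dose-response model
#' `c + (d - c) / (1 + exp(b * (ln x - ln e)))`; `e` is the ED50.
#'
#' @param b slope, `c` lower asymptote, `d` upper asymptote, `e` ED50 (> 0).
#' @param c,d,e see above; requires `d > c`.
#' @return an `ll4_params` list.
#' @export
ll4_params <- function(b, c, d, e) {
  if (!(e > 0)) stop2("e (ED50) must be > 0")
  if (!(d > c)) stop2("d must exceed c")
  structure(list(b = b, c = c, d = d, e = e), class = "ll4_params")
}

#' EXD3 parameter set
#'
#' Three-parameter exponential decay model `c + (d - c) * exp(-x / e)`.
#'
#' @param c lower asymptote, `d` intercept, `e` decay scale (> 0).
#' @param d,e see above.
#' @return an `exd3_params` list.
#' @export
exd3_params <- function(c, d, e) {
  if (!(e > 0)) stop2("e (decay scale) must be > 0")
  if (!(d > c)) stop2("d must exceed c")
  structure(list(c = c, d = d, e = e), class = "exd3_params")
}

eval_dr_model <- function(params, x) {
  if (inherits(params, "ll4_params"))
    ll4(x, params$b, params$c, params$d, params$e)
  else if (inherits(params, "exd3_params"))
    exd3(x, params$c, params$d, params$e)
  else stop2("params must be ll4_params or exd3_params")
}

#' Generate a synthetic dose-response table
#'
#' Viability = model(dose) + Gaussian noise, per replicate.
#'
#' @param params an [ll4_params()] or [exd3_params()] object.
#' @param doses strictly increasing positive doses (uM).
#' @param noise_sd Gaussian noise sd on the viability scale.
#' @param replicates replicates per dose.
#' @param seed RNG seed.
#' @return data.frame with `dose_uM`, `replicate`, `viability`.
#' @export
generate_dose_response <- function(params, doses, noise_sd = 0,
                                   replicates = 3, seed = 1) {
  if (any(doses <= 0) || is.unsorted(doses, strictly = TRUE))
    stop2("doses must be positive and strictly increasing")
  if (noise_sd < 0) stop2("noise_sd must be >= 0")
  local_seed(seed, {
    tab <- expand.grid(replicate = seq_len(replicates), dose_uM = doses)
    tab <- tab[, c("dose_uM", "replicate")]
    mu <- eval_dr_model(params, tab$dose_uM)
    tab$viability <- mu + if (noise_sd > 0)
      rnorm(nrow(tab), 0, noise_sd) else 0
    rownames(tab) <- NULL
    tab
  })
}

#' Generate synthetic exponential growth counts
#'
#' `count(t) = n0 * 2^(t / doubling_time_h) * (1 + eps)`,
#' `eps ~ N(0, noise_cv)`.
#'
#' @param n0 starting count (> 0).
#' @param doubling_time_h doubling time in hours (> 0).
#' @param times_h measurement times in hours.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param replicates replicates per time point.
#' @param seed RNG seed.
#' @return data.frame with `time_h`, `replicate`, `count`.
#' @export
generate_growth_counts <- function(n0, doubling_time_h, times_h,
                                   noise_cv = 0, replicates = 1, seed = 1) {
  if (!(n0 > 0)) stop2("n0 must be > 0")
  if (!(doubling_time_h > 0)) stop2("doubling_time_h must be > 0")
  local_seed(seed, {
    tab <- expand.grid(replicate = seq_len(replicates), time_h = times_h)
    tab <- tab[, c("time_h", "replicate")]
    mu <- n0 * 2^(tab$time_h / doubling_time_h)
    eps <- if (noise_cv > 0) rnorm(nrow(tab), 0, noise_cv) else 0
    tab$count <- mu * (1 + eps)
    rownames(tab) <- NULL
    tab
  })
}

#' Generate a synthetic gel lane profile
#'
#' One-dimensional intensity profile along the migration axis: intact DNA as
#' a peak inside the well span, fragmented DNA as a broad smear below it. The
#' integrated signal inside : below the well span equals
#' `(1 - frac_fragmented) : frac_fragmented` before baseline and noise.
#'
#' @param frac_fragmented fraction of signal below the well, in `[0, 1]`.
#' @param well_span integer `(lo, hi)` profile indices covering the well.
#' @param lane_length profile length.
#' @param noise_sd additive Gaussian noise sd.
#' @param baseline constant baseline added to the profile.
#' @param seed RNG seed.
#' @return data.frame with `position`, `intensity`; `well_span` attached as
#'   an attribute.
#' @export
generate_gel_profile <- function(frac_fragmented, well_span = c(5, 40),
                                 lane_length = 400, noise_sd = 0,
                                 baseline = 0.02, seed = 1) {
  if (frac_fragmented < 0 || frac_fragmented > 1)
    stop2("frac_fragmented must be in [0, 1]")
  stopifnot(length(well_span) == 2, well_span[1] >= 1,
            well_span[2] > well_span[1], well_span[2] < lane_length)
  local_seed(seed, {
    pos <- seq_len(lane_length)
    inside <- pos >= well_span[1] & pos <= well_span[2]
    well <- dnorm(pos, mean(well_span), diff(well_span) / 6) * inside
    well <- well / sum(well)
    smear_lo <- well_span[2] + 10
    smear <- dnorm(pos, (smear_lo + lane_length) / 2,
                   (lane_length - smear_lo) / 8) * (pos >= smear_lo)
    smear <- smear / sum(smear)
    total <- 100  # total signal mass (high band-to-noise range, as in gel densitometry)
    sig <- total * ((1 - frac_fragmented) * well + frac_fragmented * smear)
    intensity <- pmax(0, sig + baseline +
                        if (noise_sd > 0) rnorm(lane_length, 0, noise_sd)
                        else 0)
    out <- data.frame(position = pos, intensity = intensity)
    attr(out, "well_span") <- as.integer(well_span)
    out
  })
}

#' Generate a wound-healing mask pair
#'
#' Two binary cell-coverage masks 24 h apart: the wound is a vertical strip
#' of exactly `initial_gap_area_px` background pixels at t0, shrunk to
#' `round((1 - closure_fraction) * initial_gap_area_px)` pixels at t24.
#'
#' @param initial_gap_area_px wound area at t0 in px^2.
#' @param closure_fraction fraction of the wound closed by t24, in `[0, 1]`.
#' @param image_shape integer `(rows, cols)`.
#' @param seed RNG seed (jitters the wound edge).
#' @return list with logical `mask_t0`, `mask_t24` (`TRUE` = cell coverage)
#'   and `interval_h = 24`.
#' @export
generate_wound_pair <- function(initial_gap_area_px, closure_fraction,
                                image_shape = c(200, 200), seed = 1) {
  if (closure_fraction < 0 || closure_fraction > 1)
    stop2("closure_fraction must be in [0, 1]")
  nr <- image_shape[1]; nc <- image_shape[2]
  if (initial_gap_area_px > 0.6 * nr * nc)
    stop2("wound area too large for image_shape")
  local_seed(seed, {
    jitter <- sample(-2:2, nr, replace = TRUE)
    strip_mask <- function(area) {
      if (area == 0) return(matrix(TRUE, nr, nc))
      w <- area %/% nr
      extra <- area %% nr
      widths <- rep(w, nr) + (seq_len(nr) <= extra)
      m <- matrix(TRUE, nr, nc)
      mid <- nc %/% 2
      for (r in seq_len(nr)) {
        if (widths[r] == 0) next
        lo <- mid - widths[r] %/% 2 + jitter[r]
        cols <- lo:(lo + widths[r] - 1)
        cols <- cols[cols >= 1 & cols <= nc]
        m[r, cols] <- FALSE
      }
      m
    }
    area24 <- round((1 - closure_fraction) * initial_gap_area_px)
    list(mask_t0 = strip_mask(initial_gap_area_px),
         mask_t24 = strip_mask(area24), interval_h = 24)
  })
}
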