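# Small assay quantifications and the statistical layer: wound-closure rate,
# gel-lane fragmentation fraction, normality checks and multiplicity-
# corrected group comparisons.

#' Wound closure rate
#'
#' The wound is the largest background (uncovered) connected component of a
#' coverage mask; the rate is the closed area per hour.
#'
#' @param mask_t0,mask_t24 logical matrices, `TRUE` = cell coverage, same
#'   shape.
#' @param interval_h time between the masks in hours (> 0).
#' @return closure rate in px^2 / h.
#' @export
wound_closure_rate <- function(mask_t0, mask_t24, interval_h = 24) {
  stopifnot(is.logical(mask_t0), is.logical(mask_t24),
            all(dim(mask_t0) == dim(mask_t24)), interval_h > 0)
  wound_area <- function(mask) {
    bg <- !mask
    if (!any(bg)) return(0)
    lab <- .cc_label(bg, 8L)
    max(tabulate(lab[lab > 0L]))
  }
  a0 <- wound_area(mask_t0)
  if (a0 == 0) stop2("no background (wound) component at t0")
  (a0 - wound_area(mask_t24)) / interval_h
}

# rolling minimum with half-window k (window 2k + 1, edges truncated)
rolling_min <- function(x, k) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    min(x[max(1L, i - k):min(n, i + k)]), 0)
}

# moving-average smoothing (half-window k), edges kept as-is
smooth_profile <- function(x, k) {
  if (k < 1) return(x)
  v <- stats::filter(x, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
  v <- as.numeric(v)
  v[is.na(v)] <- x[is.na(v)]
  v
}

#' Fragmented-DNA fraction of a gel lane profile
#'
#' Intact DNA stays in the well; fragmented DNA migrates below it. After
#' rolling-minimum background subtraction, the fraction is the integral of
#' signal below the well span over the integral of the whole lane, clipped
#' to `[0, 1]`.
#'
#' @param lane data.frame with `position`, `intensity` (or a numeric
#'   vector); `well_span` may be attached as an attribute.
#' @param well_span integer `(lo, hi)` indices covering the well; defaults
#'   to the lane attribute.
#' @param bg_halfwidth half-window of the rolling-minimum background
#'   estimator (profile samples); the profile is lightly smoothed first so
#'   the lower envelope is not dragged down by noise.
#' @param smooth_halfwidth half-window of the pre-smoothing moving average.
#' @return fraction of fragmented DNA in `[0, 1]`.
#' @export
gel_fragmentation_fraction <- function(lane, well_span = NULL,
                                       bg_halfwidth = 100,
                                       smooth_halfwidth = 4) {
  if (is.data.frame(lane)) {
    if (is.null(well_span)) well_span <- attr(lane, "well_span")
    x <- lane$intensity
  } else x <- as.numeric(lane)
  if (is.null(well_span)) stop2("well_span must be given")
  stopifnot(length(well_span) == 2, well_span[1] >= 1,
            well_span[2] <= length(x))
  if (any(x < 0)) stop2("intensities must be non-negative")
  xs <- smooth_profile(x, smooth_halfwidth)
  sig <- pmax(0, xs - rolling_min(xs, bg_halfwidth))
  tot <- sum(sig)
  if (!(tot > 0)) stop2("no signal after background subtraction")
  below <- sum(sig[seq_along(sig) > well_span[2]])
  clip01(below / tot)
}

#' Kolmogorov-Smirnov normality check per group
#'
#' KS statistic of each group against a normal with the sample's own mean
#' and sd, flagged at alpha = 0.05. Note the estimated-parameter caveat:
#' with fitted parameters the nominal KS null distribution is conservative
#' (the Lilliefors correction is not applied).
#'
#' @param samples named list of numeric vectors, or data.frame with `group`
#'   and `value` columns. Each group needs n >= 5.
#' @param alpha flagging level.
#' @return data.frame: `group`, `n`, `statistic`, `p_value`, `non_normal`.
#' @export
normality_check <- function(samples, alpha = 0.05) {
  if (is.data.frame(samples)) {
    stopifnot(all(c("group", "value") %in% names(samples)))
    samples <- split(samples$value, samples$group)
  }
  stopifnot(is.list(samples), length(samples) >= 1)
  do.call(rbind, lapply(names(samples), function(g) {
    x <- samples[[g]]
    if (length(x) < 5) stop2("group '", g, "' has n < 5")
    ks <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
    data.frame(group = g, n = length(x),
               statistic = unname(ks$statistic),
               p_value = ks$p.value,
               non_normal = ks$p.value < alpha)
  }))
}

#' Pairwise group comparisons with multiplicity control
#'
#' Either Tukey's HSD (studentized range on a one-way ANOVA fit) or
#' all-pairs Welch t tests with Bonferroni correction
#' (`p_adj = min(1, m * p)` for `m` pairs). Stars follow the usual figure
#' convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param data data.frame with `group`, `value`, or a named list of numeric
#'   vectors. Needs >= 2 groups with >= 2 values each.
#' @param method `"tukey"` or `"bonferroni"`.
#' @param alpha significance level used for the `significant` column.
#' @return object of class `comparison_result`: data.frame with `group_1`,
#'   `group_2`, `mean_diff` (group_2 - group_1), `p_adj`, `significant`,
#'   `stars`; the method and per-group normality flags are attached as
#'   attributes.
#' @export
compare_groups <- function(data, method = c("tukey", "bonferroni"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (is.list(data) && !is.data.frame(data)) {
    data <- data.frame(
      group = rep(names(data), lengths(data)),
      value = unlist(data, use.names = FALSE))
  }
  stopifnot(all(c("group", "value") %in% names(data)))
  data$group <- factor(data$group)
  gl <- levels(data$group)
  if (length(gl) < 2) stop2("need >= 2 groups")
  ns <- table(data$group)
  if (any(ns < 2)) stop2("every group needs >= 2 values")
  vars <- vapply(split(data$value, data$group), function(v) var(v), 0)
  if (all(vars == 0))
    stop2("zero within-group variance in all groups")
  if (method == "tukey") {
    fit <- aov(value ~ group, data = data)
    tk <- TukeyHSD(fit)$group
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    out <- data.frame(
      group_1 = vapply(pairs, `[`, "", 2L),
      group_2 = vapply(pairs, `[`, "", 1L),
      mean_diff = unname(tk[, "diff"]),
      p_adj = unname(tk[, "p adj"]))
  } else {
    cmb <- utils::combn(gl, 2L)
    m <- ncol(cmb)
    out <- do.call(rbind, lapply(seq_len(m), function(i) {
      g1 <- cmb[1L, i]; g2 <- cmb[2L, i]
      v1 <- data$value[data$group == g1]
      v2 <- data$value[data$group == g2]
      tt <- t.test(v2, v1)   # Welch
      data.frame(group_1 = g1, group_2 = g2,
                 mean_diff = mean(v2) - mean(v1),
                 p_adj = min(1, m * tt$p.value))
    }))
  }
  out$significant <- out$p_adj < alpha
  out$stars <- p_stars(out$p_adj)
  rownames(out) <- NULL
  norm <- tryCatch(
    normality_check(split(data$value, data$group), alpha),
    error = function(e) NULL)
  structure(out, method = method, normality = norm, alpha = alpha,
            class = c("comparison_result", "data.frame"))
}
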