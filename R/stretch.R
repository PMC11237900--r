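## Hindlimb resistance to stretch. The resistance measure is the mechanical
## work W (gram x mm) to stretch a hindlimb: the stretching force trace,
## sampled at 100 Hz during a 5 mm/s ramp, is LOESS-smoothed and integrated
## over the 0-10 mm stretch window. Asymmetry is expressed both as a
## difference (W_L - W_R, W_C - W_I) and as a log2 asymmetry index
## (AI = log2 of the work ratio) because the two can depend differently on
## the stretching distance.

#' LOESS smoothing settings for force traces
#'
#' @param span fraction of points in the local window (default 0.4)
#' @param iterations robust-fitting iterations in the [stats::loess()]
#'   convention (the count includes the initial least-squares pass);
#'   0 disables bisquare re-weighting entirely, 4 is the conventional
#'   "symmetric" family default
#' @param degree local polynomial degree
#' @return a `smoothing_spec`
#' @export
smoothing_spec <- function(span = 0.4, iterations = 4L, degree = 2L) {
  if (!(span > 0 && span <= 1)) stop_config("span must lie in (0, 1]")
  if (iterations < 0L) stop_config("iterations must be >= 0")
  structure(list(span = span, iterations = as.integer(iterations),
                 degree = as.integer(degree)),
            class = "smoothing_spec")
}

#' Smooth a force trace by local regression
#'
#' Locally weighted polynomial regression of force on distance with tricube
#' weights; robust bisquare re-weighting when `iterations > 0`. Returns the
#' fitted force at every observed distance.
#'
#' @param distance,force numeric vectors of equal length (mm, grams)
#' @param spec a [smoothing_spec()]
#' @return numeric vector of smoothed forces, same length as the input
#' @export
loess_smooth <- function(distance, force, spec = smoothing_spec()) {
  ok <- is.finite(distance) & is.finite(force)
  if (sum(ok) < 10L) stop_input("need at least 10 finite samples to smooth")
  if (floor(spec$span * sum(ok)) < spec$degree + 1L)
    stop_input("span window too small for the polynomial degree")
  fam <- if (spec$iterations > 0L) "symmetric" else "gaussian"
  fit <- stats::loess(force[ok] ~ distance[ok], span = spec$span,
                      degree = spec$degree, family = fam,
                      control = stats::loess.control(
                        surface = "direct",
                        iterations = max(1L, spec$iterations)))
  out <- rep(NA_real_, length(distance))
  out[ok] <- stats::predict(fit, data.frame(`distance[ok]` = distance[ok],
                                            check.names = FALSE))
  out
}

#' Mechanical work of one stretch
#'
#' Smooths the trace and integrates the smoothed force over the stretch
#' window by the trapezoidal rule at the observed distances (with linear
#' interpolation to the exact window endpoints). Samples outside the window
#' inform the smoother but not the integral.
#'
#' @param distance,force the trace (mm, grams)
#' @param spec a [smoothing_spec()]
#' @param window integration window in mm, default `c(0, 10)`
#' @return work in gram x mm
#' @export
stretch_work <- function(distance, force, spec = smoothing_spec(),
                         window = c(0, 10)) {
  stopifnot(length(window) == 2L, window[1L] < window[2L])
  ok <- is.finite(distance) & is.finite(force)
  d <- distance[ok]; f <- force[ok]
  o <- order(d); d <- d[o]; f <- f[o]
  if (length(d) < 20L) stop_input("need >= 20 samples for work computation")
  eps <- 1e-9
  if (min(d) > window[1L] + eps || max(d) < window[2L] - eps)
    stop_input(sprintf("samples must cover the window [%g, %g] mm",
                       window[1L], window[2L]))
  sm <- loess_smooth(d, f, spec)
  inside <- d >= window[1L] & d <= window[2L]
  xd <- d[inside]; xf <- sm[inside]
  for (endpoint in window) {
    if (!any(abs(xd - endpoint) < eps)) {
      xf <- c(xf, stats::approx(d, sm, xout = endpoint)$y)
      xd <- c(xd, endpoint)
    }
  }
  o <- order(xd)
  trapezoid(xd[o], xf[o])
}

#' Per-limb work from a force long table
#'
#' Integrates each technical replicate stretch separately and averages the
#' works per rat, limb and timepoint (replicates are averaged after
#' integration, which is invariant to replicate-specific sampling jitter).
#'
#' @param force_table force long table (`rat_id`, `limb`, `timepoint`,
#'   `replicate`, `distance_mm`, `force_g`)
#' @param spec a [smoothing_spec()]
#' @param window integration window, mm
#' @return data.frame with one row per rat x limb x timepoint and column `w`
#' @export
work_table <- function(force_table, spec = smoothing_spec(), window = c(0, 10)) {
  df <- as.data.frame(force_table)
  key <- interaction(df$rat_id, df$limb, df$timepoint, df$replicate, drop = TRUE)
  per_rep <- do.call(rbind, lapply(split(df, key), function(d) {
    data.frame(rat_id = d$rat_id[1L], limb = d$limb[1L],
               timepoint = d$timepoint[1L],
               treatment = if ("treatment" %in% names(d)) d$treatment[1L] else NA,
               w = stretch_work(d$distance_mm, d$force_g, spec, window),
               stringsAsFactors = FALSE)
  }))
  key2 <- interaction(per_rep$rat_id, per_rep$limb, per_rep$timepoint, drop = TRUE)
  out <- do.call(rbind, lapply(split(per_rep, key2), function(d) {
    d$w[1L] <- mean(d$w); d[1L, , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}

#' Left/right and contra/ipsilesional work asymmetry
#'
#' Computes W_L - W_R and AI_L/R = log2(W_L / W_R), and, when a lesion side
#' is given, the contralesional-ipsilesional analogues W_C - W_I and
#' AI_C/I. For sham animals (`lesion_side = "none"`) the contra/ipsi fields
#' are `NA`.
#'
#' @param w_left,w_right work per limb, gram x mm (must be > 0 for the AI)
#' @param lesion_side `"left"`, `"right"` or `"none"`
#' @return one-row data.frame: `w_left`, `w_right`, `w_lr`, `ai_lr`,
#'   `w_ci`, `ai_ci`
#' @export
work_asymmetry <- function(w_left, w_right, lesion_side = "none") {
  lesion_side <- match.arg(lesion_side, c("left", "right", "none"))
  if (!is.finite(w_left) || !is.finite(w_right)) stop_input("work values must be finite")
  if (w_left <= 0 || w_right <= 0)
    stop_domain("asymmetry index requires strictly positive work values")
  w_lr <- w_left - w_right
  ai_lr <- log2(w_left / w_right)
  if (lesion_side == "none") {
    w_ci <- NA_real_; ai_ci <- NA_real_
  } else {
    w_c <- if (lesion_side == "left") w_right else w_left
    w_i <- if (lesion_side == "left") w_left else w_right
    w_ci <- w_c - w_i
    ai_ci <- log2(w_c / w_i)
  }
  data.frame(w_left = w_left, w_right = w_right, w_lr = w_lr, ai_lr = ai_lr,
             w_ci = w_ci, ai_ci = ai_ci)
}

#' Correlation between postural and stretch-work asymmetry
#'
#' Pearson correlation between the magnitude of postural asymmetry (MPA)
#' and the contralesional-ipsilesional work difference across rats.
#'
#' @param mpa MPA per rat, mm
#' @param w_ci W_C - W_I per rat, gram x mm
#' @return list with `r`, `p`, `n`
#' @export
mpa_work_correlation <- function(mpa, w_ci) {
  ok <- is.finite(mpa) & is.finite(w_ci)
  mpa <- mpa[ok]; w_ci <- w_ci[ok]
  if (length(mpa) < 3L) stop_input("need >= 3 complete pairs")
  if (sd(mpa) == 0 || sd(w_ci) == 0)
    stop_domain("correlation undefined: zero variance")
  ct <- stats::cor.test(mpa, w_ci, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(mpa))
}
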