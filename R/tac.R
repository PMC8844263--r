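#' Normalize a time--activity curve
#'
#' Rescales a sampled organ curve to activity per 1 MBq injected and to
#' the organ mass of the 70-kg reference adult. Curves measured as
#' decay-corrected fractions of injected activity are already per-MBq in
#' the bookkeeping sense, so only the mass scaling
#' (`reference mass / subject organ mass`) applies; when the subject organ
#' mass is unknown it defaults to the reference mass and the transform is
#' the identity. Curves in absolute MBq are divided by the injected
#' activity first.
#'
#' @param tac Tibble with columns `organ`, `time_min`, and `fraction_ia`
#'   (or `activity_mbq` when `values_unit = "mbq"`).
#' @param injected_mbq Injected activity (> 0).
#' @param phantom Reference phantom, see [reference_phantom()].
#' @param subject_masses Optional tibble `organ, mass_g` of subject-specific
#'   organ masses.
#' @param values_unit `"fraction"` (decay-corrected fraction of injected
#'   activity, the default) or `"mbq"` (absolute decay-corrected activity).
#' @return A tibble `organ, time_min, value` where `value` is MBq in the
#'   reference organ per MBq injected (decay-corrected).
#' @examples
#' tac <- tibble::tibble(organ = "liver", time_min = c(1, 60),
#'                       fraction_ia = c(0.158, 0.12))
#' normalize_tac(tac, injected_mbq = 220, phantom = reference_phantom())
#' @export
normalize_tac <- function(tac, injected_mbq, phantom = reference_phantom(),
                          subject_masses = NULL,
                          values_unit = c("fraction", "mbq")) {
  values_unit <- match.arg(values_unit)
  if (injected_mbq <= 0) stop("injected_mbq must be positive")
  val_col <- if (values_unit == "fraction") "fraction_ia" else "activity_mbq"
  stopifnot(all(c("organ", "time_min", val_col) %in% names(tac)))
  ref_mass <- .phantom_mass(phantom, unique(tac$organ)) # errors if unknown
  frac <- tac[[val_col]]
  if (any(frac < 0)) stop("negative activity values")
  if (values_unit == "mbq") frac <- frac / injected_mbq
  scale <- rep(1, nrow(tac))
  if (!is.null(subject_masses)) {
    i <- match(tac$organ, subject_masses$organ)
    known <- !is.na(i)
    scale[known] <- .phantom_mass(phantom, tac$organ[known]) /
      subject_masses$mass_g[i[known]]
  }
  tibble::tibble(organ = tac$organ, time_min = tac$time_min,
                 value = frac * scale)
}

#' Fit the biologic washout of a normalized curve
#'
#' Locates the curve's global maximum (ties resolved to the latest tied
#' sample) and fits `A0 * exp(-k_bio * (t - t_start))` by least squares to
#' the samples from the peak onward --- only the descending part of a
#' curve with continuing uptake is used. If the maximum is the final
#' sample (a still-rising curve) the fit is the conservative
#' `k_bio = 0, A0 = last value`, so the extrapolated tail decays by
#' physical decay only.
#'
#' @param ntac Tibble with columns `time_min` and `value` (one organ).
#' @return An object of class `washout_fit`: list with `organ`, `A0`
#'   (amplitude referenced to injection time, t = 0), `k_bio` (1/h),
#'   `t_start_min` (first fitted sample), `rss`, `n_fit`, `degenerate`.
#' @examples
#' t <- c(1, 7, 20, 40, 65, 88, 164, 234)
#' y <- 0.1 * exp(-0.5 * t / 60)
#' fit_washout(tibble::tibble(time_min = t, value = y))
#' @export
fit_washout <- function(ntac) {
  stopifnot(all(c("time_min", "value") %in% names(ntac)))
  if (nrow(ntac) < 2) stop("need at least 2 samples")
  if (any(diff(ntac$time_min) <= 0)) stop("times must be strictly increasing")
  organ <- if ("organ" %in% names(ntac)) ntac$organ[1] else NA_character_
  y <- ntac$value
  t_h <- ntac$time_min / 60
  peak <- max(which(y == max(y)))           # latest tied maximum
  t0 <- t_h[peak]
  ys <- y[peak:length(y)]
  ts <- t_h[peak:length(y)]                 # absolute time: A0 is at t = 0

  new_fit <- function(A0, k, rss, n, degenerate = FALSE) {
    structure(list(organ = organ, A0 = A0, k_bio = k,
                   t_start_min = t0 * 60, rss = rss, n_fit = n,
                   degenerate = degenerate), class = "washout_fit")
  }
  if (all(y <= 0)) {
    warning("curve is identically zero; degenerate washout fit")
    return(new_fit(0, 0, 0, length(ys), degenerate = TRUE))
  }
  if (length(ys) < 2) {                      # peak is the final sample
    return(new_fit(y[length(y)], 0, 0, 1))
  }
  # log-linear start where possible, then bounded nonlinear least squares
  pos <- ys > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(ys[pos]) ~ ts[pos])
    start <- list(A0 = exp(unname(stats::coef(lf)[1])),
                  k = max(0, -unname(stats::coef(lf)[2])))
  } else {
    start <- list(A0 = max(ys), k = 1)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(ys ~ A0 * exp(-k * ts),
                      start = start, lower = c(0, 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("washout fit failed to converge; using k_bio = 0")
    return(new_fit(ys[length(ys)], 0, NA_real_, length(ys),
                   degenerate = TRUE))
  }
  cf <- stats::coef(fit)
  new_fit(unname(cf["A0"]), unname(cf["k"]),
          sum(stats::resid(fit)^2), length(ys))
}

#' @export
print.washout_fit <- function(x, ...) {
  cat("<washout_fit> ", if (!is.na(x$organ)) paste0(x$organ, ": "),
      "A0 = ", signif(x$A0, 4), ", k_bio = ", signif(x$k_bio, 4),
      "/h from t = ", round(x$t_start_min, 1), " min (", x$n_fit,
      " samples)", if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' @rdname fit_washout
#' @param x A `washout_fit`.
#' @param ... Unused.
#' @export
tidy.washout_fit <- function(x, ...) {
  tibble::tibble(organ = x$organ, A0 = x$A0, k_bio = x$k_bio,
                 t_start_min = x$t_start_min, rss = x$rss,
                 n_fit = x$n_fit, degenerate = x$degenerate)
}

# integral of the linear interpolant (a + b t) weighted by exp(-lambda t),
# segment [t0, t1]; closed form, exact for k_bio = 0
.seg_decay_integral <- function(t0, t1, v0, v1, lambda) {
  b <- (v1 - v0) / (t1 - t0)
  a <- v0 - b * t0
  ((a + b * t0 + b / lambda) * exp(-lambda * t0) -
     (a + b * t1 + b / lambda) * exp(-lambda * t1)) / lambda
}

#' Residence time (cumulated activity per unit injected activity)
#'
#' Integrates the non-decay-corrected organ activity to infinity:
#' a leading segment assuming linear rise from (0, 0) to the first sample;
#' the observed span; and an analytic tail `A(t_last) * exp(-lambda_p *
#' t_last) / (lambda_p + k_bio)` from the washout fit. Inputs are
#' decay-corrected, so physical decay is re-applied explicitly. The
#' default method interpolates the decay-corrected curve linearly and
#' carries the decay weight exactly inside each segment (exact for pure
#' physical decay); `method = "trapezoid"` is the plain trapezoid on the
#' decayed samples.
#'
#' @param ntac Tibble with `time_min` and `value` (one organ).
#' @param fit A [fit_washout()] result for the same curve (default:
#'   computed from `ntac`).
#' @param method `"exact_decay"` (default) or `"trapezoid"`.
#' @return One-row tibble `organ, tau_h, auc_obs_h, tail_h`; `tau_h` is
#'   in hours per MBq injected (MBq h / MBq).
#' @examples
#' t <- seq(0, 240, by = 2)
#' curve <- tibble::tibble(organ = "liver", time_min = t,
#'                         value = 0.158 * exp(-0.1 * t / 60))
#' residence_time(curve)
#' @export
residence_time <- function(ntac, fit = fit_washout(ntac),
                           method = c("exact_decay", "trapezoid")) {
  method <- match.arg(method)
  if (any(ntac$value < 0)) stop("negative values in curve")
  organ <- if ("organ" %in% names(ntac)) ntac$organ[1] else NA_character_
  lam <- f18_lambda("per_h")
  t_h <- ntac$time_min / 60
  v <- ntac$value
  if (t_h[1] > 0) {                     # leading linear rise from (0, 0)
    tt <- c(0, t_h)
    vv <- c(0, v)
  } else {
    tt <- t_h
    vv <- v
  }
  if (method == "exact_decay") {
    auc <- sum(.seg_decay_integral(tt[-length(tt)], tt[-1],
                                   vv[-length(vv)], vv[-1], lam))
  } else {
    w <- vv * exp(-lam * tt)
    auc <- sum(diff(tt) * (w[-1] + w[-length(w)]) / 2)
  }
  t_last <- t_h[length(t_h)]
  a_last <- fit$A0 * exp(-fit$k_bio * t_last)
  tail <- a_last * exp(-lam * t_last) / (lam + fit$k_bio)
  tibble::tibble(organ = organ, tau_h = auc + tail,
                 auc_obs_h = auc, tail_h = tail)
}

#' Remainder-of-body residence time
#'
#' By activity conservation the whole body would carry `1 / lambda_p`
#' (about 2.639 h) if nothing were excreted; the remainder source is that
#' bound minus the explicit organ and bladder-content residence times and
#' minus the residence lost to urine that left the body, where each void
#' of decay-corrected fraction `u` at time `t` forfeits
#' `u * exp(-lambda_p t) / lambda_p`.
#'
#' @param organ_taus Tibble `organ, tau_h` of explicit source organs.
#' @param bladder_tau_h Bladder-content residence time (hours).
#' @param voided Tibble `time_min, fraction_ia` of individual voids
#'   (decay-corrected fractions of injected activity). May be empty.
#' @return One-row tibble `organ = "remainder_of_body", tau_h` (clamped at
#'   0 with a warning if the bookkeeping over-subtracts).
#' @export
remainder_residence <- function(organ_taus, bladder_tau_h = 0,
                                voided = NULL) {
  lam <- f18_lambda("per_h")
  lost <- 0
  if (!is.null(voided) && nrow(voided) > 0) {
    lost <- sum(voided$fraction_ia * exp(-lam * voided$time_min / 60)) / lam
  }
  tau <- 1 / lam - sum(organ_taus$tau_h) - bladder_tau_h - lost
  if (tau < 0) {
    warning("remainder residence negative (", signif(tau, 3),
            " h); clamped to 0")
    tau <- 0
  }
  tibble::tibble(organ = "remainder_of_body", tau_h = tau)
}

#' Cohort mean whole-blood curve
#'
#' Descriptive summary of the whole-blood radioactivity concentration
#' samples: pointwise mean (and SD) over subjects at each scheduled
#' sampling time. Not used in the dosimetry itself.
#'
#' @param samples Tibble with `subject_id`, `time_min` and a concentration
#'   column (the first column that is neither id nor time is used).
#' @return Tibble `time_min, mean, sd, n`.
#' @export
blood_curve_summary <- function(samples) {
  stopifnot(all(c("subject_id", "time_min") %in% names(samples)))
  if (nrow(samples) < 2) stop("need at least 2 samples")
  val <- setdiff(names(samples), c("subject_id", "time_min"))[1]
  samples |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(mean = mean(.data[[val]]),
                     sd = stats::sd(.data[[val]]),
                     n = dplyr::n(), .groups = "drop")
}
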