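#' Fit urinary excretion kinetics from urine collections
#'
#' Builds the cumulative decay-corrected excreted fraction at each
#' collection's end time (a collection empties the bladder at the void)
#' and fits `F(t) = f_u * (1 - exp(-lambda_b * t))` by bounded least
#' squares: `0 <= f_u <= 1`, `lambda_b >= 0`. This is the biologic
#' half-life estimate of the dynamic bladder model, assuming urine is the
#' only excretion route.
#'
#' @param collections Tibble with `t_start_min`, `t_end_min`,
#'   `fraction_ia` (decay-corrected fraction of injected activity in each
#'   collection). Pre-injection collections (`t_end_min <= 0`) are
#'   dropped.
#' @return An object of class `bladder_kinetics`: list with `f_u`,
#'   `lambda_b` (1/h), `rss`, `n`, `degenerate`.
#' @examples
#' u <- tibble::tibble(t_start_min = c(0, 111, 194),
#'                     t_end_min = c(111, 194, 263),
#'                     fraction_ia = c(0.072, 0.042, 0.034))
#' fit_excretion(u)
#' @export
fit_excretion <- function(collections) {
  stopifnot(all(c("t_start_min", "t_end_min", "fraction_ia") %in%
                  names(collections)))
  post <- collections[collections$t_end_min > 0, , drop = FALSE]
  post <- post[order(post$t_end_min), , drop = FALSE]
  if (nrow(post) < 2) stop("need at least 2 post-injection collections")
  if (any(post$fraction_ia < 0)) stop("negative urine fractions")
  if (any(post$t_end_min <= post$t_start_min)) {
    stop("collections must have t_end_min > t_start_min")
  }
  t_h <- post$t_end_min / 60
  cum <- cumsum(post$fraction_ia)
  new_k <- function(fu, lb, rss, degenerate = FALSE) {
    structure(list(f_u = fu, lambda_b = lb, rss = rss, n = length(cum),
                   degenerate = degenerate), class = "bladder_kinetics")
  }
  if (all(cum == 0)) {
    warning("all collections empty; degenerate excretion kinetics (f_u = 0)")
    return(new_k(0, 0, 0, degenerate = TRUE))
  }
  start <- list(fu = min(1, max(cum) * 1.5), lb = 0.2)
  fit <- tryCatch(
    minpack.lm::nlsLM(cum ~ fu * (1 - exp(-lb * t_h)),
                      start = start, lower = c(0, 0), upper = c(1, Inf),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) stop("urinary excretion fit failed to converge")
  cf <- stats::coef(fit)
  new_k(unname(cf["fu"]), unname(cf["lb"]), sum(stats::resid(fit)^2))
}

#' @export
print.bladder_kinetics <- function(x, ...) {
  cat("<bladder_kinetics> f_u = ", signif(x$f_u, 4), ", lambda_b = ",
      signif(x$lambda_b, 4), "/h (biologic half-life ",
      signif(log(2) / x$lambda_b, 3), " h)",
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' @rdname fit_excretion
#' @param x A `bladder_kinetics` object.
#' @param ... Unused.
#' @export
tidy.bladder_kinetics <- function(x, ...) {
  tibble::tibble(f_u = x$f_u, lambda_b = x$lambda_b, rss = x$rss,
                 n = x$n, degenerate = x$degenerate)
}

#' Bladder-content residence time, dynamic voiding model
#'
#' Closed form for the cumulated bladder-content activity per MBq injected
#' under periodic complete voiding every `interval_h` hours starting at
#' injection. Between voids at `t_k` the (non-decay-corrected) content is
#' `f_u * exp(-lambda_p t) * (exp(-lambda_b t_k) - exp(-lambda_b t))`;
#' summing the per-interval integrals over the geometric void sequence
#' gives, with `T = interval_h`:
#' \deqn{\tau = f_u \frac{(1-e^{-\lambda_p T})/\lambda_p -
#'   (1-e^{-(\lambda_p+\lambda_b) T})/(\lambda_p+\lambda_b)}
#'   {1 - e^{-(\lambda_p+\lambda_b) T}}.}
#' For `lambda_b * T < 1e-8` the numerator difference cancels
#' catastrophically and the series limit
#' `f_u * lambda_b * (1 - (1 + lambda_p T) e^{-lambda_p T}) /
#' (lambda_p^2 (1 - e^{-lambda_p T}))` is used instead; it vanishes only
#' when `f_u * lambda_b` does.
#'
#' @param kinetics A [fit_excretion()] result (or any list with `f_u`
#'   and `lambda_b` in 1/h).
#' @param interval_h Voiding interval in hours (> 0).
#' @return One-row tibble `organ = "urinary_bladder_content", tau_h,
#'   interval_h`.
#' @examples
#' k <- fit_excretion(tibble::tibble(
#'   t_start_min = c(0, 111, 194), t_end_min = c(111, 194, 263),
#'   fraction_ia = c(0.072, 0.042, 0.034)))
#' bladder_residence_dynamic(k, 1)
#' bladder_residence_dynamic(k, 3.5)
#' @export
bladder_residence_dynamic <- function(kinetics, interval_h) {
  if (interval_h <= 0) stop("voiding interval must be positive")
  fu <- kinetics$f_u
  lb <- kinetics$lambda_b
  if (fu < 0 || fu > 1 || lb < 0) stop("invalid bladder kinetics")
  lp <- f18_lambda("per_h")
  T <- interval_h
  if (lb * T < 1e-8) {
    tau <- fu * lb * (1 - (1 + lp * T) * exp(-lp * T)) /
      (lp^2 * (1 - exp(-lp * T)))
  } else {
    g <- function(x) (1 - exp(-x * T)) / x
    tau <- fu * (g(lp) - g(lp + lb)) / (1 - exp(-(lp + lb) * T))
  }
  tibble::tibble(organ = "urinary_bladder_content", tau_h = tau,
                 interval_h = interval_h)
}

#' Bladder-content residence time from VOI measurements
#'
#' The image-based estimator: bladder-content activity at each scan is the
#' VOI concentration multiplied by the bladder volume measured at the end
#' of that scan's session; the activity series is reset to zero at each
#' void, carried with physical decay from the last scan of a session to
#' the following void, and integrated (leading linear rise from zero,
#' per-segment exact physical-decay weighting as in [residence_time()]).
#' After the last void no further accumulation is counted; if no void
#' follows the last scan a pure physical-decay tail is added.
#'
#' @param voi Tibble `time_min, conc_per_ml` --- decay-corrected fraction
#'   of injected activity per mL of bladder content at each scan.
#' @param volumes Tibble `time_min, volume_ml` --- timed bladder-volume
#'   measurements (one per session, at approximately 111, 194, 263 min).
#' @param void_times Minutes at which the bladder is emptied (default: the
#'   volume-measurement times).
#' @return One-row tibble `organ = "urinary_bladder_content", tau_h`.
#' @export
bladder_residence_voi <- function(voi, volumes,
                                  void_times = volumes$time_min) {
  stopifnot(all(c("time_min", "conc_per_ml") %in% names(voi)),
            all(c("time_min", "volume_ml") %in% names(volumes)))
  if (anyNA(voi$conc_per_ml) || anyNA(volumes$volume_ml)) {
    stop("missing VOI or volume value")
  }
  lam <- f18_lambda("per_h")
  volumes <- volumes[order(volumes$time_min), ]
  # each scan uses the first volume measurement at or after it
  vol_idx <- findInterval(voi$time_min - 1e-9, volumes$time_min) + 1
  if (any(vol_idx > nrow(volumes))) {
    stop("missing volume measurement after scan at ",
         voi$time_min[vol_idx > nrow(volumes)][1], " min")
  }
  act <- voi$conc_per_ml * volumes$volume_ml[vol_idx]   # fraction of IA
  void_times <- sort(void_times)
  segs <- split(seq_along(act),
                findInterval(voi$time_min, void_times, left.open = TRUE))
  tau <- 0
  bounds <- c(0, void_times)
  for (s in names(segs)) {
    idx <- segs[[s]]
    t0 <- bounds[as.integer(s) + 1]                   # last void before
    t_h <- c(t0, voi$time_min[idx]) / 60
    v <- c(0, act[idx])                               # empty after void
    tau <- tau + sum(.seg_decay_integral(t_h[-length(t_h)], t_h[-1],
                                         v[-length(v)], v[-1], lam))
    nxt <- void_times[void_times > max(voi$time_min[idx])]
    last_dc <- act[idx[length(idx)]]
    t_last <- max(voi$time_min[idx]) / 60
    if (length(nxt) > 0) {
      # constant decay-corrected content until the next void, then empty
      t_void <- min(nxt) / 60
      tau <- tau + last_dc * (exp(-lam * t_last) - exp(-lam * t_void)) / lam
    } else {
      tau <- tau + last_dc * exp(-lam * t_last) / lam  # decay-only tail
    }
  }
  tibble::tibble(organ = "urinary_bladder_content", tau_h = tau)
}
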