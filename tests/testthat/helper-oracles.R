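# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms: brute-force sums, fine-grid quadrature and an
# ODE integration stand on their own feet.

lambda_p <- mirdose::f18_lambda("per_h")

# true residence time of the generator's kinetic model, by closed form
# integral of f (1 - e^{-ku t}) e^{-(kb + lp) t}
model_tau_exact <- function(f_peak, k_up, k_bio) {
  f_peak * (1 / (k_bio + lambda_p) - 1 / (k_up + k_bio + lambda_p))
}

# fine-grid trapezoid of the generating model (independent quadrature)
model_tau_quadrature <- function(f_peak, k_up, k_bio, t_max_h = 80,
                                 n = 4e5) {
  t <- seq(0, t_max_h, length.out = n)
  y <- f_peak * (1 - exp(-k_up * t)) * exp(-(k_bio + lambda_p) * t)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

# dynamic bladder model by numerical integration of the piecewise ODE:
# content accrues at fu lb e^{-(lb+lp) t}, decays physically, and is
# voided instantaneously every interval_h
ode_bladder_tau <- function(f_u, lambda_b, interval_h, horizon_h = 60) {
  voids <- seq(interval_h, horizon_h, by = interval_h)
  deriv <- function(t, y, p) {
    list(c(f_u * lambda_b * exp(-(lambda_b + lambda_p) * t) -
             lambda_p * y[1],
           y[1]))
  }
  times <- sort(unique(c(seq(0, horizon_h, by = 0.01), voids)))
  ev <- data.frame(var = "B", time = voids, value = 0, method = "rep")
  out <- deSolve::ode(c(B = 0, A = 0), times, deriv, NULL,
                      rtol = 1e-12, atol = 1e-14,
                      events = list(data = ev))
  unname(out[nrow(out), "A"])
}

# MIRD contraction by explicit double loop
brute_force_doses <- function(taus, s) {
  sapply(rownames(s), function(target) {
    total <- 0
    for (i in seq_len(nrow(taus))) {
      src <- taus$organ[i]
      if (src %in% colnames(s)) total <- total + taus$tau_h[i] * s[target, src]
    }
    total
  })
}

# ICRP-60 effective dose with the splitting rule, written as an explicit
# case analysis independent of the package's vectorized path
brute_force_effective <- function(d, weights, phantom) {
  get <- function(org) d$dose_mgy_per_mbq[match(org, d$organ)]
  m <- function(org) phantom$mass_g[match(org, phantom$organ)]
  expl <- c(
    gonads = mean(c(get("testes"), get("ovaries"))),
    red_marrow = get("red_marrow"),
    colon = (m("uli_wall") * get("uli_wall") +
               m("lli_wall") * get("lli_wall")) /
      (m("uli_wall") + m("lli_wall")),
    lungs = get("lungs"), stomach_wall = get("stomach_wall"),
    urinary_bladder_wall = get("urinary_bladder_wall"),
    breasts = get("breasts"), liver = get("liver"),
    esophagus = get("thymus"), thyroid = get("thyroid"),
    skin = get("skin"), osteogenic_cells = get("osteogenic_cells"))
  e <- 0
  for (tis in names(expl)) {
    e <- e + weights$w[match(tis, weights$tissue)] * expl[[tis]]
  }
  rem <- attr(weights, "remainder_tissues")
  dr <- vapply(rem, get, numeric(1))
  mr <- vapply(rem, m, numeric(1))
  hottest <- which.max(dr)
  out <- if (dr[hottest] > max(expl)) {
    rest <- setdiff(seq_along(dr), hottest)
    e + 0.025 * dr[hottest] +
      0.025 * sum(dr[rest] * mr[rest]) / sum(mr[rest])
  } else {
    e + 0.05 * sum(dr * mr) / sum(mr)
  }
  unname(out)
}

# tiny synthetic S table for dose-engine unit tests
toy_svalue_table <- function(organs = c("a", "b", "c", "d", "e"),
                             seed = 99) {
  set.seed(seed)
  n <- length(organs)
  m <- matrix(runif(n * n, 0.001, 0.01), n, n,
              dimnames = list(organs, organs))
  diag(m) <- diag(m) + 0.05 # self-dose dominates
  structure(m, units = "mGy_per_MBq_h",
            class = c("svalue_table", "matrix"))
}

# noise-free cohort shortcut
noise_free_cohort <- function(n = 1, seed = 1, ...) {
  kin <- mirdose::default_kinetics()
  kin$cv_inter <- 0
  ex <- mirdose::default_excretion()
  ex$cv_fu <- 0
  ex$cv_lambda <- 0
  mirdose::generate_cohort(n, seed = seed, kinetics = kin, excretion = ex,
                           sigma_meas = 0, ...)
}
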