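#' Parameters for the equilibrium binding-curve simulator
#'
#' One-site hyperbolic binding read out as fraction of RNA bound at
#' increasing protein concentration, the geometry of an electrophoretic
#' mobility shift titration. The default concentration grid spans
#' 0.5-60 uM (12 log-spaced points).
#'
#' @param kd_true True dissociation constant, uM.
#' @param conc_grid Protein concentrations, uM; strictly positive,
#'   ascending.
#' @param noise_sd Gaussian noise on fraction bound.
#' @param seed Master seed.
#' @return A list of class `sim_binding_params`.
#' @export
sim_binding_params <- function(kd_true = 2,
                               conc_grid = exp(seq(log(0.5), log(60),
                                                   length.out = 12)),
                               noise_sd = 0.02,
                               seed = 1L) {
  stopifnot(kd_true > 0, noise_sd >= 0)
  if (any(conc_grid <= 0) || is.unsorted(conc_grid, strictly = TRUE))
    stop("conc_grid must be strictly positive and ascending",
         call. = FALSE)
  structure(list(kd_true = kd_true, conc_grid = conc_grid,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_binding_params")
}

#' Simulate an equilibrium binding curve
#'
#' `fraction_bound = C / (Kd + C) + noise`, clipped to `[0, 1]`.
#'
#' @param params A [sim_binding_params()] object.
#' @return A `data.table` with `concentration_um` and `fraction_bound`.
#' @export
simulate_binding <- function(params) {
  stopifnot(inherits(params, "sim_binding_params"))
  with_seed(substream_seed(params$seed, "binding"), {
    f <- params$conc_grid / (params$kd_true + params$conc_grid)
    f <- pmin(1, pmax(0, f + rnorm(length(f), 0, params$noise_sd)))
    data.table(concentration_um = params$conc_grid, fraction_bound = f)
  })
}

#' Fit a one-site equilibrium dissociation constant
#'
#' Least-squares fit of `f(C) = C^h / (Kd^h + C^h)` (default Hill
#' coefficient h = 1, the one-site hyperbola; the ceiling is fixed at 1
#' because fraction bound is already a ratio). The optimizer is restarted
#' from log-spaced initial Kd values spanning the concentration range and
#' the best converged fit is kept. A fit that does not beat the flat
#' (no-binding) model in an F-test at `alpha` returns the `no_binding`
#' verdict with `kd = NA` rather than a numeric Kd.
#'
#' @param concentration Protein concentrations (any consistent unit);
#'   at least 4 distinct positive values.
#' @param fraction_bound Observed bound fractions (replicate observations
#'   may repeat concentrations).
#' @param hill Fixed Hill coefficient.
#' @param alpha F-test level for the no-binding verdict.
#' @return A list of class `kd_fit`: `kd`, `kd_se`, `rss`, `n`,
#'   `p_vs_flat`, `verdict` (`"binding"` or `"no_binding"`), `hill`.
#' @export
fit_kd <- function(concentration, fraction_bound, hill = 1,
                   alpha = 0.05) {
  stopifnot(length(concentration) == length(fraction_bound), hill > 0)
  ok <- is.finite(concentration) & is.finite(fraction_bound)
  C <- concentration[ok]; f <- fraction_bound[ok]
  if (length(unique(C)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  if (any(C <= 0)) stop("concentrations must be positive", call. = FALSE)
  n <- length(C)
  rss_flat <- sum((f - mean(f))^2)

  starts <- exp(seq(log(min(C) / 10), log(max(C) * 10), length.out = 9))
  best <- NULL
  for (k0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        f ~ C^hill / (kd^hill + C^hill),
        start = list(kd = k0),
        lower = c(kd = 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  no_binding <- function(p) {
    res <- list(kd = NA_real_, kd_se = NA_real_, rss = rss_flat, n = n,
                p_vs_flat = p, verdict = "no_binding", hill = hill)
    class(res) <- "kd_fit"
    res
  }
  if (is.null(best)) return(no_binding(NA_real_))
  rss1 <- best$rss
  df2 <- n - 2L
  p_flat <- if (rss1 <= .Machine$double.eps * n) 0 else {
    Fstat <- ((rss_flat - rss1) / 1) / (rss1 / df2)
    pf(Fstat, 1, df2, lower.tail = FALSE)
  }
  if (!is.finite(p_flat) || p_flat >= alpha) return(no_binding(p_flat))
  co <- summary(best$fit)$coefficients
  res <- list(kd = unname(co["kd", "Estimate"]),
              kd_se = unname(co["kd", "Std. Error"]),
              rss = rss1, n = n, p_vs_flat = p_flat,
              verdict = "binding", hill = hill)
  class(res) <- "kd_fit"
  res
}

#' @export
print.kd_fit <- function(x, ...) {
  if (x$verdict == "no_binding") {
    cat("Binding fit: NA (curve does not beat the flat model; p =",
        format(x$p_vs_flat, digits = 3), ")\n")
  } else {
    cat(sprintf("Binding fit: Kd = %.4g +- %.2g (RSS %.3g, n = %d)\n",
                x$kd, x$kd_se, x$rss, x$n))
  }
  invisible(x)
}

#' Log2 fold change of a pulldown signal over its baseline
#'
#' @param signal Measured co-precipitated signal(s).
#' @param baseline Positive baseline (e.g. the no-RNA control).
#' @param floor Optional positive floor substituted for zero signals
#'   (flagged); without it a zero signal is an error.
#' @return A list with `log2fc` and `flagged` (signals floored).
#' @export
pulldown_log2fc <- function(signal, baseline, floor = NULL) {
  if (any(baseline <= 0)) stop("zero or negative baseline", call. = FALSE)
  flagged <- signal <= 0
  if (any(flagged)) {
    if (is.null(floor))
      stop("non-positive signal; supply `floor` to proceed",
           call. = FALSE)
    stopifnot(floor > 0)
    signal[flagged] <- floor
  }
  list(log2fc = log2(signal / baseline), flagged = flagged)
}
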