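# Dose-response, relaxation and dwell-time survival fitting.

#' Hill dose-response fit
#'
#' Least-squares fit of the Hill equation to a dose-response curve. By
#' default the Hill coefficient is fixed to one,
#' `y = A * c / (c + EC50)`, the convention used for ATP dose responses of
#' channel opening and NBD dimerization; set `fix_n = FALSE` to fit the
#' coefficient as well.
#'
#' @param dose Concentrations (molar), at least four spanning the
#'   midpoint.
#' @param response Non-negative responses, same length as `dose`.
#' @param fix_n Fix the Hill coefficient at 1 (default) or fit it.
#' @param weights Optional fitting weights (e.g. inverse squared standard
#'   errors of per-experiment means).
#' @return A `dose_response_fit` list: `ec50_M`, `hill_n`, `amplitude`,
#'   `residuals`, `fitted`, `flag` (`"ok"` or `"no_curvature"` when the
#'   midpoint falls outside the dose range).
#' @examples
#' f <- fit_hill(c(1e-6, 1e-5, 1e-4, 1e-3), 1 * c(1e-6, 1e-5, 1e-4, 1e-3) /
#'               (c(1e-6, 1e-5, 1e-4, 1e-3) + 1e-4))
#' f$ec50_M   # 1e-4
#' @export
fit_hill <- function(dose, response, fix_n = TRUE, weights = NULL) {
  stopifnot(length(dose) == length(response))
  if (length(dose) < 4L) stop("need at least 4 doses")
  if (any(dose <= 0)) stop("doses must be positive (molar)")
  if (any(response < 0)) stop("responses must be non-negative")
  if (is.null(weights)) weights <- rep(1, length(dose))
  A0 <- max(response)
  K0 <- dose[which.min(abs(response - A0 / 2))]
  ctl <- minpack.lm::nls.lm.control(maxiter = 500)
  if (fix_n) {
    fit <- minpack.lm::nlsLM(response ~ A * dose / (dose + K),
                             start = list(A = A0, K = K0),
                             lower = c(0, 1e-12), weights = weights,
                             control = ctl)
    n_hat <- 1
  } else {
    fit <- minpack.lm::nlsLM(response ~ A * dose^n / (dose^n + K^n),
                             start = list(A = A0, K = K0, n = 1),
                             lower = c(0, 1e-12, 0.1), weights = weights,
                             control = ctl)
    n_hat <- unname(coef(fit)[["n"]])
  }
  cf <- coef(fit)
  flag <- if (cf[["K"]] < min(dose) || cf[["K"]] > max(dose))
    "no_curvature" else "ok"
  structure(list(ec50_M = unname(cf[["K"]]), hill_n = n_hat,
                 amplitude = unname(cf[["A"]]),
                 residuals = unname(residuals(fit)),
                 fitted = unname(fitted(fit)), flag = flag),
            class = "dose_response_fit")
}

# Peeling start values for a sum-of-exponentials decay of z >= 0.
# Works on the region carrying meaningful amplitude so long stationary
# tails (or plateaus of a rise) cannot poison the regressions.
.peel_starts <- function(t, z, n_components) {
  zmax <- max(z)
  dt_min <- max(min(diff(t)), 1e-9)
  span <- diff(range(t))
  if (zmax <= 0) {
    tau <- span / 5
    return(if (n_components == 1L) list(a = 1e-6, tau = tau)
           else list(a = c(1e-6, 1e-6), tau = c(tau / 10, tau)))
  }
  live <- which(z > 0.02 * zmax)
  t_live <- t[live]; z_live <- z[live]
  # crude time constant: first crossing below 1/e of the maximum
  i37 <- which(z_live <= exp(-1) * zmax)
  tau_e <- if (length(i37)) max(t_live[i37[1L]] - t_live[1L], dt_min)
           else max(span / 3, dt_min)
  # slow component from a log-linear fit over the later live region
  late <- t_live >= stats::quantile(t_live, 0.5)
  t_slow <- tau_e; a_slow <- zmax
  if (sum(late) >= 3L) {
    cf <- stats::coef(stats::lm(log(z_live[late]) ~ t_live[late]))
    if (is.finite(cf[2L]) && cf[2L] < 0) {
      t_slow <- min(max(-1 / cf[2L], dt_min), span * 5)
      a_slow <- min(exp(cf[1L]), 2 * zmax)
    }
  }
  if (n_components == 1L) return(list(a = a_slow, tau = t_slow))
  res <- z - a_slow * exp(-t / t_slow)
  early <- t <= stats::quantile(t_live, 0.25) & res > 0.02 * zmax
  if (sum(early) >= 4L) {
    cf1 <- stats::coef(stats::lm(log(res[early]) ~ t[early]))
    t_fast <- if (is.finite(cf1[2L]) && cf1[2L] < 0)
      max(min(-1 / cf1[2L], t_slow / 2), dt_min) else t_slow / 10
    a_fast <- max(min(exp(cf1[1L]), 2 * zmax), 1e-6 * zmax)
  } else {
    t_fast <- t_slow / 10
    a_fast <- max(z[1L] - a_slow, 1e-6 * zmax)
  }
  list(a = c(a_fast, a_slow), tau = c(t_fast, t_slow))
}

#' Exponential relaxation fit
#'
#' Fits `y(t) = c0 + sum_i a_i * exp(-t / tau_i)` with one or two
#' components by Levenberg-Marquardt least squares, with start values
#' obtained by exponential peeling. Handles rising and decaying series
#' (amplitudes may be negative). When `n_components` is `NULL` both
#' models are fitted and the one preferred by BIC is returned.
#'
#' @param time,value The relaxation time series (uniform or not).
#' @param n_components 1, 2, or `NULL` for BIC selection.
#' @param offset Fit an asymptotic offset `c0` (default) or pin it to 0
#'   (appropriate when the occupancy relaxes to an absorbing empty state).
#' @return A `relaxation_fit` list: `taus_s` (ascending), `amplitudes`
#'   (matching `taus_s`), `offset`, `n_components`, `bic`, `converged`,
#'   `fitted`.
#' @export
fit_relaxation <- function(time, value, n_components = NULL, offset = TRUE) {
  stopifnot(length(time) == length(value), length(time) >= 8L)
  o <- order(time)
  t <- time[o]; y <- value[o]
  fit_n <- function(nc) {
    y_inf <- if (offset) mean(y[t >= max(t) * 0.9]) else 0
    r <- y - y_inf
    s <- if (abs(r[1L]) >= abs(r[length(r)])) sign(r[1L]) else -sign(r[length(r)])
    if (s == 0) s <- 1
    st <- .peel_starts(t, pmax(s * r, 0), nc)
    ctl <- minpack.lm::nls.lm.control(maxiter = 800)
    fit <- tryCatch({
      if (nc == 1L) {
        if (offset)
          minpack.lm::nlsLM(y ~ c0 + a1 * exp(-t / t1),
            start = list(c0 = y_inf, a1 = s * st$a[1L], t1 = st$tau[1L]),
            lower = c(-Inf, -Inf, 1e-9), control = ctl)
        else
          minpack.lm::nlsLM(y ~ a1 * exp(-t / t1),
            start = list(a1 = s * st$a[1L], t1 = st$tau[1L]),
            lower = c(-Inf, 1e-9), control = ctl)
      } else {
        if (offset)
          minpack.lm::nlsLM(y ~ c0 + a1 * exp(-t / t1) + a2 * exp(-t / t2),
            start = list(c0 = y_inf, a1 = s * st$a[1L], t1 = st$tau[1L],
                         a2 = s * st$a[2L], t2 = st$tau[2L]),
            lower = c(-Inf, -Inf, 1e-9, -Inf, 1e-9), control = ctl)
        else
          minpack.lm::nlsLM(y ~ a1 * exp(-t / t1) + a2 * exp(-t / t2),
            start = list(a1 = s * st$a[1L], t1 = st$tau[1L],
                         a2 = s * st$a[2L], t2 = st$tau[2L]),
            lower = c(-Inf, 1e-9, -Inf, 1e-9), control = ctl)
      }
    }, error = function(e) NULL)
    fit
  }
  pack <- function(fit, nc) {
    if (is.null(fit)) return(NULL)
    cf <- coef(fit)
    taus <- unname(cf[grep("^t[0-9]$", names(cf))])
    amps <- unname(cf[grep("^a[0-9]$", names(cf))])
    oo <- order(taus)
    rss <- sum(residuals(fit)^2)
    n <- length(t)
    k <- length(cf)
    list(taus_s = taus[oo], amplitudes = amps[oo],
         offset = if (offset) unname(cf[["c0"]]) else 0,
         n_components = nc,
         bic = n * log(max(rss / n, 1e-300)) + k * log(n),
         converged = TRUE, fitted = unname(fitted(fit)))
  }
  ncs <- if (is.null(n_components)) c(1L, 2L) else as.integer(n_components)
  fits <- Filter(Negate(is.null), lapply(ncs, function(nc) pack(fit_n(nc), nc)))
  # an (essentially) exact simpler model wins outright: BIC on noiseless
  # data degenerates to comparing rounding error
  if (length(fits) > 1L) {
    rms <- vapply(fits, function(f)
      sqrt(mean((y - f$fitted)^2)), numeric(1))
    exact <- rms < 1e-7 * max(stats::sd(y), 1e-12)
    if (any(exact)) fits <- fits[seq_len(which(exact)[1L])]
  }
  if (!length(fits)) {
    warning("relaxation fit did not converge; returning peeling estimate")
    y_inf <- if (offset) mean(y[t >= max(t) * 0.9]) else 0
    st <- .peel_starts(t, pmax(abs(y - y_inf), 0), max(ncs))
    return(structure(list(taus_s = sort(st$tau), amplitudes = st$a,
                          offset = y_inf, n_components = max(ncs),
                          bic = NA_real_, converged = FALSE,
                          fitted = rep(NA_real_, length(t))),
                     class = "relaxation_fit"))
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
  structure(best, class = "relaxation_fit")
}

#' Exponential-mixture dwell-time fit with right censoring
#'
#' Maximum-likelihood fit of a one- or two-component exponential mixture
#' to dwell times. Right-censored sojourns (first/last dwell of a trace)
#' contribute survival terms instead of density terms, which avoids the
#' upward rate bias of discarding them. BIC is reported for model
#' comparison between one and two components.
#'
#' @param dwells A `dwell_table` (see [extract_dwells()]), or a data
#'   frame with columns `dwell_s` and optionally `censored`; a bare
#'   numeric vector is treated as fully uncensored.
#' @param n_components 1 or 2.
#' @param frame_s Optional frame duration of the source data; when the
#'   fitted mean dwell of any component is shorter than three frames a
#'   warning flags the time-averaging regime in which rate estimates from
#'   camera-sampled traces become unreliable.
#' @return A `survival_fit` list: `rates_per_s`, `weights`, `taus_s`
#'   (components ordered by ascending time constant), `loglik`, `bic`,
#'   `n`, `n_censored`.
#' @export
fit_survival <- function(dwells, n_components = 1L, frame_s = NULL) {
  if (is.numeric(dwells)) dwells <- data.frame(dwell_s = dwells)
  stopifnot(is.data.frame(dwells), "dwell_s" %in% names(dwells))
  td <- dwells$dwell_s
  cen <- if ("censored" %in% names(dwells)) as.logical(dwells$censored)
         else rep(FALSE, length(td))
  if (any(td <= 0)) stop("dwells must be positive")
  n_unc <- sum(!cen)
  if (n_unc < 2L) stop("need at least two uncensored dwells")
  if (stats::sd(td[!cen]) == 0) stop("degenerate dwell sample (all identical)")
  n_components <- as.integer(n_components)
  if (n_unc < 50L * n_components)
    warning(sprintf("only %d uncensored dwells for %d component(s); estimates may be unstable",
                    n_unc, n_components))
  if (n_components == 1L) {
    # censored-MLE closed form: events / total observation time
    lam <- n_unc / sum(td)
    ll <- n_unc * log(lam) - lam * sum(td)
    fit <- list(rates_per_s = lam, weights = 1)
  } else if (n_components == 2L) {
    q <- stats::quantile(td[!cen], c(0.3, 0.85))
    par0 <- c(0, log(1 / max(q[1L], 1e-6)), log(1 / max(q[2L], 1e-6)))
    nll <- function(p) {
      w <- stats::plogis(p[1L]); l1 <- exp(p[2L]); l2 <- exp(p[3L])
      d <- w * l1 * exp(-l1 * td) + (1 - w) * l2 * exp(-l2 * td)
      s <- w * exp(-l1 * td) + (1 - w) * exp(-l2 * td)
      -sum(log(pmax(ifelse(cen, s, d), 1e-300)))
    }
    op <- stats::optim(par0, nll, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-10))
    w <- stats::plogis(op$par[1L])
    lam <- exp(op$par[2:3])
    oo <- order(lam, decreasing = TRUE)   # report taus ascending
    fit <- list(rates_per_s = lam[oo], weights = c(w, 1 - w)[oo])
    ll <- -op$value
  } else stop("n_components must be 1 or 2")
  k <- 2L * n_components - 1L
  out <- c(fit, list(taus_s = 1 / fit$rates_per_s, loglik = ll,
                     bic = -2 * ll + k * log(length(td)),
                     n = length(td), n_censored = sum(cen)))
  if (!is.null(frame_s) && any(out$taus_s < 3 * frame_s))
    warning("fitted mean dwell below 3 frames: apparent rates are obscured by time averaging")
  structure(out, class = "survival_fit")
}
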