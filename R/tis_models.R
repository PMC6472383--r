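#' Tanks-in-series model specification
#'
#' Three hydraulic families are supported:
#' * `ESC` — equal-sized CSTRs in series; Erlang RTD with integer tank count N.
#' * `EESC` — extended equal-sized model; gamma RTD with real N > 0.
#' * `ISC` — increasing-size CSTRs; hypoexponential RTD parameterized by volume
#'   fractions `r_1 < r_2 < ... < r_N`, summing to 1.
#'
#' @param kind one of `"ESC"`, `"EESC"`, `"ISC"`.
#' @param n_tanks tank count (integer for ESC/ISC, positive real for EESC).
#' @param fractions ISC only: volume fractions, strictly increasing, sum 1.
#' @return object of class `tis_spec`.
#' @export
tis_spec <- function(kind = c("ESC", "EESC", "ISC"), n_tanks = NULL,
                     fractions = NULL) {
  kind <- match.arg(kind)
  if (kind == "ISC") {
    if (is.null(fractions)) stop("ISC spec requires volume fractions")
    fractions <- as.numeric(fractions)
    if (abs(sum(fractions) - 1) > 1e-9)
      stop("ISC volume fractions must sum to 1")
    if (any(fractions <= 0)) stop("fractions must be positive")
    if (any(diff(fractions) <= 0))
      stop("ISC requires strictly increasing tank sizes (r_k/r_(k-1) > 1)")
    n_tanks <- length(fractions)
  } else {
    if (is.null(n_tanks)) stop("n_tanks required for ESC/EESC")
    if (n_tanks < 1 && kind == "ESC") stop("ESC needs integer n_tanks >= 1")
    if (kind == "ESC" && abs(n_tanks - round(n_tanks)) > 1e-9)
      stop("ESC tank count must be an integer; use EESC for real N")
    if (n_tanks <= 0) stop("n_tanks must be positive")
  }
  structure(list(kind = kind, n_tanks = as.numeric(n_tanks),
                 fractions = fractions),
            class = "tis_spec")
}

#' @export
print.tis_spec <- function(x, ...) {
  if (x$kind == "ISC")
    cat(sprintf("<tis_spec ISC> N=%d fractions=(%s)\n", length(x$fractions),
                paste(signif(x$fractions, 4), collapse = ", ")))
  else
    cat(sprintf("<tis_spec %s> N=%g\n", x$kind, x$n_tanks))
  invisible(x)
}

#' Erlang RTD density of N equal tanks in series
#'
#' `E(theta) = N^N / (N-1)! * theta^(N-1) * exp(-N theta)`.
#'
#' @param theta dimensionless time, >= 0 (vectorized).
#' @param n integer tank count >= 1.
#' @export
esc_density <- function(theta, n) {
  if (abs(n - round(n)) > 1e-9)
    stop("esc_density requires integer n; use eesc_density for real N")
  eesc_density(theta, round(n))
}

#' Gamma RTD density of N (real) equal tanks in series
#'
#' `E(theta) = N^N / Gamma(N) * theta^(N-1) * exp(-N theta)`; reduces to
#' [esc_density()] at integer N. This is the gamma density with shape N and
#' rate N, so the mean is 1 and the variance 1/N.
#'
#' @inheritParams esc_density
#' @param n real tank count > 0.
#' @export
eesc_density <- function(theta, n) {
  if (n <= 0) stop("tank count must be > 0")
  if (any(theta < 0)) stop("theta must be >= 0")
  stats::dgamma(theta, shape = n, rate = n)
}

#' Hypoexponential RTD density of increasing-size tanks in series
#'
#' Density of the total residence time of a chain of N tanks whose stage mean
#' residence times are the volume fractions `r_i` (in units of the whole-train
#' mean): `E(theta) = sum_i r_i^(N-2) / prod_{j != i} (r_i - r_j) * exp(-theta/r_i)`.
#' When any pair of fractions is closer than `degenerate_tol` (relative), the
#' partial-fraction coefficients blow up and the density is evaluated instead
#' through the phase-type matrix exponential of the stage chain, which is
#' stable across the equal-size degeneracy.
#'
#' @param theta dimensionless time, >= 0 (vectorized).
#' @param fractions volume fractions; positive, sum to 1 (increasing for a
#'   valid ISC spec, but any distinct positive vector defines the density).
#' @param degenerate_tol relative gap below which the stable fallback is used.
#' @export
isc_density <- function(theta, fractions, degenerate_tol = 1e-6) {
  r <- as.numeric(fractions)
  if (any(r <= 0)) stop("fractions must be positive")
  if (any(theta < 0)) stop("theta must be >= 0")
  n <- length(r)
  if (n == 1L) return(exp(-theta / r) / r)
  gaps <- abs(outer(r, r, "-")) / max(r)
  diag(gaps) <- Inf
  if (min(gaps) < degenerate_tol)
    return(phase_type_chain_density(theta, r))
  vals <- numeric(length(theta))
  for (i in seq_len(n)) {
    coef <- r[i]^(n - 2) / prod(r[i] - r[-i])
    vals <- vals + coef * exp(-theta / r[i])
  }
  pmax(vals, 0)
}

# Stable evaluation of the chain density through the matrix exponential of the
# phase generator (sub-intensity matrix of the sequential stages). Handles
# repeated stage sizes, where the partial-fraction form is singular.
phase_type_chain_density <- function(theta, r) {
  n <- length(r)
  Tm <- diag(-1 / r)
  if (n > 1) for (i in seq_len(n - 1)) Tm[i, i + 1] <- 1 / r[i]
  vapply(theta, function(th) {
    E <- as.matrix(Matrix::expm(Matrix::Matrix(Tm * th)))
    max(E[1, n] / r[n], 0)
  }, numeric(1))
}

#' Analytic moments of a tanks-in-series RTD
#'
#' ESC/EESC: mean 1, variance `1/N`. ISC: mean `sum(r_i) = 1`, variance
#' `sum(r_i^2)` (independent exponential stages).
#'
#' @param spec a [tis_spec()].
#' @return list with `mean` and `variance`.
#' @export
tis_moments <- function(spec) {
  stopifnot(inherits(spec, "tis_spec"))
  if (spec$kind == "ISC")
    list(mean = sum(spec$fractions), variance = sum(spec$fractions^2))
  else
    list(mean = 1, variance = 1 / spec$n_tanks)
}

#' Evaluate any tanks-in-series density
#'
#' @param spec a [tis_spec()].
#' @param theta dimensionless time grid.
#' @export
tis_density <- function(spec, theta) {
  stopifnot(inherits(spec, "tis_spec"))
  switch(spec$kind,
         ESC = esc_density(theta, spec$n_tanks),
         EESC = eesc_density(theta, spec$n_tanks),
         ISC = isc_density(theta, spec$fractions))
}

# round half away from zero (2.5 -> 3), the convention used for N_ESC
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# chi-square between observed curve and model density on the curve grid
tis_chi2 <- function(curve, spec, sigma_obs) {
  pred <- tis_density(spec, curve$times)
  sum(((curve$density - pred) / sigma_obs)^2)
}

# ISC fractions from unconstrained parameters: successive size ratios are
# 1 + exp(u_k) > 1, guaranteeing the strict-increase constraint.
isc_fractions_from_u <- function(u) {
  ratios <- 1 + exp(u)
  rel <- cumprod(c(1, ratios))
  rel / sum(rel)
}

isc_u_from_fractions <- function(r) {
  ratios <- r[-1] / r[-length(r)]
  log(pmax(ratios - 1, 1e-12))
}

#' Fit a tanks-in-series model to an exit-age curve
#'
#' Minimizes the weighted sum of squared deviations
#' `chi^2 = sum(((E_obs - E_model) / sigma)^2)` over the free parameters of the
#' template: nothing for ESC (integer N fixed), the real tank count for EESC,
#' and the volume fractions (tank count fixed) for ISC. The ISC fit uses a
#' fixed deterministic multi-start grid over feasible size-ratio vectors,
#' each refined by Nelder-Mead on log-ratio coordinates that enforce the
#' strict-ordering constraint by construction.
#'
#' @param curve normalized theta-domain [exit_age_curve()].
#' @param template a [tis_spec()] fixing the model family and tank count.
#' @param sigma_obs per-point observation standard deviation (scalar or
#'   vector); default 1 gives plain least squares.
#' @return list with elements `spec` (fitted [tis_spec()]), `chi2`, and
#'   `converged`.
#' @export
fit_tis <- function(curve, template, sigma_obs = 1) {
  stopifnot(inherits(curve, "exit_age_curve"), inherits(template, "tis_spec"))
  if (curve$domain != "theta") stop("fit_tis expects a theta-domain curve")
  if (any(sigma_obs <= 0)) stop("sigma_obs must be positive")

  if (template$kind == "ESC") {
    return(list(spec = template, chi2 = tis_chi2(curve, template, sigma_obs),
                converged = TRUE))
  }

  if (template$kind == "EESC") {
    # the gamma density diverges at theta = 0 for N < 1; guard the objective
    obj <- function(log_n) {
      v <- tis_chi2(curve, tis_spec("EESC", exp(log_n)), sigma_obs)
      if (!is.finite(v)) 1e30 else v
    }
    opt <- optimize(obj, interval = log(c(0.2, 100)), tol = 1e-12)
    spec <- tis_spec("EESC", exp(opt$minimum))
    return(list(spec = spec, chi2 = opt$objective, converged = TRUE))
  }

  # ISC: fixed tank count, fractions free on the ordered simplex
  n <- if (!is.null(template$fractions)) length(template$fractions)
       else round(template$n_tanks)
  if (n < 2) stop("ISC fit needs at least 2 tanks")
  obj <- function(u) tis_chi2(curve,
                              structure(list(kind = "ISC", n_tanks = n,
                                             fractions = isc_fractions_from_u(u)),
                                        class = "tis_spec"),
                              sigma_obs)
  starts <- list()
  if (!is.null(template$fractions))
    starts[[1]] <- isc_u_from_fractions(template$fractions)
  grid_vals <- log(c(0.5, 2, 6))           # size ratios 1.5, 3, 7
  grid <- as.matrix(expand.grid(rep(list(grid_vals), n - 1)))
  for (i in seq_len(nrow(grid))) starts[[length(starts) + 1]] <- grid[i, ]

  best <- NULL
  for (u0 in starts) {
    fit <- optim(u0, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  fr <- isc_fractions_from_u(best$par)
  spec <- structure(list(kind = "ISC", n_tanks = n, fractions = fr),
                    class = "tis_spec")
  list(spec = spec, chi2 = best$value, converged = best$convergence == 0)
}

#' Fit several candidate hydraulic models and rank them
#'
#' @param curve normalized theta-domain [exit_age_curve()].
#' @param candidates list of [tis_spec()] templates (at least 2).
#' @param sigma_obs observation standard deviation(s) passed to [fit_tis()].
#' @return data.frame ranked by ascending chi-square with columns
#'   `model, n_tanks, fractions, chi2`, plus the fitted specs as the
#'   `"fits"` attribute.
#' @export
select_model <- function(curve, candidates, sigma_obs = 1) {
  if (length(candidates) < 2) stop("need at least 2 candidate templates")
  fits <- lapply(candidates, function(tmpl) fit_tis(curve, tmpl, sigma_obs))
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$spec$kind,
               n_tanks = f$spec$n_tanks,
               fractions = if (is.null(f$spec$fractions)) ""
                           else paste(signif(f$spec$fractions, 6), collapse = ":"),
               chi2 = f$chi2, stringsAsFactors = FALSE)
  }))
  ord <- order(tab$chi2)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}

#' Write a tanks-in-series fit report as CSV
#'
#' @param report data.frame from [select_model()].
#' @param path output file.
#' @param header_comment optional `#` comment line(s).
#' @export
write_tis_report <- function(report, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.csv(format(report, digits = 17, trim = TRUE), con,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
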