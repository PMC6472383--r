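#' Tracer time series from a pulse-injection experiment
#'
#' Container for one residence-time-distribution (RTD) run: tracer
#' concentration sampled at the reactor outlet after an (ideally
#' instantaneous) pulse injection at `t = 0`.
#'
#' Negative concentration readings (instrument noise) are clipped to zero;
#' the number of clipped points is kept in the `n_clipped` attribute.
#'
#' @param times sample times in hours; strictly increasing, at least 3 points.
#' @param concentrations tracer concentration at each time (mg/L).
#' @param run_id label for the run.
#' @param hrt_nominal nominal hydraulic residence time (h, > 0).
#' @param flow volumetric flow (L/h, > 0).
#' @param with_biomass logical; was granular sludge present during the run?
#' @return an object of class `tracer_series`.
#' @export
tracer_series <- function(times, concentrations, run_id = "run",
                          hrt_nominal = NA_real_, flow = NA_real_,
                          with_biomass = NA) {
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) != length(concentrations))
    stop("times and concentrations must have equal length")
  if (length(times) < 3L)
    stop("insufficient support: need at least 3 samples")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  n_clipped <- sum(concentrations < 0)
  if (n_clipped > 0) {
    message(sprintf("clipped %d negative concentration reading(s) to 0", n_clipped))
    concentrations[concentrations < 0] <- 0
  }
  if (all(concentrations == 0))
    stop("no tracer recovered: all concentrations are zero")
  if (!is.na(hrt_nominal) && hrt_nominal <= 0) stop("hrt_nominal must be > 0")
  if (!is.na(flow) && flow <= 0) stop("flow must be > 0")
  structure(
    list(run_id = as.character(run_id), times = times,
         concentrations = concentrations, hrt_nominal = hrt_nominal,
         flow = flow, with_biomass = with_biomass, n_clipped = n_clipped),
    class = "tracer_series")
}

#' @export
print.tracer_series <- function(x, ...) {
  cat(sprintf("<tracer_series '%s'> %d samples on [%.3g, %.3g] h, peak %.3g mg/L\n",
              x$run_id, length(x$times), min(x$times), max(x$times),
              max(x$concentrations)))
  invisible(x)
}

#' Exit-age distribution curve
#'
#' Holds an RTD density either in the time domain (`E(t)`, 1/h) or in
#' normalized time `theta = t / t_mean` (dimensionless `E(theta)`).
#'
#' @param times abscissa: time (h) for `domain = "time"`, theta otherwise.
#' @param density density values, non-negative.
#' @param domain `"time"` or `"theta"`.
#' @param normalized logical; if `TRUE` the trapezoidal integral over the
#'   support must be 1 within 1e-6.
#' @return object of class `exit_age_curve`.
#' @export
exit_age_curve <- function(times, density, domain = c("time", "theta"),
                           normalized = FALSE) {
  domain <- match.arg(domain)
  if (any(density < 0)) stop("density must be non-negative")
  if (normalized) {
    area <- trapz(times, density)
    if (abs(area - 1) > 1e-6)
      stop(sprintf("curve marked normalized but integrates to %.8f", area))
  }
  structure(list(times = times, density = density, domain = domain,
                 normalized = normalized),
            class = "exit_age_curve")
}

#' @export
print.exit_age_curve <- function(x, ...) {
  cat(sprintf("<exit_age_curve> %s domain, %d points, integral %.6f\n",
              x$domain, length(x$times), trapz(x$times, x$density)))
  invisible(x)
}

#' Exit-age function E(t) from a tracer curve
#'
#' Normalizes the measured pulse-response concentration by its trapezoidal
#' integral over the sampled window: `E(t) = C(t) / integral C dt`. No tail
#' extrapolation is performed; a warning is raised when the final sample still
#' exceeds 5% of the peak (tail-truncation risk).
#'
#' @param series a [tracer_series()].
#' @return normalized [exit_age_curve()] in the time domain (1/h).
#' @export
exit_age_from_tracer <- function(series) {
  stopifnot(inherits(series, "tracer_series"))
  t <- series$times
  c_t <- series$concentrations
  area <- trapz(t, c_t)
  if (area <= 0) stop("no tracer recovered: integral of C over window is zero")
  if (tail(c_t, 1) > 0.05 * max(c_t))
    warning("last sampled concentration exceeds 5% of peak: RTD tail truncated")
  exit_age_curve(t, c_t / area, domain = "time", normalized = TRUE)
}

#' RTD moments by trapezoidal quadrature
#'
#' Mean residence time `t_mean = integral t E(t) dt` and variance
#' `var_t = integral t^2 E(t) dt - t_mean^2` on the sampled grid.
#' Tiny negative variances from round-off are clipped to zero.
#'
#' @param curve normalized time-domain [exit_age_curve()].
#' @return list with `t_mean` (h) and `var_t` (h^2).
#' @export
rtd_moments <- function(curve) {
  stopifnot(inherits(curve, "exit_age_curve"))
  if (curve$domain != "time") stop("rtd_moments expects a time-domain curve")
  if (!curve$normalized) stop("curve must be normalized before taking moments")
  t <- curve$times
  e <- curve$density
  t_mean <- trapz(t, t * e)
  var_t <- trapz(t, t^2 * e) - t_mean^2
  if (var_t < 0) {
    if (var_t < -1e-8 * max(t_mean^2, 1))
      warning(sprintf("variance clipped from %.3g to 0", var_t))
    var_t <- 0
  }
  list(t_mean = t_mean, var_t = var_t)
}

#' Normalize an RTD curve to dimensionless time
#'
#' Rescales to `theta = t / t_mean`, `E(theta) = t_mean * E(t)` and returns the
#' dimensionless variance `theta_var = var_t / t_mean^2`. The theta grid is
#' inherited from the time grid (no resampling).
#'
#' @param curve normalized time-domain [exit_age_curve()].
#' @param moments optional precomputed [rtd_moments()] result.
#' @return list with `curve` (theta-domain [exit_age_curve()]) and `theta_var`.
#' @export
normalize_rtd <- function(curve, moments = NULL) {
  stopifnot(inherits(curve, "exit_age_curve"))
  if (is.null(moments)) moments <- rtd_moments(curve)
  if (moments$t_mean <= 0) stop("t_mean must be positive")
  theta <- curve$times / moments$t_mean
  e_theta <- moments$t_mean * curve$density
  list(curve = exit_age_curve(theta, e_theta, domain = "theta",
                              normalized = curve$normalized),
       theta_var = moments$var_t / moments$t_mean^2)
}

#' Dimensionless RTD variance of the axial-dispersion model
#'
#' For a closed-vessel axial-dispersion reactor with Peclet number `Pe`,
#' `theta_var = 2/Pe - (2/Pe^2) (1 - exp(-Pe))`. Strictly decreasing in `Pe`;
#' tends to 1 (single CSTR) as `Pe -> 0` and to 0 (plug flow) as `Pe -> Inf`.
#'
#' @param pe Peclet number(s), > 0.
#' @return dimensionless variance in (0, 1).
#' @export
variance_from_peclet <- function(pe) {
  if (any(pe <= 0)) stop("Peclet number must be > 0")
  # expm1 avoids catastrophic cancellation in (1 - exp(-pe)) at small Pe
  2 / pe + (2 / pe^2) * expm1(-pe)
}

#' Peclet number from the dimensionless RTD variance
#'
#' Numerically inverts [variance_from_peclet()] by bisection on
#' `[1e-8, 1e8]` to a residual below 1e-10.
#'
#' @param theta_var dimensionless variance, strictly in (0, 1).
#' @return Peclet number.
#' @export
peclet_from_variance <- function(theta_var) {
  if (length(theta_var) > 1)
    return(vapply(theta_var, peclet_from_variance, numeric(1)))
  if (theta_var <= 0 || theta_var >= 1)
    stop("outside axial-dispersion domain: need 0 < theta_var < 1")
  lo <- 1e-8; hi <- 1e8
  # variance is decreasing in Pe: f(lo) > theta_var > f(hi)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    v <- variance_from_peclet(mid)
    if (abs(v - theta_var) < 1e-10) break
    if (v > theta_var) lo <- mid else hi <- mid
  }
  mid
}

#' Equivalent number of tanks in series
#'
#' `N = 1 / theta_var`, left unrounded (the equal-sized-tank model rounds it
#' separately to the nearest integer).
#'
#' @param theta_var dimensionless RTD variance, > 0.
#' @return equivalent tank count (real).
#' @export
tanks_equivalent <- function(theta_var) {
  if (any(theta_var < 0)) stop("theta_var must be non-negative")
  if (any(theta_var == 0)) warning("plug-flow limit: zero variance gives infinite N")
  1 / theta_var
}

#' Full RTD analysis of a tracer run
#'
#' Chains [exit_age_from_tracer()], [rtd_moments()], [normalize_rtd()],
#' [peclet_from_variance()] and [tanks_equivalent()] into the one-row summary
#' used for run tables.
#'
#' @param series a [tracer_series()].
#' @return a data.frame with columns `run_id, t_mean_h, var_t_h2, theta_var,
#'   peclet, dispersion_number, n_tanks`.
#' @export
rtd_summary <- function(series) {
  curve <- exit_age_from_tracer(series)
  mom <- rtd_moments(curve)
  nr <- normalize_rtd(curve, mom)
  pe <- peclet_from_variance(nr$theta_var)
  data.frame(run_id = series$run_id,
             t_mean_h = mom$t_mean,
             var_t_h2 = mom$var_t,
             theta_var = nr$theta_var,
             peclet = pe,
             dispersion_number = 1 / pe,
             n_tanks = tanks_equivalent(nr$theta_var),
             stringsAsFactors = FALSE)
}

#' Read a tracer CSV
#'
#' Expects columns `time_h, conc_mg_L`; leading comment lines starting with
#' `#` may carry run metadata as `# key=value` pairs (`hrt_h`, `flow_L_h`,
#' `biomass`).
#'
#' @param path file path.
#' @param run_id optional label; defaults to the file name.
#' @return a [tracer_series()].
#' @export
read_tracer_csv <- function(path, run_id = NULL) {
  if (!file.exists(path)) stop("tracer CSV not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("#\\s*([A-Za-z_0-9]+)\\s*=\\s*(\\S+)", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  df <- read.csv(text = paste(lines[!grepl("^\\s*#", lines)], collapse = "\n"))
  if (!all(c("time_h", "conc_mg_L") %in% names(df)))
    stop(sprintf("tracer CSV %s must have columns time_h, conc_mg_L", path))
  tracer_series(df$time_h, df$conc_mg_L,
                run_id = run_id %||% sub("\\.csv$", "", basename(path)),
                hrt_nominal = as.numeric(meta$hrt_h %||% NA),
                flow = as.numeric(meta$flow_L_h %||% NA),
                with_biomass = if (is.null(meta$biomass)) NA
                               else tolower(meta$biomass) %in% c("yes", "true", "1"))
}

#' Write one or more RTD summaries to CSV
#'
#' @param summaries data.frame from [rtd_summary()] (rows may be rbind-ed).
#' @param path output file.
#' @param header_comment optional `#` comment line(s) written first.
#' @export
write_rtd_summary <- function(summaries, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  write.csv(format(summaries, digits = 17, trim = TRUE), con, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
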