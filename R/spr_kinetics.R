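# 1:1 Langmuir SPR kinetics: sensorgram simulation (closed form),
# binding/stability level extraction, dilution series, global kinetic
# fitting, rate-constant plausibility and cut-off based positivity calls.

#' Injection schedule for an SPR cycle
#' @param t_assoc_end end of analyte injection, s (default 60).
#' @param t_dissoc_end end of the dissociation read, s (default 120).
#' @param sampling_dt sampling interval, s (default 0.5).
#' @return object of class \code{injection_schedule}.
#' @export
injection_schedule <- function(t_assoc_end = 60, t_dissoc_end = 120,
                               sampling_dt = 0.5) {
  if (!(t_assoc_end > 0 && t_dissoc_end > t_assoc_end))
    stop("need 0 < t_assoc_end < t_dissoc_end")
  if (sampling_dt <= 0) stop("sampling_dt must be positive")
  structure(list(t_assoc_end = t_assoc_end, t_dissoc_end = t_dissoc_end,
                 sampling_dt = sampling_dt),
            class = "injection_schedule")
}

# Closed-form 1:1 Langmuir response. Association:
#   R(t) = Req (1 - exp(-(ka C + kd) t)),  Req = ka C rmax / (ka C + kd);
# dissociation: exponential decay of the response at injection end with
# rate kd.
langmuir_response <- function(t, ka, kd, rmax, conc, t_assoc_end) {
  kobs <- ka * conc + kd
  req <- ka * conc * rmax / kobs
  r_end <- req * (1 - exp(-kobs * t_assoc_end))
  ifelse(t <= t_assoc_end,
         req * (1 - exp(-kobs * t)),
         r_end * exp(-kd * (t - t_assoc_end)))
}

#' Simulate a 1:1 Langmuir sensorgram
#'
#' @param ka association rate constant, 1/(M s) (> 0).
#' @param kd dissociation rate constant, 1/s (>= 0).
#' @param rmax surface capacity, RU (> 0).
#' @param concentration analyte concentration, M (> 0).
#' @param schedule an \code{\link{injection_schedule}}.
#' @param noise_sd Gaussian noise standard deviation, RU (0 for noiseless).
#' @param seed RNG seed used when noise is added; recorded in the output.
#' @param label free-text trace label.
#' @return object of class \code{sensorgram}: \code{times}, \code{response},
#'   \code{concentration}, \code{schedule}, \code{noise_sd}, \code{seed},
#'   \code{label}.
#' @export
simulate_sensorgram <- function(ka, kd, rmax, concentration,
                                schedule = injection_schedule(),
                                noise_sd = 0, seed = NULL, label = "") {
  if (ka <= 0 || kd < 0 || rmax <= 0) stop("need ka > 0, kd >= 0, rmax > 0")
  if (concentration <= 0) stop("analyte concentration must be positive")
  times <- seq(0, schedule$t_dissoc_end, by = schedule$sampling_dt)
  resp <- langmuir_response(times, ka, kd, rmax, concentration,
                            schedule$t_assoc_end)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    resp <- resp + stats::rnorm(length(resp), 0, noise_sd)
  }
  structure(list(times = times, response = resp,
                 concentration = concentration, schedule = schedule,
                 noise_sd = noise_sd, seed = seed, label = label),
            class = "sensorgram")
}

#' Binding and stability levels of a sensorgram
#'
#' The binding level is the mean response just before the end of the sample
#' injection and the stability level the mean just after it; a large drop
#' between the two marks an unstable binder. Each level is a \code{window}
#' second mean separated from the injection end by a \code{guard} second gap.
#'
#' @param sg a \code{sensorgram}.
#' @param window averaging window, s (default 4).
#' @param guard guard gap around the injection end, s (default 1).
#' @return list (class \code{level_report}) with \code{binding_level},
#'   \code{stability_level}, \code{window}.
#' @export
extract_levels <- function(sg, window = 4, guard = 1) {
  stopifnot(inherits(sg, "sensorgram"))
  t_end <- sg$schedule$t_assoc_end
  if (window + guard > t_end ||
      window + guard > sg$schedule$t_dissoc_end - t_end)
    stop("window (plus guard) exceeds a phase duration")
  pre <- sg$times >= t_end - guard - window & sg$times <= t_end - guard
  post <- sg$times >= t_end + guard & sg$times <= t_end + guard + window
  if (!any(pre) || !any(post)) stop("no samples inside the level windows")
  structure(list(binding_level = mean(sg$response[pre]),
                 stability_level = mean(sg$response[post]),
                 window = window),
            class = "level_report")
}

#' Two-fold (or any geometric) dilution series
#'
#' @param start starting concentration (any unit).
#' @param factor dilution factor (> 1).
#' @param n number of concentrations.
#' @param decimals digits kept; rounding is half-up so 0.625 prints as 0.63.
#'   \code{NULL} keeps the exact geometric series.
#' @return numeric vector, highest first.
#' @examples
#' serial_dilution(2.5, 2, 5, 2)  # 2.50 1.25 0.63 0.31 0.16
#' @export
serial_dilution <- function(start, factor, n, decimals = NULL) {
  if (factor <= 1) stop("dilution factor must exceed 1")
  if (n < 1) stop("n must be >= 1")
  x <- start / factor^(seq_len(n) - 1L)
  if (!is.null(decimals)) x <- round_half_up(x, decimals)
  x
}

# Starting-value heuristic: kd from a log-linear regression on the
# dissociation tail of the strongest curve; ka from the initial association
# slope dR/dt ~ ka C rmax; rmax from the largest plateau.
kinetic_start_values <- function(sensorgrams) {
  top <- sensorgrams[[which.max(vapply(sensorgrams, function(s) s$concentration, 0))]]
  t_end <- top$schedule$t_assoc_end
  tail_idx <- top$times > t_end & top$response > 0
  kd0 <- 1e-3
  if (sum(tail_idx) >= 3L) {
    fitln <- stats::lm(log(top$response[tail_idx]) ~ top$times[tail_idx])
    kd0 <- max(1e-7, -unname(stats::coef(fitln)[2]))
  }
  rmax0 <- 1.5 * max(vapply(sensorgrams, function(s) max(s$response), 0))
  early <- top$times <= min(5, t_end / 4) & top$times > 0
  slope <- if (sum(early) >= 2L)
    unname(stats::coef(stats::lm(top$response[early] ~ top$times[early]))[2])
  else max(top$response) / t_end
  ka0 <- max(1e2, slope / (top$concentration * rmax0))
  c(ka = ka0, kd = kd0, rmax = rmax0)
}

#' Global 1:1 kinetic fit across a concentration series
#'
#' Levenberg-Marquardt least squares of (ka, kd, Rmax) shared across all
#' curves, on log-scale parameters to keep them positive, using the
#' closed-form 1:1 model. KD is derived exactly as kd/ka, never fit
#' independently. Starting values come from a deterministic heuristic
#' (dissociation-tail log regression and initial-slope estimate).
#'
#' @param sensorgrams list of \code{sensorgram} over >= 2 concentrations with
#'   a consistent schedule.
#' @return object of class \code{kinetic_fit}: \code{ka}, \code{kd},
#'   \code{rmax}, \code{kD}, \code{residual_sse}, \code{req} (per curve),
#'   \code{start}, \code{convergence}.
#' @export
fit_kinetics <- function(sensorgrams) {
  concs <- vapply(sensorgrams, function(s) s$concentration, 0)
  if (length(unique(concs)) < 2L)
    stop("global fitting needs at least two analyte concentrations")
  t_end <- unique(vapply(sensorgrams, function(s) s$schedule$t_assoc_end, 0))
  if (length(t_end) != 1L) stop("inconsistent injection schedules")
  start <- kinetic_start_values(sensorgrams)
  resid_fn <- function(par) {
    ka <- exp(par[1]); kd <- exp(par[2]); rmax <- exp(par[3])
    unlist(lapply(sensorgrams, function(s)
      s$response - langmuir_response(s$times, ka, kd, rmax,
                                     s$concentration, t_end)))
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15, ptol = 1e-15)
  # Deterministic multi-start: the heuristic start plus a decade grid of ka
  # starting points (fast binders saturate between samples, so the initial
  # slope can be blind to ka; the plateau levels across the dilution series
  # still identify it, from the right basin).
  starts <- c(list(log(start)),
              lapply(10^(3:7), function(ka0)
                log(c(ka = ka0, kd = start["kd"], rmax = start["rmax"]))))
  best <- NULL
  for (s0 in starts) {
    f <- tryCatch(minpack.lm::nls.lm(par = s0, fn = resid_fn, control = ctrl),
                  error = function(e) NULL)
    if (is.null(f) || f$info == 0) next
    if (is.null(best) || sum(f$fvec^2) < sum(best$fvec^2)) best <- f
  }
  if (is.null(best)) stop("kinetic fit did not converge from any start")
  fit <- minpack.lm::nls.lm(par = best$par, fn = resid_fn, control = ctrl)
  if (sum(best$fvec^2) < sum(fit$fvec^2)) fit <- best   # keep the better polish
  if (fit$info == 0 || fit$info == 5)
    stop("kinetic fit did not converge: ", fit$message)
  ka <- exp(fit$par[1]); kd <- exp(fit$par[2]); rmax <- exp(fit$par[3])
  structure(list(ka = ka, kd = kd, rmax = rmax, kD = kd / ka,
                 residual_sse = sum(fit$fvec^2),
                 req = ka * concs * rmax / (ka * concs + kd),
                 concentrations = concs,
                 start = start, convergence = fit$info,
                 message = fit$message),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("1:1 kinetic fit: ka = %.4g /(M s), kd = %.4g /s, KD = %.4g M, Rmax = %.4g RU (SSE %.4g)\n",
              x$ka, x$kd, x$kD, x$rmax, x$residual_sse))
  invisible(x)
}

#' Plausibility flags for fitted rate constants
#'
#' Biological 1:1 interactions typically show ka within [1e3, 1e7] 1/(M s)
#' and kd within [1e-6, 1e-1] 1/s; values outside are flagged atypical.
#'
#' @param fit a \code{kinetic_fit}.
#' @param ka_range,kd_range typical ranges.
#' @return list with logical \code{ka_atypical}, \code{kd_atypical},
#'   \code{any_flag}.
#' @export
plausibility_check <- function(fit, ka_range = c(1e3, 1e7),
                               kd_range = c(1e-6, 1e-1)) {
  stopifnot(inherits(fit, "kinetic_fit"))
  ka_bad <- fit$ka < ka_range[1] || fit$ka > ka_range[2]
  kd_bad <- fit$kd < kd_range[1] || fit$kd > kd_range[2]
  list(ka_atypical = ka_bad, kd_atypical = kd_bad,
       any_flag = ka_bad || kd_bad)
}

#' Cut-off based positivity calls on binding levels
#'
#' A sample is called positive when its binding level strictly exceeds that
#' of the designated cut-off sample (e.g. normal human plasma).
#'
#' @param levels named list of \code{level_report}, one per sample.
#' @param cutoff_sample_key name of the cut-off sample within \code{levels}.
#' @return data.frame with \code{sample}, \code{binding_level},
#'   \code{positive}; the cut-off sample itself is excluded from the calls.
#' @export
positivity_call <- function(levels, cutoff_sample_key) {
  if (!cutoff_sample_key %in% names(levels))
    stop("cut-off sample \"", cutoff_sample_key, "\" not present")
  cutoff <- levels[[cutoff_sample_key]]$binding_level
  keep <- setdiff(names(levels), cutoff_sample_key)
  data.frame(sample = keep,
             binding_level = vapply(levels[keep], function(l) l$binding_level, 0),
             positive = vapply(levels[keep], function(l)
               l$binding_level > cutoff, NA),
             row.names = NULL)
}

#' Convert a mass concentration to molar
#' @param mg_per_ml mass concentration in mg/mL.
#' @param mw_da molecular weight in Da (default 150000, a whole IgG).
#' @return molar concentration.
#' @export
mass_to_molar <- function(mg_per_ml, mw_da = 150000) {
  if (mw_da <= 0) stop("molecular weight must be positive")
  mg_per_ml / mw_da
}

#' Write / read sensorgrams as CSV
#'
#' Long format: \code{time_s}, \code{response_ru}, \code{concentration},
#' \code{phase}, \code{label}.
#' @param sensorgrams list of \code{sensorgram}.
#' @param path file path.
#' @export
write_sensorgram_csv <- function(sensorgrams, path) {
  if (inherits(sensorgrams, "sensorgram")) sensorgrams <- list(sensorgrams)
  rows <- do.call(rbind, lapply(sensorgrams, function(s)
    data.frame(time_s = s$times, response_ru = s$response,
               concentration = s$concentration,
               phase = ifelse(s$times <= s$schedule$t_assoc_end,
                              "association", "dissociation"),
               label = if (nzchar(s$label)) s$label else
                 sprintf("C_%g", s$concentration))))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensorgram_csv
#' @param schedule the \code{\link{injection_schedule}} the traces follow
#'   (phase boundaries are not re-derived from the CSV).
#' @export
read_sensorgram_csv <- function(path, schedule = injection_schedule()) {
  d <- utils::read.csv(path)
  lapply(split(d, d$label), function(g) {
    g <- g[order(g$time_s), ]
    structure(list(times = g$time_s, response = g$response_ru,
                   concentration = g$concentration[1], schedule = schedule,
                   noise_sd = NA_real_, seed = NULL, label = g$label[1]),
              class = "sensorgram")
  })
}
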