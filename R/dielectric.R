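#' Equivalent complex permittivity of a single-shell cell
#'
#' Combines membrane and cytoplasm into the equivalent homogeneous
#' inclusion permittivity of the single-shell model,
#'
#'   eps_p* = eps_m* (2(1-v) eps_m* + (1+2v) eps_c*) /
#'            ((2+v) eps_m* + (1-v) eps_c*),
#'
#' with shell factor v = (1 - dm/R)^n. The same algebraic form is used
#' for both n = 2 and n = 3 models (only v changes with n).
#'
#' @param cell A [cell_model()].
#' @param f Frequency in Hz (> 0); vectorised.
#' @return Complex equivalent relative permittivity eps_p*.
#' @examples
#' cm <- cell_model(radius = 5e-6, membrane_thickness = 5e-9, dimension = 2,
#'                  membrane = material(1e-7, 5), cytoplasm = material(1, 80),
#'                  medium = material(1, 80))
#' single_shell_permittivity(cm, 1e4)  # membrane-dominated plateau
#' @export
single_shell_permittivity <- function(cell, f) {
  stopifnot(inherits(cell, "cell_model"))
  check_frequency(f)
  v <- shell_factor(cell)
  em <- membrane_eps_star(cell, f)
  ec <- complex_permittivity(cell$cytoplasm, f)
  den <- (2 + v) * em + (1 - v) * ec
  scale <- pmax(Mod(em), Mod(ec))
  if (any(Mod(den) <= .Machine$double.eps * scale))
    stop("single-shell denominator is degenerate: ",
         "(2+v) eps_m* + (1-v) eps_c* vanishes for the given materials",
         call. = FALSE)
  em * (2 * (1 - v) * em + (1 + 2 * v) * ec) / den
}

#' Wagner's mixture equation
#'
#' Effective complex permittivity of a dilute suspension of inclusions of
#' permittivity `eps_p` at volume fraction `P` in a medium `eps_a`:
#'
#'   eps* = eps_a* (2(1-P) eps_a* + (1+2P) eps_p*) /
#'          ((2+P) eps_a* + (1-P) eps_p*).
#'
#' The formula interpolates exactly: P = 0 gives the medium, P = 1 the
#' inclusion phase. It is applied as printed (its three-dimensional
#' dilute form) for both 2D and 3D cell models; see the methods vignette
#' for the consequences in 2D.
#'
#' @param eps_p Complex inclusion (cell) permittivity.
#' @param eps_a Complex medium permittivity.
#' @param P Volume (area) fraction in \[0, 1\].
#' @return Complex effective relative permittivity.
#' @export
wagner_mixture <- function(eps_p, eps_a, P) {
  if (!is.numeric(P) || length(P) != 1L || !is.finite(P) || P < 0 || P > 1)
    stop("'P' must be a single volume fraction in [0, 1]", call. = FALSE)
  den <- (2 + P) * eps_a + (1 - P) * eps_p
  scale <- pmax(Mod(eps_a), Mod(eps_p))
  if (any(Mod(den) <= .Machine$double.eps * scale))
    stop("Wagner mixture denominator vanishes for the given phases",
         call. = FALSE)
  eps_a * (2 * (1 - P) * eps_a + (1 + 2 * P) * eps_p) / den
}

#' Construct a dispersion spectrum
#'
#' A spectrum is a data frame with one row per frequency carrying the
#' effective complex conductivity sigma* and its decomposition
#' sigma_r = Re(sigma*), eps_r = Im(sigma*)/(omega eps0).
#'
#' @param frequencies Strictly increasing frequencies in Hz.
#' @param sigma_star Complex conductivities in S/m, one per frequency.
#' @return A `data.frame` of class `spectrum` with columns
#'   `frequency_hz`, `sigma_star`, `sigma_r`, `eps_r`.
#' @export
spectrum <- function(frequencies, sigma_star) {
  check_frequency(frequencies)
  if (is.unsorted(frequencies, strictly = TRUE))
    stop("'frequencies' must be strictly increasing", call. = FALSE)
  if (length(sigma_star) != length(frequencies))
    stop("'sigma_star' must match 'frequencies' in length", call. = FALSE)
  if (any(!is.finite(sigma_star)))
    stop("'sigma_star' must be finite", call. = FALSE)
  w <- 2 * pi * frequencies
  out <- data.frame(frequency_hz = frequencies,
                    sigma_star = as.complex(sigma_star),
                    sigma_r = Re(sigma_star),
                    eps_r = Im(sigma_star) / (w * EPS0))
  class(out) <- c("spectrum", "data.frame")
  out
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d frequencies, %.3g Hz - %.3g Hz\n",
              nrow(x), min(x$frequency_hz), max(x$frequency_hz)))
  print.data.frame(cbind(x[, c("frequency_hz", "sigma_r", "eps_r")],
                         sigma_im = Im(x$sigma_star)), ...)
  invisible(x)
}

#' Default frequency grid
#'
#' Log-spaced frequencies covering the beta-dispersion band, 1 kHz to
#' 100 MHz with 15 points by default.
#'
#' @param n Number of points.
#' @param fmin,fmax Band edges in Hz.
#' @return Numeric vector of frequencies in Hz.
#' @export
default_frequencies <- function(n = 15, fmin = 1e3, fmax = 1e8) {
  stopifnot(n >= 2, fmin > 0, fmax > fmin)
  10^seq(log10(fmin), log10(fmax), length.out = n)
}

#' Analytical dispersion sweep of a cell suspension
#'
#' Composes the single-shell model and Wagner's mixture across a
#' frequency grid and converts to complex conductivity, giving the
#' analytical beta-dispersion spectrum of the suspension.
#'
#' @param cell A [cell_model()].
#' @param P Volume (area) fraction of cells in \[0, 1\].
#' @param frequencies Strictly increasing frequencies in Hz;
#'   defaults to [default_frequencies()].
#' @return A [spectrum()].
#' @examples
#' cm <- cell_model(radius = 5e-6, membrane_thickness = 5e-9, dimension = 2,
#'                  membrane = material(1e-7, 5), cytoplasm = material(1, 80),
#'                  medium = material(1, 80))
#' sp <- analytical_sweep(cm, P = 0.035)
#' sp$eps_r[nrow(sp)]  # high-frequency plateau ~ 80
#' @export
analytical_sweep <- function(cell, P, frequencies = default_frequencies()) {
  stopifnot(inherits(cell, "cell_model"))
  if (length(frequencies) < 1L)
    stop("'frequencies' must be non-empty", call. = FALSE)
  ea <- complex_permittivity(cell$medium, frequencies)
  ep <- single_shell_permittivity(cell, frequencies)
  es <- wagner_mixture(ep, ea, P)
  spectrum(frequencies, eps_to_sigma(es, frequencies))
}

#' Write / read a spectrum as CSV
#'
#' The on-disk format has header
#' `frequency_hz,sigma_re,sigma_im,sigma_r,eps_r`; the round trip is
#' lossless to full double precision.
#'
#' @param sp A [spectrum()].
#' @param path File path.
#' @return `read_spectrum()` returns a [spectrum()];
#'   `write_spectrum()` returns `path` invisibly.
#' @export
write_spectrum <- function(sp, path) {
  stopifnot(inherits(sp, "spectrum"))
  df <- data.frame(frequency_hz = format(sp$frequency_hz, digits = 17),
                   sigma_re = format(Re(sp$sigma_star), digits = 17),
                   sigma_im = format(Im(sp$sigma_star), digits = 17),
                   sigma_r = format(sp$sigma_r, digits = 17),
                   eps_r = format(sp$eps_r, digits = 17))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frequency_hz", "sigma_re", "sigma_im")
  if (!all(need %in% names(df)))
    stop("not a spectrum CSV: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  spectrum(df$frequency_hz, complex(real = df$sigma_re,
                                    imaginary = df$sigma_im))
}

#' Debye relaxation model
#'
#' Single-time-constant dispersion with a conduction term:
#'
#'   eps* = eps_h + (eps_l - eps_h) / (1 + j omega tau) +
#'          k_l / (j omega eps0).
#'
#' Equivalently, sigma* = j omega eps0 eps* gives
#' sigma_r = k_l + (eps_l - eps_h) eps0 omega^2 tau / (1 + omega^2 tau^2)
#' and eps_r = eps_h + (eps_l - eps_h) / (1 + omega^2 tau^2).
#'
#' @param params A [debye_parameters()] or a `debye_fit`.
#' @param f Frequency in Hz (> 0); vectorised.
#' @return Complex relative permittivity eps*.
#' @export
debye_model <- function(params, f) {
  p <- as_debye_parameters(params)
  check_frequency(f)
  w <- 2 * pi * f
  p$eps_h + (p$eps_l - p$eps_h) / (1 + 1i * w * p$tau) +
    p$k_l / (1i * w * EPS0)
}

#' Debye relaxation parameters
#'
#' @param eps_l,eps_h Low/high-frequency permittivity limits
#'   (eps_l >= eps_h > 0).
#' @param tau Relaxation time in s (> 0).
#' @param k_l Low-frequency conductivity limit in S/m (>= 0).
#' @return A list of class `debye_parameters` including the derived
#'   characteristic frequency `f_c = 1/(2 pi tau)`.
#' @export
debye_parameters <- function(eps_l, eps_h, tau, k_l) {
  if (!all(is.finite(c(eps_l, eps_h, tau, k_l))))
    stop("Debye parameters must be finite", call. = FALSE)
  if (!(eps_l >= eps_h && eps_h > 0))
    stop("Debye parameters require eps_l >= eps_h > 0", call. = FALSE)
  if (tau <= 0) stop("'tau' must be > 0", call. = FALSE)
  if (k_l < 0) stop("'k_l' must be >= 0", call. = FALSE)
  structure(list(eps_l = eps_l, eps_h = eps_h, tau = tau, k_l = k_l,
                 f_c = 1 / (2 * pi * tau)),
            class = "debye_parameters")
}

as_debye_parameters <- function(x) {
  if (inherits(x, "debye_parameters")) return(x)
  if (inherits(x, "debye_fit")) return(x$parameters)
  stop("expected 'debye_parameters' or 'debye_fit'", call. = FALSE)
}

#' @export
print.debye_parameters <- function(x, ...) {
  cat(sprintf(
    "<debye_parameters> eps_l = %.6g, eps_h = %.6g, tau = %.6g s (f_c = %.6g Hz), k_l = %.6g S/m\n",
    x$eps_l, x$eps_h, x$tau, x$f_c, x$k_l))
  invisible(x)
}

# sigma_r / eps_r predicted by the Debye model at frequencies f
debye_components <- function(eps_l, eps_h, tau, k_l, f) {
  w <- 2 * pi * f
  wt2 <- (w * tau)^2
  list(sigma_r = k_l + (eps_l - eps_h) * EPS0 * w^2 * tau / (1 + wt2),
       eps_r = eps_h + (eps_l - eps_h) / (1 + wt2))
}

#' Fit the Debye relaxation model to a dispersion spectrum
#'
#' Joint bounded least-squares fit of the Debye model to sigma_r(f) and
#' eps_r(f), using relative residuals so that the two channels (which
#' differ by orders of magnitude in units) contribute comparably.
#' Initial values: eps_l, eps_h from the first/last eps_r samples, k_l
#' from the first sigma_r sample, tau from the frequency of steepest
#' descent of eps_r against log f. Optimisation is Levenberg-Marquardt
#' with box bounds (via minpack.lm); tau is fitted on a log scale.
#'
#' @param sp A [spectrum()] spanning the relaxation (at least one decade
#'   each side of the eps_r inflection is recommended).
#' @return An object of class `debye_fit` with elements `parameters`
#'   (a [debye_parameters()]), `residual_norm` (root-mean-square relative
#'   residual), `fitted` (data frame of fitted sigma_r/eps_r), `spectrum`
#'   and the underlying optimiser report.
#' @examples
#' p <- debye_parameters(960, 80, 1e-7, 0.925)
#' f <- default_frequencies(50)
#' sp <- spectrum(f, eps_to_sigma(debye_model(p, f), f))
#' fit <- fit_debye(sp)
#' coef(fit)
#' @export
fit_debye <- function(sp) {
  stopifnot(inherits(sp, "spectrum"))
  if (nrow(sp) < 5L)
    stop("at least 5 frequencies are needed to fit the Debye model",
         call. = FALSE)
  f <- sp$frequency_hz
  er <- sp$eps_r
  sr <- sp$sigma_r
  span <- max(er) - min(er)
  if (span <= 1e-6 * max(abs(er)))
    stop("no relaxation detected: eps_r is flat over the sampled band",
         call. = FALSE)

  # initial guesses
  eps_l0 <- max(er[1], 1e-12)
  eps_h0 <- max(er[length(er)], 1e-12)
  k_l0 <- max(sr[1], 0)
  slope <- -diff(er) / diff(log(f))
  f_steep <- sqrt(f[which.max(slope)] * f[which.max(slope) + 1L])
  tau0 <- 1 / (2 * pi * f_steep)

  rel_resid <- function(theta) {
    eps_l <- theta[1]; eps_h <- theta[2]
    tau <- exp(theta[3]); k_l <- theta[4]
    pred <- debye_components(eps_l, eps_h, tau, k_l, f)
    c((pred$sigma_r - sr) / pmax(abs(sr), 1e-30),
      (pred$eps_r - er) / pmax(abs(er), 1e-30))
  }
  theta0 <- c(eps_l0, eps_h0, log(tau0), k_l0)
  lower <- c(1e-12, 1e-12, log(tau0) - log(1e6), 0)
  upper <- c(Inf, Inf, log(tau0) + log(1e6), Inf)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                     ptol = 1e-15)
  opt <- minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                            fn = rel_resid, control = ctrl)
  theta <- opt$par
  res <- rel_resid(theta)
  rnorm_ <- sqrt(mean(res^2))
  if (opt$info %in% c(0, 9) || !all(is.finite(theta)))
    stop(sprintf(paste0("Debye fit did not converge (lm info %d); ",
                        "initial guess eps_l=%.4g eps_h=%.4g tau=%.4g ",
                        "k_l=%.4g, residual %.4g"),
                 opt$info, eps_l0, eps_h0, tau0, k_l0, rnorm_),
         call. = FALSE)
  # enforce eps_l >= eps_h in the reported parameters (the model is
  # symmetric under swapping the limits with tau unchanged only at the
  # half-relaxation point, so a swapped optimum is simply relabelled)
  eps_l <- max(theta[1], theta[2]); eps_h <- min(theta[1], theta[2])
  pars <- debye_parameters(eps_l, eps_h, exp(theta[3]), theta[4])
  pred <- debye_components(pars$eps_l, pars$eps_h, pars$tau, pars$k_l, f)
  structure(list(parameters = pars,
                 residual_norm = rnorm_,
                 fitted = data.frame(frequency_hz = f,
                                     sigma_r = pred$sigma_r,
                                     eps_r = pred$eps_r),
                 spectrum = sp,
                 optim = opt),
            class = "debye_fit")
}

#' @export
print.debye_fit <- function(x, ...) {
  cat("Debye relaxation fit\n")
  print(x$parameters)
  cat(sprintf("  rms relative residual: %.3g over %d frequencies\n",
              x$residual_norm, nrow(x$spectrum)))
  invisible(x)
}

#' @export
coef.debye_fit <- function(object, ...) {
  p <- object$parameters
  c(eps_l = p$eps_l, eps_h = p$eps_h, tau = p$tau, k_l = p$k_l, f_c = p$f_c)
}

#' @export
predict.debye_fit <- function(object, f = object$spectrum$frequency_hz, ...) {
  debye_model(object$parameters, f)
}

#' @export
residuals.debye_fit <- function(object, ...) {
  with(object, cbind(sigma_r = fitted$sigma_r - spectrum$sigma_r,
                     eps_r = fitted$eps_r - spectrum$eps_r))
}

#' @export
summary.debye_fit <- function(object, ...) {
  p <- object$parameters
  cat("Debye relaxation fit\n")
  cat(sprintf("  eps_l = %.6g, eps_h = %.6g\n", p$eps_l, p$eps_h))
  cat(sprintf("  tau   = %.6g s  ->  f_c = %.6g Hz\n", p$tau, p$f_c))
  cat(sprintf("  k_l   = %.6g S/m\n", p$k_l))
  cat(sprintf("  rms relative residual %.3g; band %.3g Hz - %.3g Hz\n",
              object$residual_norm, min(object$spectrum$frequency_hz),
              max(object$spectrum$frequency_hz)))
  invisible(object)
}
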