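#' @title One-compartment labeling kinetics
#' @description Nonlinear least-squares fitting of the exponential-rise
#'   labeling model `I(t) = I0 + (Ip - I0) * (1 - exp(-k t))`, studentized
#'   outlier removal, half-life conversion, and peptide-to-protein
#'   aggregation.  Under metabolic steady state the fractional synthesis and
#'   catabolic rates coincide and equal the rate constant `k`.
#' @name kinetics
NULL

curve_I <- function(par, t) {
  par[["I0"]] + (par[["Ip"]] - par[["I0"]]) * (1 - exp(-par[["k"]] * t))
}

# Analytic Jacobian of the model at (k, I0, Ip); columns in that order.
curve_jacobian <- function(par, t) {
  ek <- exp(-par[["k"]] * t)
  cbind(k = (par[["Ip"]] - par[["I0"]]) * t * ek,
        I0 = ek,
        Ip = 1 - ek)
}

# Damped Gauss-Newton polish with the analytic Jacobian: drives the
# solution to machine precision (the port algorithm stops at its relative
# tolerance, which is too loose for exact-recovery work).
polish_fit <- function(par, t, I, lower, upper, free_plateau,
                       max_iter = 60L) {
  free <- c("k", "I0", if (free_plateau) "Ip")
  sse <- function(p) sum((I - curve_I(p, t))^2)
  cur <- sse(par)
  for (it in seq_len(max_iter)) {
    r <- I - curve_I(par, t)
    J <- curve_jacobian(par, t)[, free, drop = FALSE]
    step <- tryCatch(
      solve(crossprod(J) + diag(1e-14, ncol(J)), crossprod(J, r)),
      error = function(e) NULL)
    if (is.null(step)) break
    step <- as.numeric(step)
    lam <- 1
    improved <- FALSE
    for (h in 1:12) {
      cand <- par
      cand[free] <- pmin(pmax(par[free] + lam * step, lower), upper)
      s <- sse(cand)
      if (s <= cur) {
        par <- cand
        improved <- s < cur
        cur <- s
        break
      }
      lam <- lam / 2
    }
    if (!improved || max(abs(lam * step)) < 1e-14) break
  }
  par
}

# Deterministic initialization: I0 from the baseline point, plateau from
# the last point, k from the through-origin slope of -log(1 - Ihat) where
# Ihat is the plateau-normalized labeling.
init_par <- function(time_h, I, k_bounds) {
  I0 <- I[which.min(time_h)]
  Ip <- I[which.max(time_h)]
  if (Ip <= I0) Ip <- I0 + max(1e-3, abs(I0) * 0.05)
  ihat <- (I - I0) / (Ip - I0)
  use <- time_h > 0 & ihat > 0 & ihat < 1
  k0 <- if (any(use)) {
    y <- -log(1 - ihat[use])
    sum(y * time_h[use]) / sum(time_h[use]^2)
  } else {
    log(2) / max(time_h[time_h > 0])
  }
  c(k = min(max(k0, k_bounds[1] * 1.01), k_bounds[2] * 0.99),
    I0 = I0, Ip = Ip)
}

#' Fit the exponential-rise labeling model to one enrichment series
#'
#' Nonlinear least squares (port algorithm, analytic fallback to bounded
#' BFGS) for `(k, I0, Iplateau)`.  Initialization is deterministic, so the
#' fit is reproducible for fixed input and options.  The plateau is a free
#' parameter by default; supply `fix_plateau` to pin it to a theoretical
#' asymptotic value.
#'
#' @param series Output of [enrichment_series()] (columns `time_h`, `I`),
#'   with >= `min_points` points, a baseline at t = 0, and at least
#'   `min_span_h` hours of labeling.
#' @param k_bounds Admissible range of the rate constant, per hour.
#' @param plateau_max Upper bound of the plateau parameter.  Total labeling
#'   of tryptic-size peptides starts from a large natural baseline, so the
#'   physical ceiling is just below 1, not 0.5.
#' @param fix_plateau Optional fixed plateau value; `NULL` fits it freely.
#' @param min_points Minimum points required (default 4).
#' @param min_span_h Required labeling span in hours (default 48).
#' @return Object of class `kinetic_fit`: list with `k`, `k_se`, `I0`,
#'   `Iplateau`, `t_half`, `rse` (residual standard error), `n_points`,
#'   `removed` (indices dropped by [remove_outliers()]), `converged`,
#'   `residuals`, `time_h`, `I`.
#' @export
fit_exponential <- function(series, k_bounds = c(1e-5, 2),
                            plateau_max = 0.995, fix_plateau = NULL,
                            min_points = 4L, min_span_h = 48) {
  stopifnot(is.data.frame(series), all(c("time_h", "I") %in% names(series)))
  t <- series$time_h
  I <- series$I
  if (length(t) < min_points) {
    stop("need at least ", min_points, " points to fit; got ", length(t))
  }
  if (!any(t == 0)) stop("series lacks a baseline point")
  if (max(t) < min_span_h) {
    stop("series spans only ", max(t), " h; need >= ", min_span_h, " h")
  }
  start <- init_par(t, I, k_bounds)
  free_plateau <- is.null(fix_plateau)
  if (!free_plateau) start[["Ip"]] <- fix_plateau

  sse <- function(p) {
    par <- c(k = p[1], I0 = p[2],
             Ip = if (free_plateau) p[3] else fix_plateau)
    sum((I - curve_I(par, t))^2)
  }
  lower <- c(k_bounds[1], 0, if (free_plateau) 0)
  upper <- c(k_bounds[2], 1, if (free_plateau) plateau_max)
  p0 <- pmin(pmax(unname(start[c(1, 2, if (free_plateau) 3)]), lower), upper)

  fitted_par <- NULL
  converged <- FALSE
  res <- tryCatch({
    df <- data.frame(t = t, I = I)
    if (free_plateau) {
      fm <- stats::nls(I ~ I0 + (Ip - I0) * (1 - exp(-k * t)), data = df,
                       start = list(k = p0[1], I0 = p0[2], Ip = p0[3]),
                       algorithm = "port", lower = lower, upper = upper,
                       control = stats::nls.control(maxiter = 200,
                                                    warnOnly = FALSE))
    } else {
      fm <- stats::nls(I ~ I0 + (fix_plateau - I0) * (1 - exp(-k * t)),
                       data = df,
                       start = list(k = p0[1], I0 = p0[2]),
                       algorithm = "port", lower = lower, upper = upper,
                       control = stats::nls.control(maxiter = 200,
                                                    warnOnly = FALSE))
    }
    cf <- stats::coef(fm)
    fitted_par <<- c(k = cf[["k"]], I0 = cf[["I0"]],
                     Ip = if (free_plateau) cf[["Ip"]] else fix_plateau)
    converged <<- TRUE
    fm
  }, error = function(e) NULL)

  if (!converged) {
    # zero-residual and edge cases: bounded quasi-Newton on the SSE
    op <- tryCatch(
      stats::optim(p0, sse, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(op)) {
      fitted_par <- c(k = op$par[1], I0 = op$par[2],
                      Ip = if (free_plateau) op$par[3] else fix_plateau)
    }
  }
  if (is.null(fitted_par)) {
    fitted_par <- c(k = p0[1], I0 = p0[2],
                    Ip = if (free_plateau) p0[3] else fix_plateau)
  }
  # Always polish from the best available parameters; judge convergence by
  # first-order stationarity rather than the optimizer's exit code (port
  # errors out on zero-residual data, L-BFGS-B on very flat SSE surfaces).
  fitted_par <- polish_fit(fitted_par, t, I, lower, upper, free_plateau)
  resid0 <- I - curve_I(fitted_par, t)
  J0 <- curve_jacobian(fitted_par, t)
  if (!free_plateau) J0 <- J0[, c("k", "I0"), drop = FALSE]
  grad <- crossprod(J0, resid0)
  converged <- all(is.finite(fitted_par)) &&
    max(abs(grad)) < 1e-6 * (1 + sum(resid0^2))

  n <- length(t)
  npar <- if (free_plateau) 3L else 2L
  resid <- if (converged) I - curve_I(fitted_par, t) else rep(NA_real_, n)
  rse <- if (converged && n > npar) sqrt(sum(resid^2) / (n - npar)) else NA_real_
  k_se <- NA_real_
  if (converged && n > npar && !is.na(rse)) {
    J <- curve_jacobian(fitted_par, t)
    if (!free_plateau) J <- J[, c("k", "I0"), drop = FALSE]
    jtj <- crossprod(J)
    cv <- tryCatch(solve(jtj), error = function(e) NULL)
    if (!is.null(cv)) k_se <- rse * sqrt(cv[1, 1])
  }
  k <- fitted_par[["k"]]
  structure(list(
    k = k, k_se = k_se,
    I0 = fitted_par[["I0"]], Iplateau = fitted_par[["Ip"]],
    t_half = if (converged && !is.na(k) && k > 0) log(2) / k else NA_real_,
    rse = rse, n_points = n, npar = npar,
    removed = integer(0), converged = converged,
    residuals = resid, time_h = t, I = I,
    free_plateau = free_plateau, fix_plateau = fix_plateau,
    k_bounds = k_bounds, plateau_max = plateau_max,
    min_points = min_points, min_span_h = min_span_h
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "kinetic_fit: k = %.4g /h (se %.2g), t1/2 = %.4g h, I0 = %.4g, Ip = %.4g\n",
    x$k, x$k_se, x$t_half, x$I0, x$Iplateau))
  cat(sprintf("  %d points, %d outlier(s) removed, converged: %s\n",
              x$n_points, length(x$removed), x$converged))
  invisible(x)
}

# Externally studentized residuals of a nonlinear fit via the linearized
# hat matrix from the analytic Jacobian.
studentized_residuals <- function(fit) {
  par <- c(k = fit$k, I0 = fit$I0, Ip = fit$Iplateau)
  J <- curve_jacobian(par, fit$time_h)
  if (!fit$free_plateau) J <- J[, c("k", "I0"), drop = FALSE]
  h <- diag(J %*% solve(crossprod(J), t(J)))
  h <- pmin(h, 1 - 1e-8)
  n <- fit$n_points
  p <- fit$npar
  e <- fit$residuals
  sse <- sum(e^2)
  s2_i <- (sse - e^2 / (1 - h)) / (n - p - 1)
  s2_i <- pmax(s2_i, 0)
  out <- e / sqrt(s2_i * (1 - h))
  out[!is.finite(out)] <- 0
  out
}

#' Remove statistical outliers from a fitted enrichment series
#'
#' Drops points whose externally studentized residual exceeds `threshold`
#' in absolute value, at most `max_removals` per series (worst first), as a
#' reproducible stand-in for interactive outlier cleaning.  If a removal
#' would leave fewer than `min_points` points, nothing is removed and the
#' series is flagged instead.
#'
#' @param series The series that produced `fit`.
#' @param fit A converged [fit_exponential()] result.
#' @param threshold Absolute studentized-residual cutoff (default 3).
#' @param max_removals Maximum points to drop (default 1).
#' @param min_points Floor on remaining points (default 4).
#' @return `series` without the removed rows; attributes `removed` (original
#'   row indices) and `flagged` (TRUE when an indicated removal was blocked
#'   or more outliers remained than `max_removals`).
#' @export
remove_outliers <- function(series, fit, threshold = 3, max_removals = 1L,
                            min_points = 4L) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (!fit$converged) stop("cannot screen outliers without a converged fit")
  r <- abs(studentized_residuals(fit))
  cand <- order(r, decreasing = TRUE)
  cand <- cand[r[cand] > threshold]
  flagged <- length(cand) > max_removals
  cand <- utils::head(cand, max_removals)
  # the measured baseline anchors I(0); it is never removed, only flagged
  if (any(series$time_h[cand] == 0)) {
    cand <- cand[series$time_h[cand] != 0]
    flagged <- TRUE
  }
  if (length(cand) && (nrow(series) - length(cand)) < min_points) {
    attr(series, "removed") <- integer(0)
    attr(series, "flagged") <- TRUE
    return(series)
  }
  out <- if (length(cand)) series[-cand, , drop = FALSE] else series
  rownames(out) <- NULL
  attr(out, "removed") <- sort(cand)
  attr(out, "flagged") <- flagged
  out
}

#' Fit one peptide with outlier screening
#'
#' The standard per-peptide procedure: initial fit, one round of
#' studentized-residual outlier removal, refit on the cleaned series.
#'
#' @inheritParams fit_exponential
#' @inheritParams remove_outliers
#' @param ... Passed to [fit_exponential()].
#' @return A `kinetic_fit` whose `removed` records dropped point indices.
#' @export
fit_peptide <- function(series, threshold = 3, max_removals = 1L, ...) {
  fit0 <- fit_exponential(series, ...)
  if (!fit0$converged || max_removals < 1L) return(fit0)
  cleaned <- remove_outliers(series, fit0, threshold = threshold,
                             max_removals = max_removals,
                             min_points = fit0$min_points)
  removed <- attr(cleaned, "removed")
  if (!length(removed)) {
    fit0$outlier_flag <- isTRUE(attr(cleaned, "flagged"))
    return(fit0)
  }
  fit1 <- fit_exponential(cleaned, ...)
  fit1$removed <- removed
  fit1$outlier_flag <- isTRUE(attr(cleaned, "flagged"))
  fit1
}

#' Half-life from a first-order rate constant
#'
#' @param k Rate constant (per hour), strictly positive.
#' @return `log(2) / k`, hours.
#' @examples
#' half_life(0.0693147)  # 10 h
#' @export
half_life <- function(k) {
  if (!is.numeric(k) || anyNA(k) || any(k <= 0)) {
    stop("rate constant must be > 0")
  }
  log(2) / k
}

#' Aggregate peptide fits to protein-level turnover
#'
#' Unweighted mean and SD of the peptide rate constants over converged
#' fits; proteins with fewer than `min_peptides` converged fits are
#' excluded.  The protein half-life is derived from the mean rate constant
#' (`t_half = log(2) / mean_k`), and under steady state FSR = FCR = mean k.
#'
#' @param fits List of `kinetic_fit` objects for one (protein, animal).
#' @param min_peptides Minimum converged peptide fits (default 3).
#' @return list with `mean_k`, `sd_k`, `t_half`, `n_peptides` (converged),
#'   `n_total`, `excluded` (logical), `reason`.
#' @export
aggregate_protein <- function(fits, min_peptides = 3L) {
  if (!length(fits)) stop("no peptide fits supplied")
  ok <- vapply(fits, function(f) isTRUE(f$converged) && !is.na(f$k) &&
                 f$k > 0, logical(1))
  ks <- vapply(fits[ok], function(f) f$k, numeric(1))
  n_ok <- sum(ok)
  if (n_ok < min_peptides) {
    return(list(mean_k = NA_real_, sd_k = NA_real_, t_half = NA_real_,
                n_peptides = n_ok, n_total = length(fits), excluded = TRUE,
                reason = sprintf("only %d converged peptide fits (< %d)",
                                 n_ok, min_peptides)))
  }
  mk <- mean(ks)
  list(mean_k = mk, sd_k = stats::sd(ks), t_half = log(2) / mk,
       n_peptides = n_ok, n_total = length(fits), excluded = FALSE,
       reason = NA_character_)
}
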