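#' Annealing control parameters
#'
#' Settings for the bounded simulated-annealing search used by
#' [traj_fit()]: geometric cooling from `t0` by `cooling` per temperature
#' level, `steps` proposals per level, stopping below `tmin`, Gaussian
#' proposals with standard deviation `prop_frac` times each parameter's
#' bound width, and `restarts` independent chains (best kept). The
#' acceptance criterion works on SSE normalised by `n * var(y)`, so `t0`
#' is scale-free. A bounded Nelder-Mead polish refines the best chain
#' state when `polish = TRUE`.
#'
#' @param t0 Initial temperature (> 0).
#' @param cooling Geometric cooling factor in (0, 1).
#' @param steps Proposals per temperature level.
#' @param tmin Final temperature (> 0).
#' @param prop_frac Proposal SD as a fraction of each bound width.
#' @param restarts Independent annealing chains.
#' @param polish Apply a local Nelder-Mead refinement to the best state.
#' @return A list of class `anneal_control`.
#' @export
anneal_control <- function(t0 = 1.0, cooling = 0.95, steps = 50,
                           tmin = 1e-4, prop_frac = 0.05, restarts = 3,
                           polish = TRUE) {
  stopifnot(t0 > 0, cooling > 0, cooling < 1, steps >= 1, tmin > 0,
            prop_frac > 0, restarts >= 1)
  structure(list(t0 = t0, cooling = cooling, steps = as.integer(steps),
                 tmin = tmin, prop_frac = prop_frac,
                 restarts = as.integer(restarts), polish = isTRUE(polish)),
            class = "anneal_control")
}

# Default parameter box. A: [0, 2 * max(y)] unless an explicit upper bound
# (e.g. 53 for the ALSFRS-R total) is supplied; k: [-5, 5] per day, except
# the weibull where (k*t)^b requires k >= 0; b: [0.0001, 5].
default_bounds <- function(family, y, A_upper = NULL) {
  A_hi <- if (!is.null(A_upper)) A_upper else 2 * max(y, 0)
  if (A_hi <= 0) A_hi <- 1
  b <- list(A = c(0, A_hi), k = c(-5, 5))
  if (family == "weibull") {
    b$k <- c(0, 5)
    b$b <- c(1e-4, 5)
  }
  b
}

#' Fit a parametric decline trajectory to one subject's series
#'
#' Fits one of the four candidate decline models (see
#' [trajectory_families()]) to a single subject's `(day, value)` series by
#' bounded simulated annealing on the Gaussian likelihood. With a common
#' error variance the Gaussian negative log-likelihood is minimised exactly
#' where the sum of squared errors is, so the search minimises SSE over the
#' bounded parameter box and the error SD is profiled out afterwards.
#'
#' Parameter bounds follow the clinical-modelling conventions of the
#' method: rate `k` restricted to \[-5, 5\] per day (`[0, 5]` for the
#' Weibull, whose `(k t)^b` is undefined for negative `k t`), Weibull
#' shape `b` in \[0.0001, 5\], and baseline `A` in \[0, 2 max(y)\] unless
#' `A_upper` is given (53 for the ALSFRS-R total score).
#'
#' A series needs at least one more point than the family has parameters
#' (3 for two-parameter families, 4 for the Weibull) at distinct days;
#' shorter series return a no-fit object (`fitted_ok(fit)` is `FALSE`)
#' carrying the earliest observed value as a baseline-only feature.
#'
#' @param x A formula `value ~ day` (with `data`), or a numeric vector of
#'   days.
#' @param ... Passed between methods.
#' @return An object of class `traj_fit` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot` and `simulate` methods.
#' @examples
#' d <- data.frame(day = seq(0, 300, 30))
#' d$score <- plant_trajectory("exponential", A = 40, k = 0.004,
#'                             times = d$day, noise_sd = 0)
#' fit <- traj_fit(score ~ day, d, family = "exponential")
#' coef(fit)
#' @export
traj_fit <- function(x, ...) UseMethod("traj_fit")

#' @rdname traj_fit
#' @param formula,data Model formula `value ~ day` and a data frame
#'   containing both variables.
#' @export
traj_fit.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data = data, na.action = stats::na.omit)
  if (ncol(mf) != 2)
    stop("formula must have the form value ~ day", call. = FALSE)
  out <- traj_fit.default(mf[[2L]], mf[[1L]], ...)
  out$call <- match.call()
  out
}

#' @rdname traj_fit
#' @param y Numeric measurements at the days in `x`.
#' @param family One of [trajectory_families()].
#' @param A_upper Optional hard upper bound for the baseline parameter
#'   `A` (use 53 for the ALSFRS-R total score).
#' @param bounds Optional named list overriding the parameter box, e.g.
#'   `list(A = c(0, 53), k = c(-5, 5))`.
#' @param control An [anneal_control()] object.
#' @param variable Optional variable name stored on the fit.
#' @param subject Optional subject identifier stored on the fit.
#' @export
traj_fit.default <- function(x, y, family = "exponential", A_upper = NULL,
                             bounds = NULL, control = anneal_control(),
                             variable = NULL, subject = NULL, ...) {
  family <- match.arg(family, .FAMILIES)
  keep <- is.finite(x) & is.finite(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  p <- family_arity(family)
  n <- length(x)

  no_fit <- function() {
    structure(list(
      family = family, coefficients = c(A = if (n) y[1L] else NA_real_,
                                        k = NA_real_),
      sse = NA_real_, rmse = NA_real_, aicc = NA_real_, sigma = NA_real_,
      n = n, day = x, value = y, ok = FALSE, collapsed = FALSE,
      variable = variable, subject = subject, control = control,
      call = match.call()), class = "traj_fit")
  }
  if (length(unique(x)) < p + 1) return(no_fit())

  fam_code <- .family_code(family)
  bx <- default_bounds(family, y, A_upper)
  if (!is.null(bounds)) bx[names(bounds)] <- bounds
  lower <- vapply(bx, `[`, numeric(1), 1L)
  upper <- vapply(bx, `[`, numeric(1), 2L)

  sa <- .sa_fit_cpp(fam_code, x, y, lower, upper, control$t0,
                    control$cooling, control$steps, control$tmin,
                    control$prop_frac, control$restarts)
  par <- sa$par
  sse <- sa$sse
  if (control$polish) {
    fn <- function(pp) {
      pp <- pmin(pmax(pp, lower), upper)
      s <- .sse_cpp(fam_code, pp, x, y)
      if (!is.finite(s)) 1e300 else s
    }
    op <- optim(par, fn, method = "Nelder-Mead",
                control = list(maxit = 500, reltol = 1e-12))
    cand <- pmin(pmax(op$par, lower), upper)
    cand_sse <- .sse_cpp(fam_code, cand, x, y)
    if (is.finite(cand_sse) && cand_sse < sse) {
      par <- cand
      sse <- cand_sse
    }
  }
  names(par) <- names(bx)

  structure(list(
    family = family, coefficients = par, sse = sse,
    rmse = sqrt(sse / n),
    aicc = if (n > p + 1) aicc(sse, n, p) else NA_real_,
    sigma = sqrt(sse / n), n = n, day = x, value = y, ok = TRUE,
    collapsed = FALSE, bounds = bx, variable = variable,
    subject = subject, control = control, call = match.call()),
    class = "traj_fit")
}

#' Did the trajectory fit succeed?
#'
#' @param object A `traj_fit`.
#' @return `FALSE` for the no-fit marker returned when a series has too
#'   few distinct time points for the family.
#' @export
fitted_ok <- function(object) isTRUE(object$ok)

#' Gaussian negative log-likelihood of a trajectory model
#'
#' With common error SD `sigma`, the NLL is
#' `n/2 log(2 pi sigma^2) + SSE / (2 sigma^2)`; for fixed `sigma` (or with
#' `sigma` profiled out) it is a monotone function of SSE, so the
#' likelihood and least-squares minimisers coincide. When `sigma = NULL`
#' the profiled value `sqrt(SSE/n)` is used; a zero-SSE fit is guarded by
#' returning `-Inf`-bounded large negative value rather than `-Inf`.
#'
#' @param day,value The series.
#' @param family Model family.
#' @param params Named vector with `A`, `k` and, for the Weibull, `b`.
#' @param sigma Error SD, or `NULL` to profile it out.
#' @return The negative log-likelihood (scalar).
#' @export
neg_log_likelihood <- function(day, value, family, params, sigma = NULL) {
  family <- match.arg(family, .FAMILIES)
  if (length(unique(day)) <= 1)
    stop("degenerate series: all observations at the same day",
         call. = FALSE)
  n <- length(value)
  p <- c(params[["A"]], params[["k"]],
         if (family == "weibull") params[["b"]] else NULL)
  sse <- .sse_cpp(.family_code(family), p, as.numeric(day),
                  as.numeric(value))
  if (is.null(sigma)) {
    if (sse <= 0) return(-1e300)  # perfect fit: profiled sigma -> 0
    sigma <- sqrt(sse / n)
  }
  n / 2 * log(2 * pi * sigma^2) + sse / (2 * sigma^2)
}

#' Collapse a boundary Weibull fit to the exponential
#'
#' When the fitted Weibull shape sits at (within `eps` of) its bounds
#' 0.0001 or 5, or near 1 where the Weibull is exactly the exponential,
#' the three-parameter model is discarded and the series is refitted with
#' the two-parameter exponential. The tolerance at 1 (`eps_unit`) is
#' deliberately wider than the boundary tolerance: on series of a dozen
#' visits at clinical noise levels the shape estimate scatters by about
#' 0.1 around its true value, so shapes within that band are not
#' distinguishable from an exponential.
#'
#' @param fit A `traj_fit` with `family = "weibull"`.
#' @param eps Proximity tolerance at the bounds 0.0001 and 5.
#' @param eps_unit Proximity tolerance at b = 1.
#' @return The exponential refit (with attribute `"collapsed_from"`) when
#'   the rule fires, otherwise `fit` unchanged.
#' @export
collapse_weibull <- function(fit, eps = 1e-3, eps_unit = 0.15) {
  stopifnot(inherits(fit, "traj_fit"), fit$family == "weibull")
  if (!fitted_ok(fit)) return(fit)
  b <- fit$coefficients[["b"]]
  if (abs(b - 1e-4) < eps || abs(b - 5) < eps || abs(b - 1) < eps_unit) {
    out <- traj_fit.default(fit$day, fit$value, family = "exponential",
                            A_upper = fit$bounds$A[2L],
                            control = fit$control,
                            variable = fit$variable, subject = fit$subject)
    out$collapsed <- TRUE
    attr(out, "collapsed_from") <- b
    return(out)
  }
  fit
}

#' Fit all four candidate families to one series
#'
#' Runs [traj_fit()] for the linear, exponential, harmonic and Weibull
#' families and applies the boundary collapse rule ([collapse_weibull()])
#' to the Weibull fit.
#'
#' @inheritParams traj_fit.default
#' @param day,value The series.
#' @return A named list of `traj_fit` objects, class `traj_fitlist`.
#' @export
fit_all_families <- function(day, value, A_upper = NULL,
                             control = anneal_control(), variable = NULL,
                             subject = NULL) {
  fits <- lapply(.FAMILIES, function(fam)
    traj_fit.default(day, value, family = fam, A_upper = A_upper,
                     control = control, variable = variable,
                     subject = subject))
  names(fits) <- .FAMILIES
  fits$weibull <- collapse_weibull(fits$weibull)
  structure(fits, class = "traj_fitlist")
}

# ---- methods -------------------------------------------------------------

#' @export
print.traj_fit <- function(x, digits = 4, ...) {
  cat("Trajectory fit:", x$family,
      if (x$collapsed) "(collapsed from weibull)" else "", "\n")
  if (!is.null(x$variable)) cat("Variable:", x$variable, "\n")
  if (!fitted_ok(x)) {
    cat("No fit: only", x$n, "usable points;",
        "baseline-only feature A =", format(x$coefficients[["A"]]), "\n")
    return(invisible(x))
  }
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat("n =", x$n, " SSE =", format(x$sse, digits = digits),
      " RMSE =", format(x$rmse, digits = digits),
      " AICc =", format(x$aicc, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.traj_fit <- function(object, ...) object$coefficients

#' @export
summary.traj_fit <- function(object, ...) {
  structure(list(fit = object,
                 residuals = if (fitted_ok(object))
                   object$value - fitted(object) else numeric(0)),
            class = "summary.traj_fit")
}

#' @export
print.summary.traj_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  if (length(x$residuals)) {
    cat("Residuals:\n")
    print(summary(x$residuals, digits = digits))
    cat("Residual SD (profiled):", format(x$fit$sigma, digits = digits),
        "\n")
  }
  invisible(x)
}

#' @export
fitted.traj_fit <- function(object, ...) {
  stopifnot(fitted_ok(object))
  cf <- object$coefficients
  model_value(object$family, cf[["A"]], cf[["k"]],
              if ("b" %in% names(cf)) cf[["b"]] else 1, object$day)
}

#' @export
residuals.traj_fit <- function(object, ...) object$value - fitted(object)

#' @export
predict.traj_fit <- function(object, newdata = NULL, ...) {
  stopifnot(fitted_ok(object))
  day <- if (is.null(newdata)) object$day
         else if (is.data.frame(newdata)) newdata$day
         else as.numeric(newdata)
  cf <- object$coefficients
  model_value(object$family, cf[["A"]], cf[["k"]],
              if ("b" %in% names(cf)) cf[["b"]] else 1, day)
}

#' @export
plot.traj_fit <- function(x, ..., npoints = 200) {
  stopifnot(fitted_ok(x))
  plot(x$day, x$value, xlab = "day", ylab = x$variable %||% "value",
       main = paste("Trajectory fit:", x$family), ...)
  tt <- seq(min(x$day), max(x$day), length.out = npoints)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' @export
simulate.traj_fit <- function(object, nsim = 1, seed = NULL, ...) {
  stopifnot(fitted_ok(object))
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- as.data.frame(replicate(
    nsim, pmax(mu + rnorm(length(mu), 0, object$sigma), 0)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.traj_fitlist <- function(x, ...) {
  cat("Trajectory fits (", length(x), " families)\n", sep = "")
  for (f in x) print(f)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit trajectories across a cohort
#'
#' Fits the requested model families to every (subject, variable) series
#' in a long-format visit table and returns one row per fit. Series with
#' fewer distinct days than the family needs contribute a baseline-only
#' row (`A` = value at the earliest visit, `k` missing).
#'
#' @param visits Data frame with columns `subject_id`, `variable`, `day`,
#'   `value`.
#' @param families Families to fit (default exponential only, the family
#'   used for downstream feature construction).
#' @param variables Optional subset of variable names.
#' @param alsfrs_variable Name of the ALSFRS-R total-score variable, which
#'   gets the hard baseline bound `A <= 53`.
#' @param control An [anneal_control()].
#' @param seed Integer seed making the annealing reproducible.
#' @return Data frame with columns `subject_id`, `variable`, `family`,
#'   `A`, `k`, `b`, `n`, `sse`, `rmse`, `aicc`, `converged`.
#' @export
fit_trajectories <- function(visits, families = "exponential",
                             variables = NULL,
                             alsfrs_variable = "alsfrs_total",
                             control = anneal_control(), seed = 1L) {
  stopifnot(all(c("subject_id", "variable", "day", "value") %in%
                  names(visits)))
  families <- match.arg(families, .FAMILIES, several.ok = TRUE)
  if (!is.null(variables)) visits <- visits[visits$variable %in% variables, ]
  set.seed(seed)
  key <- interaction(visits$subject_id, visits$variable, drop = TRUE)
  groups <- split(visits, key)
  rows <- vector("list", length(groups) * length(families))
  i <- 0L
  for (g in groups) {
    A_up <- if (g$variable[1L] == alsfrs_variable) 53 else NULL
    for (fam in families) {
      fit <- traj_fit.default(g$day, g$value, family = fam,
                              A_upper = A_up, control = control)
      if (fam == "weibull") fit <- collapse_weibull(fit)
      cf <- fit$coefficients
      i <- i + 1L
      rows[[i]] <- data.frame(
        subject_id = g$subject_id[1L], variable = g$variable[1L],
        family = fit$family, A = cf[["A"]],
        k = if ("k" %in% names(cf)) cf[["k"]] else NA_real_,
        b = if ("b" %in% names(cf)) cf[["b"]] else NA_real_,
        n = fit$n, sse = fit$sse, rmse = fit$rmse, aicc = fit$aicc,
        converged = fitted_ok(fit), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(i)])
  rownames(out) <- NULL
  out
}
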