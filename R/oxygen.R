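#' Steady-state slice oxygen model
#'
#' Parameterizes a one-dimensional two-layer model of oxygen supply to a
#' brain slice in an interface chamber: an unstirred fluid boundary layer of
#' thickness `delta_top` above the slice surface (pure diffusion, far-field
#' concentration `C_top_far` fixed by the chamber atmosphere), tissue of
#' thickness `L` with diffusion coefficient `D_tissue` and Michaelis-Menten
#' oxygen consumption `Vmax * C / (Km + C)`, and a fixed concentration
#' `C_bottom` at the solution-facing lower boundary. `Vmax` is the maximal
#' volumetric consumption rate, i.e. the cerebral metabolic rate of oxygen
#' (CMRO2). A small `Km` (default 1% of `C_top_far`) approximates zero-order
#' consumption at physiological oxygen while keeping anoxic regions
#' well-posed without an explicit free boundary.
#'
#' Concentrations default to arbitrary units normalized to `C_top_far = 1`;
#' calibrated µM values may be supplied instead. The default interface-chamber
#' asymmetry `C_bottom = 0.5 * C_top_far` reflects the weaker supply from the
#' perfusion side.
#'
#' @param L slice thickness in µm (400 for acute ex vivo slices, ~250 for
#'   slice cultures).
#' @param D_tissue,D_fluid oxygen diffusion coefficients in µm²/s for tissue
#'   and for the fluid boundary layer.
#' @param delta_top boundary-layer thickness in µm; `0` pins the surface
#'   concentration to `C_top_far` directly (no convective resistance).
#' @param C_top_far far-field concentration on the gas-facing side.
#' @param C_bottom concentration at the solution-facing boundary (depth `L`).
#' @param Vmax maximal consumption rate (concentration units per second).
#' @param Km Michaelis constant (concentration units).
#' @return An object of class `oxygen_model`.
#' @seealso [forward_profile()], [fit_cmro2()]
#' @export
oxygen_model <- function(L = 400, D_tissue = 1500, D_fluid = 2000,
                         delta_top = 100, C_top_far = 1,
                         C_bottom = 0.5 * C_top_far,
                         Vmax = 0, Km = 0.01 * C_top_far) {
  m <- list(L = L, D_tissue = D_tissue, D_fluid = D_fluid,
            delta_top = delta_top, C_top_far = C_top_far,
            C_bottom = C_bottom, Vmax = Vmax, Km = Km)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("L", "D_tissue", "D_fluid", "Km"))
    if (!num1(m[[f]]) || m[[f]] <= 0) stop("`", f, "` must be > 0")
  if (!num1(m$delta_top) || m$delta_top < 0) stop("`delta_top` must be >= 0")
  if (!num1(m$Vmax) || m$Vmax < 0) stop("`Vmax` must be >= 0")
  if (!num1(m$C_top_far) || m$C_top_far < 0 || !num1(m$C_bottom) || m$C_bottom < 0)
    stop("concentrations must be >= 0")
  structure(m, class = "oxygen_model")
}

#' @export
print.oxygen_model <- function(x, ...) {
  cat(sprintf(paste0("Slice oxygen model: L = %g µm, D_tissue = %g µm²/s, ",
                     "boundary layer %g µm (D_fluid = %g µm²/s)\n",
                     "  C_top_far = %g, C_bottom = %g, Vmax (CMRO2) = %g /s, Km = %g\n"),
              x$L, x$D_tissue, x$delta_top, x$D_fluid,
              x$C_top_far, x$C_bottom, x$Vmax, x$Km))
  invisible(x)
}

#' Oxygen depth profile
#'
#' Depth-resolved oxygen concentration through a slice, with depth 0 at the
#' gas-facing surface and increasing into the tissue.
#'
#' @param depth strictly increasing depths in µm.
#' @param concentration non-negative concentrations (arbitrary units or µM).
#' @param atmosphere gas phase above the slice, e.g. `"95%"` or `"20%"`.
#' @param meta optional list of sensor/provenance metadata.
#' @return An object of class `oxygen_profile`.
#' @export
oxygen_profile <- function(depth, concentration, atmosphere = "95%", meta = list()) {
  depth <- as.numeric(depth)
  concentration <- as.numeric(concentration)
  if (length(depth) != length(concentration) || !length(depth))
    stop("`depth` and `concentration` must be non-empty and equal length")
  if (is.unsorted(depth, strictly = TRUE)) stop("`depth` must be strictly increasing")
  if (any(depth < 0)) stop("`depth` must be >= 0")
  if (any(concentration < -1e-9)) stop("`concentration` must be >= 0")
  structure(list(depth = depth, concentration = pmax(concentration, 0),
                 atmosphere = atmosphere, meta = meta),
            class = "oxygen_profile")
}

#' @export
print.oxygen_profile <- function(x, ...) {
  cat(sprintf("Oxygen depth profile: %d points over [%g, %g] µm, atmosphere %s\n",
              length(x$depth), min(x$depth), max(x$depth), x$atmosphere))
  cat(sprintf("  concentration range [%.4g, %.4g], lowest O2 = %.4g\n",
              min(x$concentration), max(x$concentration), lowest_o2(x)))
  invisible(x)
}

#' @export
as.data.frame.oxygen_profile <- function(x, ...) {
  data.frame(depth_um = x$depth, o2 = x$concentration)
}

#' @param x an `oxygen_profile`.
#' @param ... passed to [graphics::plot()].
#' @rdname oxygen_profile
#' @export
plot.oxygen_profile <- function(x, ...) {
  graphics::plot(x$depth, x$concentration, type = "b", pch = 16, cex = 0.6,
                 xlab = "depth (µm)", ylab = "O2 concentration", ...)
  invisible(x)
}

#' Read and write oxygen depth profiles as two-column CSV
#'
#' The on-disk format is `depth_um, o2`.
#'
#' @param path file path.
#' @param atmosphere,meta passed to [oxygen_profile()] on read.
#' @export
read_oxygen_csv <- function(path, atmosphere = "95%", meta = list()) {
  if (!file.exists(path)) stop("input file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L || !all(c("depth_um", "o2") %in% names(dt)))
    stop("expected columns `depth_um, o2` in ", path)
  oxygen_profile(dt$depth_um, dt$o2, atmosphere = atmosphere, meta = meta)
}

#' @param profile an [oxygen_profile()].
#' @rdname read_oxygen_csv
#' @export
write_oxygen_csv <- function(profile, path) {
  stopifnot(inherits(profile, "oxygen_profile"))
  data.table::fwrite(as.data.frame(profile), path)
  invisible(path)
}

# ---- forward boundary-value solver ------------------------------------------

# Solve an "almost tridiagonal" system: tridiagonal plus one extra entry
# J[1,3] (from the second-order one-sided Robin boundary stencil). The extra
# entry is eliminated against row 2, then the Thomas algorithm runs.
solve_robin_tridiag <- function(sub, diag, sup, extra13, rhs) {
  m <- length(diag)
  if (extra13 != 0) {
    fac <- extra13 / sup[2L]
    diag[1L] <- diag[1L] - fac * sub[2L]
    sup[1L] <- sup[1L] - fac * diag[2L]
    rhs[1L] <- rhs[1L] - fac * rhs[2L]
  }
  # forward sweep
  for (i in 2:m) {
    w <- sub[i] / diag[i - 1L]
    diag[i] <- diag[i] - w * sup[i - 1L]
    rhs[i] <- rhs[i] - w * rhs[i - 1L]
  }
  x <- numeric(m)
  x[m] <- rhs[m] / diag[m]
  for (i in (m - 1L):1L) x[i] <- (rhs[i] - sup[i] * x[i + 1L]) / diag[i]
  x
}

# residual of the discretized BVP at iterate C
oxygen_bvp_residual <- function(C, mod, h) {
  m <- length(C)
  res <- numeric(m)
  if (mod$delta_top > 0) {
    res[1L] <- mod$D_tissue * (-3 * C[1L] + 4 * C[2L] - C[3L]) / (2 * h) -
      (mod$D_fluid / mod$delta_top) * (C[1L] - mod$C_top_far)
  } else {
    res[1L] <- C[1L] - mod$C_top_far
  }
  i <- 2:(m - 1L)
  res[i] <- mod$D_tissue * (C[i - 1L] - 2 * C[i] + C[i + 1L]) / h^2 -
    mod$Vmax * C[i] / (mod$Km + C[i])
  res[m] <- C[m] - mod$C_bottom
  res
}

#' Forward solution of the slice oxygen model
#'
#' Solves the steady-state reaction-diffusion boundary-value problem
#' `D_tissue * C'' = Vmax * C / (Km + C)` on `[0, L]` with a convective
#' (Robin) boundary at the gas-facing surface — flux continuity through the
#' fluid boundary layer, `D_tissue C'(0) = (D_fluid / delta_top) (C(0) -
#' C_top_far)` — and a fixed concentration `C_bottom` at depth `L`. The
#' discretization is second-order finite differences (including the one-sided
#' surface stencil) with damped Newton iteration; anoxic regions are handled
#' by the saturable kinetics, so no explicit free boundary is needed.
#'
#' @param model an [oxygen_model()].
#' @param n_grid number of uniform grid points over `[0, L]`.
#' @param tol Newton convergence tolerance on the max-norm update, relative
#'   to `max(C_top_far, C_bottom)`.
#' @param max_iter maximum Newton iterations.
#' @return An [oxygen_profile()] on the uniform grid; the converged iteration
#'   count is recorded in `meta$n_iter`.
#' @examples
#' m <- oxygen_model(Vmax = 0.05)
#' prof <- forward_profile(m)
#' lowest_o2(prof)
#' @export
forward_profile <- function(model, n_grid = 401L, tol = 1e-12, max_iter = 100L) {
  stopifnot(inherits(model, "oxygen_model"))
  m <- as.integer(n_grid)
  if (m < 5L) stop("`n_grid` must be at least 5")
  h <- model$L / (m - 1L)
  z <- seq(0, model$L, length.out = m)
  cscale <- max(model$C_top_far, model$C_bottom, model$Km)
  # initial iterate: linear between the boundary concentrations
  C <- seq(model$C_top_far, model$C_bottom, length.out = m)
  res <- oxygen_bvp_residual(C, model, h)
  rnorm0 <- function(r) max(abs(r))
  for (iter in seq_len(max_iter)) {
    # Jacobian bands
    sub <- c(0, rep(model$D_tissue / h^2, m - 2L), 0)
    dg <- c(0, -2 * model$D_tissue / h^2 -
              model$Vmax * model$Km / (model$Km + C[2:(m - 1L)])^2, 1)
    sup <- c(0, rep(model$D_tissue / h^2, m - 2L), 0)
    extra13 <- 0
    if (model$delta_top > 0) {
      dg[1L] <- -3 * model$D_tissue / (2 * h) - model$D_fluid / model$delta_top
      sup[1L] <- 4 * model$D_tissue / (2 * h)
      extra13 <- -model$D_tissue / (2 * h)
    } else {
      dg[1L] <- 1
      sup[1L] <- 0
    }
    dC <- solve_robin_tridiag(sub, dg, sup, extra13, -res)
    # damped update with positivity clamp
    step <- 1
    repeat {
      Cn <- pmax(C + step * dC, 0)
      resn <- oxygen_bvp_residual(Cn, model, h)
      if (rnorm0(resn) <= rnorm0(res) * (1 - 1e-4 * step) + 1e-30 || step < 1e-6) break
      step <- step / 2
    }
    upd <- max(abs(Cn - C))
    C <- Cn
    res <- resn
    if (upd < tol * cscale && rnorm0(res) < 1e-8 * model$D_tissue * cscale / h^2) {
      return(oxygen_profile(z, C, meta = list(n_iter = iter, model = unclass(model))))
    }
  }
  stop(sprintf(paste0("oxygen BVP solver did not converge in %d iterations ",
                      "(residual max %.3g, last update %.3g); ",
                      "check model parameters"), max_iter, rnorm0(res), upd))
}

#' Lowest oxygen concentration of a depth profile
#'
#' @param profile an [oxygen_profile()].
#' @return The minimum concentration over depth (the deepest point for a
#'   monotone profile, the mid-slab trough for symmetric supply).
#' @export
lowest_o2 <- function(profile) {
  stopifnot(inherits(profile, "oxygen_profile"))
  min(profile$concentration)
}

# ---- CMRO2 inversion --------------------------------------------------------

#' Estimate CMRO2 from an oxygen depth profile
#'
#' Fits the forward slice model to a measured depth profile by nonlinear
#' least squares, with the maximal consumption rate `Vmax` (the CMRO2) free
#' and optionally the lower boundary concentration `C_bottom` as well; all
#' other parameters are fixed by `template`. Three initial `Vmax` values
#' (scaled from a curvature-based guess) are tried and the best residual
#' wins, guarding against local minima.
#'
#' @param profile an [oxygen_profile()] with at least 10 depth points.
#' @param template an [oxygen_model()] fixing all non-free parameters.
#' @param free character vector: `"Vmax"` or `c("Vmax", "C_bottom")`.
#' @param n_grid forward-solver grid resolution used during fitting.
#' @return An object of class `cmro2_fit` with components `CMRO2_hat`,
#'   `C_bottom_hat`, `residual_rms`, `lowest_O2` (of the fitted curve),
#'   `converged`, `n_iter` (total objective evaluations), `starts`
#'   (per-start diagnostics), the fitted `model`, `profile` and a dense
#'   `curve`. Supports `coef()`, `predict()`, `fitted()`, `residuals()`,
#'   `simulate()`, `plot()`, `print()` and `summary()`.
#' @examples
#' truth <- oxygen_model(Vmax = 0.05)
#' prof <- gen_oxygen_profile(truth, seq(0, 400, by = 10), noise_sd = 0.02, seed = 7)
#' fit <- fit_cmro2(prof, oxygen_model())
#' coef(fit)
#' @export
fit_cmro2 <- function(profile, template, free = "Vmax", n_grid = 201L) {
  stopifnot(inherits(profile, "oxygen_profile"), inherits(template, "oxygen_model"))
  if (length(profile$depth) < 10L)
    stop("CMRO2 fitting needs at least 10 depth points")
  if (!all(free %in% c("Vmax", "C_bottom")) || !"Vmax" %in% free)
    stop('`free` must be "Vmax" or c("Vmax", "C_bottom")')
  fit_cb <- "C_bottom" %in% free

  n_eval <- 0L
  objective <- function(par) {
    n_eval <<- n_eval + 1L
    mod <- template
    mod$Vmax <- par[1L]
    if (fit_cb) mod$C_bottom <- par[2L]
    fwd <- tryCatch(forward_profile(mod, n_grid = n_grid),
                    error = function(e) NULL)
    if (is.null(fwd)) return(1e12)
    pred <- stats::spline(fwd$depth, fwd$concentration, xout = profile$depth)$y
    sum((pred - profile$concentration)^2)
  }

  # curvature-based initial guess: for near-zero-order consumption the
  # depletion below the supply level scales as Vmax * L^2 / (8 D)
  depl <- max(template$C_top_far - max(min(profile$concentration), 0), 1e-3 * template$C_top_far)
  v_guess <- 8 * template$D_tissue * depl / template$L^2
  starts <- v_guess * c(0.3, 1, 3)

  runs <- lapply(starts, function(v0) {
    par0 <- if (fit_cb) c(v0, template$C_bottom) else v0
    lo <- if (fit_cb) c(0, 0) else 0
    hi <- if (fit_cb) c(Inf, 2 * max(template$C_top_far, template$C_bottom, 1)) else Inf
    tryCatch(
      stats::optim(par0, objective, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(factr = 1e2, maxit = 200,
                                  parscale = pmax(abs(par0), 1e-8))),
      error = function(e) list(par = par0, value = Inf, convergence = 1L,
                               message = conditionMessage(e))
    )
  })
  vals <- vapply(runs, function(r) r$value, numeric(1))
  best <- runs[[which.min(vals)]]
  converged <- is.finite(best$value) && best$value < 1e12 &&
    identical(best$convergence, 0L)

  mod <- template
  mod$Vmax <- best$par[1L]
  if (fit_cb) mod$C_bottom <- best$par[2L]
  curve <- if (converged || best$value < 1e12)
    forward_profile(mod, n_grid = max(n_grid, 401L)) else NULL

  structure(list(
    CMRO2_hat = best$par[1L],
    C_bottom_hat = if (fit_cb) best$par[2L] else template$C_bottom,
    residual_rms = sqrt(best$value / length(profile$depth)),
    lowest_O2 = if (!is.null(curve)) lowest_o2(curve) else NA_real_,
    converged = converged,
    n_iter = n_eval,
    starts = data.frame(Vmax_start = starts, ssr = vals),
    free = free, model = mod, profile = profile, curve = curve,
    call = match.call()
  ), class = "cmro2_fit")
}

#' @export
print.cmro2_fit <- function(x, ...) {
  cat("CMRO2 fit (steady-state diffusion-consumption model)\n")
  cat(sprintf("  CMRO2 (Vmax): %.6g concentration/s%s\n", x$CMRO2_hat,
              if ("C_bottom" %in% x$free)
                sprintf(";  C_bottom: %.4g", x$C_bottom_hat) else ""))
  cat(sprintf("  residual RMS: %.4g;  lowest O2 of fit: %.4g;  converged: %s\n",
              x$residual_rms, x$lowest_O2, x$converged))
  invisible(x)
}

#' @export
summary.cmro2_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.cmro2_fit")
}

#' @export
print.summary.cmro2_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  %d depth points over [%g, %g] µm; %d objective evaluations\n",
              length(f$profile$depth), min(f$profile$depth),
              max(f$profile$depth), f$n_iter))
  cat("  multi-start diagnostics:\n")
  print(f$starts, row.names = FALSE)
  cat("  fixed parameters: ")
  fixed <- unclass(f$model)[setdiff(names(f$model), c("Vmax", "C_bottom"))]
  cat(paste(sprintf("%s = %g", names(fixed), unlist(fixed)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.cmro2_fit <- function(object, ...) {
  out <- c(Vmax = object$CMRO2_hat)
  if ("C_bottom" %in% object$free) out <- c(out, C_bottom = object$C_bottom_hat)
  out
}

#' @param object a `cmro2_fit`.
#' @param depth depths (µm) at which to evaluate the fitted profile; defaults
#'   to the measured depths.
#' @rdname fit_cmro2
#' @export
predict.cmro2_fit <- function(object, depth = NULL, ...) {
  if (is.null(object$curve)) stop("fit did not converge; no fitted curve")
  if (is.null(depth)) depth <- object$profile$depth
  stats::spline(object$curve$depth, object$curve$concentration, xout = depth)$y
}

#' @export
fitted.cmro2_fit <- function(object, ...) predict(object)

#' @export
residuals.cmro2_fit <- function(object, ...) {
  object$profile$concentration - fitted(object)
}

#' @export
plot.cmro2_fit <- function(x, ...) {
  graphics::plot(x$profile$depth, x$profile$concentration, pch = 16, cex = 0.6,
                 xlab = "depth (µm)", ylab = "O2 concentration", ...)
  if (!is.null(x$curve))
    graphics::lines(x$curve$depth, x$curve$concentration, col = "firebrick", lwd = 2)
  graphics::legend("topright", bty = "n", pch = c(16, NA), lty = c(NA, 1),
                   col = c("black", "firebrick"),
                   legend = c("measured", sprintf("fit: CMRO2 = %.3g /s", x$CMRO2_hat)))
  invisible(x)
}

#' @export
simulate.cmro2_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$curve)) stop("fit did not converge; cannot simulate")
  sd <- object$residual_rms
  base_seed <- if (is.null(seed)) stats::runif(1, 1, 2^31 - 1) else seed
  lapply(seq_len(nsim), function(i) {
    gen_oxygen_profile(object$model, object$profile$depth, noise_sd = sd,
                       seed = as.integer(base_seed) + i - 1L,
                       atmosphere = object$profile$atmosphere)
  })
}

#' Contrast two CMRO2 estimates
#'
#' Fold and percent change between two fitted consumption rates, the form in
#' which state contrasts (e.g. gamma oscillations versus sharp wave-ripples)
#' are reported.
#'
#' @param fit_a,fit_b `cmro2_fit` objects (or bare non-negative numbers).
#' @return A list with `fold_change` (`a / b`) and `percent_change`
#'   (`100 * (a - b) / b`).
#' @export
cmro2_contrast <- function(fit_a, fit_b) {
  val <- function(f) {
    if (inherits(f, "cmro2_fit")) {
      if (!isTRUE(f$converged)) stop("cannot contrast a non-converged fit")
      f$CMRO2_hat
    } else as.numeric(f)
  }
  a <- val(fit_a)
  b <- val(fit_b)
  if (b == 0) stop("reference CMRO2 is zero; contrast undefined")
  list(fold_change = a / b, percent_change = 100 * (a - b) / b)
}
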