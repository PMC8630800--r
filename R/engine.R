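#' Fitting options for the Gauss-Newton engine
#'
#' @param sign_stop SIGN convergence threshold (default `1e-9`).
#' @param stop_window Number of consecutive iterations that must satisfy the
#'   stopping criteria (default 3).
#' @param cost_slack Fractional slack on the best-ever cost for stopping
#'   (default 0.10: the last `stop_window` costs must lie within 10 percent
#'   of the lowest cost encountered).
#' @param stall_window Iterations inspected by the stall detector (default 3).
#' @param stall_rel_dev Relative spread below which SIGN and cost are deemed
#'   flat (default 0.01).
#' @param fd_rel_step Relative central-difference step (default `1e-4`);
#'   the absolute step for parameter k is
#'   `fd_rel_step * max(|p_k|, 0.01 * (hi_k - lo_k))`.
#' @param max_iters Total iteration budget (default 200).
#' @param max_restarts Random-restart budget (default 20).
#' @param armijo_c1 Armijo sufficient-decrease constant (default `1e-4`).
#' @param armijo_shrink Step-halving factor (default 0.5).
#' @param armijo_max_backtracks Maximum backtracks (default 25).
#' @param rcond_min Reciprocal-condition threshold below which the
#'   Gauss-Newton system is declared (nearly) singular (default `1e-12`).
#' @param sign_variant `"elementwise"` (norm of the elementwise product of
#'   gradient and standard errors; default) or `"scalar"` (absolute value of
#'   the scalar product) -- two readings of the same scale-invariant metric.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(sign_stop = 1e-9, stop_window = 3, cost_slack = 0.10,
                        stall_window = 3, stall_rel_dev = 0.01,
                        fd_rel_step = 1e-4, max_iters = 200, max_restarts = 20,
                        armijo_c1 = 1e-4, armijo_shrink = 0.5,
                        armijo_max_backtracks = 25, rcond_min = 1e-12,
                        sign_variant = c("elementwise", "scalar")) {
  stopifnot(sign_stop > 0, stop_window >= 1, cost_slack > 0,
            stall_window >= 1, stall_rel_dev > 0, fd_rel_step > 0,
            max_iters >= 1, max_restarts >= 0)
  structure(list(sign_stop = sign_stop, stop_window = stop_window,
                 cost_slack = cost_slack, stall_window = stall_window,
                 stall_rel_dev = stall_rel_dev, fd_rel_step = fd_rel_step,
                 max_iters = max_iters, max_restarts = max_restarts,
                 armijo_c1 = armijo_c1, armijo_shrink = armijo_shrink,
                 armijo_max_backtracks = armijo_max_backtracks,
                 rcond_min = rcond_min,
                 sign_variant = match.arg(sign_variant)),
            class = "fit_options")
}

stall_signal <- function(reason) {
  structure(list(reason = reason), class = "stall_signal")
}

is_stall <- function(x) inherits(x, "stall_signal")

#' Weighted least-squares cost
#'
#' `C = sum(w_i r_i^2)` with diagonal inverse-variance weights; with unit
#' weights this is the squared residual norm.
#'
#' @param residual Residual vector `r = D - M(p)`.
#' @param weights Nonnegative weights (recycled scalar allowed).
#' @return Scalar `C >= 0`.
#' @export
ls_cost <- function(residual, weights = 1) {
  if (length(weights) != 1 && length(weights) != length(residual))
    stop("ls_cost: length mismatch between residual and weights")
  sum(weights * residual^2)
}

#' Central-difference Jacobian
#'
#' Column k is `dM/dp_k` by central differences, using exactly `2 * N_p`
#' model evaluations.  Evaluation points are clipped into the bounds and the
#' divisor adjusted, so parameters at a boundary get a one-sided-shifted
#' stencil of the same width.
#'
#' @param model_fn Function mapping a parameter vector to a numeric vector.
#' @param p Parameter vector.
#' @param bounds 2-row matrix (lo, hi) or NULL for unbounded.
#' @param fd_rel_step Relative step size.
#' @param counter Optional environment with an `evals` field to increment.
#' @return `length(M) x length(p)` matrix.
#' @export
jacobian_fd <- function(model_fn, p, bounds = NULL, fd_rel_step = 1e-4,
                        counter = NULL) {
  np <- length(p)
  scale <- if (is.null(bounds)) pmax(abs(p), 1e-8) else {
    pmax(abs(p), 0.01 * (bounds[2, ] - bounds[1, ]))
  }
  h <- fd_rel_step * scale
  J <- NULL
  for (k in seq_len(np)) {
    ph <- p; pl <- p
    hi <- if (is.null(bounds)) p[k] + h[k] else min(p[k] + h[k], bounds[2, k])
    lo <- if (is.null(bounds)) p[k] - h[k] else max(p[k] - h[k], bounds[1, k])
    if (hi <= lo) { hi <- p[k] + h[k]; lo <- p[k] - h[k] } # degenerate bounds
    ph[k] <- hi; pl[k] <- lo
    mh <- model_fn(ph); ml <- model_fn(pl)
    if (!is.null(counter)) counter$evals <- counter$evals + 2L
    col <- (mh - ml) / (hi - lo)
    if (any(!is.finite(col)))
      stop("jacobian_fd: non-finite model output while differencing parameter ",
           if (!is.null(names(p))) names(p)[k] else k)
    if (is.null(J)) J <- matrix(0, length(col), np)
    J[, k] <- col
  }
  colnames(J) <- names(p)
  J
}

#' Gradient of the least-squares cost
#'
#' `grad C = -2 r^T W J` (row vector) for residual `r = D - M(p)`.
#'
#' @param residual Residual vector.
#' @param weights Weights (scalar or vector).
#' @param J Jacobian matrix.
#' @return `1 x N_p` matrix.
#' @export
ls_gradient <- function(residual, weights, J) {
  if (nrow(J) != length(residual))
    stop("ls_gradient: shape mismatch")
  -2 * crossprod(residual * weights, J)[1, , drop = FALSE] -> g
  matrix(g, 1, ncol(J), dimnames = list(NULL, colnames(J)))
}

#' Gauss-Newton Hessian approximation
#'
#' `hess C ~ 2 J^T W J`; symmetric positive semi-definite by construction.
#'
#' @param J Jacobian matrix.
#' @param weights Weights (scalar or vector).
#' @return `N_p x N_p` matrix.
#' @export
gn_hessian <- function(J, weights = 1) {
  H <- 2 * crossprod(J * sqrt(weights))
  (H + t(H)) / 2
}

#' Solve the Gauss-Newton step
#'
#' Solves `hess . dp = -grad^T`.  A reciprocal condition estimate below
#' `rcond_min` raises a stall signal instead of returning an unreliable step.
#'
#' @param hessian Gauss-Newton Hessian.
#' @param gradient `1 x N_p` gradient.
#' @param rcond_min Near-singularity threshold.
#' @return Step vector, or a `stall_signal` with reason
#'   `"singular_hessian"`.
#' @export
solve_step <- function(hessian, gradient, rcond_min = 1e-12) {
  d <- sqrt(diag(hessian))
  if (any(!is.finite(d)) || any(d <= 0))
    return(stall_signal("singular_hessian"))
  # Jacobi-scale to unit diagonal so the condition estimate measures
  # collinearity rather than parameter units
  Hn <- hessian / outer(d, d)
  rc <- tryCatch(rcond(Hn), error = function(e) 0)
  if (!is.finite(rc) || rc < rcond_min)
    return(stall_signal("singular_hessian"))
  dp <- tryCatch(solve(Hn, -as.vector(gradient) / d) / d,
                 error = function(e) NULL)
  if (is.null(dp) || any(!is.finite(dp)))
    return(stall_signal("singular_hessian"))
  dp
}

#' Backtracking line search under the Armijo condition
#'
#' Halves the step fraction `s` from 1 until
#' `C(p + s dp) <= C(p) + c1 * s * grad . dp`.  An ascent direction or an
#' exhausted backtrack budget raises a stall signal.
#'
#' @param p Current parameters.
#' @param dp Proposed step.
#' @param cost_fn Function `p -> C(p)`.
#' @param gradient `1 x N_p` gradient at `p`.
#' @param c_current `C(p)` (avoids recomputation).
#' @param options A [fit_options()] object.
#' @return List with `s`, `p_new`, `cost_new`, or a `stall_signal`
#'   (reason `"line_search"`).
#' @export
armijo_backtrack <- function(p, dp, cost_fn, gradient, c_current, options) {
  if (any(!is.finite(dp))) return(stall_signal("line_search"))
  slope <- sum(as.vector(gradient) * dp)
  if (slope >= 0) return(stall_signal("line_search"))
  s <- 1
  # allow for roundoff in the cost when the sufficient-decrease margin is
  # below machine precision (near convergence)
  tol0 <- 1e-12 * abs(c_current)
  for (i in seq_len(options$armijo_max_backtracks + 1)) {
    p_new <- p + s * dp
    cn <- cost_fn(p_new)
    if (is.finite(cn) && cn <= c_current + options$armijo_c1 * s * slope + tol0)
      return(list(s = s, p_new = p_new, cost_new = cn))
    s <- s * options$armijo_shrink
  }
  stall_signal("line_search")
}

#' Project a step onto the parameter box (plus optional constraint surface)
#'
#' Clamps `p + dp` into `[lo, hi]` per parameter; an additional projection
#' function (e.g., enforcing `inv_t_hom > inv_t_lt / 2`) is applied
#' afterwards.  Returns the corrected step and which bounds went active.
#'
#' @param p Current parameters (inside bounds).
#' @param dp Proposed step.
#' @param bounds 2-row matrix (lo, hi), or NULL.
#' @param project Optional function `p -> p` projecting onto a constraint
#'   surface.
#' @return List with `dp` (corrected), `p_new`, and logical `active`.
#' @export
apply_bounds <- function(p, dp, bounds = NULL, project = NULL) {
  p_new <- p + dp
  if (!is.null(bounds)) p_new <- pmin(pmax(p_new, bounds[1, ]), bounds[2, ])
  if (!is.null(project)) p_new <- project(p_new)
  list(dp = p_new - p, p_new = p_new,
       active = if (is.null(bounds)) rep(FALSE, length(p)) else
         (p_new <= bounds[1, ] + 0 | p_new >= bounds[2, ] - 0) &
         (abs(p_new - (p + dp)) > 0))
}

#' Scale-invariant gradient norm (SIGN)
#'
#' `SIGN_i = || grad C(p_i) * sigma_p(p_i) || / C(p_{i-1})` with the
#' elementwise product of the gradient and the per-parameter standard errors
#' (diagonal root of the scaled covariance).  By construction SIGN is
#' invariant to rescaling data and model by a common factor, to rescaling
#' the weights, and to the number of data points.  The denominator is the
#' cost of the previous iteration, which is better behaved across random
#' restarts.
#'
#' @param gradient `1 x N_p` gradient at iteration i.
#' @param sigma_p Per-parameter standard errors at iteration i.
#' @param cost_prev Cost at iteration i - 1 (`> 0`; a zero cost
#'   short-circuits to SIGN = 0, i.e. converged).
#' @param variant `"elementwise"` or `"scalar"` (see [fit_options()]).
#' @return Scalar `SIGN >= 0`.
#' @export
sign_metric <- function(gradient, sigma_p, cost_prev,
                        variant = "elementwise") {
  if (cost_prev <= 0) return(0)
  g <- as.vector(gradient)
  if (variant == "scalar") abs(sum(g * sigma_p)) / cost_prev
  else sqrt(sum((g * sigma_p)^2)) / cost_prev
}

#' Stopping criterion
#'
#' TRUE when the last `stop_window` SIGN values are below `sign_stop` and
#' the last `stop_window` costs are within `cost_slack` of the lowest cost
#' encountered so far.
#'
#' @param state Fit state list with `sign_trace`, `cost_trace`, `best_cost`,
#'   `iters_since_restart`.
#' @param options A [fit_options()] object.
#' @return Logical.
#' @export
check_stop <- function(state, options) {
  w <- options$stop_window
  n <- length(state$sign_trace)
  if (state$iters_since_restart < w || n < w) return(FALSE)
  s <- state$sign_trace[(n - w + 1):n]
  cc <- state$cost_trace[(n - w + 1):n]
  isTRUE(all(s < options$sign_stop)) &&
    isTRUE(all(cc <= (1 + options$cost_slack) * state$best_cost))
}

#' Stall criterion
#'
#' TRUE when, while the stopping criterion is not met, SIGN and the cost
#' have each varied by less than `stall_rel_dev` (relative spread) over the
#' last `stall_window` iterations, or when a stall signal (singular system,
#' failed line search) was raised.
#'
#' @inheritParams check_stop
#' @return Logical.
#' @export
check_stall <- function(state, options) {
  if (isTRUE(state$stall_flag)) return(TRUE)
  w <- options$stall_window
  n <- length(state$sign_trace)
  if (state$iters_since_restart < w || n < w) return(FALSE)
  if (check_stop(state, options)) return(FALSE)
  rel_spread <- function(x) {
    m <- mean(abs(x))
    if (m == 0) 0 else (max(x) - min(x)) / m
  }
  s <- state$sign_trace[(n - w + 1):n]
  cc <- state$cost_trace[(n - w + 1):n]
  if (anyNA(s)) return(FALSE)
  rel_spread(s) < options$stall_rel_dev &&
    rel_spread(cc) < options$stall_rel_dev
}

#' Uniform random restart within bounds
#'
#' @param bounds 2-row matrix (lo, hi); all entries must be finite.
#' @return New parameter vector drawn uniformly within the box.
#' @export
random_restart <- function(bounds) {
  if (is.null(bounds) || any(!is.finite(bounds)))
    stop("random_restart: all parameters need finite bounds")
  p <- bounds[1, ] + runif(ncol(bounds)) * (bounds[2, ] - bounds[1, ])
  names(p) <- colnames(bounds)
  p
}

#' Gauss-Newton least-squares fit with SIGN stopping and random restarts
#'
#' Iterates finite-difference Jacobian, Gauss-Newton step, Armijo
#' backtracking, boundary correction, SIGN evaluation, and stop/stall checks
#' until convergence or budget exhaustion.  Stalls (flat SIGN and cost,
#' singular system, failed line search, or a boundary-rejected step) trigger
#' a uniform random restart within the bounds.  The returned parameters are
#' the best (lowest-cost) ever visited; covariance, confidence intervals and
#' VIFs are evaluated there.
#'
#' @param data Numeric data vector `D`.
#' @param model_fn Function `p -> M(p)` returning a vector conformable with
#'   `data`.
#' @param p0 Initial parameter vector (named; inside bounds).
#' @param bounds 2-row matrix (rows lo, hi; columns follow `p0`), or NULL
#'   for an unbounded fit (restarts then unavailable).
#' @param weights Diagonal inverse-variance weights (scalar or vector).
#' @param options A [fit_options()] object.
#' @param project Optional constraint projection applied after the box
#'   clamp (see [apply_bounds()]).
#' @return A list of class `fit_result`: `p_hat`, `vcov`, `sigma`, `ci95`,
#'   `vif`, `status` (`"converged"` or `"budget_exhausted"`), `state`
#'   (traces and restart log), `n_evals`, `boundary_active`.
#' @export
fit_ls <- function(data, model_fn, p0, bounds = NULL, weights = 1,
                   options = fit_options(), project = NULL) {
  np <- length(p0)
  nd <- length(data)
  if (nd <= np) stop("fit_ls: need more data points than parameters")
  if (!is.null(bounds)) {
    bounds <- as.matrix(bounds)
    stopifnot(nrow(bounds) == 2, ncol(bounds) == np,
              all(bounds[1, ] < bounds[2, ]))
    colnames(bounds) <- names(p0)
  }
  counter <- new.env()
  counter$evals <- 0L
  counter$last_p <- NULL
  counter$last_m <- NULL
  cost_fn <- function(p) {
    m <- model_fn(p)
    counter$evals <- counter$evals + 1L
    counter$last_p <- p
    counter$last_m <- m
    ls_cost(data - m, weights)
  }
  model_at <- function(p) { # reuse the line search's last evaluation
    if (!is.null(counter$last_p) && identical(counter$last_p, p))
      return(counter$last_m)
    m <- model_fn(p)
    counter$evals <- counter$evals + 1L
    m
  }
  clamp <- function(p) {
    if (!is.null(bounds)) p <- pmin(pmax(p, bounds[1, ]), bounds[2, ])
    if (!is.null(project)) p <- project(p)
    p
  }

  p <- clamp(p0)
  c_cur <- cost_fn(p)
  c_prev <- c_cur
  # absolute floor: a cost this far below the data scale is a perfect fit
  # (noiseless round trips collapse to the arithmetic floor, where the
  # relative stopping window is meaningless)
  perfect_floor <- 1e-24 * max(ls_cost(data, weights), .Machine$double.xmin)
  state <- list(cost_trace = numeric(0), sign_trace = numeric(0),
                restart_log = list(), best_cost = c_cur, best_p = p,
                iters_since_restart = 0L, stall_flag = FALSE)
  status <- "budget_exhausted"
  restarts <- 0L

  do_restart <- function(reason, it) {
    state$restart_log[[length(state$restart_log) + 1L]] <<-
      list(iteration = it, reason = reason)
    p <<- clamp(random_restart(bounds))
    c_cur <<- cost_fn(p)
    c_prev <<- c_cur
    state$iters_since_restart <<- 0L
    state$stall_flag <<- FALSE
  }

  for (it in seq_len(options$max_iters)) {
    r <- data - model_at(p)
    J <- jacobian_fd(model_fn, p, bounds, options$fd_rel_step, counter)
    grad <- ls_gradient(r, weights, J)
    H <- gn_hessian(J, weights)

    # per-iteration standard errors for SIGN (Jacobi-scaled inversion)
    gram <- H / 2
    dg <- sqrt(diag(gram))
    sigma_p <- if (all(is.finite(dg)) && all(dg > 0)) tryCatch({
      vd <- diag(solve(gram / outer(dg, dg))) / dg^2
      sqrt(pmax(vd * c_cur / (nd - np), 0))
    }, error = function(e) NULL) else NULL

    stall_now <- NULL
    if (is.null(sigma_p)) {
      stall_now <- "singular_hessian"
      sg <- NA_real_
    } else {
      sg <- sign_metric(grad, sigma_p, c_prev, options$sign_variant)
    }

    boundary_hit <- FALSE
    if (is.null(stall_now)) {
      dp <- solve_step(H, grad, options$rcond_min)
      if (is_stall(dp)) stall_now <- dp$reason
    }
    if (is.null(stall_now)) {
      # correct the step by the boundaries first, then search along the
      # corrected (feasible) direction; the feasible set is convex, so
      # every backtracked point stays feasible
      bb <- apply_bounds(p, dp, bounds, project)
      boundary_hit <- any(bb$active) || max(abs(bb$dp - dp)) > 0
      if (max(abs(bb$dp)) == 0) stall_now <- "boundary"
    }
    if (is.null(stall_now)) {
      ls <- armijo_backtrack(p, bb$dp, cost_fn, grad, c_cur, options)
      if (is_stall(ls))
        stall_now <- if (boundary_hit) "boundary" else ls$reason
    }
    c_prev <- c_cur
    if (is.null(stall_now)) {
      p <- ls$p_new
      # the roundoff allowance in the line search can admit an increase of
      # order 1e-12 C; clamp the recorded cost so traces never increase
      c_cur <- min(ls$cost_new, c_cur)
    }

    state$cost_trace <- c(state$cost_trace, c_cur)
    state$sign_trace <- c(state$sign_trace, sg)
    state$iters_since_restart <- state$iters_since_restart + 1L
    if (c_cur < state$best_cost) {
      state$best_cost <- c_cur
      state$best_p <- p
    }
    if (!is.null(stall_now)) state$stall_flag <- TRUE

    if (check_stop(state, options) || c_cur <= perfect_floor) {
      status <- "converged"
      break
    }
    if (check_stall(state, options)) {
      if (is.null(bounds) || restarts >= options$max_restarts) {
        status <- "budget_exhausted"
        break
      }
      restarts <- restarts + 1L
      do_restart(if (!is.null(stall_now)) stall_now else "stall", it)
    }
  }

  p_hat <- state$best_p
  J <- jacobian_fd(model_fn, p_hat, bounds, options$fd_rel_step, counter)
  r <- data - model_fn(p_hat)
  chat <- ls_cost(r, weights)
  rep_cov <- tryCatch(ls_covariance(J, weights, chat, nd, np),
                      error = function(e) NULL)
  vifrep <- tryCatch(vif(J, weights), error = function(e) NULL)
  res <- list(p_hat = p_hat,
              cost = chat,
              vcov = rep_cov$vcov,
              sigma = rep_cov$sigma,
              ci95 = if (!is.null(rep_cov))
                confidence_intervals(rep_cov, 0.95) else NULL,
              vif = vifrep$vif,
              vif_flag = isTRUE(vifrep$condition_flag),
              status = status,
              n_restarts = restarts,
              n_evals = counter$evals,
              boundary_active = if (!is.null(bounds))
                p_hat <= bounds[1, ] | p_hat >= bounds[2, ] else
                rep(FALSE, np),
              state = state)
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Gauss-Newton fit: %s after %d iterations, %d restart(s), cost %.6g\n",
              x$status, length(x$state$cost_trace), x$n_restarts, x$cost))
  tab <- data.frame(estimate = x$p_hat,
                    ci95 = if (!is.null(x$ci95)) x$ci95 else NA,
                    vif = if (!is.null(x$vif)) x$vif else NA)
  print(tab, digits = 4)
  invisible(x)
}

# ---- 2D IR spectrum fitting wrapper --------------------------------------

#' Flatten a (complex) spectrum into the fitted data vector
#'
#' Real mode fits the real (absorptive-detection) part; complex mode stacks
#' real and imaginary quadratures.
#'
#' @param spec Complex array.
#' @param complex_fid Logical.
#' @return Numeric vector.
#' @export
flatten_spectrum <- function(spec, complex_fid = FALSE) {
  if (complex_fid) c(as.vector(Re(spec)), as.vector(Im(spec)))
  else as.vector(Re(spec))
}

#' Constraint projection enforcing the homogeneous-lifetime bound
#'
#' Returns a function clamping `inv_t_hom` to `inv_t_lt / 2 * (1 + eps)`
#' whenever a step violates the physical bound.
#'
#' @param eps Relative margin (default `1e-6`).
#' @return Projection function usable as `project` in [fit_ls()].
#' @export
project_lifetime_bound <- function(eps = 1e-6) {
  function(p) {
    if (all(c("inv_t_hom", "inv_t_lt") %in% names(p)) &&
        p[["inv_t_hom"]] <= p[["inv_t_lt"]] / 2)
      p[["inv_t_hom"]] <- p[["inv_t_lt"]] / 2 * (1 + eps)
    p
  }
}

#' Default fitting bounds for the water-regime two-Kubo model
#'
#' Boundaries follow the usual practice: wide enough that random restarts
#' explore freely, with the two Kubo correlation times restricted to
#' different time scales (fast: 0.05-2 ps; slow: 1-20 ps) to avoid
#' degenerate pairs.
#'
#' @param params Optional [lineshape_params()] fixing the center-frequency
#'   window (default [params_mescn_h2o()]).
#' @return 2-row bounds matrix for the 12-parameter vector.
#' @export
default_bounds_two_kubo <- function(params = params_mescn_h2o()) {
  nm <- param_names(2)
  lo <- c(a01 = 0.1, a12 = 0.1, omega01 = params$omega01 - 10,
          d_omega1 = -1, anh = 20, tau1 = 0.05, dsq1 = 0.5,
          tau2 = 1, dsq2 = 0.5, beta = 0.5, inv_t_lt = 0.01,
          inv_t_hom = 0.02)
  hi <- c(a01 = 10, a12 = 10, omega01 = params$omega01 + 10,
          d_omega1 = 1, anh = 30, tau1 = 2, dsq1 = 60,
          tau2 = 20, dsq2 = 60, beta = 2, inv_t_lt = 1,
          inv_t_hom = 2)
  rbind(lo[nm], hi[nm])
}

#' Fit the three-level Kubo model to a 2D IR waiting-time series
#'
#' Thin wrapper around [fit_ls()]: builds the model closure mapping the flat
#' parameter vector to the flattened measurement-domain spectrum on the
#' dataset's grid, applies the lifetime-bound projection, and returns the
#' engine's result augmented with the fitted `lineshape_params`.
#'
#' @param dataset A `spectral_dataset` (see [simulate_dataset()]).
#' @param p0 Named initial parameter vector ([param_names()] order), or
#'   `"random"` to draw it uniformly within the bounds.
#' @param bounds 2-row bounds matrix matching `p0`.
#' @param options A [fit_options()] object.
#' @param fixed Optional named vector of parameters held constant.
#' @param lt12_ratio Passed to the forward model.
#' @return A `fit_result` with an extra `params_hat` field.
#' @export
fit_spectrum <- function(dataset, p0, bounds, options = fit_options(),
                         fixed = NULL, lt12_ratio = 0.5) {
  grid <- dataset$grid
  cplx <- isTRUE(dataset$complex_fid)
  if (identical(p0, "random")) p0 <- random_restart(bounds)
  free_names <- names(p0)
  model_fn <- function(p) {
    # line-search trial points may overshoot the feasible box or graze the
    # physical lifetime bound; evaluate the model on the projection so the
    # cost stays defined everywhere (accepted iterates are clamped anyway)
    p <- pmin(pmax(p, bounds[1, ]), bounds[2, ])
    full <- c(p, fixed)
    if (full[["inv_t_hom"]] <= full[["inv_t_lt"]] / 2)
      full[["inv_t_hom"]] <- full[["inv_t_lt"]] / 2 * (1 + 1e-6)
    pp <- vector_to_params(full, lt12_ratio = lt12_ratio)
    if (cplx) flatten_spectrum(model_spectrum(pp, grid), TRUE)
    else as.vector(model_spectrum_real(pp, grid))
  }
  data_vec <- flatten_spectrum(dataset$values, cplx)
  w <- dataset$weights
  w_vec <- if (is.null(w)) 1 else {
    wv <- as.vector(w)
    if (cplx) c(wv, wv) else wv
  }
  res <- fit_ls(data_vec, model_fn, p0, bounds, w_vec, options,
                project = project_lifetime_bound())
  res$params_hat <- vector_to_params(c(res$p_hat, fixed),
                                     lt12_ratio = lt12_ratio)
  res
}
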