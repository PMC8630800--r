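test_that("least-squares cost handles weights and degenerate input", {
  expect_identical(ls_cost(numeric(3)), 0)
  expect_equal(ls_cost(c(1, 2, 2)), 9)
  expect_equal(ls_cost(c(1, 3), c(2, 1)), 11)
  expect_error(ls_cost(c(1, 2), c(1, 2, 3)), "length mismatch")
})

test_that("central-difference Jacobian is exact on polynomials and counts evals", {
  X <- cbind(1, seq(0, 1, length.out = 7), seq(0, 1, length.out = 7)^2)
  lin_model <- function(p) as.vector(X %*% p)
  counter <- new.env(); counter$evals <- 0L
  p <- c(a = 0.5, b = -1, c = 2)
  J <- jacobian_fd(lin_model, p, counter = counter)
  expect_equal(unname(J), unname(X), tolerance = 1e-9)
  expect_identical(counter$evals, 6L) # exactly 2 N_p
  # quadratic in p: central differences second-order exact
  quad_model <- function(p) c(p[1]^2, 3 * p[1]^2 + 1)
  Jq <- jacobian_fd(quad_model, c(x = 2))
  expect_equal(as.vector(Jq), c(4, 12), tolerance = 1e-7)
})

test_that("gradient matches the convention grad C = -2 r^T W J", {
  J <- matrix(rnorm(12), 4, 3)
  expect_equal(as.vector(ls_gradient(numeric(4), 1, J)), numeric(3))
  # 1-D quadratic C = (p - 3)^2 at p = 0: r = 3, J = dM/dp = 1 => grad = -6
  expect_equal(as.vector(ls_gradient(3, 1, matrix(1))), -6)
  # finite-difference oracle on the cost of a smooth model
  set.seed(7)
  X <- matrix(rnorm(30), 10, 3)
  d <- rnorm(10)
  w <- runif(10, 0.5, 2)
  model <- function(p) as.vector(sin(X %*% p))
  p <- c(0.3, -0.2, 0.5)
  Jm <- jacobian_fd(model, p, fd_rel_step = 1e-6)
  g <- ls_gradient(d - model(p), w, Jm)
  cost_at <- function(p) ls_cost(d - model(p), w)
  h <- 1e-6
  g_fd <- vapply(1:3, function(k) {
    ph <- p; pm <- p; ph[k] <- p[k] + h; pm[k] <- p[k] - h
    (cost_at(ph) - cost_at(pm)) / (2 * h)
  }, numeric(1))
  expect_equal(as.vector(g), g_fd, tolerance = 1e-6)
})

test_that("Gauss-Newton Hessian is 2 J^T W J, PSD, rank-revealing", {
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:3] # orthonormal columns
  expect_equal(gn_hessian(Q, 1), 2 * diag(3), tolerance = 1e-12)
  Jdup <- cbind(1:4, 1:4)
  ev <- eigen(gn_hessian(Jdup), symmetric = TRUE)$values
  expect_lt(min(ev), 1e-12)
  set.seed(3)
  J <- matrix(rnorm(20), 5, 4); w <- runif(5, 0.5, 2)
  expect_equal(gn_hessian(J, w), 2 * t(J) %*% diag(w) %*% J,
               tolerance = 1e-12)
})

test_that("step solve recovers quadratic minima and flags singularity", {
  # 2-D quadratic C = (p1-a)^2 + (p2-b)^2: H = 2 I, grad = (2, -4) => step
  # lands on the minimum in one move
  dp <- solve_step(2 * diag(2), matrix(c(2, -4), 1))
  expect_equal(dp, c(-1, 2))
  # 1-D quadratic C = (p-3)^2 from p = 0
  dp1 <- solve_step(matrix(2), matrix(-6, 1))
  expect_equal(dp1, 3)
  H_sing <- matrix(c(1, 1, 1, 1 + 1e-14), 2, 2)
  expect_s3_class(solve_step(H_sing, matrix(c(1, 1), 1)), "stall_signal")
})

test_that("Armijo backtracking accepts, shortens, and rejects correctly", {
  opt <- fit_options()
  cost_fn <- function(p) (p - 3)^2
  # exact Gauss-Newton step on the quadratic: full step accepted
  res <- armijo_backtrack(0, 3, cost_fn, matrix(-6, 1), 9, opt)
  expect_equal(res$s, 1)
  expect_equal(res$cost_new, 0)
  # overshoot by 10x: backtracks, still decreases the cost
  res2 <- armijo_backtrack(0, 30, cost_fn, matrix(-6, 1), 9, opt)
  expect_lt(res2$s, 1)
  expect_lt(res2$cost_new, 9)
  # ascent direction: unsatisfiable
  expect_s3_class(armijo_backtrack(0, -3, cost_fn, matrix(-6, 1), 9, opt),
                  "stall_signal")
})

test_that("bounds projection clamps the box and the lifetime constraint", {
  b <- rbind(c(0, 0), c(10, 5))
  inside <- apply_bounds(c(1, 1), c(2, 2), b)
  expect_equal(inside$p_new, c(3, 3))
  expect_false(any(inside$active))
  # tau crossing its upper bound tau <= 10 is clamped and flagged
  hit <- apply_bounds(c(8, 1), c(5, 0), b)
  expect_equal(hit$p_new, c(10, 1))
  expect_true(hit$active[1])
  # step violating inv_t_hom > inv_t_lt / 2 lands on the constraint surface
  p <- c(inv_t_lt = 0.4, inv_t_hom = 0.5)
  bb <- rbind(c(0.01, 0.01), c(1, 2))
  colnames(bb) <- names(p)
  out <- apply_bounds(p, c(0, -0.45), bb, project = project_lifetime_bound())
  expect_gt(out$p_new[["inv_t_hom"]], 0.2)
  expect_lt(out$p_new[["inv_t_hom"]], 0.201)
})

test_that("SIGN is zero at stationarity and invariant to common rescaling", {
  expect_identical(sign_metric(matrix(0, 1, 3), rep(1, 3), 5), 0)
  expect_identical(sign_metric(matrix(1, 1, 3), rep(1, 3), 0), 0)
  # rescale data, model and residual by alpha; weights by gamma:
  # grad -> alpha^2 gamma grad, sigma -> alpha / (alpha gamma^(1/2))...
  # verify numerically through the defining quantities
  set.seed(11)
  J <- matrix(rnorm(40), 10, 4)
  r <- rnorm(10)
  w <- runif(10, 0.5, 2)
  sign_of <- function(alpha, gamma) {
    Ja <- alpha * J; ra <- alpha * r; wa <- gamma * w
    g <- ls_gradient(ra, wa, Ja)
    cost <- ls_cost(ra, wa)
    gram <- t(Ja) %*% diag(wa) %*% Ja
    sp <- sqrt(diag(solve(gram)) * cost / (10 - 4))
    sign_metric(g, sp, cost)
  }
  s0 <- sign_of(1, 1)
  expect_equal(sign_of(7.3, 1), s0, tolerance = 1e-12)
  expect_equal(sign_of(1, 0.37), s0, tolerance = 1e-12)
  expect_equal(sign_of(251, 19), s0, tolerance = 1e-12)
  # the scalar-product reading is exposed as an alternative
  expect_true(is.finite(sign_metric(matrix(c(1, -1), 1), c(1, 1), 2,
                                    variant = "scalar")))
})

test_that("stopping and stall criteria follow the three-iteration windows", {
  opt <- fit_options()
  st <- function(sg, cc, best) list(sign_trace = sg, cost_trace = cc,
                                    best_cost = best,
                                    iters_since_restart = length(sg),
                                    stall_flag = FALSE)
  expect_true(check_stop(st(rep(1e-10, 3), rep(1, 3), 1), opt))
  expect_false(check_stop(st(c(1e-10, 1e-8, 1e-10), rep(1, 3), 1), opt))
  # SIGN fine but cost 1.2x the best ever: not stopped
  expect_false(check_stop(st(rep(1e-10, 3), rep(1.2, 3), 1), opt))
  # flat SIGN above threshold and flat cost: stalled
  expect_true(check_stall(st(c(1e-5, 1.0004e-5, 0.9996e-5),
                             c(2, 2.0001, 1.9999), 1.9), opt))
  expect_false(check_stall(st(c(1e-4, 1e-5, 1e-6), c(3, 2.5, 2), 1.9), opt))
  # a raised stall signal wins regardless of the traces
  s <- st(c(1e-4, 1e-5, 1e-6), c(3, 2.5, 2), 1.9)
  s$stall_flag <- TRUE
  expect_true(check_stall(s, opt))
  # stopped state is not stalled
  expect_false(check_stall(st(rep(1e-10, 3), rep(1, 3), 1), opt))
})

test_that("random restarts stay in bounds and are seed-reproducible", {
  b <- rbind(c(-1, 0, 2), c(1, 5, 2.5))
  set.seed(99)
  draws <- t(replicate(1e4, random_restart(b)))
  expect_true(all(draws >= rep(b[1, ], each = 1e4)))
  expect_true(all(draws <= rep(b[2, ], each = 1e4)))
  set.seed(123); a <- replicate(5, random_restart(b))
  set.seed(123); bbb <- replicate(5, random_restart(b))
  expect_identical(a, bbb)
  expect_error(random_restart(rbind(c(0, -Inf), c(1, 1))), "finite")
})

test_that("Gauss-Newton converges in one iteration on linear models", {
  set.seed(5)
  X <- cbind(1, rnorm(20), runif(20))
  p_true <- c(2, -1, 0.5)
  d <- as.vector(X %*% p_true)
  model <- function(p) as.vector(X %*% p)
  for (trial in 1:3) {
    p0 <- rnorm(3, sd = 5)
    names(p0) <- c("a", "b", "c")
    res <- fit_ls(d, model, p0, options = fit_options(max_iters = 10))
    expect_equal(unname(res$p_hat), p_true, tolerance = 1e-8)
    # the first accepted iteration already attains (near-)zero cost
    expect_lt(res$state$cost_trace[1], 1e-16 * ls_cost(d - model(p0)) + 1e-20)
  }
})

test_that("noiseless one-Kubo series is recovered to 1e-5 in all 10 parameters", {
  truth <- one_kubo_params()
  grid <- small_grid()
  ds <- simulate_dataset(truth, grid, snr = Inf)
  pv <- params_to_vector(truth)
  set.seed(21)
  p0 <- pv * runif(length(pv), 0.85, 1.18)
  b <- one_kubo_bounds()
  p0 <- pmin(pmax(p0, b[1, ]), b[2, ])
  res <- fit_spectrum(ds, p0, b)
  expect_equal(res$status, "converged")
  expect_lt(max(abs(res$p_hat - pv) / abs(pv)), 1e-5)
})

test_that("SIGN plateaus between machine rounding and the stop threshold", {
  truth <- one_kubo_params()
  grid <- small_grid()
  ds <- simulate_dataset(truth, grid, snr = 600, seed = 33)
  pv <- params_to_vector(truth)
  b <- one_kubo_bounds()
  set.seed(34)
  res <- fit_spectrum(ds, pv, b) # start at truth: terminal phase only
  expect_equal(res$status, "converged")
  tail_sign <- utils::tail(res$state$sign_trace, 3)
  # the converged plateau sits above accumulated machine rounding (~2e-16)
  # but below the 1e-9 stopping threshold
  expect_true(all(tail_sign < 1e-9))
  expect_true(all(tail_sign > .Machine$double.eps / 10))
})

test_that("fit optimum matches an exhaustive grid search on a toy problem", {
  # 3-parameter exponential-decay toy: d = a exp(-t/tau) + c
  t <- seq(0, 5, by = 0.25)
  truth <- c(a = 2, tau = 1.3, c = 0.4)
  model <- function(p) p[["a"]] * exp(-t / max(p[["tau"]], 1e-6)) + p[["c"]]
  d <- model(truth) + 0.01 * sin(7 * t) # deterministic "noise"
  b <- rbind(c(a = 0.5, tau = 0.3, c = -1), c(a = 4, tau = 4, c = 1))
  set.seed(31)
  res <- fit_ls(d, model, c(a = 1, tau = 2, c = 0), b,
                options = fit_options())
  # exhaustive grid search over the box
  gr <- expand.grid(a = seq(0.5, 4, length.out = 40),
                    tau = seq(0.3, 4, length.out = 40),
                    c = seq(-1, 1, length.out = 40))
  costs <- vapply(seq_len(nrow(gr)), function(i)
    ls_cost(d - model(unlist(gr[i, ]))), numeric(1))
  best_grid <- unlist(gr[which.min(costs), ])
  step <- c(3.5, 3.7, 2) / 39
  expect_true(all(abs(res$p_hat - best_grid) <= step + 1e-9))
  expect_lte(res$cost, min(costs))
})

test_that("identical inputs and seed give bit-identical traces", {
  truth <- one_kubo_params()
  grid <- tiny_grid(4, 3, 16)
  ds <- simulate_dataset(truth, grid, snr = 100, seed = 17)
  b <- one_kubo_bounds()
  run <- function() {
    set.seed(55)
    fit_spectrum(ds, random_restart(b), b,
                 options = fit_options(max_iters = 25))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$state$cost_trace, r2$state$cost_trace)
  expect_identical(r1$state$sign_trace, r2$state$sign_trace)
  expect_identical(r1$p_hat, r2$p_hat)
})

test_that("accepted iterations never increase the cost between restarts", {
  truth <- one_kubo_params()
  grid <- small_grid()
  ds <- simulate_dataset(truth, grid, snr = 50, seed = 9)
  b <- one_kubo_bounds()
  set.seed(41)
  res <- fit_spectrum(ds, random_restart(b), b,
                      options = fit_options(max_iters = 60))
  cc <- res$state$cost_trace
  seg_start <- c(1, vapply(res$state$restart_log, function(r) r$iteration + 1,
                           numeric(1)))
  seg_end <- c(vapply(res$state$restart_log, function(r) r$iteration,
                      numeric(1)), length(cc))
  for (k in seq_along(seg_start)) {
    if (seg_start[k] < seg_end[k]) {
      seg <- cc[seg_start[k]:seg_end[k]]
      expect_true(all(diff(seg) <= 1e-12 * seg[-length(seg)]))
    }
  }
})

test_that("an overfitted two-Kubo model on one-Kubo data triggers restarts", {
  truth <- one_kubo_params()
  grid <- small_grid()
  ds <- simulate_dataset(truth, grid, snr = 600, seed = 13)
  b2 <- default_bounds_two_kubo(truth)
  b2[, "omega01"] <- c(2150, 2170)
  set.seed(77)
  restart_counts <- vapply(1:3, function(i) {
    res <- fit_spectrum(ds, random_restart(b2), b2,
                        options = fit_options(max_iters = 60))
    res$n_restarts
  }, numeric(1))
  expect_gt(sum(restart_counts), 0)
})
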