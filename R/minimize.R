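# Energy minimization: steepest descent, Polak-Ribiere+ conjugate
# gradient, and limited-memory BFGS, all sharing a backtracking Armijo
# line search and an RMS-gradient stopping rule. Only movable atoms
# are displaced; the full system contributes to the energy.

#' Minimizer options
#'
#' @param max_iterations iteration cap.
#' @param grad_tolerance RMS gradient convergence threshold,
#'   kcal/mol/Angstrom.
#' @param energy_output_frequency iterations between log lines (>= 1).
#' @param line_search `"armijo"` (backtracking, c1 = 1e-4, factor 0.5,
#'   initial displacement 1 Angstrom along the unit direction) or
#'   `"exact"` (1D golden-section refinement; used by the quadratic
#'   termination contracts).
#' @param lbfgs_memory number of curvature pairs kept.
#' @param verbose emit `iter <n> E= <e> kcal/mol RMSgrad= <g>` lines
#'   via `message()`.
#' @return an options list.
#' @export
minimizer_options <- function(max_iterations = 1000, grad_tolerance = 0.1,
                              energy_output_frequency = 10,
                              line_search = c("armijo", "exact"),
                              lbfgs_memory = 5, verbose = FALSE) {
  stopifnot(max_iterations >= 0, grad_tolerance > 0,
            energy_output_frequency >= 1, lbfgs_memory >= 1)
  list(max_iterations = max_iterations, grad_tolerance = grad_tolerance,
       energy_output_frequency = as.integer(energy_output_frequency),
       line_search = match.arg(line_search),
       lbfgs_memory = lbfgs_memory, verbose = isTRUE(verbose))
}

## Backtracking Armijo line search. Returns list(alpha, f, x) or NULL.
armijo_search <- function(fn, x, f0, g, d, max_backtracks = 30) {
  dn <- sqrt(sum(d^2))
  if (dn == 0) return(NULL)
  slope <- sum(g * d)
  if (slope >= 0) return(NULL)  # not a descent direction
  alpha <- 1 / dn  # first trial: 1 Angstrom displacement
  for (k in seq_len(max_backtracks)) {
    xt <- x + alpha * d
    ft <- fn(xt)
    if (is.finite(ft) && ft <= f0 + 1e-4 * alpha * slope)
      return(list(alpha = alpha, f = ft, x = xt))
    alpha <- alpha / 2
  }
  NULL
}

## Exact line search along d. With a gradient function available the
## step solves phi'(alpha) = 0 by root finding (machine-precision on
## quadratics, which the CG termination contract needs); otherwise a
## golden-section refinement over a doubling bracket.
exact_search <- function(fn, x, f0, g, d, gr = NULL) {
  slope <- sum(g * d)
  if (slope >= 0) return(NULL)
  phi <- function(a) fn(x + a * d)
  if (!is.null(gr)) {
    dphi <- function(a) sum(gr(x + a * d) * d)
    hi <- 1 / sqrt(sum(d^2))
    tries <- 0
    while (dphi(hi) < 0 && tries < 60) { hi <- 2 * hi; tries <- tries + 1 }
    if (dphi(hi) >= 0) {
      root <- stats::uniroot(dphi, c(0, hi), tol = 1e-13 * max(1, hi),
                             f.lower = slope)
      a <- root$root
      fa <- phi(a)
      if (is.finite(fa) && fa <= f0)
        return(list(alpha = a, f = fa, x = x + a * d))
    }
  }
  hi <- 1 / sqrt(sum(d^2))
  while (phi(hi) < phi(2 * hi) && is.finite(phi(2 * hi))) hi <- 2 * hi
  while (phi(hi) > f0 && hi > 1e-14) hi <- hi / 2
  opt <- stats::optimize(phi, c(0, 2 * hi), tol = 1e-12)
  if (opt$objective > f0) return(NULL)
  list(alpha = opt$minimum, f = opt$objective, x = x + opt$minimum * d)
}

## Core driver shared by the three methods. `direction` consumes the
## current gradient and per-method state and returns list(d, state).
minimize_driver <- function(fn, gr, x0, opts, direction, init_state) {
  x <- x0
  f <- fn(x)
  g <- gr(x)
  nmov <- length(x) / 3
  rmsg <- function(g) sqrt(mean(g^2))
  trace <- f
  state <- init_state
  iters <- 0L
  converged <- rmsg(g) <= opts$grad_tolerance
  reason <- if (converged) "gradient below tolerance" else ""
  search <- if (opts$line_search == "armijo") armijo_search else exact_search

  while (!converged && iters < opts$max_iterations) {
    dir <- direction(g, state, iters)
    d <- dir$d; state <- dir$state
    if (sum(d * g) >= 0) {  # safeguard: fall back to steepest descent
      d <- -g
      state <- init_state
    }
    ls <- search(fn, x, f, g, d)
    if (is.null(ls)) {
      ls <- if (!identical(d, -g)) search(fn, x, f, g, -g) else NULL
      if (is.null(ls)) {
        reason <- "line search failed"
        break
      }
      state <- init_state
    }
    state$x_prev <- x; state$g_prev <- g; state$d_prev <- ls$x - x
    x <- ls$x
    f <- ls$f
    g <- gr(x)
    iters <- iters + 1L
    trace <- c(trace, f)
    if (opts$verbose && (iters %% opts$energy_output_frequency == 0 ||
                         rmsg(g) <= opts$grad_tolerance))
      message(sprintf("iter %d E= %.6f kcal/mol RMSgrad= %.6f",
                      iters, f, rmsg(g)))
    if (rmsg(g) <= opts$grad_tolerance) {
      converged <- TRUE
      reason <- "gradient below tolerance"
    }
  }
  if (!converged && iters >= opts$max_iterations)
    reason <- "iteration limit reached"
  structure(list(final_energy = f, iterations = iters,
                 converged = converged, reason = reason,
                 energy_trace = trace, final_rms_gradient = rmsg(g),
                 x = x), class = "minimizer_result")
}

#' @export
print.minimizer_result <- function(x, ...) {
  cat(sprintf("minimizer: E = %.6f kcal/mol after %d iterations (%s, RMS grad %.4g)\n",
              x$final_energy, x$iterations,
              if (x$converged) "converged" else paste("stopped:", x$reason),
              x$final_rms_gradient))
  invisible(x)
}

## Build flat objective/gradient closures over movable atoms of a
## force field, then write the result back into the system.
minimize_ff <- function(sys, ff, opts, direction, init_state) {
  movable <- which(ff$movable)
  if (!length(movable)) stop("no movable atoms")
  base <- coords(sys)
  unflatten <- function(x) {
    xyz <- base
    xyz[movable, ] <- matrix(x, ncol = 3)
    xyz
  }
  fn <- function(x) compute_energy(ff, unflatten(x))$total
  gr <- function(x) {
    g <- compute_gradient(ff, unflatten(x))
    as.numeric(g[movable, ])
  }
  res <- minimize_driver(fn, gr, as.numeric(base[movable, ]), opts,
                         direction, init_state)
  set_coords(sys, unflatten(res$x))
  res$x <- NULL
  res
}

#' Steepest-descent minimization
#'
#' @param sys a `molsys` (its coordinates are updated in place).
#' @param ff a `forcefield` from [ff_setup()].
#' @param opts see [minimizer_options()].
#' @return a `minimizer_result`.
#' @export
minimize_steepest_descent <- function(sys, ff, opts = minimizer_options()) {
  minimize_ff(sys, ff, opts,
              direction = function(g, state, iter) list(d = -g, state = state),
              init_state = list())
}

#' Conjugate-gradient minimization (Polak-Ribiere+)
#'
#' Restarts to steepest descent on a non-descent direction and every
#' `3 * n` iterations.
#'
#' @inheritParams minimize_steepest_descent
#' @return a `minimizer_result`.
#' @export
minimize_conjugate_gradient <- function(sys, ff, opts = minimizer_options()) {
  minimize_ff_cg(sys, ff, opts, nvar = 3 * sum(ff$movable))
}

## CG needs the previous *direction*; implemented directly on the
## driver loop for clarity.
minimize_ff_cg <- function(sys, ff, opts, nvar) {
  movable <- which(ff$movable)
  if (!length(movable)) stop("no movable atoms")
  base <- coords(sys)
  unflatten <- function(x) {
    xyz <- base
    xyz[movable, ] <- matrix(x, ncol = 3)
    xyz
  }
  fn <- function(x) compute_energy(ff, unflatten(x))$total
  gr <- function(x) as.numeric(compute_gradient(ff, unflatten(x))[movable, ])
  res <- cg_core(fn, gr, as.numeric(base[movable, ]), opts, nvar)
  set_coords(sys, unflatten(res$x))
  res$x <- NULL
  res
}

## Polak-Ribiere+ conjugate gradient on a plain objective; also used
## directly by the quadratic-termination contracts.
cg_core <- function(fn, gr, x0, opts, nvar = length(x0)) {
  g_prev <- NULL; d_prev <- NULL
  since_restart <- 0L
  direction <- function(g, state, iter) {
    if (is.null(g_prev) || since_restart >= 3 * nvar) {
      since_restart <<- 0L
      return(list(d = -g, state = state))
    }
    beta <- max(0, sum(g * (g - g_prev)) / sum(g_prev^2))
    d <- -g + beta * d_prev
    if (sum(d * g) >= 0) {
      since_restart <<- 0L
      d <- -g
    }
    list(d = d, state = state)
  }
  ## run a custom loop so g_prev/d_prev track accepted steps
  x <- x0
  f <- fn(x); g <- gr(x)
  rmsg <- function(g) sqrt(mean(g^2))
  trace <- f
  iters <- 0L
  converged <- rmsg(g) <= opts$grad_tolerance
  reason <- if (converged) "gradient below tolerance" else ""
  search <- if (opts$line_search == "armijo") armijo_search else
    function(fn, x, f0, g, d) exact_search(fn, x, f0, g, d, gr)
  while (!converged && iters < opts$max_iterations) {
    d <- direction(g, NULL, iters)$d
    ls <- search(fn, x, f, g, d)
    if (is.null(ls)) {
      d <- -g
      since_restart <- 0L
      ls <- search(fn, x, f, g, d)
      if (is.null(ls)) { reason <- "line search failed"; break }
    }
    g_new <- gr(ls$x)
    g_prev <- g; d_prev <- d
    since_restart <- since_restart + 1L
    x <- ls$x; f <- ls$f; g <- g_new
    iters <- iters + 1L
    trace <- c(trace, f)
    if (opts$verbose && (iters %% opts$energy_output_frequency == 0 ||
                         rmsg(g) <= opts$grad_tolerance))
      message(sprintf("iter %d E= %.6f kcal/mol RMSgrad= %.6f",
                      iters, f, rmsg(g)))
    if (rmsg(g) <= opts$grad_tolerance) {
      converged <- TRUE; reason <- "gradient below tolerance"
    }
  }
  if (!converged && iters >= opts$max_iterations)
    reason <- "iteration limit reached"
  structure(list(final_energy = f, iterations = iters,
                 converged = converged, reason = reason,
                 energy_trace = trace, final_rms_gradient = rmsg(g),
                 x = x),
            class = "minimizer_result")
}

#' L-BFGS minimization
#'
#' Two-loop recursion with memory `opts$lbfgs_memory`; curvature pairs
#' with `s.y <= 1e-10` are skipped.
#'
#' @inheritParams minimize_steepest_descent
#' @return a `minimizer_result`.
#' @export
minimize_lbfgs <- function(sys, ff, opts = minimizer_options()) {
  movable <- which(ff$movable)
  if (!length(movable)) stop("no movable atoms")
  base <- coords(sys)
  unflatten <- function(x) {
    xyz <- base
    xyz[movable, ] <- matrix(x, ncol = 3)
    xyz
  }
  fn <- function(x) compute_energy(ff, unflatten(x))$total
  gr <- function(x) as.numeric(compute_gradient(ff, unflatten(x))[movable, ])

  m <- opts$lbfgs_memory
  S <- list(); Y <- list(); RHO <- list()
  two_loop <- function(g) {
    q <- g
    k <- length(S)
    if (!k) return(-g)
    alpha <- numeric(k)
    for (i in k:1) {
      alpha[i] <- RHO[[i]] * sum(S[[i]] * q)
      q <- q - alpha[i] * Y[[i]]
    }
    gamma <- sum(S[[k]] * Y[[k]]) / sum(Y[[k]] * Y[[k]])
    r <- gamma * q
    for (i in 1:k) {
      beta <- RHO[[i]] * sum(Y[[i]] * r)
      r <- r + S[[i]] * (alpha[i] - beta)
    }
    -r
  }

  x <- as.numeric(base[movable, ])
  f <- fn(x); g <- gr(x)
  rmsg <- function(g) sqrt(mean(g^2))
  trace <- f
  iters <- 0L
  converged <- rmsg(g) <= opts$grad_tolerance
  reason <- if (converged) "gradient below tolerance" else ""
  search <- if (opts$line_search == "armijo") armijo_search else exact_search
  while (!converged && iters < opts$max_iterations) {
    d <- two_loop(g)
    if (sum(d * g) >= 0) { d <- -g; S <- Y <- RHO <- list() }
    ls <- search(fn, x, f, g, d)
    if (is.null(ls)) {
      S <- Y <- RHO <- list()
      ls <- search(fn, x, f, g, -g)
      if (is.null(ls)) { reason <- "line search failed"; break }
    }
    g_new <- gr(ls$x)
    s <- ls$x - x; y <- g_new - g
    sy <- sum(s * y)
    if (sy > 1e-10) {
      S[[length(S) + 1]] <- s; Y[[length(Y) + 1]] <- y
      RHO[[length(RHO) + 1]] <- 1 / sy
      if (length(S) > m) { S <- S[-1]; Y <- Y[-1]; RHO <- RHO[-1] }
    }
    x <- ls$x; f <- ls$f; g <- g_new
    iters <- iters + 1L
    trace <- c(trace, f)
    if (opts$verbose && (iters %% opts$energy_output_frequency == 0 ||
                         rmsg(g) <= opts$grad_tolerance))
      message(sprintf("iter %d E= %.6f kcal/mol RMSgrad= %.6f",
                      iters, f, rmsg(g)))
    if (rmsg(g) <= opts$grad_tolerance) {
      converged <- TRUE; reason <- "gradient below tolerance"
    }
  }
  if (!converged && iters >= opts$max_iterations)
    reason <- "iteration limit reached"
  set_coords(sys, unflatten(x))
  structure(list(final_energy = f, iterations = iters,
                 converged = converged, reason = reason,
                 energy_trace = trace, final_rms_gradient = rmsg(g)),
            class = "minimizer_result")
}
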