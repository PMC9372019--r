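#' Discrete Laplacian with boundary closure
#'
#' Second-order central differences on a uniform grid over the
#' boundary-condition-appropriate domain: \eqn{[-1/2, 1/2]} for Dirichlet
#' conditions (boundary values pinned to the homogeneous steady state and
#' substituted into the interior stencil, so the unknowns are the interior
#' nodes) and \eqn{[0, 1]} for zero-flux Neumann conditions (ghost-node
#' reflection; all nodes are unknowns).
#'
#' @param system an \code{\link{rd_system}} (used for the pinned boundary
#'   values via the steady state).
#' @param bc \code{"dirichlet"} or \code{"neumann"}.
#' @param n_nodes total number of grid nodes (including boundaries),
#'   at least 32.
#' @param steady_state optional \code{steady_state}; computed when missing.
#' @return object of class \code{rd_operator}: list with the full grid
#'   \code{x}, spacing \code{h}, index vector \code{unknowns} into the grid,
#'   matvec closures \code{lap_u(w)}, \code{lap_v(w)} acting on the unknown
#'   vectors (Dirichlet closures include the pinned-boundary contribution),
#'   the homogeneous-part matrix builder \code{lap_matrix()} and the
#'   boundary inhomogeneity \code{lap_const_u}, \code{lap_const_v}.
#' @export
build_operator <- function(system, bc = c("dirichlet", "neumann"),
                           n_nodes = 256, steady_state = NULL) {
  bc <- match.arg(bc)
  if (n_nodes < 32) stop("n_nodes must be at least 32")
  if (is.null(steady_state)) steady_state <- find_steady_state(system)
  ss <- as_uv(steady_state)
  dom <- if (bc == "dirichlet") c(-0.5, 0.5) else c(0, 1)
  x <- seq(dom[1], dom[2], length.out = n_nodes)
  h <- x[2] - x[1]
  if (bc == "dirichlet") {
    unknowns <- 2:(n_nodes - 1)
    n <- length(unknowns)
    lap_hom <- function(w) {                     # zero-boundary part
      c(w[2] - 2 * w[1],
        if (n > 2) w[1:(n - 2)] - 2 * w[2:(n - 1)] + w[3:n],
        w[n - 1] - 2 * w[n]) / h^2
    }
    lap_const_u <- c(ss[1], numeric(n - 2), ss[1]) / h^2
    lap_const_v <- c(ss[2], numeric(n - 2), ss[2]) / h^2
    lap_u <- function(w) lap_hom(w) + lap_const_u
    lap_v <- function(w) lap_hom(w) + lap_const_v
    lap_matrix <- function() tridiag_matrix(n, -2 / h^2, 1 / h^2)
  } else {
    unknowns <- seq_len(n_nodes)
    n <- n_nodes
    lap_hom <- function(w) {
      c(2 * (w[2] - w[1]),
        w[1:(n - 2)] - 2 * w[2:(n - 1)] + w[3:n],
        2 * (w[n - 1] - w[n])) / h^2
    }
    lap_const_u <- lap_const_v <- numeric(n)
    lap_u <- lap_v <- lap_hom
    lap_matrix <- function() {
      A <- tridiag_matrix(n, -2 / h^2, 1 / h^2)
      A[1, 2] <- 2 / h^2; A[n, n - 1] <- 2 / h^2
      A
    }
  }
  structure(list(bc = bc, x = x, h = h, n_nodes = n_nodes,
                 unknowns = unknowns, n_unknowns = length(unknowns),
                 steady = ss,
                 lap_u = lap_u, lap_v = lap_v, lap_matrix = lap_matrix,
                 lap_const_u = lap_const_u, lap_const_v = lap_const_v),
            class = "rd_operator")
}

tridiag_matrix <- function(n, d, off) {
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- d
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  A
}

#' Initial conditions for the simulator
#'
#' Builds the initial fields on the full grid.  \code{"random"}:
#' \eqn{|(u_s, v_s) + \mathcal U(-\sigma, \sigma)|} pointwise (absolute
#' value keeps concentrations nonnegative), with Dirichlet boundary nodes
#' reset to the steady state and Neumann boundary nodes copied from their
#' neighbours.  \code{"nonneg_poly"} / \code{"nonpos_poly"} (Dirichlet
#' domain only): the activator is perturbed by the sign-definite quadratic
#' \eqn{\pm(1/2 - x)(x + 1/2)}, which selects the subcritical
#' (solution-above-steady-state) or supercritical (below) branch near
#' onset; the inhibitor starts at \eqn{v_s}.
#'
#' @param op an \code{\link{build_operator}} result.
#' @param kind one of \code{"random"}, \code{"nonneg_poly"},
#'   \code{"nonpos_poly"}.
#' @param sigma perturbation amplitude for \code{"random"} (much less
#'   than 1).
#' @param seed optional integer seed for reproducible random fields.
#' @return list with vectors \code{u}, \code{v} on the full grid.
#' @export
make_initial_condition <- function(op, kind = c("random", "nonneg_poly",
                                                "nonpos_poly"),
                                   sigma = 0.01, seed = NULL) {
  kind <- match.arg(kind)
  ss <- op$steady; x <- op$x; n <- op$n_nodes
  if (kind == "random") {
    if (sigma < 0) stop("sigma must be nonnegative")
    if (!is.null(seed)) set.seed(seed)
    u <- abs(ss[1] + stats::runif(n, -sigma, sigma))
    v <- abs(ss[2] + stats::runif(n, -sigma, sigma))
    if (op$bc == "dirichlet") {
      u[c(1, n)] <- ss[1]; v[c(1, n)] <- ss[2]
    } else {
      u[1] <- u[2]; u[n] <- u[n - 1]; v[1] <- v[2]; v[n] <- v[n - 1]
    }
  } else {
    if (op$bc != "dirichlet")
      stop("polynomial initial conditions are defined on the Dirichlet ",
           "domain [-1/2, 1/2] only")
    pert <- (0.5 - x) * (x + 0.5)
    if (kind == "nonpos_poly") pert <- -pert
    u <- ss[1] + pert
    v <- rep(ss[2], n)
  }
  list(u = u, v = v)
}

#' Simulate the reaction-diffusion system (method of lines)
#'
#' Integrates the full nonlinear system with a stiff implicit solver
#' (\code{deSolve::ode}, \code{lsodes}), on a static domain or with a
#' time-dependent domain scale \code{L_schedule(t)} (slow growth; the
#' dilution term is neglected, appropriate when growth is slow).  Records
#' the fields at the requested cadence together with the activator extrema
#' and the projected amplitude of the critical mode.
#'
#' @param system an \code{\link{rd_system}}.
#' @param bc \code{"dirichlet"} or \code{"neumann"}.
#' @param t_end final time.
#' @param n_nodes grid nodes (including boundaries).
#' @param L domain scale (default the system's).
#' @param L_schedule optional function of time overriding \code{L}.
#' @param ic initial condition: a \code{kind} string for
#'   \code{\link{make_initial_condition}} or a list \code{(u, v)} on the
#'   full grid.
#' @param sigma,seed passed to \code{\link{make_initial_condition}} for
#'   random initial conditions.
#' @param n_save number of saved time points (uniform cadence).
#' @param rtol,atol integrator tolerances.
#' @param steady_tol if non-\code{NULL}, integration reports convergence
#'   when the max-norm time derivative falls below this value at a saved
#'   step.
#' @param kernel_u u-component of the kernel vector used to scale the
#'   projected amplitude (\code{NULL}: raw cosine projection).
#' @return object of class \code{solution_trace}: list with \code{times},
#'   matrices \code{u}, \code{v} (time x space, full grid), \code{x},
#'   \code{max_u}, \code{min_u}, \code{a} (projected amplitude),
#'   \code{L_of_t}, \code{steady} (logical: steady detection triggered).
#' @examples
#' \donttest{
#' sys <- schnakenberg()
#' tr <- simulate_rd(sys, "neumann", t_end = 50, n_nodes = 64,
#'                   L = 0.09, ic = "random", sigma = 0.01, seed = 1)
#' max(abs(tr$max_u[length(tr$times)] - 2)) < 1e-2  # decays below onset
#' }
#' @export
simulate_rd <- function(system, bc = c("dirichlet", "neumann"), t_end,
                        n_nodes = 256, L = system$L, L_schedule = NULL,
                        ic = "random", sigma = 0.01, seed = NULL,
                        n_save = 201, rtol = 1e-8, atol = 1e-10,
                        steady_tol = NULL, kernel_u = NULL) {
  bc <- match.arg(bc)
  ss <- find_steady_state(system)
  op <- build_operator(system, bc, n_nodes, ss)
  ic <- if (is.character(ic))
    make_initial_condition(op, ic, sigma = sigma, seed = seed) else ic
  if (length(ic$u) != n_nodes || length(ic$v) != n_nodes)
    stop("initial condition length does not match the grid")
  idx <- op$unknowns; n <- op$n_unknowns
  Lfun <- if (is.null(L_schedule)) function(t) L else L_schedule
  rhs <- function(t, y, parms) {
    u <- y[1:n]; v <- y[(n + 1):(2 * n)]
    L2 <- Lfun(t)^2
    list(c(system$D_u / L2 * op$lap_u(u) + system$f(u, v),
           system$D_v / L2 * op$lap_v(v) + system$g(u, v)))
  }
  y0 <- c(ic$u[idx], ic$v[idx])
  times <- seq(0, t_end, length.out = n_save)
  sol <- deSolve::ode(y0, times, rhs, parms = NULL, method = "lsodes",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integration failed at t = ", max(sol[, 1]),
         " (of ", t_end, "); consider loosening tolerances or refining the grid")
  tt <- sol[, 1]
  U <- matrix(NA_real_, length(tt), n_nodes)
  V <- matrix(NA_real_, length(tt), n_nodes)
  U[, idx] <- sol[, 1 + (1:n)]
  V[, idx] <- sol[, 1 + n + (1:n)]
  if (bc == "dirichlet") {
    U[, c(1, n_nodes)] <- op$steady[1]
    V[, c(1, n_nodes)] <- op$steady[2]
  }
  steady <- FALSE
  if (!is.null(steady_tol) && length(tt) >= 2) {
    i <- length(tt)
    d <- unlist(rhs(tt[i], c(U[i, idx], V[i, idx]), NULL))
    steady <- max(abs(d)) < steady_tol
  }
  tr <- structure(list(times = tt, x = op$x, u = U, v = V,
                       max_u = apply(U, 1, max), min_u = apply(U, 1, min),
                       bc = bc, steady_state = op$steady,
                       L_of_t = vapply(tt, Lfun, numeric(1)),
                       steady = steady),
                  class = "solution_trace")
  tr$a <- extract_amplitude(tr, kernel_u = kernel_u)
  tr
}

#' Simulation with a slowly growing domain
#'
#' Runs \code{\link{simulate_rd}} with the linear growth law
#' \eqn{L(t) = L_0 (1 + t/100)}, the standard slow uniform-growth proxy in
#' which the domain scale enters only through the diffusion prefactor
#' (dilution neglected).
#'
#' @inheritParams simulate_rd
#' @param L0 initial domain scale.
#' @export
growing_domain_run <- function(system, bc, L0, t_end, ...) {
  if (L0 <= 0) stop("L0 must be positive")
  simulate_rd(system, bc, t_end = t_end,
              L_schedule = function(t) L0 * (1 + t / 100), ...)
}

#' Projected amplitude of the critical mode
#'
#' Projects the activator deviation \eqn{u - u_s} onto \eqn{\cos(\pi x)}
#' under the boundary-condition-appropriate inner product (trapezoid rule
#' on the grid) and normalizes so the result is the amplitude \eqn{A} in
#' \eqn{u \approx u_s + A\,\Lambda_u \cos(\pi x)}.  Orthogonality of the
#' cosine basis makes the projection insensitive to higher harmonics.
#'
#' @param trace a \code{solution_trace}, or a list with \code{x}, \code{u}
#'   (vector or time-by-space matrix), \code{steady_state}.
#' @param kernel_u u-component of the kernel vector; \code{NULL} returns
#'   the raw cosine coefficient (\eqn{\Lambda_u = 1}).
#' @return numeric vector \code{a(t)}.
#' @export
extract_amplitude <- function(trace, kernel_u = NULL) {
  x <- trace$x
  us <- trace$steady_state[1]
  U <- trace$u
  if (is.null(dim(U))) U <- matrix(U, 1)
  w <- cos(pi * x)
  h <- x[2] - x[1]
  proj <- apply(U, 1, function(u) {
    z <- (u - us) * w
    2 * h * (sum(z) - 0.5 * (z[1] + z[length(z)]))   # <cos,cos> = 1/2
  })
  if (is.null(kernel_u)) proj else proj / kernel_u
}

#' @export
print.solution_trace <- function(x, ...) {
  nt <- length(x$times)
  cat(sprintf("solution trace (%s): %d saved steps to t = %g, %d nodes\n",
              x$bc, nt, max(x$times), length(x$x)))
  cat(sprintf("  final max(u) = %.4g, min(u) = %.4g, amplitude = %.4g\n",
              x$max_u[nt], x$min_u[nt], x$a[nt]))
  invisible(x)
}

#' @export
plot.solution_trace <- function(x, what = c("extrema", "field"), ...) {
  what <- match.arg(what)
  if (what == "extrema") {
    graphics::matplot(x$L_of_t, cbind(x$max_u, x$min_u), type = "l",
                      lty = c(1, 2), xlab = "L", ylab = "u extrema", ...)
  } else {
    nt <- length(x$times)
    graphics::matplot(x$x, t(x$u[unique(round(seq(1, nt, length.out = 6))), ]),
                      type = "l", xlab = "x", ylab = "u", ...)
  }
  invisible(x)
}

#' Count interior pattern peaks of a field
#'
#' Simple structural statistic used to track peak splitting on growing
#' domains: the number of strict local maxima of the activator profile
#' exceeding the homogeneous steady state (boundary maxima counted as half
#' peaks are included as maxima of the padded profile).
#'
#' @param u activator profile.
#' @param us homogeneous steady-state value.
#' @param min_height minimum excess over \code{us} for a peak to count.
#' @return integer peak count.
#' @export
count_peaks <- function(u, us, min_height = 0.05) {
  n <- length(u)
  up <- c(u[2], u, u[n - 1])      # reflective padding: boundary extrema count
  is_peak <- up[2:(n + 1)] > up[1:n] & up[2:(n + 1)] >= up[3:(n + 2)] &
    up[2:(n + 1)] > us + min_height
  sum(is_peak)
}
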