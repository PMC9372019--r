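#' Stability of the diffusion-free kinetics
#'
#' Routh-Hurwitz conditions for the homogeneous steady state of the kinetic
#' ODEs: the steady state is stable iff the Jacobian trace is negative and
#' its determinant positive.
#'
#' @param derivs a \code{\link{derivative_table}}.
#' @return list with logical \code{trace_condition} (\eqn{f_u + g_v < 0}),
#'   \code{determinant_condition} (\eqn{f_u g_v - g_u f_v > 0}) and
#'   \code{stable} (both).
#' @export
ode_stability <- function(derivs) {
  tr <- derivs$f_u + derivs$g_v
  dt <- derivs$f_u * derivs$g_v - derivs$g_u * derivs$f_v
  list(trace_condition = tr < 0, determinant_condition = dt > 0,
       stable = tr < 0 && dt > 0, trace = tr, det = dt)
}

#' Dispersion relation growth rates
#'
#' The two eigenvalues \eqn{\lambda(k)} of the linearization about the
#' homogeneous steady state for a Fourier perturbation of wavenumber
#' \eqn{k}, i.e. the roots of
#' \deqn{\det(\lambda I + (k^2/L^2) D - J) = 0.}
#' At \eqn{k = 0} this reduces to the diffusion-free quadratic.  Admissible
#' discrete wavenumbers are \eqn{k = n\pi} for zero-flux (Neumann) and
#' \eqn{k = (2n+1)\pi} for steady-state-pinned (Dirichlet) boundary
#' conditions on the even subspace; \code{k} is treated as continuous here.
#'
#' @param system an \code{\link{rd_system}} (supplies \code{D_u}, \code{D_v}).
#' @param derivs a \code{\link{derivative_table}}.
#' @param k nonnegative wavenumber(s).
#' @param L domain scale (default: the system's).
#' @return for scalar \code{k}, a list with \code{k}, complex
#'   \code{lambda_pair} and \code{max_real}; for vector \code{k}, a data
#'   frame with columns \code{k} and \code{max_real}.
#' @export
dispersion_eigenvalues <- function(system, derivs, k, L = system$L) {
  stopifnot(all(k >= 0), L > 0)
  one <- function(k1) {
    q <- k1^2 / L^2
    tr <- derivs$f_u + derivs$g_v - q * (system$D_u + system$D_v)
    dt <- (q * system$D_u - derivs$f_u) * (q * system$D_v - derivs$g_v) -
      derivs$g_u * derivs$f_v
    disc <- as.complex(tr^2 - 4 * dt)
    lam <- (tr + c(1, -1) * sqrt(disc)) / 2
    list(k = k1, lambda_pair = lam, max_real = max(Re(lam)))
  }
  if (length(k) == 1L) return(one(k))
  data.frame(k = k,
             max_real = vapply(k, function(k1) one(k1)$max_real, numeric(1)))
}

#' Window of diffusion-unstable squared wavenumbers
#'
#' Endpoints \eqn{k_\pm^2} of the interval of squared wavenumbers for which
#' the constant term of the dispersion quadratic is negative (one real
#' positive growth rate):
#' \deqn{k^2_\pm = L^2\,\frac{(D_u g_v + f_u D_v) \pm
#'   \sqrt{(D_u g_v + f_u D_v)^2 - 4 D_u D_v (f_u g_v - g_u f_v)}}{2 D_u D_v}.}
#' Both endpoints scale with \eqn{L^2}.
#'
#' @inheritParams dispersion_eigenvalues
#' @return list with \code{k_minus_sq}, \code{k_plus_sq}.
#' @export
instability_window <- function(system, derivs, L = system$L) {
  h <- system$D_u * derivs$g_v + derivs$f_u * system$D_v
  det_j <- derivs$f_u * derivs$g_v - derivs$g_u * derivs$f_v
  disc <- h^2 - 4 * system$D_u * system$D_v * det_j
  if (h <= 0 || disc < 0)
    stop("no diffusion-driven instability: D_u*g_v + f_u*D_v must exceed ",
         "2*sqrt(D_u*D_v*det(J))")
  s <- sqrt(disc)
  list(k_minus_sq = L^2 * (h - s) / (2 * system$D_u * system$D_v),
       k_plus_sq  = L^2 * (h + s) / (2 * system$D_u * system$D_v))
}

#' Critical domain scale of the first Turing bifurcation
#'
#' The smallest \eqn{L} at which a heterogeneous mode destabilizes, obtained
#' by pinning the upper endpoint of the instability window to the first
#' admissible mode, \eqn{k_+^2 = \pi^2}:
#' \deqn{L_c^2 = \frac{2 D_u D_v \pi^2}{(D_u g_v + f_u D_v) +
#'   \sqrt{(D_u g_v + f_u D_v)^2 - 4 D_u D_v (f_u g_v - g_u f_v)}}.}
#' Scaling both diffusivities by \eqn{c} scales \eqn{L_c} by \eqn{\sqrt c}.
#'
#' @inheritParams dispersion_eigenvalues
#' @return positive scalar \code{L_c}.
#' @export
critical_length <- function(system, derivs) {
  os <- ode_stability(derivs)
  if (!os$trace_condition)
    stop("Turing condition violated: kinetic trace f_u + g_v is not negative")
  if (!os$determinant_condition)
    stop("Turing condition violated: kinetic determinant is not positive")
  h <- system$D_u * derivs$g_v + derivs$f_u * system$D_v
  disc <- h^2 - 4 * system$D_u * system$D_v * os$det
  if (h <= 0 || disc < 0)
    stop("Turing condition violated: no real positive instability window ",
         "(D_u*g_v + f_u*D_v <= 2*sqrt(D_u*D_v*det(J)))")
  sqrt(2 * system$D_u * system$D_v * pi^2 / (h + sqrt(disc)))
}

#' Kernel and adjoint-kernel vectors at the bifurcation point
#'
#' Null vectors of the critical-mode matrix
#' \eqn{M = J - (\pi^2/L_c^2)\,\mathrm{diag}(D_u, D_v)} and of its
#' transpose, both normalized so their second (v) component is 1.  The
#' scalar ratios \eqn{\Lambda} (kernel) and \eqn{\eta} (adjoint) are the
#' u-components under that normalization.  When \code{sign_convention} is
#' \code{TRUE} the kernel vector's overall sign is flipped whenever the
#' flip makes the quadratic coefficient of the Dirichlet amplitude equation
#' positive, so that reported amplitude-equation signs follow the usual
#' presentation of the transcritical case.
#'
#' @inheritParams dispersion_eigenvalues
#' @param L_c critical scale from \code{\link{critical_length}}.
#' @param sign_convention apply the sign convention described above.
#' @return list with \code{Lambda}, \code{eta} (u/v component ratios),
#'   \code{kernel_vector}, \code{adjoint_vector} (length-2 numerics),
#'   \code{flipped} (was the kernel sign flipped), and \code{residual}.
#' @export
kernel_vectors <- function(system, derivs, L_c, sign_convention = TRUE) {
  M <- jacobian_matrix(derivs) - (pi^2 / L_c^2) * diffusion_matrix(system)
  # null space of a singular 2x2: use the numerically larger row
  row <- which.max(abs(M[, 1]))
  Lambda <- -M[row, 2] / M[row, 1]
  col <- which.max(abs(M[1, ]))
  eta <- if (col == 1) -M[2, 1] / M[1, 1] else -M[2, 2] / M[1, 2]
  kv <- c(Lambda, 1)
  av <- c(eta, 1)
  res <- max(max(abs(M %*% kv)), max(abs(t(M) %*% av)))
  if (res > 1e-6 * max(abs(M)))
    stop("critical-mode matrix is not numerically singular; residual ", res)
  flipped <- FALSE
  if (sign_convention) {
    qp <- quadratic_form_projection(derivs, kv)
    p2_sign <- sum(av * qp) / sum(av * kv)
    if (is.finite(p2_sign) && p2_sign < 0) { kv <- -kv; flipped <- TRUE }
  }
  list(Lambda = Lambda, eta = eta, kernel_vector = kv, adjoint_vector = av,
       flipped = flipped, residual = res)
}

#' Full linear Turing analysis
#'
#' Runs the complete linear chain: kinetic (diffusion-free) stability,
#' diffusion-driven instability test, instability window at the stored
#' \code{L}, critical scale \eqn{L_c}, and kernel/adjoint vectors at
#' \eqn{L_c}.
#'
#' @param system an \code{\link{rd_system}}.
#' @param derivs optional \code{\link{derivative_table}}; computed from
#'   \code{guess} when missing.
#' @param guess steady-state guess used when \code{derivs} is missing.
#' @return object of class \code{linear_analysis}: list with
#'   \code{ode_stable}, \code{diffusion_driven}, \code{k_minus_sq},
#'   \code{k_plus_sq} (at the system's \code{L}), \code{L_c},
#'   \code{Lambda}, \code{eta}, \code{kernel_vector},
#'   \code{adjoint_vector}, \code{derivs}, \code{steady_state}.
#' @examples
#' la <- linear_analysis(schnakenberg())
#' la$L_c                      # about 0.107
#' sqrt(instability_window(schnakenberg(), la$derivs, la$L_c)$k_minus_sq)
#' @export
linear_analysis <- function(system, derivs = NULL, guess = c(1, 1)) {
  if (is.null(derivs)) {
    ss <- find_steady_state(system, guess)
    derivs <- derivative_table(system, ss)
  }
  os <- ode_stability(derivs)
  h <- system$D_u * derivs$g_v + derivs$f_u * system$D_v
  dd <- os$stable &&
    h > 2 * sqrt(system$D_u * system$D_v * max(os$det, 0))
  win <- if (dd) instability_window(system, derivs) else
    list(k_minus_sq = NA_real_, k_plus_sq = NA_real_)
  L_c <- if (dd) critical_length(system, derivs) else NA_real_
  kv <- if (dd) kernel_vectors(system, derivs, L_c) else NULL
  structure(list(
    ode_stable = os$stable, diffusion_driven = dd,
    k_minus_sq = win$k_minus_sq, k_plus_sq = win$k_plus_sq,
    L_c = L_c,
    Lambda = kv$Lambda, eta = kv$eta,
    kernel_vector = kv$kernel_vector, adjoint_vector = kv$adjoint_vector,
    kernel_flipped = isTRUE(kv$flipped),
    derivs = derivs,
    steady_state = c(u_s = derivs$u_s, v_s = derivs$v_s)
  ), class = "linear_analysis")
}

#' @export
print.linear_analysis <- function(x, ...) {
  cat("linear Turing analysis\n")
  cat(sprintf("  kinetics stable without diffusion: %s\n", x$ode_stable))
  cat(sprintf("  diffusion-driven instability:      %s\n", x$diffusion_driven))
  if (x$diffusion_driven) {
    cat(sprintf("  L_c = %.6g  (first unstable mode k = pi)\n", x$L_c))
    cat(sprintf("  instability window at stored L: k in [%.4g, %.4g]\n",
                sqrt(x$k_minus_sq), sqrt(x$k_plus_sq)))
    cat(sprintf("  kernel ratio Lambda = %.6g, adjoint ratio eta = %.6g\n",
                x$Lambda, x$eta))
  }
  invisible(x)
}

#' Turing patterning region in the (L, D_v) plane
#'
#' Holding \code{D_u} fixed, evaluates the sign of the leading growth rate of
#' the first mode (\eqn{k = \pi}) over a grid of inhibitor diffusivities and
#' domain scales, and locates the region boundary (\eqn{\max \mathrm{Re}\,
#' \lambda = 0}) by root bracketing in \eqn{L} for each \eqn{D_v}.
#'
#' @inheritParams dispersion_eigenvalues
#' @param D_v_grid,L_grid numeric grids.
#' @param tol absolute bracketing tolerance in \eqn{L}.
#' @return object of class \code{patterning_region}: list with \code{mask}
#'   (logical matrix, rows = \code{L_grid}, cols = \code{D_v_grid}),
#'   \code{boundary} (data frame \code{D_v}, \code{L_boundary}; \code{NA}
#'   where no crossing is bracketed) and \code{extremes}
#'   (see \code{\link{region_extremes}}).
#' @export
patterning_region <- function(system, derivs,
                              D_v_grid = seq(0.04, 0.4, length.out = 60),
                              L_grid = seq(0.08, 0.4, length.out = 60),
                              tol = 1e-8) {
  growth <- function(L, D_v) {
    sys1 <- system; sys1$D_v <- D_v
    dispersion_eigenvalues(sys1, derivs, k = pi, L = L)$max_real
  }
  mask <- vapply(D_v_grid, function(dv)
    vapply(L_grid, function(L) growth(L, dv) > 0, logical(1)),
    logical(length(L_grid)))
  boundary <- vapply(D_v_grid, function(dv) {
    g <- vapply(L_grid, growth, numeric(1), D_v = dv)
    i <- which(g[-1] * g[-length(g)] < 0)        # first sign change, L increasing
    if (!length(i)) return(NA_real_)
    i <- i[1]
    stats::uniroot(growth, interval = c(L_grid[i], L_grid[i + 1]), D_v = dv,
                   tol = tol)$root
  }, numeric(1))
  structure(list(
    mask = mask, L_grid = L_grid, D_v_grid = D_v_grid,
    boundary = data.frame(D_v = D_v_grid, L_boundary = boundary),
    extremes = region_extremes(system, derivs)
  ), class = "patterning_region")
}

#' Closed-form boundary and extremes of the patterning region
#'
#' On the region boundary the first mode is marginal
#' (\eqn{\mathrm{Re}\,\lambda(\pi; L) = 0}), which solves to
#' \deqn{D_v(L) = \frac{L^2}{\pi^2}\Big(g_v +
#'   \frac{g_u f_v}{\pi^2 D_u / L^2 - f_u}\Big).}
#' The boundary has a vertical asymptote at \eqn{L_{\min} =
#' \pi\sqrt{D_u / f_u}} (admissible only for an activator, \eqn{f_u > 0})
#' and an interior minimum over \eqn{L} giving the smallest inhibitor
#' diffusivity that supports the first mode.
#'
#' @inheritParams dispersion_eigenvalues
#' @param method closed-form curve minimization, or generic root bracketing
#'   of the growth rate (the two agree to tight tolerance; the bracketing
#'   path exercises no model-specific algebra).
#' @return list with \code{L_min}, \code{D_v_min}, \code{L_at_D_v_min} and
#'   the boundary function \code{D_v_of_L}.
#' @export
region_extremes <- function(system, derivs,
                            method = c("closed_form", "bracketing")) {
  method <- match.arg(method)
  if (derivs$f_u <= 0)
    stop("region extremes require an activator (f_u > 0)")
  L_min <- pi * sqrt(system$D_u / derivs$f_u)
  D_v_of_L <- function(L)
    (L^2 / pi^2) * (derivs$g_v +
                      derivs$g_u * derivs$f_v / (pi^2 * system$D_u / L^2 - derivs$f_u))
  if (method == "closed_form") {
    opt <- stats::optimize(D_v_of_L, interval = c(L_min * 1.0001, L_min * 40),
                           tol = 1e-12)
    list(L_min = L_min, D_v_min = opt$objective, L_at_D_v_min = opt$minimum,
         D_v_of_L = D_v_of_L)
  } else {
    # generic path: for a given D_v, bracket the smaller root of
    # max Re lambda(pi; L) = 0 in L, then minimize D_v s.t. a root exists
    boundary_L <- function(D_v) {
      sys1 <- system; sys1$D_v <- D_v
      g <- function(L) dispersion_eigenvalues(sys1, derivs, pi, L)$max_real
      Ls <- seq(L_min * 1.0001, L_min * 40, length.out = 400)
      gv <- vapply(Ls, g, numeric(1))
      i <- which(gv[-1] * gv[-length(gv)] < 0)
      if (!length(i)) return(NA_real_)
      stats::uniroot(g, c(Ls[i[1]], Ls[i[1] + 1]), tol = 1e-8)$root
    }
    # smallest D_v with a nonempty unstable interval: bisection on existence
    exists_at <- function(D_v) {
      sys1 <- system; sys1$D_v <- D_v
      g <- function(L) dispersion_eigenvalues(sys1, derivs, pi, L)$max_real
      any(vapply(seq(L_min * 1.0001, L_min * 40, length.out = 400), g,
                 numeric(1)) > 0)
    }
    lo <- system$D_u; hi <- system$D_v
    while (!exists_at(hi)) hi <- hi * 2
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (exists_at(mid)) hi <- mid else lo <- mid
    }
    D_v_min <- hi
    # just above the threshold the unstable bump in L is narrow: locate it
    # on a grid, then polish locally
    sys1 <- system; sys1$D_v <- D_v_min * (1 + 1e-3)
    g <- function(L) dispersion_eigenvalues(sys1, derivs, pi, L)$max_real
    Ls <- seq(L_min * 1.0001, L_min * 40, length.out = 2000)
    gv <- vapply(Ls, g, numeric(1))
    i <- which.max(gv)
    opt <- stats::optimize(function(L) -g(L),
                           interval = c(Ls[max(1, i - 2)],
                                        Ls[min(length(Ls), i + 2)]),
                           tol = 1e-10)
    list(L_min = L_min, D_v_min = D_v_min, L_at_D_v_min = opt$minimum,
         boundary_L = boundary_L)
  }
}
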