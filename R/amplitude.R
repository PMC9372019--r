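#' Fourier cosine coefficient of cos^2(pi x) on the Dirichlet domain
#'
#' On \eqn{[-1/2, 1/2]} the square of the critical mode expands in the odd
#' cosine basis as
#' \deqn{\cos^2(\pi x) = \sum_{n \ge 0}
#'   \frac{8(-1)^{n+1}}{\pi (2n+3)(2n+1)(2n-1)} \cos((2n+1)\pi x),}
#' so the coefficient of \eqn{\cos(\pi x)} is \eqn{8/(3\pi)} and the series
#' decays cubically in the mode number.  This resonant projection is what
#' makes the Dirichlet bifurcation transcritical: under zero-flux (Neumann)
#' conditions \eqn{\cos^2(\pi x) = (1 + \cos(2\pi x))/2} is orthogonal to the
#' critical mode and the quadratic term is non-secular.
#'
#' @param n nonnegative integer mode index (vectorized).
#' @return coefficient(s) of \eqn{\cos((2n+1)\pi x)}.
#' @examples
#' cos_sq_fourier_coef(0)  # 8/(3*pi)
#' @export
cos_sq_fourier_coef <- function(n) {
  if (any(n < 0) || any(n != round(n))) stop("n must be a nonnegative integer")
  8 * (-1)^(n + 1) / (pi * (2*n + 3) * (2*n + 1) * (2*n - 1))
}

# Projection coefficient of cos(2*m*pi*x) onto cos(pi*x) on [-1/2, 1/2]
# (inner-product ratio; the even cosines are what products of odd cosines
# generate).  m = 0 is the constant function.
even_mode_projection <- function(m) 4 * (-1)^(m + 1) / ((4 * m^2 - 1) * pi)

#' Quadratic form of the kinetics along the kernel direction
#'
#' The coefficient pair multiplying \eqn{a^2 \cos^2(\pi x)} in the
#' second-order expansion: with kernel vector \eqn{(\Lambda_u, \Lambda_v)},
#' \deqn{\Big(\tfrac12(f_{uu}\Lambda_u^2 + 2 f_{uv}\Lambda_u\Lambda_v +
#'  f_{vv}\Lambda_v^2),\ \tfrac12(g_{uu}\Lambda_u^2 +
#'  2 g_{uv}\Lambda_u\Lambda_v + g_{vv}\Lambda_v^2)\Big).}
#' Vanishes identically for linear kinetics.
#'
#' @param derivs a \code{\link{derivative_table}}.
#' @param Lambda_vector kernel vector (length 2; the usual normalization has
#'   v-component 1, possibly sign-flipped by the convention in
#'   \code{\link{kernel_vectors}}).
#' @return numeric length-2 vector.
#' @export
quadratic_form_projection <- function(derivs, Lambda_vector) {
  stopifnot(length(Lambda_vector) == 2L)
  0.5 * bilinear_form(derivs, Lambda_vector, Lambda_vector)
}

# Shared multiple-scales context: everything the order-by-order solves need.
ms_context <- function(system, derivs, linres) {
  J <- jacobian_matrix(derivs)
  D <- diffusion_matrix(system)
  L_c <- linres$L_c
  kv <- linres$kernel_vector
  av <- linres$adjoint_vector
  list(J = J, D = D, L_c = L_c, kv = kv, av = av,
       eL = sum(av * kv),                          # <eta, Lambda> vector dot
       Qv = quadratic_form_projection(derivs, kv),
       M = function(k) J - (k^2 / L_c^2) * D,
       derivs = derivs)
}

# Solve the singular critical-mode system M0 w = rhs under a gauge
# constraint fixing the kernel freedom: zero v-component ("vcomp", default),
# zero u-component ("ucomp"), or zero kernel-direction component ("kernel").
# rhs must satisfy the solvability condition (orthogonal to the adjoint
# kernel); the stacked least-squares system is then consistent.
solve_critical_mode <- function(ctx, rhs, gauge) {
  con <- switch(gauge,
                vcomp = c(0, 1), ucomp = c(1, 0), kernel = ctx$kv,
                stop("unknown gauge: ", gauge))
  M0 <- ctx$M(pi)
  sol <- qr.solve(rbind(M0, con), c(rhs, 0))
  if (max(abs(M0 %*% sol - rhs)) > 1e-8 * (1 + max(abs(rhs))))
    stop("critical-mode solve inconsistent; solvability condition violated")
  sol
}

#' Quadratic (transcritical) amplitude-equation coefficients, Dirichlet case
#'
#' Fredholm solvability of the second-order equation under Dirichlet
#' boundary conditions yields the transcritical normal form
#' \eqn{\partial a/\partial t_1 = p_1 L_1 a + p_2 a^2} with
#' \deqn{p_1 = \frac{2\pi^2(\eta\Lambda D_u + D_v)}{L_c^3(\eta\Lambda + 1)},
#' \qquad
#' p_2 = \frac{4(\eta\Lambda^2 f_{uu} + 2\eta\Lambda f_{uv} + \eta f_{vv} +
#'   g_{uu}\Lambda^2 + 2 g_{uv}\Lambda + g_{vv})}{3\pi(\eta\Lambda + 1)},}
#' evaluated with the sign convention of \code{\link{kernel_vectors}}
#' (so \eqn{p_2 \ge 0}).  \eqn{p_1} equals the derivative of the leading
#' dispersion growth rate with respect to \eqn{L} at \eqn{L_c}.
#'
#' @param system an \code{\link{rd_system}}.
#' @param derivs a \code{\link{derivative_table}}.
#' @param linres a \code{\link{linear_analysis}}.
#' @return list with \code{p1}, \code{p2}.
#' @export
dirichlet_quadratic_coefficients <- function(system, derivs, linres) {
  ctx <- ms_context(system, derivs, linres)
  if (abs(ctx$eL) < 1e-10 * sum(abs(ctx$av) * abs(ctx$kv)))
    stop("degenerate normalization: adjoint and kernel vectors are orthogonal")
  p1 <- 2 * pi^2 * sum(ctx$av * (ctx$D %*% ctx$kv)) / (ctx$L_c^3 * ctx$eL)
  p2 <- cos_sq_fourier_coef(0) * sum(ctx$av * ctx$Qv) / ctx$eL
  list(p1 = p1, p2 = p2)
}

#' Second-order field of the multiple-scales expansion
#'
#' Solves the second-order equation mode by mode after the secular part has
#' been removed by the quadratic solvability condition.  Under Dirichlet
#' conditions the field spans the odd cosine modes \eqn{\cos((2n+1)\pi x)},
#' \eqn{n = 0, \dots, N}; the critical mode \eqn{n = 0} is solved in a gauge
#' that zeroes one component of its coefficient (see Details).  Under
#' Neumann conditions (with \eqn{L_1 = 0}) exactly two modes appear: the
#' constant mode and \eqn{\cos(2\pi x)}.
#'
#' @details The critical-mode coefficient is determined only up to a
#' multiple of the kernel vector.  The default gauge \code{"vcomp"} zeroes
#' its v (inhibitor) component, in both the \eqn{a L_1} and \eqn{a^2}
#' sectors; \code{"ucomp"} zeroes the u component and \code{"kernel"} the
#' component along the kernel direction.  Physical predictions (steady
#' branch shapes, \eqn{p_1, p_2, p_3, p_5}) are gauge-invariant; the
#' third-order coefficient \eqn{p_4} is reported in the chosen gauge.
#'
#' @inheritParams dirichlet_quadratic_coefficients
#' @param bc \code{"dirichlet"} or \code{"neumann"}.
#' @param truncation_N number of odd cosine modes retained (Dirichlet).
#' @param gauge critical-mode gauge, see Details.
#' @return object of class \code{second_order_field}.  Dirichlet: list with
#'   \code{w_L}, \code{w_Q} (critical-mode coefficients per unit
#'   \eqn{a L_1} and \eqn{a^2}) and matrix \code{s} (2 x N, per-mode
#'   coefficients of \eqn{\cos((2n+1)\pi x)} per unit \eqn{a^2}).  Neumann:
#'   list with \code{c0}, \code{c2} (constant and \eqn{\cos(2\pi x)}
#'   coefficients per unit \eqn{a^2}).
#' @export
solve_second_order <- function(system, derivs, linres,
                               bc = c("dirichlet", "neumann"),
                               truncation_N = 128,
                               gauge = c("vcomp", "ucomp", "kernel")) {
  bc <- match.arg(bc); gauge <- match.arg(gauge)
  ctx <- ms_context(system, derivs, linres)
  if (bc == "neumann") {
    # cos^2 = 1/2 + cos(2 pi x)/2; the critical mode receives no forcing and
    # its free kernel multiple is set to zero.
    M2 <- ctx$M(2 * pi)
    if (abs(det(M2)) < 1e-10 * max(abs(M2))^2 ||
        abs(det(ctx$J)) < 1e-10 * max(abs(ctx$J))^2)
      stop("resonance: a non-critical mode matrix is singular ",
           "(violates the single-unstable-wavelength assumption)")
    out <- list(bc = bc,
                c0 = solve(ctx$J, -ctx$Qv / 2),
                c2 = solve(M2, -ctx$Qv / 2))
  } else {
    if (truncation_N < 8) stop("truncation_N must be at least 8")
    q <- dirichlet_quadratic_coefficients(system, derivs, linres)
    rhs_L <- q$p1 * ctx$kv - (2 * pi^2 / ctx$L_c^3) * c(ctx$D %*% ctx$kv)
    rhs_Q <- q$p2 * ctx$kv - cos_sq_fourier_coef(0) * ctx$Qv
    w_L <- solve_critical_mode(ctx, rhs_L, gauge)
    w_Q <- solve_critical_mode(ctx, rhs_Q, gauge)
    s <- vapply(seq_len(truncation_N), function(n) {
      Mn <- ctx$M((2 * n + 1) * pi)
      if (abs(det(Mn)) < 1e-10 * max(abs(Mn))^2)
        stop("resonance at mode ", 2 * n + 1,
             " (violates the single-unstable-wavelength assumption)")
      solve(Mn, -cos_sq_fourier_coef(n) * ctx$Qv)
    }, numeric(2))
    out <- list(bc = bc, w_L = w_L, w_Q = w_Q, s = s,
                gauge = gauge, p1 = q$p1, p2 = q$p2)
  }
  structure(out, class = "second_order_field")
}

#' Cubic (third-order) transcritical coefficients, Dirichlet case
#'
#' Assembles the third-order Fredholm solvability condition under Dirichlet
#' boundary conditions, combining the kernel-direction projections of the
#' slow-time derivative of the second-order field, the domain-scale
#' expansion of the diffusion prefactor, the quadratic cross terms between
#' first- and second-order fields, and the cubic Taylor term.  Together with
#' the quadratic condition this yields the amplitude equation
#' \deqn{\frac{1}{\epsilon}\frac{da}{dt} =
#'  (p_1(L_1 + \epsilon L_2) - p_3 \epsilon L_1^2)\,a +
#'  (p_2 - p_4 \epsilon L_1)\,a^2 - \epsilon p_5\,a^3,}
#' with all coefficients reported as plain numbers (the bookkeeping
#' \eqn{\epsilon} stripped).  \eqn{p_3} and \eqn{p_5} are gauge-invariant;
#' \eqn{p_4} depends on the critical-mode gauge (default \code{"vcomp"}).
#'
#' @inheritParams solve_second_order
#' @param conv_tol relative tolerance for the truncation convergence check
#'   (coefficients recomputed with \code{2 * truncation_N} modes must agree
#'   to this tolerance).
#' @return object of class \code{transcritical_coefficients}: list with
#'   \code{p1} ... \code{p5}, \code{slope_m} (\eqn{= p_1/p_2}, the
#'   magnitude of the supercritical branch slope \eqn{a = -m L_1}),
#'   \code{gauge}, \code{truncation_N}.
#' @examples
#' \donttest{
#' sys <- schnakenberg()
#' la <- linear_analysis(sys)
#' co <- dirichlet_cubic_coefficients(sys, la$derivs, la)
#' round(unlist(co[c("p1", "p2", "p3", "p4", "p5")]), 2)
#' }
#' @export
dirichlet_cubic_coefficients <- function(system, derivs = NULL, linres = NULL,
                                         truncation_N = 128,
                                         gauge = c("vcomp", "ucomp", "kernel"),
                                         conv_tol = 1e-6) {
  gauge <- match.arg(gauge)
  if (is.null(linres)) linres <- linear_analysis(system, derivs)
  if (is.null(derivs)) derivs <- linres$derivs
  one <- function(N) {
    ctx <- ms_context(system, derivs, linres)
    sof <- solve_second_order(system, derivs, linres, "dirichlet", N, gauge)
    p1 <- sof$p1; p2 <- sof$p2
    av <- ctx$av; kv <- ctx$kv; D <- ctx$D; L_c <- ctx$L_c; eL <- ctx$eL
    dvK <- sum(av * (D %*% kv))
    pr01 <- 0.5 * (even_mode_projection(0) + even_mode_projection(1)) # = 8/(3 pi)
    p3 <- -(-p1 * sum(av * sof$w_L) +
              (2 * pi^2 / L_c^3) * sum(av * (D %*% sof$w_L)) -
              (3 * pi^2 / L_c^4) * dvK) / eL
    p4 <- -(-2 * p1 * sum(av * sof$w_Q) - p2 * sum(av * sof$w_L) +
              (2 * pi^2 / L_c^3) * sum(av * (D %*% sof$w_Q)) +
              pr01 * sum(av * bilinear_form(derivs, kv, sof$w_L))) / eL
    harm <- sum(vapply(seq_len(N), function(n)
      0.5 * (even_mode_projection(n) + even_mode_projection(n + 1)) *
        sum(av * bilinear_form(derivs, kv, sof$s[, n])), numeric(1)))
    p5 <- -(-2 * p2 * sum(av * sof$w_Q) +
              pr01 * sum(av * bilinear_form(derivs, kv, sof$w_Q)) +
              harm + sum(av * trilinear_form(derivs, kv)) / 8) / eL
    list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5)
  }
  res <- one(truncation_N)
  res2 <- one(2 * truncation_N)
  rel <- abs(unlist(res2) - unlist(res)) / pmax(abs(unlist(res2)), 1e-12)
  if (any(rel > conv_tol))
    stop(sprintf(
      "cubic coefficients not converged in truncation: N=%d gives (%s), N=%d gives (%s)",
      truncation_N, paste(signif(unlist(res), 8), collapse = ", "),
      2 * truncation_N, paste(signif(unlist(res2), 8), collapse = ", ")))
  structure(c(res2, list(slope_m = res2$p1 / res2$p2, gauge = gauge,
                         truncation_N = truncation_N)),
            class = "transcritical_coefficients")
}

#' Cubic (pitchfork) amplitude-equation coefficients, Neumann case
#'
#' Under zero-flux boundary conditions the quadratic term is non-secular
#' (with \eqn{L_1 = 0}), so the first solvability condition arises at third
#' order and yields the pitchfork normal form
#' \eqn{\partial a/\partial t_2 = \mathrm{lin}\, L_2 a - \mathrm{cub}\, a^3}.
#' The linear coefficient equals the Dirichlet \eqn{p_1} (both are the
#' dispersion-rate derivative \eqn{d\,\mathrm{Re}\lambda_{\max}(\pi; L)/dL}
#' at \eqn{L_c}).  The cubic coefficient collects three contributions:
#' the mean-mode cross term, the \eqn{\cos(2\pi x)} second-harmonic cross
#' term, and the cubic Taylor term; all three are reported so their
#' relative sizes can be inspected.  The cubic coefficient has no gauge
#' freedom (kernel multiples of the critical mode project to zero under the
#' Neumann inner product).
#'
#' @inheritParams dirichlet_quadratic_coefficients
#' @return object of class \code{pitchfork_coefficients}: list with
#'   \code{lin}, \code{cub} and the breakdown \code{cub_mean_mode},
#'   \code{cub_second_harmonic}, \code{cub_taylor}.
#' @export
neumann_cubic_coefficients <- function(system, derivs = NULL, linres = NULL) {
  if (is.null(linres)) linres <- linear_analysis(system, derivs)
  if (is.null(derivs)) derivs <- linres$derivs
  ctx <- ms_context(system, derivs, linres)
  sof <- solve_second_order(system, derivs, linres, "neumann")
  av <- ctx$av; kv <- ctx$kv
  lin <- 2 * pi^2 * sum(av * (ctx$D %*% kv)) / (ctx$L_c^3 * ctx$eL)
  t_mean <- -sum(av * bilinear_form(derivs, kv, sof$c0)) / ctx$eL
  t_harm <- -0.5 * sum(av * bilinear_form(derivs, kv, sof$c2)) / ctx$eL
  t_cubic <- -sum(av * trilinear_form(derivs, kv)) / (8 * ctx$eL)
  structure(list(lin = lin, cub = t_mean + t_harm + t_cubic,
                 cub_mean_mode = t_mean, cub_second_harmonic = t_harm,
                 cub_taylor = t_cubic),
            class = "pitchfork_coefficients")
}

#' Amplitude equations for both boundary conditions
#'
#' Convenience wrapper running the full weakly nonlinear chain for a system:
#' linear analysis, Dirichlet transcritical coefficients to third order and
#' Neumann pitchfork coefficients.
#'
#' @inheritParams dirichlet_cubic_coefficients
#' @return list with \code{linear} (the \code{\link{linear_analysis}}),
#'   \code{dirichlet} (\code{transcritical_coefficients}) and
#'   \code{neumann} (\code{pitchfork_coefficients}).
#' @examples
#' \donttest{
#' amp <- amplitude_equations(schnakenberg())
#' round(amp$dirichlet$p1, 2); round(amp$neumann$cub, 2)
#' }
#' @export
amplitude_equations <- function(system, truncation_N = 128,
                                gauge = c("vcomp", "ucomp", "kernel")) {
  gauge <- match.arg(gauge)
  linres <- linear_analysis(system)
  if (!linres$diffusion_driven)
    stop("no diffusion-driven instability: amplitude equations undefined")
  list(linear = linres,
       dirichlet = dirichlet_cubic_coefficients(system, linres$derivs, linres,
                                                truncation_N, gauge),
       neumann = neumann_cubic_coefficients(system, linres$derivs, linres))
}

#' @export
print.transcritical_coefficients <- function(x, ...) {
  cat("transcritical amplitude equation (Dirichlet boundary conditions)\n")
  cat(sprintf(
    "  da/dt * (1/eps) = (%.2f (L1 + eps L2) - %.2f eps L1^2) a + (%.2f - %.2f eps L1) a^2 - %.2f eps a^3\n",
    x$p1, x$p3, x$p2, x$p4, x$p5))
  cat(sprintf("  supercritical branch slope m = p1/p2 = %.4f (gauge %s)\n",
              x$slope_m, x$gauge))
  invisible(x)
}

#' @export
print.pitchfork_coefficients <- function(x, ...) {
  cat("pitchfork amplitude equation (Neumann boundary conditions)\n")
  cat(sprintf("  da/dt2 = %.2f L2 a - %.2f a^3\n", x$lin, x$cub))
  cat(sprintf("  (cubic terms: mean mode %.2f, second harmonic %.2f, Taylor %.2f)\n",
              -x$cub_mean_mode, -x$cub_second_harmonic, -x$cub_taylor))
  invisible(x)
}

#' Steady amplitudes of an amplitude equation
#'
#' Transcritical case: steady states \eqn{a = 0} and \eqn{a = -p_1 L_1/p_2};
#' their stability exchanges at \eqn{L_1 = 0} and the two are never stable
#' simultaneously.  Pitchfork case: \eqn{a = 0} and, when the radicand is
#' nonnegative, \eqn{a = \pm\sqrt{\mathrm{lin}\, L_2/\mathrm{cub}}}; the
#' trivial state loses stability as \eqn{L_2} becomes positive.
#'
#' @param coeffs \code{transcritical_coefficients} or
#'   \code{pitchfork_coefficients}.
#' @param L1_or_L2 bifurcation-parameter offset (\eqn{L_1} for the
#'   transcritical case, \eqn{L_2} for the pitchfork case).
#' @return data frame with columns \code{amplitude}, \code{is_stable}.
#' @export
amplitude_steady_states <- function(coeffs, L1_or_L2) {
  UseMethod("amplitude_steady_states")
}

#' @export
amplitude_steady_states.transcritical_coefficients <- function(coeffs,
                                                               L1_or_L2) {
  p1 <- coeffs$p1; p2 <- coeffs$p2; L1 <- L1_or_L2
  if (abs(p2) < .Machine$double.eps * 100)
    stop("degenerate bifurcation: quadratic coefficient p2 is zero ",
         "(not transcritical at this order)")
  if (L1 == 0)
    return(data.frame(amplitude = 0, is_stable = NA))  # branches cross
  a1 <- -p1 * L1 / p2
  # d/da (p1 L1 a + p2 a^2) = p1 L1 + 2 p2 a
  data.frame(amplitude = c(0, a1),
             is_stable = c(p1 * L1 < 0, p1 * L1 + 2 * p2 * a1 < 0))
}

#' @export
amplitude_steady_states.pitchfork_coefficients <- function(coeffs, L1_or_L2) {
  lin <- coeffs$lin; cub <- coeffs$cub; L2 <- L1_or_L2
  if (abs(cub) < .Machine$double.eps * 100)
    stop("degenerate bifurcation: cubic coefficient is zero")
  rad <- lin * L2 / cub
  amps <- if (rad > 0) c(0, sqrt(rad), -sqrt(rad)) else 0
  data.frame(amplitude = amps,
             is_stable = vapply(amps, function(a)
               lin * L2 - 3 * cub * a^2 < 0, logical(1)))
}

#' Analytic bifurcation-branch prediction near onset
#'
#' Converts the amplitude equations into branch curves in the physical
#' variables for overlay against numerical continuation: for each \eqn{L},
#' the steady physical amplitude \eqn{A} (\eqn{= \epsilon a}) and the
#' extremum prediction \eqn{u_s + \Lambda_u A} of the activator field
#' (the critical mode evaluated at the domain centre).
#'
#' Transcritical quadratic order: a straight line \eqn{A = -m (L - L_c)}.
#' Third order: the quadratic-in-\eqn{A} steady-state relation
#' \eqn{p_5 A^2 - (p_2 - p_4\ell) A - (p_1\ell - p_3\ell^2) = 0}
#' (\eqn{\ell = L - L_c}), which is multivalued in \eqn{A} for some
#' \eqn{\ell > 0} -- a known artefact of the cubic truncation rather than a
#' real fold.  Pitchfork: \eqn{A = \pm\sqrt{\mathrm{lin}\,\ell/\mathrm{cub}}}.
#'
#' @param coeffs \code{transcritical_coefficients} or
#'   \code{pitchfork_coefficients}.
#' @param steady_state \code{steady_state} or length-2 numeric.
#' @param kernel_vector kernel vector (u, v), sign convention applied.
#' @param L_values domain scales at which to evaluate the branches.
#' @param L_c critical scale.
#' @param order \code{"quadratic"} or \code{"cubic"} (transcritical only).
#' @return data frame with columns \code{L}, \code{branch}, \code{A},
#'   \code{u_extremum}.
#' @export
predicted_branch <- function(coeffs, steady_state, kernel_vector, L_values,
                             L_c, order = c("quadratic", "cubic")) {
  order <- match.arg(order)
  us <- as_uv(steady_state)[1]
  Lu <- kernel_vector[1]
  ell <- L_values - L_c
  rows <- list()
  if (inherits(coeffs, "transcritical_coefficients")) {
    if (order == "quadratic") {
      A <- -coeffs$slope_m * ell
      rows[[1]] <- data.frame(L = L_values, branch = "transcritical", A = A)
    } else {
      disc <- (coeffs$p2 - coeffs$p4 * ell)^2 +
        4 * coeffs$p5 * (coeffs$p1 * ell - coeffs$p3 * ell^2)
      ok <- disc >= 0
      for (sgn in c(1, -1)) {
        A <- rep(NA_real_, length(ell))
        A[ok] <- ((coeffs$p2 - coeffs$p4 * ell[ok]) +
                    sgn * sqrt(disc[ok])) / (2 * coeffs$p5)
        rows[[length(rows) + 1L]] <-
          data.frame(L = L_values,
                     branch = if (sgn > 0) "cubic_upper" else "cubic_lower",
                     A = A)
      }
    }
  } else if (inherits(coeffs, "pitchfork_coefficients")) {
    rad <- coeffs$lin * ell / coeffs$cub
    for (sgn in c(1, -1)) {
      A <- ifelse(rad >= 0, sgn * sqrt(pmax(rad, 0)), NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(L = L_values,
                   branch = if (sgn > 0) "pitchfork_plus" else "pitchfork_minus",
                   A = A)
    }
  } else stop("unsupported coefficient object")
  out <- do.call(rbind, rows)
  out$u_extremum <- us + Lu * out$A
  out
}
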