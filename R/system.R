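#' Two-species reaction-diffusion system
#'
#' Constructs a reaction-diffusion model
#' \deqn{u_t = (D_u/L^2) u_{xx} + f(u, v), \qquad
#'       v_t = (D_v/L^2) v_{xx} + g(u, v)}
#' on a nondimensional unit interval, where the domain scale \code{L} plays
#' the role of the bifurcation parameter (growing \code{L} is equivalent to
#' growing the physical domain).
#'
#' Kinetics are supplied as closed-form expressions in \code{u} and \code{v},
#' either as strings or as unevaluated R expressions, with any extra named
#' parameters given through \code{params}.  All partial derivatives up to
#' third order are produced symbolically via \code{\link[stats]{D}}, so the
#' expressions must be at least three times differentiable wherever they are
#' evaluated.
#'
#' @param f,g kinetics for the two species, e.g. \code{"1 - 2*u + u^2*v"}.
#' @param D_u,D_v positive diffusivities.
#' @param L positive domain scale.
#' @param params named list of numeric kinetic parameters referenced by the
#'   expressions.
#' @param name optional label used in printing.
#' @return An object of class \code{rd_system}: a list carrying the kinetic
#'   expressions, vectorized evaluators \code{$f}, \code{$g} and first-order
#'   derivative evaluators \code{$f_u}, \code{$f_v}, \code{$g_u}, \code{$g_v}
#'   (functions of \code{(u, v)}), the diffusivities and the domain scale.
#' @seealso \code{\link{schnakenberg}}, \code{\link{find_steady_state}},
#'   \code{\link{derivative_table}}
#' @examples
#' sys <- rd_system("a - u", "1 - v", D_u = 0.001, D_v = 0.1,
#'                  params = list(a = 1))
#' find_steady_state(sys, c(0.5, 0.5))
#' @export
rd_system <- function(f, g, D_u, D_v, L = 1, params = list(), name = NULL) {
  stopifnot(is.numeric(D_u), is.numeric(D_v), is.numeric(L),
            length(D_u) == 1L, length(D_v) == 1L, length(L) == 1L)
  if (D_u <= 0 || D_v <= 0) stop("diffusivities D_u and D_v must be positive")
  if (L <= 0) stop("domain scale L must be positive")
  fexpr <- as_kinetics_expr(f)
  gexpr <- as_kinetics_expr(g)
  if (length(params) && is.null(names(params)))
    stop("'params' must be a named list")
  sys <- structure(list(
    fexpr = fexpr, gexpr = gexpr,
    D_u = D_u, D_v = D_v, L = L,
    params = lapply(params, as.numeric),
    name = name %||% "reaction-diffusion system"
  ), class = "rd_system")
  sys$f <- kinetics_fun(fexpr, sys$params)
  sys$g <- kinetics_fun(gexpr, sys$params)
  sys$f_u <- kinetics_fun(stats::D(fexpr, "u"), sys$params)
  sys$f_v <- kinetics_fun(stats::D(fexpr, "v"), sys$params)
  sys$g_u <- kinetics_fun(stats::D(gexpr, "u"), sys$params)
  sys$g_v <- kinetics_fun(stats::D(gexpr, "v"), sys$params)
  sys
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_kinetics_expr <- function(x) {
  if (is.character(x)) x <- str2lang(x)
  if (is.expression(x)) x <- x[[1]]
  if (!is.call(x) && !is.name(x) && !is.numeric(x))
    stop("kinetics must be a string or an R expression in (u, v)")
  x
}

kinetics_fun <- function(expr, params) {
  function(u, v) {
    r <- eval(expr, envir = c(list(u = u, v = v), params))
    if (length(r) == 1L && length(u) > 1L) r <- rep(r, length(u))
    r
  }
}

#' Schnakenberg reaction-diffusion system
#'
#' The cross-kinetics activator-inhibitor model
#' \deqn{f(u,v) = a - d\,u + u^2 v, \qquad g(u,v) = b - u^2 v,}
#' whose two morphogen patterns are out of phase (peaks of one sit at troughs
#' of the other).  The defaults \code{a = 1}, \code{b = 3}, \code{d = 2},
#' \code{D_u = 1/1000}, \code{D_v = 1/10} give the canonical Turing-unstable
#' fixture with homogeneous steady state \eqn{(u_s, v_s) = (2, 3/4)}.  With
#' \code{d = 1} the steady state is \eqn{(a + b,\; b/(a+b)^2)}.
#'
#' @param a,b production rates of the two species.
#' @param d linear decay rate of the activator.
#' @inheritParams rd_system
#' @return an \code{\link{rd_system}}.
#' @examples
#' sys <- schnakenberg()
#' find_steady_state(sys, c(1, 1))  # (2, 3/4)
#' @export
schnakenberg <- function(a = 1, b = 3, d = 2,
                         D_u = 1/1000, D_v = 1/10, L = 1) {
  rd_system("a - d*u + u^2*v", "b - u^2*v", D_u = D_u, D_v = D_v, L = L,
            params = list(a = a, b = b, d = d), name = "Schnakenberg")
}

#' Look up a built-in kinetics fixture by name
#'
#' @param name currently only \code{"schnakenberg"}.
#' @param ... passed on to the fixture constructor.
#' @return an \code{\link{rd_system}}.
#' @export
builtin_system <- function(name, ...) {
  switch(tolower(name),
         schnakenberg = schnakenberg(...),
         stop("unknown built-in system: ", name))
}

#' @export
print.rd_system <- function(x, ...) {
  cat(x$name, "\n")
  cat("  f(u,v) =", deparse(x$fexpr), "\n")
  cat("  g(u,v) =", deparse(x$gexpr), "\n")
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params),
                           sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  D_u = %g, D_v = %g, L = %g\n", x$D_u, x$D_v, x$L))
  invisible(x)
}

#' Homogeneous steady state of the kinetics
#'
#' Finds a root of \eqn{(f, g)} by damped Newton iteration from the supplied
#' guess, using the symbolic Jacobian.  Only the root reached from the guess
#' is returned; the analysis downstream is local to one steady state.  Roots
#' with negative components are rejected by default, reflecting the
#' convention that concentrations are nonnegative.
#'
#' @param system an \code{\link{rd_system}}.
#' @param guess numeric length-2 positive initial guess \code{c(u, v)}.
#' @param tol residual tolerance (max norm) for acceptance of the root.
#' @param max_iter maximum Newton iterations.
#' @param positivity \code{"error"} rejects negative roots, \code{"warn"}
#'   keeps them with a warning, \code{"ignore"} keeps them silently.  The
#'   positivity assumption is a modelling convenience and may be relaxed.
#' @return object of class \code{steady_state}: list with components
#'   \code{u_s}, \code{v_s} and the final \code{residual}.
#' @examples
#' find_steady_state(schnakenberg(), c(1, 1))
#' @export
find_steady_state <- function(system, guess = c(1, 1), tol = 1e-12,
                              max_iter = 50,
                              positivity = c("error", "warn", "ignore")) {
  positivity <- match.arg(positivity)
  stopifnot(inherits(system, "rd_system"), length(guess) == 2L)
  if (any(guess <= 0) && positivity == "error")
    stop("initial guess must have positive entries")
  x <- as.numeric(guess)
  res_fun <- function(x) c(system$f(x[1], x[2]), system$g(x[1], x[2]))
  jac_fun <- function(x) matrix(c(system$f_u(x[1], x[2]),
                                  system$g_u(x[1], x[2]),
                                  system$f_v(x[1], x[2]),
                                  system$g_v(x[1], x[2])), 2L, 2L)
  r <- res_fun(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol) break
    step <- tryCatch(solve(jac_fun(x), -r),
                     error = function(e)
                       stop(sprintf(
                         "no steady-state convergence: singular kinetics Jacobian at (%g, %g), residual %g",
                         x[1], x[2], max(abs(r)))))
    lam <- 1
    repeat {                           # damped step: insist on residual decrease
      xn <- x + lam * step
      rn <- res_fun(xn)
      if (all(is.finite(rn)) && max(abs(rn)) < max(abs(r))) break
      lam <- lam / 2
      if (lam < 1e-10)
        stop(sprintf(
          "steady-state iteration failed to converge from (%g, %g); residual %g",
          guess[1], guess[2], max(abs(r))))
    }
    x <- xn; r <- rn
  }
  if (max(abs(r)) >= tol)
    stop(sprintf(
      "no steady-state convergence from (%g, %g) after %d iterations; residual %g",
      guess[1], guess[2], max_iter, max(abs(r))))
  if (any(x < 0)) {
    msg <- sprintf("steady state (%g, %g) violates positivity", x[1], x[2])
    if (positivity == "error") stop(msg)
    if (positivity == "warn") warning(msg)
  }
  structure(list(u_s = x[1], v_s = x[2], residual = max(abs(r))),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady state: u_s = %.10g, v_s = %.10g (residual %.2e)\n",
              x$u_s, x$v_s, x$residual))
  invisible(x)
}

#' Kinetic partial derivatives at the steady state
#'
#' Evaluates all partial derivatives of \eqn{f} and \eqn{g} up to third order
#' at \eqn{(u_s, v_s)}: the Jacobian entries, the six second-order and the
#' eight third-order derivatives.  One value is stored per multi-index, so
#' mixed partials are symmetric by construction.  Differentiation is symbolic
#' by default, with central finite differences available as a fallback for
#' expressions \code{\link[stats]{D}} cannot handle.
#'
#' @param system an \code{\link{rd_system}}.
#' @param steady_state a \code{steady_state} (from
#'   \code{\link{find_steady_state}}) or a numeric length-2 vector.
#' @param method \code{"symbolic"} or \code{"fd"}.
#' @return object of class \code{derivative_table}: a named list with entries
#'   \code{f_u, f_v, g_u, g_v}, \code{f_uu, f_uv, f_vv, g_uu, g_uv, g_vv},
#'   \code{f_uuu, f_uuv, f_uvv, f_vvv, g_uuu, g_uuv, g_uvv, g_vvv}.
#' @examples
#' sys <- schnakenberg()
#' ss <- find_steady_state(sys, c(1, 1))
#' derivative_table(sys, ss)$f_u   # 1
#' @export
derivative_table <- function(system, steady_state,
                             method = c("symbolic", "fd")) {
  method <- match.arg(method)
  pt <- as_uv(steady_state)
  tab <- if (method == "symbolic")
    deriv_table_symbolic(system, pt) else deriv_table_fd(system, pt)
  bad <- !vapply(tab, function(z) is.finite(z), logical(1))
  if (any(bad))
    stop("non-finite kinetic derivatives at the steady state: ",
         paste(names(tab)[bad], collapse = ", "))
  structure(c(tab, list(u_s = pt[1], v_s = pt[2])),
            class = "derivative_table")
}

as_uv <- function(ss) {
  if (inherits(ss, "steady_state")) c(ss$u_s, ss$v_s)
  else { stopifnot(is.numeric(ss), length(ss) == 2L); as.numeric(ss) }
}

deriv_table_symbolic <- function(system, pt) {
  env <- c(list(u = pt[1], v = pt[2]), system$params)
  d_eval <- function(expr, vars) {
    for (v in vars) {
      expr <- tryCatch(stats::D(expr, v),
                       error = function(e)
                         stop("kinetics not symbolically differentiable in '",
                              v, "': ", conditionMessage(e)))
    }
    as.numeric(eval(expr, envir = env))
  }
  out <- list()
  for (h in c("f", "g")) {
    expr <- if (h == "f") system$fexpr else system$gexpr
    for (idx in deriv_multi_indices()) {
      out[[paste0(h, "_", paste(idx, collapse = ""))]] <- d_eval(expr, idx)
    }
  }
  out
}

deriv_multi_indices <- function() {
  list(c("u"), c("v"),
       c("u", "u"), c("u", "v"), c("v", "v"),
       c("u", "u", "u"), c("u", "u", "v"), c("u", "v", "v"), c("v", "v", "v"))
}

# Central finite differences; step size balances truncation against round-off,
# h ~ eps^(1/(order + 2)) scaled by the magnitude of the base point.
deriv_table_fd <- function(system, pt) {
  eps <- .Machine$double.eps
  scale <- pmax(1, abs(pt))
  h1 <- eps^(1/3) * scale; h2 <- eps^(1/4) * scale; h3 <- eps^(1/5) * scale
  out <- list()
  for (h in c("f", "g")) {
    fn <- if (h == "f") system$f else system$g
    e <- function(du, dv) fn(pt[1] + du, pt[2] + dv)
    d1 <- function(i) {
      s <- if (i == 1) c(h1[1], 0) else c(0, h1[2])
      (e(s[1], s[2]) - e(-s[1], -s[2])) / (2 * h1[i])
    }
    d2 <- function(i, j) {
      if (i == j) {
        s <- if (i == 1) c(h2[1], 0) else c(0, h2[2])
        (e(s[1], s[2]) - 2 * e(0, 0) + e(-s[1], -s[2])) / h2[i]^2
      } else {
        (e(h2[1], h2[2]) - e(h2[1], -h2[2]) - e(-h2[1], h2[2]) +
           e(-h2[1], -h2[2])) / (4 * h2[1] * h2[2])
      }
    }
    d3 <- function(idx) {
      nu <- sum(idx == "u")
      hu <- h3[1]; hv <- h3[2]
      if (nu == 3) (e(2*hu,0) - 2*e(hu,0) + 2*e(-hu,0) - e(-2*hu,0)) / (2*hu^3)
      else if (nu == 0) (e(0,2*hv) - 2*e(0,hv) + 2*e(0,-hv) - e(0,-2*hv)) / (2*hv^3)
      else if (nu == 2) {  # d^3/du^2 dv: second difference in u of first difference in v
        (e(hu,hv) - e(hu,-hv) - 2*(e(0,hv) - e(0,-hv)) + e(-hu,hv) - e(-hu,-hv)) /
          (2 * hv * hu^2)
      } else {             # d^3/du dv^2
        (e(hu,hv) - e(-hu,hv) - 2*(e(hu,0) - e(-hu,0)) + e(hu,-hv) - e(-hu,-hv)) /
          (2 * hu * hv^2)
      }
    }
    out[[paste0(h, "_u")]] <- d1(1); out[[paste0(h, "_v")]] <- d1(2)
    out[[paste0(h, "_uu")]] <- d2(1, 1); out[[paste0(h, "_uv")]] <- d2(1, 2)
    out[[paste0(h, "_vv")]] <- d2(2, 2)
    out[[paste0(h, "_uuu")]] <- d3(c("u","u","u"))
    out[[paste0(h, "_uuv")]] <- d3(c("u","u","v"))
    out[[paste0(h, "_uvv")]] <- d3(c("u","v","v"))
    out[[paste0(h, "_vvv")]] <- d3(c("v","v","v"))
  }
  out
}

#' @export
print.derivative_table <- function(x, ...) {
  cat(sprintf("kinetic derivatives at (u_s, v_s) = (%.6g, %.6g)\n",
              x$u_s, x$v_s))
  nm <- setdiff(names(x), c("u_s", "v_s"))
  cat(paste(sprintf("  %-6s = %.6g", nm, unlist(x[nm])), collapse = "\n"), "\n")
  invisible(x)
}

# Jacobian and diffusivity matrices used throughout the analysis chain.
jacobian_matrix <- function(derivs)
  matrix(c(derivs$f_u, derivs$g_u, derivs$f_v, derivs$g_v), 2L, 2L)

diffusion_matrix <- function(system) diag(c(system$D_u, system$D_v))

# Symmetric bilinear form B(x, y) from the second-order Taylor terms:
# F(us + w) = J w + B(w, w)/2 + T(w, w, w)/6 + ...
bilinear_form <- function(derivs, x, y) {
  c(derivs$f_uu * x[1]*y[1] + derivs$f_uv * (x[1]*y[2] + x[2]*y[1]) +
      derivs$f_vv * x[2]*y[2],
    derivs$g_uu * x[1]*y[1] + derivs$g_uv * (x[1]*y[2] + x[2]*y[1]) +
      derivs$g_vv * x[2]*y[2])
}

# Trilinear form T(x, x, x) from the third-order Taylor terms.
trilinear_form <- function(derivs, x) {
  c(derivs$f_uuu * x[1]^3 + 3 * derivs$f_uuv * x[1]^2 * x[2] +
      3 * derivs$f_uvv * x[1] * x[2]^2 + derivs$f_vvv * x[2]^3,
    derivs$g_uuu * x[1]^3 + 3 * derivs$g_uuv * x[1]^2 * x[2] +
      3 * derivs$g_uvv * x[1] * x[2]^2 + derivs$g_vvv * x[2]^3)
}
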