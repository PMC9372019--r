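#' Discretized steady-state problem for continuation
#'
#' Assembles the finite-difference steady problem
#' \eqn{0 = (1/L^2) D \Delta_h y + F(y)} on the boundary-condition-
#' appropriate grid, with residual, dense Jacobian and parameter-derivative
#' closures used by the Newton corrector and the arclength continuation.
#'
#' @param system an \code{\link{rd_system}}.
#' @param bc \code{"dirichlet"} or \code{"neumann"}.
#' @param n_interior number of interior unknowns per species (Dirichlet) or
#'   total nodes per species (Neumann).
#' @return object of class \code{rd_discrete}: list with the operator
#'   \code{op}, \code{n} (unknowns per species), \code{residual(y, L)},
#'   \code{jacobian(y, L)}, \code{dFdL(y, L)}, \code{homogeneous()} (the
#'   pinned steady state as a state vector), extractors \code{u_of(y)},
#'   \code{v_of(y)}.
#' @export
discretize_steady <- function(system, bc = c("dirichlet", "neumann"),
                              n_interior = 200) {
  bc <- match.arg(bc)
  ss <- find_steady_state(system)
  n_nodes <- if (bc == "dirichlet") n_interior + 2L else n_interior
  op <- build_operator(system, bc, n_nodes, ss)
  n <- op$n_unknowns
  A <- op$lap_matrix()
  Du <- system$D_u; Dv <- system$D_v
  structure(list(
    system = system, bc = bc, op = op, n = n,
    residual = function(y, L) {
      u <- y[1:n]; v <- y[(n + 1):(2 * n)]
      c(Du / L^2 * op$lap_u(u) + system$f(u, v),
        Dv / L^2 * op$lap_v(v) + system$g(u, v))
    },
    jacobian = function(y, L) {
      u <- y[1:n]; v <- y[(n + 1):(2 * n)]
      J <- matrix(0, 2 * n, 2 * n)
      J[1:n, 1:n] <- Du / L^2 * A
      diag(J[1:n, 1:n]) <- diag(J[1:n, 1:n]) + system$f_u(u, v)
      J[1:n, (n + 1):(2 * n)] <- diag(system$f_v(u, v), n)
      J[(n + 1):(2 * n), 1:n] <- diag(system$g_u(u, v), n)
      J[(n + 1):(2 * n), (n + 1):(2 * n)] <- Dv / L^2 * A
      diag(J[(n + 1):(2 * n), (n + 1):(2 * n)]) <-
        diag(J[(n + 1):(2 * n), (n + 1):(2 * n)]) + system$g_v(u, v)
      J
    },
    dFdL = function(y, L) {
      u <- y[1:n]; v <- y[(n + 1):(2 * n)]
      -2 / L * c(Du / L^2 * op$lap_u(u), Dv / L^2 * op$lap_v(v))
    },
    homogeneous = function() c(rep(op$steady[1], n), rep(op$steady[2], n)),
    u_of = function(y) y[1:n],
    v_of = function(y) y[(n + 1):(2 * n)]
  ), class = "rd_discrete")
}

#' Newton corrector for a discretized steady state
#'
#' Damped Newton iteration at fixed \eqn{L}, with the rightmost eigenvalues
#' of the linearization attached for stability classification.
#'
#' @param disc an \code{\link{discretize_steady}} result.
#' @param L domain scale.
#' @param guess state vector (length \code{2 * disc$n}).
#' @param tol residual tolerance (max norm).
#' @param max_iter Newton iteration cap.
#' @param n_eigs number of rightmost eigenvalues to retain.
#' @return object of class \code{branch_point}: list with \code{L},
#'   \code{y}, \code{res_norm}, \code{iterations},
#'   \code{leading_eigenvalues} (complex, sorted by decreasing real part),
#'   \code{stable}, \code{max_u}, \code{min_u}.
#' @export
corrector <- function(disc, L, guess, tol = 1e-10, max_iter = 30,
                      n_eigs = 6, tol_floor = 1e-8) {
  y <- as.numeric(guess)
  r <- disc$residual(y, L)
  hist <- max(abs(r))
  stalled <- FALSE
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol) break
    step <- solve(disc$jacobian(y, L), -r)
    lam <- 1
    repeat {
      yn <- y + lam * step
      rn <- disc$residual(yn, L)
      if (all(is.finite(rn)) &&
          (max(abs(rn)) < max(abs(r)) || max(abs(rn)) < tol)) break
      lam <- lam / 2
      if (lam < 1e-8) {
        # stalled at the round-off floor of the discrete residual
        if (max(abs(r)) < tol_floor) { stalled <- TRUE; break }
        stop("Newton corrector diverged at L = ", signif(L, 6),
             "; residual history: ", paste(signif(hist, 3), collapse = " "))
      }
    }
    if (stalled) break
    y <- yn; r <- rn
    hist <- c(hist, max(abs(r)))
  }
  if (max(abs(r)) >= tol && !stalled)
    stop("Newton corrector did not reach tolerance at L = ", signif(L, 6),
         "; residual history: ", paste(signif(hist, 3), collapse = " "))
  branch_point(disc, L, y, max(abs(r)), it, n_eigs)
}

branch_point <- function(disc, L, y, res_norm, iterations, n_eigs = 6) {
  ev <- eigen(disc$jacobian(y, L), only.values = TRUE)$values
  ev <- ev[order(-Re(ev))][seq_len(min(n_eigs, length(ev)))]
  u <- disc$u_of(y)
  structure(list(L = L, y = y, res_norm = res_norm,
                 iterations = iterations,
                 leading_eigenvalues = ev, stable = Re(ev[1]) < 0,
                 max_u = max(u), min_u = min(u)),
            class = "branch_point")
}

#' @export
print.branch_point <- function(x, ...) {
  cat(sprintf(
    "branch point: L = %.6g, max(u) = %.4g, min(u) = %.4g, %s (Re lambda_1 = %.3g)\n",
    x$L, x$max_u, x$min_u, if (x$stable) "stable" else "unstable",
    Re(x$leading_eigenvalues[1])))
  invisible(x)
}

#' Pseudo-arclength continuation of a steady branch
#'
#' Secant-predictor / bordered-Newton-corrector continuation in \eqn{L}
#' with adaptive step length.  The arclength metric weights the state by
#' \eqn{1/\sqrt{n}} so diagrams are resolution-independent, and the
#' parameter is unweighted; folds are traversed without requiring
#' monotonicity in \eqn{L}.  Stability is classified at every accepted
#' point from the rightmost eigenvalues.
#'
#' @param disc an \code{\link{discretize_steady}} result.
#' @param start a \code{\link{corrector}}-converged \code{branch_point}.
#' @param direction initial direction of travel in \eqn{L} (+1 or -1).
#' @param L_window numeric length-2; continuation stops when \eqn{L} leaves
#'   this window.
#' @param ds0,ds_max,ds_min initial, maximal, minimal arclength steps.
#' @param max_steps cap on accepted points.
#' @param stop_when optional function of the latest \code{branch_point}
#'   returning \code{TRUE} to stop early (e.g. amplitude bound).
#' @param tol corrector residual tolerance (max norm).
#' @param tol_floor acceptance bound for iterates stalled at the
#'   round-off floor of the discrete residual (the \eqn{1/h^2} Laplacian
#'   scale bounds the attainable residual from below).
#' @param prev optional \code{branch_point} preceding \code{start} on the
#'   same branch; when given, the initial tangent is the secant from
#'   \code{prev} to \code{start} (useful after branch switching).  Otherwise
#'   the tangent comes from the Jacobian bordered with the parameter
#'   derivative.
#' @return object of class \code{branch}: list with \code{points} (list of
#'   \code{branch_point}), \code{s} (arclength), \code{events} (see
#'   \code{\link{detect_events}}; filled by it), \code{reason} (why
#'   continuation stopped).
#' @export
continue_branch <- function(disc, start, direction = +1,
                            L_window = c(0.04, 1.0),
                            ds0 = 1e-3, ds_max = 5e-3, ds_min = 1e-8,
                            max_steps = 400, stop_when = NULL,
                            prev = NULL, tol = 1e-10, tol_floor = 1e-8) {
  n <- disc$n
  th2 <- 1 / (2 * n)                       # state weight^2 (1/sqrt(2n) scaling)
  znorm <- function(dy, dL) sqrt(th2 * sum(dy^2) + dL^2)
  pts <- list(start)
  svals <- 0
  if (!is.null(prev)) {
    dy <- start$y - prev$y; dLp <- start$L - prev$L
    nrm <- znorm(dy, dLp)
    ty <- dy / nrm; tL <- dLp / nrm
  } else {
    # initial tangent: solve J ydot = -dF/dL, tangent ~ (ydot, 1) oriented
    J <- disc$jacobian(start$y, start$L)
    ydot <- tryCatch(solve(J, -disc$dFdL(start$y, start$L)),
                     error = function(e) numeric(2 * n))  # singular: y constant
    nrm <- znorm(ydot, 1)
    ty <- ydot / nrm; tL <- 1 / nrm
    if (direction < 0) { ty <- -ty; tL <- -tL }
  }
  ds <- ds0
  reason <- "max_steps"
  step_ct <- 0
  while (step_ct < max_steps) {
    cur <- pts[[length(pts)]]
    ok <- FALSE
    while (!ok) {
      y <- cur$y + ds * ty
      L <- cur$L + ds * tL
      it_used <- NA
      converged <- FALSE
      r <- disc$residual(y, L)
      cres <- th2 * sum(ty * (y - cur$y)) + tL * (L - cur$L) - ds
      for (it in 1:20) {
        if (max(abs(r)) < tol && abs(cres) < tol) {
          converged <- TRUE; it_used <- it; break
        }
        J <- disc$jacobian(y, L)
        bigA <- rbind(cbind(J, disc$dFdL(y, L)), c(th2 * ty, tL))
        dz <- tryCatch(solve(bigA, -c(r, cres)), error = function(e) NULL)
        if (is.null(dz)) break
        # damped update: insist the combined residual norm decreases
        n0 <- max(max(abs(r)), abs(cres))
        lam <- 1
        repeat {
          yn <- y + lam * dz[1:(2 * n)]
          Ln <- L + lam * dz[2 * n + 1]
          rn <- disc$residual(yn, Ln)
          cn <- th2 * sum(ty * (yn - cur$y)) + tL * (Ln - cur$L) - ds
          if (all(is.finite(rn)) &&
              (max(max(abs(rn)), abs(cn)) < n0 || n0 < tol)) break
          lam <- lam / 2
          if (lam < 1e-6) break
        }
        if (lam < 1e-6) {
          # round-off floor: the 1/h^2 Laplacian scale bounds the attainable
          # residual; accept a stalled iterate that is already tiny
          if (n0 < tol_floor) { converged <- TRUE; it_used <- it }
          break
        }
        y <- yn; L <- Ln; r <- rn; cres <- cn
      }
      if (converged) {
        ok <- TRUE
      } else {
        ds <- ds / 2
        if (ds < ds_min) {
          attr(pts, "truncated") <- TRUE
          return(finish_branch(pts, svals, "corrector failure at minimum step"))
        }
      }
    }
    new_pt <- branch_point(disc, L, y, max(abs(r)), it_used)
    pts[[length(pts) + 1L]] <- new_pt
    svals <- c(svals, svals[length(svals)] + ds)
    step_ct <- step_ct + 1
    # exact tangent at the new point from the bordered Jacobian, oriented to
    # keep travelling forward; secant as fallback
    tau <- tryCatch({
      J <- disc$jacobian(new_pt$y, new_pt$L)
      bigA <- rbind(cbind(J, disc$dFdL(new_pt$y, new_pt$L)), c(th2 * ty, tL))
      solve(bigA, c(numeric(2 * n), 1))
    }, error = function(e) NULL)
    if (is.null(tau) || !all(is.finite(tau))) {
      tau <- c(new_pt$y - cur$y, new_pt$L - cur$L)
    }
    nrm <- znorm(tau[1:(2 * n)], tau[2 * n + 1])
    tyn <- tau[1:(2 * n)] / nrm; tLn <- tau[2 * n + 1] / nrm
    if (th2 * sum(tyn * ty) + tLn * tL < 0) { tyn <- -tyn; tLn <- -tLn }
    ty <- tyn; tL <- tLn
    if (!is.na(it_used) && it_used <= 4) ds <- min(ds * 1.4, ds_max)
    else if (!is.na(it_used) && it_used > 7) ds <- max(ds * 0.6, ds_min)
    if (new_pt$L < L_window[1] || new_pt$L > L_window[2]) {
      reason <- "left L window"; break
    }
    if (!is.null(stop_when) && isTRUE(stop_when(new_pt))) {
      reason <- "stop condition"; break
    }
  }
  finish_branch(pts, svals, reason)
}

finish_branch <- function(pts, svals, reason) {
  structure(list(points = pts, s = svals, events = NULL, reason = reason),
            class = "branch")
}

#' @export
print.branch <- function(x, ...) {
  Ls <- vapply(x$points, `[[`, numeric(1), "L")
  cat(sprintf("branch: %d points, L in [%.4g, %.4g] (%s)\n",
              length(x$points), min(Ls), max(Ls), x$reason))
  if (!is.null(x$events) && nrow(x$events))
    print(x$events)
  invisible(x)
}

#' Detect bifurcation and fold events along a branch
#'
#' Scans consecutive points for sign changes of the leading real eigenvalue
#' part (stability change) and of \eqn{dL/ds} (fold).  A stability change
#' without a fold is classified as a bifurcation and its location refined
#' by bisection in \eqn{L} with the Newton corrector (states interpolated
#' along the branch); a fold location is refined by a local quadratic fit
#' of \eqn{L(s)}.
#'
#' @param branch a \code{\link{continue_branch}} result.
#' @param disc the discretization used to compute the branch (needed for
#'   refinement; omit to skip refinement).
#' @param L_tol refinement tolerance in \eqn{L}.
#' @return the branch with \code{$events} set: data frame with columns
#'   \code{type} (\code{"bifurcation"}/\code{"fold"}), \code{L},
#'   \code{index} (segment start).
#' @export
detect_events <- function(branch, disc = NULL, L_tol = 1e-4) {
  pts <- branch$points
  if (length(pts) < 3) { branch$events <- empty_events(); return(branch) }
  Ls <- vapply(pts, `[[`, numeric(1), "L")
  lead <- vapply(pts, function(p) Re(p$leading_eigenvalues[1]), numeric(1))
  dL <- diff(Ls)
  ev <- list()
  for (i in seq_len(length(pts) - 1)) {
    fold_here <- i >= 2 && dL[i - 1] * dL[i] < 0
    eig_cross <- lead[i] * lead[i + 1] < 0
    if (fold_here) {
      # quadratic fit of L(s) through the three surrounding points
      s3 <- branch$s[(i - 1):(i + 1)]; L3 <- Ls[(i - 1):(i + 1)]
      co <- stats::coef(stats::lm(L3 ~ s3 + I(s3^2)))
      Lf <- if (abs(co[3]) > 0) co[1] - co[2]^2 / (4 * co[3]) else Ls[i]
      ev[[length(ev) + 1L]] <- data.frame(type = "fold", L = unname(Lf),
                                          index = i)
    } else if (eig_cross) {
      Lb <- Ls[i + 1]
      if (!is.null(disc)) {
        lo <- i; hi <- i + 1
        ya <- pts[[lo]]$y; yb <- pts[[hi]]$y
        La <- Ls[lo]; Lb2 <- Ls[hi]
        ga <- lead[lo]; gb <- lead[hi]
        for (k in 1:40) {
          if (abs(Lb2 - La) < L_tol) break
          Lm <- (La + Lb2) / 2
          w <- (Lm - La) / (Lb2 - La)
          pm <- tryCatch(corrector(disc, Lm, (1 - w) * ya + w * yb),
                         error = function(e) NULL)
          if (is.null(pm)) break
          gm <- Re(pm$leading_eigenvalues[1])
          if (ga * gm <= 0) { Lb2 <- Lm; yb <- pm$y; gb <- gm }
          else { La <- Lm; ya <- pm$y; ga <- gm }
        }
        Lb <- (La + Lb2) / 2
      }
      ev[[length(ev) + 1L]] <- data.frame(type = "bifurcation",
                                          L = unname(Lb), index = i)
    }
  }
  branch$events <- if (length(ev)) do.call(rbind, ev) else empty_events()
  branch
}

empty_events <- function()
  data.frame(type = character(), L = numeric(), index = integer())

#' Switch onto a bifurcating branch
#'
#' At a simple bifurcation point, seeds the corrector with the converged
#' state perturbed along the critical eigenvector,
#' \eqn{y \pm \delta\,\phi}, at a slightly offset parameter value, and
#' converges to an off-branch point.  The eigenvector sign is
#' canonicalized so that \code{sign = +1} perturbs toward positive
#' projected amplitude (activator above the steady state for the first
#' mode).  If the corrector falls back onto the original branch the
#' perturbation is enlarged and retried.
#'
#' @param disc the discretization.
#' @param point a \code{branch_point} at (or near) the bifurcation.
#' @param sign +1 or -1: which side of the kernel direction to take.
#' @param delta initial perturbation amplitude.
#' @param L_offset parameter offset applied before correcting.
#' @param retries enlargement retries.
#' @return a converged off-branch \code{branch_point}.
#' @export
switch_branch <- function(disc, point, sign = +1, delta = 0.02,
                          L_offset = 1e-3, retries = 4) {
  es <- eigen(disc$jacobian(point$y, point$L))
  i0 <- which.max(Re(es$values))
  phi <- Re(es$vectors[, i0])
  phi <- phi / sqrt(sum(phi^2) / (2 * disc$n))       # rms-normalized
  xs <- disc$op$x[disc$op$unknowns]
  # canonical sign: positive projection of the u-part on the first mode
  pr <- sum(phi[1:disc$n] * cos(pi * xs))
  if (pr < 0) phi <- -phi
  L_new <- point$L + L_offset
  base <- corrector(disc, L_new, point$y)
  d <- delta
  for (k in seq_len(retries)) {
    cand <- tryCatch(corrector(disc, L_new, point$y + sign * d * phi),
                     error = function(e) NULL)
    if (!is.null(cand)) {
      dist <- sqrt(sum((cand$y - base$y)^2) / (2 * disc$n))
      if (dist > 1e-5) return(cand)
    }
    d <- d * 4
  }
  stop("branch switching failed: corrector kept returning to the old branch")
}

#' Long-format bifurcation-diagram table
#'
#' @param branches a \code{branch} or list of branches.
#' @return data frame with columns \code{branch}, \code{s}, \code{L},
#'   \code{max_u}, \code{min_u}, \code{stable}, \code{event}.
#' @export
branch_diagram <- function(branches) {
  if (inherits(branches, "branch")) branches <- list(branches)
  out <- lapply(seq_along(branches), function(b) {
    br <- branches[[b]]
    ev_idx <- if (!is.null(br$events) && nrow(br$events)) br$events$index
      else integer()
    data.frame(
      branch = b,
      s = br$s,
      L = vapply(br$points, `[[`, numeric(1), "L"),
      max_u = vapply(br$points, `[[`, numeric(1), "max_u"),
      min_u = vapply(br$points, `[[`, numeric(1), "min_u"),
      stable = vapply(br$points, `[[`, logical(1), "stable"),
      event = seq_along(br$points) %in% ev_idx
    )
  })
  do.call(rbind, out)
}

#' @export
plot.branch <- function(x, ...) {
  d <- branch_diagram(x)
  graphics::matplot(d$L, cbind(d$max_u, d$min_u), type = "p",
                    pch = ifelse(d$stable, 16, 1), cex = 0.5,
                    xlab = "L", ylab = "u extrema", ...)
  invisible(x)
}
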