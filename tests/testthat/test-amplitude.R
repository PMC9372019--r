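test_that("cos^2 Fourier coefficients match quadrature on [-1/2, 1/2]", {
  expect_equal(cos_sq_fourier_coef(0), 8 / (3 * pi))
  # quadrature oracle: coefficient of cos((2n+1) pi x) is
  # 2 * integral of cos^2(pi x) cos((2n+1) pi x)
  for (n in 0:5) {
    oracle <- 2 * stats::integrate(function(x)
      cos(pi * x)^2 * cos((2 * n + 1) * pi * x), -0.5, 0.5,
      rel.tol = 1e-12)$value
    expect_equal(cos_sq_fourier_coef(n), oracle, tolerance = 1e-10)
  }
  expect_error(cos_sq_fourier_coef(-1), "nonnegative")
  # partial sums converge in L^2; two terms already approximate well
  x <- seq(-0.5, 0.5, length.out = 2001)
  l2err <- function(N) {
    approx <- Reduce(`+`, lapply(0:(N - 1), function(n)
      cos_sq_fourier_coef(n) * cos((2 * n + 1) * pi * x)))
    sqrt(mean((cos(pi * x)^2 - approx)^2))
  }
  errs <- vapply(c(2, 4, 8, 16), l2err, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[1], 0.02)
})

test_that("kinetic quadratic form projects correctly along the kernel", {
  la <- fixture_linear()
  kv <- la$kernel_vector
  qp <- quadratic_form_projection(la$derivs, kv)
  d <- la$derivs
  expect_equal(qp[1], 0.5 * (d$f_uu * kv[1]^2 + 2 * d$f_uv * kv[1] * kv[2] +
                               d$f_vv * kv[2]^2), tolerance = 1e-12)
  expect_equal(qp[2], 0.5 * (d$g_uu * kv[1]^2 + 2 * d$g_uv * kv[1] * kv[2] +
                               d$g_vv * kv[2]^2), tolerance = 1e-12)
  # linear kinetics: identically zero
  dl <- derivative_table(linearized_fixture(), c(2, 3/4))
  expect_equal(quadratic_form_projection(dl, kv), c(0, 0))
  # u <-> v relabelling oracle: the transposed system swaps the projection
  swapped <- rd_system("3 - v^2*u", "1 - 2*v + v^2*u",
                       D_u = 1/10, D_v = 1/1000)
  ds <- derivative_table(swapped, c(3/4, 2))
  qs <- quadratic_form_projection(ds, rev(kv))
  expect_equal(qs, rev(qp), tolerance = 1e-12)
})

test_that("quadratic coefficients match the dispersion-derivative oracle", {
  sys <- fixture_system(); la <- fixture_linear()
  q <- dirichlet_quadratic_coefficients(sys, la$derivs, la)
  # independent oracle: p1 is the slope of the leading growth rate in L
  dL <- 1e-6 * la$L_c
  lam <- function(L) dispersion_eigenvalues(sys, la$derivs, pi, L)$max_real
  slope <- (lam(la$L_c + dL) - lam(la$L_c - dL)) / (2 * dL)
  expect_equal(q$p1, slope, tolerance = 1e-4)
  expect_gt(q$p2, 0)   # sign convention makes the quadratic term positive
  # linear kinetics with the same Jacobian: transcritical term vanishes
  lsys <- linearized_fixture()
  lla <- linear_analysis(lsys, guess = c(2, 3/4))
  ql <- dirichlet_quadratic_coefficients(lsys, lla$derivs, lla)
  expect_equal(ql$p2, 0)
  expect_equal(ql$p1, q$p1, tolerance = 1e-10)  # same linear problem
})

test_that("second-order field solves the mode-by-mode equations", {
  sys <- fixture_system(); la <- fixture_linear()
  sof <- solve_second_order(sys, la$derivs, la, "dirichlet",
                            truncation_N = 32)
  d <- la$derivs
  J <- matrix(c(d$f_u, d$g_u, d$f_v, d$g_v), 2, 2)
  D <- diag(c(sys$D_u, sys$D_v))
  Qv <- quadratic_form_projection(d, la$kernel_vector)
  for (n in 1:32) {
    Mn <- J - ((2 * n + 1)^2 * pi^2 / la$L_c^2) * D
    res <- Mn %*% sof$s[, n] + cos_sq_fourier_coef(n) * Qv
    expect_lt(max(abs(res)), 1e-8)
  }
  # critical-mode solves are exact and satisfy the vcomp gauge
  M0 <- J - (pi^2 / la$L_c^2) * D
  rhs_L <- sof$p1 * la$kernel_vector -
    (2 * pi^2 / la$L_c^3) * c(D %*% la$kernel_vector)
  expect_lt(max(abs(M0 %*% sof$w_L - rhs_L)), 1e-8)
  expect_equal(sof$w_L[2], 0)
  expect_equal(sof$w_Q[2], 0)
  # coefficients decay at least cubically in the mode number
  nrm <- apply(abs(sof$s), 2, max)
  fit <- stats::lm(log(nrm[5:32]) ~ log(2 * (5:32) + 1))
  expect_lt(stats::coef(fit)[2], -3)

  # Neumann: exactly the constant and second-harmonic modes
  sofn <- solve_second_order(sys, la$derivs, la, "neumann")
  expect_named(sofn[c("c0", "c2")], c("c0", "c2"))
  expect_lt(max(abs(J %*% sofn$c0 + Qv / 2)), 1e-8)
  M2 <- J - (4 * pi^2 / la$L_c^2) * D
  expect_lt(max(abs(M2 %*% sofn$c2 + Qv / 2)), 1e-8)
})

test_that("third-order transcritical coefficients are truncation-stable", {
  sys <- fixture_system(); la <- fixture_linear()
  c64 <- dirichlet_cubic_coefficients(sys, la$derivs, la, truncation_N = 64)
  c128 <- dirichlet_cubic_coefficients(sys, la$derivs, la, truncation_N = 128)
  for (nm in c("p1", "p2", "p3", "p4", "p5")) {
    expect_lt(abs(c128[[nm]] - c64[[nm]]) / abs(c128[[nm]]), 1e-6)
  }
  # p1, p2 recovered at third order match the second-order computation
  q <- dirichlet_quadratic_coefficients(sys, la$derivs, la)
  expect_equal(c128$p1, q$p1, tolerance = 1e-10)
  expect_equal(c128$p2, q$p2, tolerance = 1e-10)
  expect_equal(c128$slope_m, c128$p1 / c128$p2, tolerance = 1e-10)
})

test_that("gauge choice moves p4 only; p3 and p5 are gauge-invariant", {
  sys <- fixture_system(); la <- fixture_linear()
  cs <- lapply(c("vcomp", "ucomp", "kernel"), function(g)
    dirichlet_cubic_coefficients(sys, la$derivs, la, truncation_N = 64,
                                 gauge = g))
  for (nm in c("p1", "p2", "p3", "p5")) {
    vals <- vapply(cs, `[[`, numeric(1), nm)
    expect_lt(diff(range(vals)) / abs(vals[1]), 1e-8)
  }
  p4s <- vapply(cs, `[[`, numeric(1), "p4")
  expect_gt(diff(range(p4s)), 1)
})

test_that("Neumann linear coefficient equals the Dirichlet one", {
  sys <- fixture_system(); la <- fixture_linear()
  nc <- fixture_neumann_coeffs()
  q <- dirichlet_quadratic_coefficients(sys, la$derivs, la)
  expect_equal(nc$lin, q$p1, tolerance = 1e-10)
  # quadratic solvability under Neumann conditions holds automatically:
  # cos^2(pi x) is orthogonal to cos(pi x) on [0, 1]
  orth <- stats::integrate(function(x) cos(pi * x)^2 * cos(pi * x), 0, 1,
                           rel.tol = 1e-12)$value
  expect_lt(abs(orth), 1e-12)
})

test_that("Neumann pitchfork cubic is validated by direct simulation", {
  # independent oracle: the converged pattern amplitude near onset obeys
  # A^2 = lin (L - L_c) / cub, so the measured branch slope pins the cubic
  sys <- fixture_system(); la <- fixture_linear()
  nc <- fixture_neumann_coeffs()
  delta <- 0.01
  L <- la$L_c * (1 + delta)
  op <- build_operator(sys, "neumann", 201)
  ic <- list(u = 2 + 1e-3 * cos(pi * op$x), v = rep(3/4, 201))
  tr <- simulate_rd(sys, "neumann", t_end = 4000, n_nodes = 201, L = L,
                    ic = ic, n_save = 3, rtol = 1e-9, atol = 1e-11,
                    kernel_u = la$kernel_vector[1])
  A <- tr$a[3]
  cub_measured <- nc$lin * (L - la$L_c) / A^2
  expect_equal(cub_measured, nc$cub, tolerance = 0.02)
  # breakdown adds up
  expect_equal(nc$cub, nc$cub_mean_mode + nc$cub_second_harmonic +
                 nc$cub_taylor, tolerance = 1e-12)
})

test_that("amplitude steady states and their stability are classified", {
  dc <- fixture_dirichlet_coeffs()
  # branches cross at the bifurcation point
  expect_equal(amplitude_steady_states(dc, 0)$amplitude, 0)
  st <- amplitude_steady_states(dc, -0.01)   # L1 < 0, p1, p2 > 0
  expect_equal(st$amplitude[1], 0)
  expect_true(st$is_stable[1])
  expect_gt(st$amplitude[2], 0)
  expect_false(st$is_stable[2])
  # integration oracle: above onset a small positive seed departs from zero
  # (growth rate p1 * L1, then quadratic acceleration)
  a <- 1e-6
  for (i in 1:60000) {
    a <- a + 1e-3 * (dc$p1 * 0.01 * a + dc$p2 * a^2)
    if (a > 1e-3) break
  }
  expect_gt(a, 1e-4)

  nc <- fixture_neumann_coeffs()
  pf <- amplitude_steady_states(nc, 0.01)
  expect_equal(sort(pf$amplitude),
               sort(c(0, 1, -1) * sqrt(nc$lin * 0.01 / nc$cub)),
               tolerance = 1e-12)
  expect_equal(pf$is_stable, c(FALSE, TRUE, TRUE))
  expect_equal(amplitude_steady_states(nc, -0.01)$amplitude, 0)
})

test_that("supercritical branch slope is non-monotonic in D_v", {
  # the rise sits just above the patterning threshold D_v ~ 0.0396; the
  # slope peaks near D_v ~ 0.046 and then decays
  dvs <- c(seq(0.041, 0.06, length.out = 10), seq(0.08, 0.4, length.out = 9))
  slopes <- vapply(dvs, function(dv) {
    sys <- schnakenberg(D_v = dv)
    la <- linear_analysis(sys)
    q <- dirichlet_quadratic_coefficients(sys, la$derivs, la)
    q$p1 / q$p2
  }, numeric(1))
  sgn <- sign(diff(slopes))
  expect_equal(sum(diff(sgn) != 0), 1)   # single interior maximum
  expect_gt(which.max(slopes), 1)
  expect_lt(which.max(slopes), length(slopes))
})

test_that("predicted branches pass through the steady state at onset", {
  la <- fixture_linear(); dc <- fixture_dirichlet_coeffs()
  nc <- fixture_neumann_coeffs()
  Ls <- seq(la$L_c * 0.98, la$L_c * 1.1, length.out = 31)
  pb0 <- predicted_branch(dc, c(2, 3/4), la$kernel_vector, la$L_c, la$L_c,
                          "quadratic")
  expect_equal(pb0$u_extremum, 2, tolerance = 1e-10)
  # at onset the transcritical curve is the lower cubic root; the upper root
  # is the spurious large-amplitude branch of the truncation
  pbc0 <- predicted_branch(dc, c(2, 3/4), la$kernel_vector, la$L_c, la$L_c,
                           "cubic")
  expect_equal(pbc0$u_extremum[pbc0$branch == "cubic_lower"], 2,
               tolerance = 1e-10)
  pbq <- predicted_branch(dc, c(2, 3/4), la$kernel_vector, Ls, la$L_c,
                          "quadratic")
  slopes <- diff(pbq$A) / diff(pbq$L)
  expect_equal(slopes, rep(-dc$slope_m, length(slopes)), tolerance = 1e-10)
  # cubic truncation is multivalued in A for some L above onset
  pbc <- predicted_branch(dc, c(2, 3/4), la$kernel_vector, Ls, la$L_c,
                          "cubic")
  both <- merge(pbc[pbc$branch == "cubic_upper", c("L", "A")],
                pbc[pbc$branch == "cubic_lower", c("L", "A")], by = "L")
  multi <- both$L[!is.na(both$A.x) & !is.na(both$A.y) &
                    abs(both$A.x - both$A.y) > 1e-8]
  expect_true(any(multi > la$L_c))
  # pitchfork pair is symmetric
  pbp <- predicted_branch(nc, c(2, 3/4), la$kernel_vector, Ls, la$L_c)
  plus <- pbp[pbp$branch == "pitchfork_plus", "A"]
  minus <- pbp[pbp$branch == "pitchfork_minus", "A"]
  expect_equal(plus, -minus, tolerance = 1e-12)
})
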