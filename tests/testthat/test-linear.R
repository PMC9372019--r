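test_that("diffusion-free stability follows the Routh-Hurwitz conditions", {
  la <- fixture_linear()
  os <- ode_stability(la$derivs)
  expect_equal(os$trace, -3)
  expect_equal(os$det, 8)
  expect_true(os$stable)

  stab <- derivative_table(rd_system("-u", "-v", 1, 1), c(0, 0))
  expect_true(ode_stability(stab)$stable)
  unst <- derivative_table(rd_system("u", "v", 1, 1), c(0, 0))
  expect_false(ode_stability(unst)$stable)
})

test_that("dispersion quadratic reduces to the kinetic quadratic at k = 0", {
  sys <- fixture_system(); la <- fixture_linear()
  d0 <- dispersion_eigenvalues(sys, la$derivs, k = 0)
  tr <- la$derivs$f_u + la$derivs$g_v
  dt <- la$derivs$f_u * la$derivs$g_v - la$derivs$g_u * la$derivs$f_v
  roots <- polyroot(c(dt, -tr, 1))
  expect_equal(sort(Re(d0$lambda_pair)), sort(Re(roots)), tolerance = 1e-10)
  expect_equal(sort(Im(d0$lambda_pair)), sort(Im(roots)), tolerance = 1e-10)
})

test_that("dispersion roots satisfy the quadratic's coefficient identities", {
  sys <- fixture_system(); la <- fixture_linear()
  for (k in c(0.5, pi, 2 * pi, 7)) {
    for (L in c(0.08, la$L_c, 0.3)) {
      d <- dispersion_eigenvalues(sys, la$derivs, k, L)
      q <- k^2 / L^2
      tr <- la$derivs$f_u + la$derivs$g_v - q * (sys$D_u + sys$D_v)
      dt <- (q * sys$D_u - la$derivs$f_u) * (q * sys$D_v - la$derivs$g_v) -
        la$derivs$g_u * la$derivs$f_v
      expect_equal(sum(d$lambda_pair), complex(real = tr), tolerance = 1e-10)
      expect_equal(prod(d$lambda_pair), complex(real = dt), tolerance = 1e-10)
    }
  }
})

test_that("critical scale pins the first mode to marginal stability", {
  sys <- fixture_system(); la <- fixture_linear()
  L_c <- critical_length(sys, la$derivs)
  expect_equal(round(L_c, 4), 0.1066)
  # dispersion root exactly zero at (k, L) = (pi, L_c)
  expect_lt(abs(dispersion_eigenvalues(sys, la$derivs, pi, L_c)$max_real),
            1e-8)
  # constant term of the dispersion quadratic vanishes there
  q <- pi^2 / L_c^2
  expect_lt(abs((q * sys$D_u - la$derivs$f_u) * (q * sys$D_v - la$derivs$g_v) -
                  la$derivs$g_u * la$derivs$f_v), 1e-10)
  # below L_c the first mode decays
  expect_lt(dispersion_eigenvalues(sys, la$derivs, pi, 0.9 * L_c)$max_real, 0)
  # homogeneity: scaling both diffusivities scales L_c by sqrt(c)
  sys4 <- schnakenberg(D_u = 4/1000, D_v = 4/10)
  expect_equal(critical_length(sys4, la$derivs), 2 * L_c, tolerance = 1e-12)
})

test_that("instability window endpoints scale as L^2 and hit pi at L_c", {
  sys <- fixture_system(); la <- fixture_linear()
  w1 <- instability_window(sys, la$derivs, L = la$L_c)
  expect_equal(sqrt(w1$k_plus_sq), pi, tolerance = 1e-10)
  expect_equal(round(sqrt(w1$k_minus_sq), 2), 1.02)
  w2 <- instability_window(sys, la$derivs, L = 2 * la$L_c)
  expect_equal(w2$k_minus_sq, 4 * w1$k_minus_sq, tolerance = 1e-12)
  expect_equal(w2$k_plus_sq, 4 * w1$k_plus_sq, tolerance = 1e-12)
  # every k^2 strictly inside the window destabilizes
  for (k2 in seq(w1$k_minus_sq * 1.01, w1$k_plus_sq * 0.99, length.out = 7)) {
    expect_gt(dispersion_eigenvalues(sys, la$derivs, sqrt(k2),
                                     la$L_c)$max_real, 0)
  }
  # equal diffusivities cannot satisfy the window condition for this fixture
  eq <- schnakenberg(D_u = 0.01, D_v = 0.01)
  expect_error(instability_window(eq, la$derivs), "instability")
})

test_that("kernel and adjoint vectors solve the singular critical system", {
  sys <- fixture_system(); la <- fixture_linear()
  kv <- kernel_vectors(sys, la$derivs, la$L_c, sign_convention = FALSE)
  M0 <- matrix(c(la$derivs$f_u, la$derivs$g_u, la$derivs$f_v, la$derivs$g_v),
               2, 2) - (pi^2 / la$L_c^2) * diag(c(sys$D_u, sys$D_v))
  expect_lt(max(abs(M0 %*% kv$kernel_vector)), 1e-8)
  expect_lt(max(abs(t(M0) %*% kv$adjoint_vector)), 1e-8)
  # independent null-space oracle: SVD of the 2x2 critical matrix
  sv <- svd(M0)
  null_ratio <- sv$v[1, 2] / sv$v[2, 2]
  adj_ratio <- sv$u[1, 2] / sv$u[2, 2]
  expect_equal(kv$Lambda, null_ratio, tolerance = 1e-8)
  expect_equal(kv$eta, adj_ratio, tolerance = 1e-8)
  expect_equal(round(kv$Lambda, 1), -30.3)
  expect_equal(round(kv$eta, 1), 22.7)
  # biorthogonality: the adjoint vector annihilates the image of M0
  for (x in list(c(1, 0), c(0, 1), c(2, -3))) {
    expect_lt(abs(sum(kv$adjoint_vector * (M0 %*% x))), 1e-8)
  }
})

test_that("only the first admissible mode is unstable just above onset", {
  sys <- fixture_system(); la <- fixture_linear()
  L <- 1.01 * la$L_c
  neumann_modes <- (1:6) * pi
  growth_n <- vapply(neumann_modes, function(k)
    dispersion_eigenvalues(sys, la$derivs, k, L)$max_real, numeric(1))
  expect_true(growth_n[1] > 0 && all(growth_n[-1] < 0))
  dirichlet_modes <- (2 * (0:5) + 1) * pi
  growth_d <- vapply(dirichlet_modes, function(k)
    dispersion_eigenvalues(sys, la$derivs, k, L)$max_real, numeric(1))
  expect_true(growth_d[1] > 0 && all(growth_d[-1] < 0))
})

test_that("patterning-region boundary and extremes match the closed form", {
  sys <- fixture_system(); la <- fixture_linear()
  ex <- region_extremes(sys, la$derivs)
  expect_equal(ex$L_min, pi / sqrt(1000), tolerance = 1e-12)
  expect_equal(round(ex$L_min, 4), 0.0993)
  expect_equal(round(ex$D_v_min, 4), 0.0396)
  expect_equal(round(ex$L_at_D_v_min, 3), 0.148)
  # fixture closed form for the boundary curve (activator-rate algebra):
  # D_v = 4 L^2 (2000 L^2 + pi^2) / (pi^2 (1000 L^2 - pi^2))
  fixture_boundary <- function(L)
    4 * L^2 * (2000 * L^2 + pi^2) / (pi^2 * (1000 * L^2 - pi^2))
  for (L in seq(0.11, 0.4, length.out = 20)) {
    expect_equal(ex$D_v_of_L(L), fixture_boundary(L), tolerance = 1e-10)
  }
  # generic root-bracketing path agrees with the closed form
  reg <- patterning_region(sys, la$derivs,
                           D_v_grid = seq(0.05, 0.3, length.out = 20),
                           L_grid = seq(0.09, 0.4, length.out = 80))
  b <- reg$boundary
  ok <- !is.na(b$L_boundary)
  expect_gt(sum(ok), 15)
  for (i in which(ok)) {
    expect_equal(ex$D_v_of_L(b$L_boundary[i]), b$D_v[i], tolerance = 1e-6)
  }
  expect_true(any(reg$mask) && !all(reg$mask))
})

test_that("bracketing path recovers the region extremes generically", {
  sys <- fixture_system(); la <- fixture_linear()
  exb <- region_extremes(sys, la$derivs, method = "bracketing")
  expect_equal(round(exb$D_v_min, 4), 0.0396)
  expect_equal(round(exb$L_at_D_v_min, 3), 0.148)
  # boundary root at very diffusive inhibitor approaches the L asymptote
  expect_equal(exb$boundary_L(50), pi / sqrt(1000), tolerance = 1e-3)
})
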