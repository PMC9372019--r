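# Shared fixtures: the canonical Schnakenberg system and cached analysis
# results (each test file re-sources helpers; memoize the cheap-but-repeated
# chain so the suite stays fast).

fixture_system <- function() schnakenberg()

.fixture_cache <- new.env(parent = emptyenv())

fixture_linear <- function() {
  if (is.null(.fixture_cache$la))
    .fixture_cache$la <- linear_analysis(fixture_system())
  .fixture_cache$la
}

fixture_dirichlet_coeffs <- function() {
  if (is.null(.fixture_cache$dc)) {
    la <- fixture_linear()
    .fixture_cache$dc <-
      dirichlet_cubic_coefficients(fixture_system(), la$derivs, la)
  }
  .fixture_cache$dc
}

fixture_neumann_coeffs <- function() {
  if (is.null(.fixture_cache$nc)) {
    la <- fixture_linear()
    .fixture_cache$nc <-
      neumann_cubic_coefficients(fixture_system(), la$derivs, la)
  }
  .fixture_cache$nc
}

# A linear kinetics system sharing the fixture's Jacobian at (2, 3/4): same
# linear Turing analysis, identically zero higher-order kinetics.
linearized_fixture <- function() {
  rd_system("(u - 2) + 4*(v - 3/4)", "-3*(u - 2) - 4*(v - 3/4)",
            D_u = 1/1000, D_v = 1/10, name = "linearized fixture")
}

# Run the homogeneous branch across the first bifurcation and return the
# refined bifurcation point (used by several continuation tests).
turing_point <- function(disc, la) {
  hom <- corrector(disc, la$L_c - 0.005, disc$homogeneous())
  br <- continue_branch(disc, hom, +1, L_window = c(0.09, 0.13),
                        ds0 = 5e-4, ds_max = 2e-3)
  br <- detect_events(br, disc)
  stopifnot(nrow(br$events) >= 1)
  list(branch = br,
       point = corrector(disc, br$events$L[1],
                         br$points[[br$events$index[1]]]$y))
}
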