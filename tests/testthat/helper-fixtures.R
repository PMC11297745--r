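# Shared fixtures, built once per test run and memoised in this environment.
.fixtures <- new.env()

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# default rhizotron geometry + a moderately coarse mesh for fast tests
fix_geometry <- function() memo("geom", rhizotron_geometry())

fix_mesh <- function() memo("mesh", build_mesh(fix_geometry(),
                                               refinement_level = 0.5,
                                               base_h = 0.06))

# a small deterministic measurement scheme spanning the tank; near-null
# configurations (unmeasurably small homogeneous |Z|) are filtered out
fix_scheme <- function(n = 120) {
  memo(paste0("scheme", n), {
    cand <- enumerate_candidates(fix_geometry()$electrodes,
                                 list(min_ab_sep = 0.2, max_mn_sep = 0.15))
    cand <- cand[round(seq(1, nrow(cand), length.out = 3 * n)), ]
    fld <- complex_field(0, rep(0.01 + 0i, nrow(fix_mesh()$cells)))
    z <- abs(simulate_scheme(fix_mesh(), fld, cand)$Z[, 1])
    cand <- cand[z >= 0.05 * stats::median(z), ]
    cand[round(seq(1, nrow(cand), length.out = n)), ]
  })
}

# homogeneous tap-water field on the test mesh
fix_water_field <- function(frequency = 1000) {
  complex_field(frequency,
                rep(105.1e-4 / 100 + 0i, nrow(fix_mesh()$cells)))
}

# simulated homogeneous dataset with geometric factors
fix_water_dataset <- function() {
  memo("water_ds", {
    ds <- simulate_scheme(fix_mesh(), fix_water_field(), fix_scheme())
    ds$K <- geometric_factors(fix_mesh(), fix_scheme())
    ds
  })
}

# default phantom on the test mesh (single frequency, 1 kHz)
fix_phantom <- function() memo("phantom", make_phantom(phantom_spec(), fix_mesh()))
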