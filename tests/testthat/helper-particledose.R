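# Shared fixtures, memoised so the transport solver runs once per session.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Delivered-dose series for the packaged SPIO exposure at the study times,
# default solver settings.
paper_delivered <- function() {
  memo("paper_delivered",
       simulate_delivery(spio_exposure(10), c(1, 2, 4, 8, 24)))
}

# Same series on a 2x refined grid (for convergence checks).
paper_delivered_fine <- function() {
  memo("paper_delivered_fine",
       simulate_delivery(spio_exposure(10), c(1, 2, 4, 8, 24),
                         n_nodes = 600, dt_s = 3))
}

# Denser schedule for saturable-model recovery studies.
paper_delivered_dense <- function() {
  memo("paper_delivered_dense",
       simulate_delivery(spio_exposure(10),
                         c(0.5, 1, 2, 4, 6, 8, 12, 18, 24)))
}

# Transport coefficients for the packaged agglomerate.
paper_transport <- function() {
  memo("paper_transport", {
    agg <- spio_agglomerate()
    med <- rpmi_medium()
    rho <- as.numeric(effective_density(agg, med))
    list(D = as.numeric(diffusion_coefficient(276, med)),
         V = as.numeric(sedimentation_velocity(276, rho, med)),
         rho_eff = rho, h_mm = 2.6)
  })
}

mouse_table <- function(seed = 1) {
  memo(paste0("mouse_table_", seed),
       gen_deposition_table("mouse_like", seed = seed))
}
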