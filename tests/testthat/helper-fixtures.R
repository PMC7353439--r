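# Shared fixtures, built in code at test time.

cu_spec <- function() particle_spec_cu()

# Default shell-control world: Table-scale De and N0, completion near 48 h.
shell_params <- function(spec = cu_spec(), De = 2.39e-11, N0 = 1.17e12,
                         tau_h = 48) {
  C_s <- solubility_for_tau("porous_shell", spec, De, hours_to_seconds(tau_h))
  scm_parameters(D_e = De, C_s = C_s, C_l = C_s, N0 = N0)
}

# A sampling schedule (hours) covering conversion X_lo..X_hi under a given
# generating regime, n points, with t = tau * g(X).
transient_schedule_h <- function(regime, tau_h, n = 20, X_lo = 0.05,
                                 X_hi = 0.95) {
  tau_h * g_regime(seq(X_lo, X_hi, length.out = n), regime)
}

# Write a small dissolution CSV and return its path.
write_tmp_dissolution <- function(time_h, conc_mg_l, dir = tempdir()) {
  path <- tempfile("diss", tmpdir = dir, fileext = ".csv")
  utils::write.csv(data.frame(time = time_h, conc_mg_l = conc_mg_l), path,
                   row.names = FALSE)
  path
}
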