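# Shared fixtures, built in code at test time.

# small, fast force curve (lower sampling rate, short dwell) for unit tests
quick_curve <- function(e_star = 2000, lambda1 = 5, lambda2 = 0.2, a = 0.6,
                        noise_sd = 0, seed = 1, sampling_rate = 100,
                        dwell_duration = 5, ...) {
  simulate_force_curve(curve_sim_config(
    e_star = e_star, lambda1 = lambda1, lambda2 = lambda2, a = a,
    noise_sd = noise_sd, seed = seed, sampling_rate = sampling_rate,
    dwell_duration = dwell_duration, ...))
}

# hand-built flat curve (never contacts anything)
flat_curve <- function(n = 64) {
  force_curve(time = seq_len(n) / 100, piezo_z = seq_len(n) * 1e-8,
              deflection = rep(0, n), spring_constant = 0.02,
              segment = rep("approach", n))
}

# minimal Ct table with explicit values (one housekeeping gene "HK")
tiny_ct_table <- function() {
  data.frame(
    sample_id = rep(c("control_1", "control_2", "treated_1", "treated_2"),
                    each = 2),
    group = rep(c("control", "treated"), each = 4),
    target_id = rep(c("HK", "TG"), times = 4),
    replicate = rep(c(1L, 2L, 1L, 2L), each = 2),
    ct = c(20, 25, 20, 25, 20, 23, 20, 23),
    stringsAsFactors = FALSE)
}

# tiny hand-built signed network
tiny_network <- function() {
  causal_network(data.frame(
    regulator_id = c("R1", "R1", "R1", "R2", "R2"),
    target_gene = c("G1", "G2", "G3", "G1", "G4"),
    sign = c(1L, 1L, -1L, -1L, 1L),
    molecule_type = "gene", stringsAsFactors = FALSE),
    universe = paste0("G", 1:6))
}
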