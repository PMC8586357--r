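# Shared fixtures, built in code.

# Random valid reduced parameters (moderate energies unless widened).
random_reduced <- function(energy_range = c(-5, 5)) {
  reduced_params(
    gamma1 = 10^runif(1, -2, 1.5),
    gamma2 = 10^runif(1, -1, 2),
    gamma3 = 10^runif(1, -6, 0.5),
    m = runif(1),
    ddE0 = runif(1, energy_range[1], energy_range[2]),
    ddEm = runif(1, energy_range[1], energy_range[2]))
}

# Random valid general rate set (no u1 == u2 symmetry imposed).
random_rates <- function() {
  rate_set(u0 = 10^runif(1, -2, 2), u1 = 10^runif(1, -2, 2),
           u2 = 10^runif(1, -2, 2), u3 = 10^runif(1, -2, 2),
           u4 = 10^runif(1, -2, 2), w0 = 10^runif(1, -2, 2),
           w1 = 10^runif(1, -2, 2), w2 = 10^runif(1, -2, 2),
           m = runif(1))
}

# Outcome probabilities via the exact linear-solve oracle, in closed-form
# field order.
solve_outcomes <- function(r) {
  p <- splitting_probabilities(build_editing_network(r))
  c(p_ctc = unname(p["CTC"]), p_ctt = unname(p["CTT"]),
    p_ttc = unname(p["TTC"]), p_ttt = unname(p["TTT"]))
}

outcome_vec <- function(o) {
  c(p_ctc = o$p_ctc, p_ctt = o$p_ctt, p_ttc = o$p_ttc, p_ttt = o$p_ttt)
}

# ddEm values standing in for a small variant panel spanning the calibrated
# selectivity rise (wild type through a strongly destabilising mutant).
PANEL_DDEM <- c(0, 0.9, 2.2, 3.4, 4.5)
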