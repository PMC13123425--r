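# Elasticity and kinetics parameter sets used throughout the suite:
# an A2-like domain alone and bound to wild-type or mutant ligand.
wlc_alone <- function() wlc_params(Lc = 55.3, Lp = 0.28)
wlc_wt <- function() wlc_params(Lc = 40.0, Lp = 0.38)
wlc_mut <- function() wlc_params(Lc = 31.8, Lp = 0.38)

bell_alone <- function() bell_evans_params(k0 = 0.15, gamma = 0.71)
bell_wt <- function() bell_evans_params(k0 = 0.017, gamma = 1.88)
bell_mut <- function() bell_evans_params(k0 = 0.034, gamma = 1.38)

# affinity table: wild-type and mutant Kd (M) with published fold ratios
kd_table <- function() {
  data.frame(
    fragment = c("AIM-A1", "A2", "A1-A2-A3", "D'D3", "D'D3-A1", "D'D3-A1-A2"),
    kd_wt = c(3.0, 6.1, 3.4, 9.6, 6.8, 9.6) * 1e-9,
    kd_mut = c(3.6, 2.3, 0.9, 2.6, 3.0, 5.5) * 1e-9,
    fold = c(0.8, 2.7, 3.8, 3.7, 2.3, 1.7)
  )
}

# two-step pathway: a faster first step (lower rupture force) followed by a
# control-like second step; increments sum to the one-step total
two_step_pathway <- function() {
  unfolding_pathway(c(27.0, 28.3),
                    list(bell_evans_params(0.30, 0.71),
                         bell_evans_params(0.15, 0.71)),
                    Lp = 0.28)
}

one_step_pathway <- function() unfolding_pathway(55.3, bell_alone(), Lp = 0.28)
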