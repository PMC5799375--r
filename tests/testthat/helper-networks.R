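## Small reusable fixtures (built in code; nothing stored on disk).

birth_death_network <- function(k = 2, gamma = 0.1, x0 = 0) {
  custom_network(
    "X",
    list(list(name = "birth", rate = k, reactants = character(),
              stoich = c(X = 1)),
         list(name = "death", rate = gamma, reactants = "X",
              stoich = c(X = -1))),
    c(X = x0))
}

decay_network <- function(gamma = 0.05, x0 = 10) {
  custom_network(
    "X",
    list(list(name = "death", rate = gamma, reactants = "X",
              stoich = c(X = -1))),
    c(X = x0))
}

## time-average mean/variance of a species over the second half of a
## trajectory (burn-in discarded)
traj_stationary_moments <- function(tr, species) {
  v <- species_profile(tr, species)
  v <- v[seq(ceiling(length(v) / 2), length(v))]
  list(mean = mean(v), var = stats::var(v), n = length(v))
}
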