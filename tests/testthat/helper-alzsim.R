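# Shared fixtures: one cached baseline run reused across test files, and a
# generator of random admissible states.

.alzsim_test_cache <- new.env(parent = emptyenv())

baseline_trajectory <- function() {
  if (is.null(.alzsim_test_cache$traj)) {
    .alzsim_test_cache$traj <- simulate_ad(times = seq(0, 3650, by = 10))
  }
  .alzsim_test_cache$traj
}

baseline_end <- function() {
  traj <- baseline_trajectory()
  traj[nrow(traj), ]
}

# random admissible state: each species scattered around its initial /
# typical scale
random_state <- function(seed) {
  set.seed(seed)
  base <- ad_initial_state()
  base[c("Nd", "Mh1", "Mh2", "AO")] <- c(1e-5, 0.02, 0.01, 1e-7)
  out <- base * exp(stats::runif(length(base), -1, 1))
  out["N"] <- min(out[["N"]], 0.14)
  out
}

species_names <- c("Abi", "Abo", "tau", "Fi", "Fo", "N", "A", "Nd", "AO", "H",
                   "M1", "M2", "Mh1", "Mh2", "Tb", "I10", "Ta", "P")

# column values of a trajectory, with all extra attributes stripped
traj_values <- function(x) {
  l <- as.list(as.data.frame(x))
  attributes(l) <- list(names = names(l))
  l
}
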