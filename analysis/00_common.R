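# Shared setup for the numbered analysis scripts: the three study
# embodiments at desk scale (5 individuals x 150 cycles each), simulated,
# processed and fitted once, then cached under scratch/ so later scripts
# reuse the same data.

library(stablegait)

SPECIES <- c("biped", "quadruped", "hexapod")
N_IND <- 5L
N_CYCLES <- 150L
SEED <- 20260901L

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

front_legs <- function(profile) {
  lv <- sub("_(left|right)$", "", profile$leg_labels)
  profile$leg_labels[lv == lv[1]]
}

study_data <- function() {
  cache <- file.path("scratch", "study_data.rds")
  if (file.exists(cache)) return(readRDS(cache))
  message("simulating and processing the three embodiments ...")
  out <- list()
  for (k in seq_along(SPECIES)) {
    sp <- SPECIES[k]
    set.seed(SEED + k)
    per <- lapply(seq_len(N_IND), function(i) {
      p <- walker_params(sp, a = 0.9, gain = 0.4)
      sim <- simulate_walker(p, n_cycles = N_CYCLES,
                             bout_id = sprintf("b%02d", i))
      b <- align_heading(select_straight_bouts(list(sim$bout))[[1]])
      build_cycles(list(b), p$profile, animal = sprintf("ind%02d", i))
    })
    cyc <- combine_cycles(per)
    ff <- fit_feedforward(cyc)
    out[[sp]] <- list(cycles = cyc, ff = ff,
                      dev = compute_deviations(cyc, ff),
                      profile = cyc$profile)
  }
  saveRDS(out, cache)
  out
}
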