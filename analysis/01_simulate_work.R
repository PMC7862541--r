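#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs.
#
# Emulates the data layout of the host-guest campaign: for one host-guest
# system, two binding poses (primary/secondary orientation), three
# independent repeats each, bidirectional non-equilibrium transitions whose
# work distributions satisfy the Crooks fluctuation theorem with known pose
# free energies. Writes the per-transition dH/dlambda files plus a manifest
# under results/workdata/, and the planted ground truth for later stages.

suppressMessages(library(neqbind))

out_root <- file.path("results", "workdata")
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

seed <- 2024L
temperature <- 300.15
sigma <- 0.8                      # per-transition work spread, kJ/mol
n_transitions <- 30L              # per repeat and direction
pose_dgs <- c(primary = -22, secondary = -16)   # transition dG, kJ/mol

b <- beta_kJ(temperature)
set.seed(seed)
rows <- list()
for (pose in names(pose_dgs)) {
  for (rep_i in 1:3) {
    for (dirn in c("forward", "reverse")) {
      mu <- if (dirn == "forward") pose_dgs[[pose]] + b * sigma^2 / 2
            else -pose_dgs[[pose]] + b * sigma^2 / 2
      for (k in seq_len(n_transitions)) {
        w <- rnorm(1, mu, sigma)
        # constant dH/dl whose path integral equals the sampled work
        lvl <- if (dirn == "reverse") -w else w
        fn <- sprintf("%s_%s_r%d_%03d.xvg", pose, dirn, rep_i, k)
        write_dhdl_xvg(dhdl_series(c(0, 0.5, 1), rep(lvl, 3), dirn),
                       file.path(out_root, fn),
                       comment = sprintf("synthetic %s transition", dirn))
        row <- data.frame(host = "hostA", guest = "g1", forcefield = "ffA",
                          pose = pose, direction = dirn, path = fn,
                          check.names = FALSE)
        row$`repeat` <- rep_i
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
}
manifest <- do.call(rbind, rows)
write.csv(manifest, file.path(out_root, "manifest.csv"), row.names = FALSE)
write.csv(data.frame(pose = names(pose_dgs), dg_true_kj = unname(pose_dgs),
                     sigma_kj = sigma, temperature_k = temperature),
          file.path("results", "ground_truth.csv"), row.names = FALSE)

cat(sprintf("wrote %d transition files (2 poses x 3 repeats x 2 directions x %d)\n",
            nrow(manifest), n_transitions))
cat(sprintf("planted pose free energies: primary %.1f, secondary %.1f kJ/mol\n",
            pose_dgs["primary"], pose_dgs["secondary"]))
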