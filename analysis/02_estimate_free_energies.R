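#!/usr/bin/env Rscript
# Step 2: per-repeat free energy estimation.
#
# Integrates every dH/dlambda series to a work value, pools each repeat's
# bidirectional works and estimates the transition free energy with the
# Crooks maximum-likelihood (BAR) estimator; the Jarzynski and Crooks
# Gaussian intersection estimators are run alongside for comparison.
# Finding to check: all three agree with the planted values within
# statistical error on these CFT-consistent work sets.

suppressMessages(library(neqbind))

manifest <- read_manifest(file.path("results", "workdata", "manifest.csv"))
truth <- read.csv(file.path("results", "ground_truth.csv"))
cfg <- run_config(seed = 7L, n_boot = 200L)

repeats <- estimate_from_manifest(manifest, cfg)
write.csv(repeats, file.path("results", "repeats_cftml.csv"),
          row.names = FALSE)

cat("per-repeat CFT-ML estimates (kJ/mol):\n")
print(repeats[, c("pose", "rep", "dg_kj", "stderr_kj")], row.names = FALSE)

# estimator comparison on the pooled works of each pose
cmp <- do.call(rbind, lapply(split(manifest, manifest$pose), function(g) {
  works <- vapply(seq_len(nrow(g)), function(i)
    integrate_work(read_dhdl_xvg(g$path[i], g$direction[i])), numeric(1))
  ws <- work_set(works[g$direction == "forward"],
                 works[g$direction == "reverse"], cfg$temperature)
  data.frame(pose = g$pose[1],
             dg_true = truth$dg_true_kj[truth$pose == g$pose[1]],
             cft_ml = estimate_cft_ml(ws)$dg,
             cgi = estimate_cgi(ws, n_boot = 0)$dg,
             jarzynski = estimate_jarzynski(ws, n_boot = 0)$dg)
}))
write.csv(cmp, file.path("results", "estimator_comparison.csv"),
          row.names = FALSE)
cat("\npooled estimator comparison (kJ/mol):\n")
print(cmp, row.names = FALSE, digits = 4)
dev <- max(abs(cmp$cft_ml - cmp$dg_true))
cat(sprintf("\nlargest CFT-ML deviation from planted dG: %.3f kJ/mol\n", dev))
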