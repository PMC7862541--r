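#!/usr/bin/env Rscript
# Step 5: force-field dihedral audit.
#
# Generates an AMBER-style parameter block with an injected over-defined
# c3-c3-os-c3 group (a general-purpose and a stiffer sugar-specific set,
# entered non-sequentially), runs the linter, and applies the three repair
# policies to a sugar-ring topology. Also demonstrates the 0.81 side-chain
# charge scaling used to reconcile GAFF with CGenFF charge magnitudes.

suppressMessages(library(neqbind))
dir.create("results", showWarnings = FALSE)

fx <- gen_ff_fixture(20, duplicates = list(
  list(quad = "c3-c3-os-c3", periodicity = 3, barriers = c(0.16, 1.4))),
  seed = 2024)
writeLines(fx$text, file.path("results", "gaff_fixture.dat"))

params <- parse_dihedral_params(fx$text, "amber-dat")
groups <- detect_overdefined(params)
cat("over-defined dihedral groups found:\n")
print(groups, row.names = FALSE)
write.csv(groups, file.path("results", "overdefined_groups.csv"),
          row.names = FALSE)

atoms <- data.frame(index = 1:4, type = c("c3", "c3", "os", "c3"),
                    name = c("C1", "C2", "O5", "C5"),
                    charge = c(0.117, 0.117, -0.389, 0.117),
                    mass = c(12.011, 12.011, 15.999, 12.011),
                    residue = "GLC")
topo <- topology(atoms, data.frame(ai = 1L, aj = 2L, ak = 3L, al = 4L,
                                   barrier_kj = NA_real_,
                                   phase_deg = NA_real_,
                                   periodicity = NA_integer_))
for (pol in c("first-match", "preferred-variant", "all-variants")) {
  fixed <- apply_dihedral_policy(topo, params, groups, pol)
  cat(sprintf("%-18s -> %d term(s), barriers [%s] kJ/mol\n", pol,
              nrow(fixed$dihedrals),
              paste(round(fixed$dihedrals$barrier_kj, 3), collapse = ", ")))
}
cat("preferred-variant selects the stiffer sugar-specific set;",
    "all-variants stacks both, as PrimaDORAC-style topologies do\n")

scaled <- scale_charges(topo, selection = 1:4, factor = 0.81)
cat(sprintf("\ncharge scaling x0.81: net charge %+.4f -> %+.4f e (delta %+.4f)\n",
            sum(topo$atoms$charge), sum(scaled$atoms$charge),
            attr(scaled, "net_charge_delta")))
write.csv(scaled$atoms, file.path("results", "scaled_atoms.csv"),
          row.names = FALSE)
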