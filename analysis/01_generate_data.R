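#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study that stands in for the field data —
# a 32-species unit-height chronogram with a designated shift clade, a
# jittered posterior tree set, and a specimen-level morphometric table
# (standard length + 15 locomotor traits, 1-6 specimens per species).
# Outputs go to results/data/.

suppressMessages(library(peakscape))

seed <- 42
n_posterior <- 25   # desk-scale stand-in for the full posterior sample

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

st <- gen_study(synthetic_spec(), seed = seed, n_posterior = n_posterior)

write_newick(st$tree, "results/data/mcc.nwk")
ape::write.tree(st$trees$trees, "results/data/posterior.nwk")
utils::write.csv(st$specimens, "results/data/specimens.csv",
                 row.names = FALSE)

truth <- data.frame(
  quantity = c("seed", "n_species", "n_posterior", "shift_edge",
               "shift_clade_size", "hansen_alpha", "hansen_sigma2",
               "hansen_theta_base", "hansen_theta_shift",
               "ou_alpha", "ou_sigma2", "ou_theta"),
  value = c(seed, st$spec$n_species, n_posterior, st$truth$shift_edge,
            length(st$truth$shift_clade), st$spec$hansen$alpha,
            st$spec$hansen$sigma2, st$spec$hansen$theta_base,
            st$spec$hansen$theta_shift, st$spec$ou$alpha,
            st$spec$ou$sigma2, st$spec$ou$theta))
utils::write.csv(truth, "results/data/ground_truth.csv", row.names = FALSE)

cat("Generated", nrow(unique(st$specimens[c("species", "specimen_id")])),
    "specimens across", st$spec$n_species, "species;",
    "shift clade of", length(st$truth$shift_clade), "tips on edge",
    st$truth$shift_edge, "\n")
cat("Files written under results/data/\n")
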