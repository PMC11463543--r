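#!/usr/bin/env Rscript
# Generate the synthetic study: Endo-IP and Lyso-IP experiments in two cell
# states (triplicate tagged vs untagged control), annotations with ground
# truth, motif-bearing cargo sequences, and a differentiation time-course.
# Everything downstream (02-06) reads the files written here.

suppressPackageStartupMessages(library(endocargo))

seed <- 1L
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- sim_config(n_proteins = 1500L, seed = seed)
write_run_config(run_config(rng_seed = seed), file.path(out, "run.cfg"))

for (ip in c("endo", "lyso")) {
  for (state in c("hESC", "iNeuron")) {
    sim <- simulate_ip_experiment(cfg, ip_type = ip, cell_state = state)
    stem <- file.path(out, paste0(ip, "_", state))
    write_intensity_table(sim$matrix, paste0(stem, "_intensities.tsv"))
    write_table(as.data.frame(sim$design), paste0(stem, "_design.tsv"),
                sort_by = NULL)
    message("[simulate] ", ip, "/", state, ": ",
            nrow(sim$matrix$values), " proteins x ",
            ncol(sim$matrix$values), " channels; ",
            sum(sim$truth[[paste0("effect_", ip)]] > 0),
            " proteins carry a true effect")
  }
}

# one shared truth + annotations (biological truth is identical across IPs)
sim <- simulate_ip_experiment(cfg)
ann <- simulate_annotations(sim$truth)
write_table(ann$truth, file.path(out, "truth.tsv"))
write_table(ann$annotations, file.path(out, "annotations.tsv"))

# synthetic gene sets as GMT (synaptic set emulates a curated resource)
gs <- split_labels(ann$annotations$gene_sets)
sets <- list()
for (i in seq_along(gs)) {
  for (s in gs[[i]]) sets[[s]] <- c(sets[[s]], ann$annotations$protein[i])
}
write_gmt(sets, file.path(out, "gene_sets.gmt"))
message("[simulate] gene sets: ",
        paste(names(sets), lengths(sets), collapse = ", "))

# motif-bearing candidate-cargo sequences with planted truth
seqs <- simulate_sequences(300, plant_snx27 = 0.5, plant_snx17 = 0.5,
                           seed = seed)
write_fasta(seqs$sequences, file.path(out, "cargo_sequences.fasta"))
write_table(seqs$motifs, file.path(out, "motif_truth.tsv"))
message("[simulate] sequences: ", length(seqs$sequences), " (",
        sum(seqs$motifs$planted), " planted motifs, ",
        sum(!seqs$motifs$planted), " accidental background matches)")

# 12-day differentiation time-course with three trajectory templates
tc <- simulate_timecourse(300, noise_sd = 0.2, seed = seed)
prof <- data.frame(protein = rownames(tc$profiles), tc$profiles,
                   check.names = FALSE)
write_table(prof, file.path(out, "timecourse_profiles.tsv"))
write_table(data.frame(protein = names(tc$labels),
                       truth_cluster = as.integer(tc$labels)),
            file.path(out, "timecourse_truth.tsv"))
message("[simulate] time-course: ", nrow(tc$profiles), " proteins over ",
        ncol(tc$profiles), " sampling days")
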