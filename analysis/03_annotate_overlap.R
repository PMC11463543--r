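#!/usr/bin/env Rscript
# Join compartment annotations onto the enrichment results: per-compartment
# log2FC distributions (violin-style summaries), Endo/Lyso and hESC/iNeuron
# overlaps, state-selectivity bins, and gene-set over-representation.

suppressPackageStartupMessages(library(endocargo))

out <- "results"
ann <- read_table(file.path(out, "annotations.tsv"))
sets <- read_gmt(file.path(out, "gene_sets.gmt"))

et <- lapply(c(endo_hESC = "endo_hESC", endo_iNeuron = "endo_iNeuron",
               lyso_iNeuron = "lyso_iNeuron"), function(stem)
  read_table(file.path(out, paste0(stem, "_enrichment.tsv"))))

# compartment-wise log2FC distributions in the iNeuron Endo-IP
cs <- compartment_summary(et$endo_iNeuron, ann)
write_table(cs, file.path(out, "compartment_summary.tsv"), sort_by = NULL)
message("[annotate] compartment log2FC means (Endo-IP, iNeuron):")
for (i in seq_len(nrow(cs)))
  message(sprintf("  %-16s n=%4d  mean %+.2f", cs$compartment[i], cs$n[i],
                  cs$mean_log2FC[i]))

enriched <- lapply(et, function(e) e$protein[e$enriched])

# Endo vs Lyso captured proteomes (iNeuron)
ov_ip <- overlap_sets(list(EndoIP = enriched$endo_iNeuron,
                           LysoIP = enriched$lyso_iNeuron))
# hESC vs iNeuron Endo-IP proteomes
ov_state <- overlap_sets(list(hESC = enriched$endo_hESC,
                              iNeuron = enriched$endo_iNeuron))
ov <- rbind(data.frame(comparison = "endo_vs_lyso",
                       region = names(ov_ip$counts),
                       count = unname(ov_ip$counts)),
            data.frame(comparison = "hESC_vs_iNeuron",
                       region = names(ov_state$counts),
                       count = unname(ov_state$counts)))
write_table(ov, file.path(out, "overlaps.tsv"), sort_by = NULL)
message("[annotate] Endo/Lyso shared: ", ov_ip$counts["EndoIP_and_LysoIP"],
        "; hESC/iNeuron shared: ", ov_state$counts["hESC_and_iNeuron"])

# state selectivity of hESC-only proteins, judged on the true baseline
# difference is not simulated, so use observed log2FC difference between
# states as the abundance ratio input
shared <- intersect(et$endo_hESC$protein, et$endo_iNeuron$protein)
ratio <- with(list(
  h = et$endo_hESC$log2FC[match(shared, et$endo_hESC$protein)],
  n = et$endo_iNeuron$log2FC[match(shared, et$endo_iNeuron$protein)]),
  stats::setNames(h - n, shared))
hesc_only <- ov_state$members$hESC_only
if (length(hesc_only)) {
  sel <- classify_state_selectivity(hesc_only, ratio)
  write_table(data.frame(bin = names(sel$counts),
                         count = unname(sel$counts)),
              file.path(out, "selectivity.tsv"), sort_by = NULL)
  message(sprintf(
    "[annotate] hESC-selective: %.0f%% higher, %.0f%% equal, %.0f%% lower",
    100 * sel$proportions["higher"], 100 * sel$proportions["equal"],
    100 * sel$proportions["lower"]))
}

# gene-set over-representation of the iNeuron Endo-IP proteome against the
# quantified universe
universe <- et$endo_iNeuron$protein
ge <- geneset_enrichment(enriched$endo_iNeuron, universe, sets)
write_table(ge, file.path(out, "geneset_enrichment.tsv"), sort_by = NULL)
top <- ge[1, ]
message(sprintf("[annotate] top gene set: %s (k=%d/%d, q=%.2g)",
                top$set, top$k, top$K, top$q))
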