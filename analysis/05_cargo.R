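#!/usr/bin/env Rscript
# Candidate endocytic cargo: Endo-IP-enriched iNeuron proteins with >= 1
# transmembrane segment and cell-membrane localization; cargo fractions of
# the plasma-membrane universe (whole and synaptic), and the domain/family
# classification. Also recomputes the published headline arithmetic
# (152/504 and 70/347).

suppressPackageStartupMessages(library(endocargo))

out <- "results"
ann <- read_table(file.path(out, "annotations.tsv"))
sets <- read_gmt(file.path(out, "gene_sets.gmt"))
et <- read_table(file.path(out, "endo_iNeuron_enrichment.tsv"))
enriched <- et$protein[et$enriched]

cc <- select_candidate_cargo(enriched, ann, synaptic_set = sets$synaptic)
write_table(data.frame(protein = cc$candidates),
            file.path(out, "cargo_candidates.tsv"))
message(sprintf("[cargo] %d candidate cargo among %d enriched proteins",
                length(cc$candidates), length(enriched)))
message(sprintf(
  "[cargo] PM/TM universe %d, in Endo-IP %d -> %.1f%% (headline %d%%)",
  cc$counts["pm_universe"], cc$counts["pm_in_ip"],
  cc$fractions$pm$percent_1dp, cc$fractions$pm$percent_rounded))
if (!is.null(cc$fractions$syngo))
  message(sprintf(
    "[cargo] synaptic PM/TM universe %d, in Endo-IP %d -> %.1f%%",
    cc$counts["syngo_pm_universe"], cc$counts["syngo_pm_in_ip"],
    cc$fractions$syngo$percent_1dp))

# published arithmetic: 504/347 PM-TM proteins, 152/70 captured
pub_pm <- cargo_fraction(152, 504)
pub_syn <- cargo_fraction(70, 347)
fr <- data.frame(
  quantity = c("sim_pm", "sim_syngo", "published_pm", "published_syngo"),
  in_ip = c(cc$counts["pm_in_ip"], cc$counts["syngo_pm_in_ip"], 152, 70),
  universe = c(cc$counts["pm_universe"], cc$counts["syngo_pm_universe"],
               504, 347),
  percent = c(cc$fractions$pm$percent_1dp,
              if (is.null(cc$fractions$syngo)) NA else
                cc$fractions$syngo$percent_1dp,
              pub_pm$percent_1dp, pub_syn$percent_1dp),
  percent_rounded = c(cc$fractions$pm$percent_rounded,
                      if (is.null(cc$fractions$syngo)) NA else
                        cc$fractions$syngo$percent_rounded,
                      pub_pm$percent_rounded, pub_syn$percent_rounded))
write_table(fr, file.path(out, "cargo_fractions.tsv"), sort_by = NULL)
message(sprintf(
  "[cargo] published counts give %d%% (PM) and %d%% (synaptic)",
  pub_pm$percent_rounded, pub_syn$percent_rounded))

dm <- domain_family_matrix(cc$candidates, ann)
write_table(dm$table, file.path(out, "domain_family_table.tsv"),
            sort_by = NULL)
message(sprintf(
  "[cargo] domain/family classes: %d both, %d one, %d neither",
  dm$categories["both"], dm$categories["one"], dm$categories["neither"]))
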