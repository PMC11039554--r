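#!/usr/bin/env Rscript
# Stage 6: association with symptom severity. Partial correlation
# (controlling age and gender) between patients' HAMD-17 scores and every
# harmonised network measure: the topology AUC features and every edge's
# KLS as two separate Bonferroni families.

suppressPackageStartupMessages(library(iscn))

phen <- read_phenotype("results/phenotype.tsv")
topo_h <- as.matrix(read.delim("results/topology_features_harmonized.tsv",
                               row.names = 1, check.names = FALSE))
edges_h <- as.matrix(read.delim("results/edge_features_harmonized.tsv",
                                row.names = 1, check.names = FALSE))
truth <- jsonlite::read_json("results/ground_truth.json",
                             simplifyVector = TRUE)

assoc_topo <- clinical_association(topo_h, phen, score = "hamd17")
assoc_edge <- clinical_association(edges_h, phen, score = "hamd17")
out <- rbind(cbind(family = "topology", assoc_topo),
             cbind(family = "connectivity", assoc_edge))
write.table(out, "results/clinical_association.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

he <- sprintf("edge_r%03d_r%03d", truth$hamd_edge$i, truth$hamd_edge$j)
hit <- assoc_edge[assoc_edge$feature == he, ]
message(sprintf(
  "coupled edge %s: partial r = %.3f (truth %.2f), p = %.4g (n = %d patients)",
  he, hit$partial_r, truth$hamd_edge$r, hit$p, hit$n))
message(sprintf("strongest uncorrected edge association: %s (r = %.3f)",
                assoc_edge$feature[which.max(abs(assoc_edge$partial_r))],
                assoc_edge$partial_r[which.max(abs(assoc_edge$partial_r))]))
message(sum(out$significant), " association(s) survive Bonferroni")
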