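#!/usr/bin/env Rscript
# Stage 3: genomic descriptors and combined-distance clustering.
#
# Builds 96-channel trinucleotide catalogs and per-sample fraction of genome
# altered, combines the cosine-based mutational distance with the FGA
# distance into one Euclidean metric, clusters, and assigns each
# multiple-classifier query to the single-classifier reference group it
# co-clusters with. An association test asks whether query type tracks the
# assigned group.

library(mcec)

snv <- read_snv_table("results/cohort/snv.tsv")
seg <- read_seg("results/cohort/segments.seg")
cls <- read.delim("results/classification.tsv")

catalogs <- build_catalog_matrix(snv)
fga <- fga_by_sample(seg)
write_catalog_tsv(catalogs, "results/catalogs.tsv")
write.table(data.frame(sample_id = names(fga), fga = unname(fga)),
            "results/fga.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

is_multi <- grepl("-", cls$raw_classifier_set, fixed = TRUE)
refs <- cls[!is_multi & cls$resolved_class %in% c("POLEmut", "MMRd", "p53abn"), ]
labels <- setNames(refs$resolved_class, refs$sample_id)
queries <- cls$sample_id[is_multi]
keep <- c(names(labels), queries)

dm <- build_distance_matrix(catalogs[keep, , drop = FALSE], fga[keep],
                            mode = "combined")
hc <- hierarchical_cluster(dm, "complete")
write_dendrogram_newick(hc, "results/dendrogram.nwk")

asg <- assign_groups(dm, labels, queries)
write.table(asg, "results/assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

driver <- setNames(ifelse(grepl("POLEmut", cls$raw_classifier_set[is_multi]),
                          "POLEmut", "MMRd"), queries)
coas <- coassignment_table(asg, driver)
at <- association_test(coas)

cat("Co-assignment of", length(queries), "multiple-classifier queries:\n")
print(coas)
for (d in c("MMRd", "POLEmut")) {
  qd <- names(driver)[driver == d]
  hits <- sum(asg$assigned_group[match(qd, asg$sample_id)] == d)
  cat(sprintf("  %s-driven queries co-assigned to %s: %d/%d\n",
              d, d, hits, length(qd)))
}
cat(sprintf("Association (query type x assigned group): %s p = %.3g\n",
            at$method, at$p_value))
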