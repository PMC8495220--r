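#!/usr/bin/env Rscript
# Step 4: compositional clonotype selection.
#
# Pools all samples into a cross-sample IGK clonotype matrix, drops rarely
# shared clonotypes, CLR-transforms (offset 1), selects tumor/normal
# discriminative clonotypes by cross-validated CLR-LASSO, checks the planted
# truth, and clusters the tumor samples on the selected clonotypes.

suppressPackageStartupMessages({
  library(tumorir)
  library(jsonlite)
})

cohort <- read_airr_table("scratch/cohort/cohort_airr.tsv",
                          "scratch/cohort/cohort_metadata.tsv")
truth <- read_json("scratch/cohort/truth.json", simplifyVector = TRUE)

cmat <- filter_clonotypes(build_clonotype_matrix(cohort, "IGK"))
message(sprintf("clonotype matrix after presence filter: %d samples x %d clonotypes",
                nrow(cmat$counts), ncol(cmat$counts)))

clr <- clr_transform(cmat, offset = 1)
labels <- cohort$metadata$group[match(rownames(cmat$counts),
                                      cohort$metadata$sample_id)]
sel <- lasso_select(clr, labels, n_folds = 10, seed = 7)
planted <- planted_clonotype_ids(cmat, list(planted = as.data.frame(truth$planted)))
message(sprintf("CLR-LASSO selected %d clonotypes; %d of %d planted recovered, %d others",
                length(sel$selected), sum(planted %in% sel$selected),
                length(planted), sum(!sel$selected %in% planted)))

write_json(list(selected = sel$selected,
                coefficients = as.list(sel$coefficients),
                lambda = sel$lambda, rule = sel$rule,
                planted_recovered = sum(planted %in% sel$selected)),
           "results/selection.json", auto_unbox = TRUE, digits = NA)

# heatmap-ready CLR values of the selected clonotypes
sel_vals <- clr$values[, sel$selected, drop = FALSE]
utils::write.table(data.frame(sample_id = rownames(sel_vals), group = labels,
                              sel_vals, check.names = FALSE),
                   "results/selected_clr_values.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# three-cluster structure of the tumor samples on the selected clonotypes
tumor_ids <- rownames(clr$values)[labels == "tumor"]
clr_tumor <- clr
clr_tumor$values <- clr$values[tumor_ids, , drop = FALSE]
clr_tumor$sample_ids <- tumor_ids
clusters <- cluster_samples(clr_tumor, selected = sel$selected, k = 3)
utils::write.table(data.frame(sample_id = names(clusters), cluster = clusters),
                   "results/tumor_clusters.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message(sprintf("tumor clusters (1 = lowest infiltration): sizes %s",
                paste(table(clusters), collapse = " / ")))
message("wrote results/selection.json, selected_clr_values.tsv, tumor_clusters.tsv")
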