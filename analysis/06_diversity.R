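#!/usr/bin/env Rscript
# Step 6 — genetic relatedness: allele-sharing distances over the QC-passed
# panel, a neighbor-joining tree, and a k-cluster cut cross-tabulated
# against the sample categories.

source("analysis/_common.R")

manifest <- read.delim(file.path(RESULTS, "manifest.tsv"))
gm <- read_genotypes(file.path(SIM_DIR, "genotypes.tsv"), snps = manifest)
qc <- sample_qc(gm, min_call_rate = STUDY_PARAMS$qc_min_call_rate)

D <- allele_sharing_distance(qc$passed)
tree <- neighbor_joining(D)
clusters <- assign_clusters(tree, STUDY_PARAMS$k_clusters)
message(sprintf("cut the NJ tree into %d clusters; composition by category:",
                STUDY_PARAMS$k_clusters))
print(table(cluster = clusters,
            category = qc$passed$samples$category[
              match(names(clusters), qc$passed$samples$sample)]))

write.table(round(D, 6), file.path(RESULTS, "distances.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
write_tree_newick(tree, file.path(RESULTS, "tree.nwk"))
write_tsv(data.frame(sample = names(clusters), cluster = unname(clusters)),
          file.path(RESULTS, "clusters.tsv"))
message("wrote distances.tsv, tree.nwk, clusters.tsv")
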