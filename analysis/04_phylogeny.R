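#!/usr/bin/env Rscript
# Step 4 — distance phylogeny of the mined families.
#
# Aligns the two homolog families from the mining step, derives p-distances,
# builds the neighbor-joining tree with column-resampling bootstrap support,
# and checks that the low and high bit-score families separate into two
# sub-clades. Exports Newick plus the distance matrix (PHYLIP and TSV).

suppressPackageStartupMessages(library(petasetyper))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
dir.create("results/analysis", showWarnings = FALSE, recursive = TRUE)

fix <- make_stand_ins(seed)
halo <- fix$sequences$synthetic_HaloPETase1_like_typeIII
ref <- fix$sequences$synthetic_IsPETase_like_typeIIb

fam <- c(list(`$<-`(halo, "id", "lowgroup_HaloPETase1_like"),
              `$<-`(fix$pmc, "id", "lowgroup_PmC_like")),
         lapply(1:3, function(i)
           mutate_seq(`$<-`(halo, "id", sprintf("lowgroup_homolog_%d", i)),
                      rate = 0.08, seed = seed + 300L + i)),
         list(`$<-`(ref, "id", "highgroup_IsPETase_like")),
         lapply(1:3, function(i)
           mutate_seq(`$<-`(ref, "id", sprintf("highgroup_homolog_%d", i)),
                      rate = 0.08, seed = seed + 400L + i)))

msa <- progressive_msa(fam)
write_msa_fasta(msa, "results/analysis/hit_family.afa")
dm <- distances_from_msa(msa)
write_distance_matrix(dm, "results/analysis/hit_family_dist.phy", "phylip")
write_distance_matrix(dm, "results/analysis/hit_family_dist.tsv", "tsv")

tree <- bootstrap_support(msa, replicates = 1000L, seed = seed)
write_newick(tree, "results/analysis/hit_family_nj.nwk")

groups <- split(tree$tip.label, sub("_.*$", "", tree$tip.label))
mono_low <- ape::is.monophyletic(tree, groups[["lowgroup"]])
support <- attr(tree, "support")

cat(sprintf("NJ tree over %d sequences, 1000 bootstrap replicates\n",
            length(fam)))
cat(sprintf("low/high families form two sub-clades: %s\n",
            ifelse(mono_low, "yes", "no")))
cat(sprintf("max bipartition support: %.3f\n", max(support, na.rm = TRUE)))
low_ids <- grep("^lowgroup", msa$ids)
cat(sprintf("within-low-group identity: %.0f%% to %.0f%%\n",
            100 * (1 - max(dm[low_ids, low_ids])),
            100 * (1 - min(dm[low_ids, low_ids][dm[low_ids, low_ids] > 0]))))
cat("wrote results/analysis/hit_family_nj.nwk\n")
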