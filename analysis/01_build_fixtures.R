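#!/usr/bin/env Rscript
# Step 1 — build the synthetic study set.
#
# Generates the four type-consistent archetype sequences (types I, IIa, IIb,
# III), the PmC-like stand-in planted at 62.4% identity to the
# HaloPETase1-like archetype, the toy coordinate file carrying the published
# disulfide/triad geometry, and the editable annotation tables. Everything
# downstream (mining, typing, phylogeny) reads from this directory.

suppressPackageStartupMessages(library(petasetyper))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

outdir <- "results/fixtures"
files <- write_fixture_suite(outdir, seed = seed)

fix <- make_stand_ins(seed)
cat(sprintf("seed %d -> %d archetypes + PmC-like stand-in\n",
            seed, length(fix$sequences)))
for (id in names(fix$sequences))
  cat(sprintf("  %-38s %3d aa  (type %s)\n", id,
              nchar(fix$sequences[[id]]$residues), fix$truth[[id]]))
cat(sprintf("  %-38s %3d aa\n", fix$pmc$id, nchar(fix$pmc$residues)))
cat("files:\n")
for (f in files) cat("  ", f, "\n")
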