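#!/usr/bin/env Rscript
# Step 2: run the per-species genome-wide IR1 screen.
#
# For every annotated gene, the -20,000..+10,000 bp window around the first
# exon's 5' end is extracted (oriented to the gene) and scanned for the IR1
# consensus [GA]GGT[TC]A-N-T[AG]ACC[TC] at the default zero-mismatch budget.
# Reads the bundle written by 01_simulate.R from FASTA/GFF3 on disk, i.e.
# the same path real genome releases would take.

suppressPackageStartupMessages(library(ir1screen))

bundle_dir <- "results/bundle"
species <- c("sp1", "sp2", "sp3")

for (sp in species) {
  genome <- read_genome(file.path(bundle_dir, paste0(sp, ".fasta")))
  tab <- run_screen(screen_config(sp),
                    genome, file.path(bundle_dir, paste0(sp, ".gff3")))
  out <- file.path("results", paste0("hits_", sp, ".tsv"))
  write_hits_tsv(tab, out)
  cat(sp, ": ", tab$n_genes_hit, " of ", tab$n_genes_total,
      " genes carry >=1 IR1 element (", nrow(tab$hits), " hits) -> ", out, "\n",
      sep = "")
}
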