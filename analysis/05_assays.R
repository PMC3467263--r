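#!/usr/bin/env Rscript
# Step 5: assay quantification formulas on simulated bench data.
#
# Demonstrates the delta-delta-Ct fold change (TBP-normalised), the
# relative-luciferase-activity fold induction, and the unpaired t-test with
# the star convention, on a simulated agonist-induction experiment with a
# true 2.5-fold induction.

suppressPackageStartupMessages(library(ir1screen))
set.seed(99)

n <- 4  # wells per group
true_fold <- 2.5

# qPCR: target Ct drops by log2(true_fold) cycles under agonist
cts <- rbind(
  data.frame(sample_id = paste0("d", 1:n), group = "DMSO", gene = "NDRG2",
             ct = rnorm(n, 26, 0.15)),
  data.frame(sample_id = paste0("p", 1:n), group = "PX", gene = "NDRG2",
             ct = rnorm(n, 26 - log2(true_fold), 0.15)),
  data.frame(sample_id = c(paste0("d", 1:n), paste0("p", 1:n)),
             group = rep(c("DMSO", "PX"), each = n), gene = "TBP",
             ct = rnorm(2 * n, 21, 0.1)))
dd <- ddct_fold(cts, "NDRG2", "TBP", control_group = "DMSO")
print(dd$groups, row.names = FALSE)
tt <- unpaired_t(dd$samples$fold[dd$samples$group == "PX"],
                 dd$samples$fold[dd$samples$group == "DMSO"])
cat(sprintf("NDRG2 induction: t = %.2f, p = %.3g (%s)\n",
            tt$statistic, tt$p_value, tt$stars))

# luciferase: firefly scales with the fold, Renilla is the transfection control
wells <- data.frame(
  well_id = paste0("w", 1:(2 * n)),
  condition = rep(c("DMSO", "PX"), each = n),
  firefly = c(rnorm(n, 1000, 60), rnorm(n, 1000 * true_fold, 150)),
  renilla = rnorm(2 * n, 100, 5))
rl <- rla_fold(wells, "PX", "DMSO")
cat(sprintf("reporter fold induction (RLA PX / RLA DMSO): %.2f\n", rl$fold))

dir.create("results", showWarnings = FALSE)
write.table(dd$samples, "results/ddct_samples.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rl$rla, "results/rla_wells.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
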