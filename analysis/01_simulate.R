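#!/usr/bin/env Rscript
# Step 1 — simulate the study inputs with known ground truth.
#
# The original EST libraries were never deposited, so every downstream step
# runs on generated data: an EST set with 20 planted precursor hairpins and
# 200 decoys, a 3'UTR set with planted target sites for the 11
# highly-expressed miRNAs, and a noiseless band-intensity table mirroring
# the reported class composition (11 high / 45 moderate / 2 very low).

suppressPackageStartupMessages(library(mirest))
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)
seed <- 1L

cat58 <- load_catalogue()

ds <- generate_est_dataset(cat58, n_planted = 20, n_decoys = 200, seed = seed)
write_fasta(ds$ests, "results/sim/ests.fasta")
jsonlite::write_json(ds$truth, "results/sim/est_truth.json",
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("wrote %d ESTs (%d planted, %d decoys)\n",
            nrow(ds$ests), sum(ds$ests$planted), sum(!ds$ests$planted)))

eleven <- load_target_counts()$mirna
# variant letters were dropped in the expression naming; map back to
# catalogue rows by family core where needed
pick <- cat58[cat58$name %in% c("sli-miR-33a", "sli-miR-33b", "sli-miR-34",
                                "sli-miR-71", "sli-miR-210", "sli-miR-283a",
                                "sli-miR-307", "sli-miR-928a", "sli-miR-928b",
                                "sli-miR-983", "sli-miR-1890a-1"), ]
utr <- generate_utr_set(pick, n_genes = 40, sites_per_mirna = 2, seed = seed,
                        class2_per_mirna = 1)
write_fasta(tibble::tibble(id = utr$utrs$gene_id,
                           sequence = utr$utrs$sequence),
            "results/sim/utrs.fasta")
write.table(utr$truth, "results/sim/utr_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("wrote %d UTRs with %d planted sites\n",
            nrow(utr$utrs), nrow(utr$truth)))

classes <- setNames(c(rep("high", 11), rep("moderate", 45), rep("very_low", 2)),
                    sprintf("clone_%02d", 1:58))
it <- generate_intensity_table(classes, noise_cv = 0.1, seed = seed)
write.table(it$table, "results/sim/intensities.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
cat("wrote 58-miRNA intensity table (+U6snRNA control)\n")
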