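#!/usr/bin/env Rscript
# Step 2 — homology scan, hairpin validation and cluster detection.
#
# Scans the simulated ESTs against the 58-entry mature catalogue with at
# most 5 mismatches, folds ~100 nt windows around each hit, keeps the
# lowest-energy window passing all precursor criteria (dG <= -20 kcal/mol,
# >= 14-pair stem, mature confined to one arm and >= 60% paired, GC within
# 0.2-0.8, core-energy ratio >= 0.8) and scores recovery of the planted
# truth.

suppressPackageStartupMessages(library(mirest))
dir.create("results/discover", showWarnings = FALSE, recursive = TRUE)

ests <- read_fasta("results/sim/ests.fasta", "DNA")
truth <- jsonlite::read_json("results/sim/est_truth.json", simplifyVector = TRUE)
refs <- load_catalogue()

res <- run_discover(ests, refs)
cat(sprintf("pipeline: %d ESTs -> %d with homology hits -> %d accepted precursors\n",
            res$stage_counts["n_ests"], res$stage_counts["n_ests_with_hits"],
            res$stage_counts["n_accepted"]))

write.table(res$accepted[, c("name", "est_id", "ref_name", "win_start",
                             "win_end", "strand", "mfe", "placement",
                             "mismatches")],
            "results/discover/accepted.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_fasta(tibble::tibble(id = res$accepted$name,
                           sequence = res$accepted$sequence),
            "results/discover/precursors.fasta")
export_hits_bed(res$hits, "results/discover/hits.bed")
acc_named <- res$accepted
export_clusters_gff3(res$clusters, acc_named, "results/discover/clusters.gff3")

sc <- score_recovery(res$accepted, truth, hits = res$hits)
cat(sprintf("recovery: hit sensitivity %.2f, precursor sensitivity %.2f, precision %.2f\n",
            sc$hit_sensitivity, sc$sensitivity, sc$precision))
cat(sprintf("decoy false-accept: %.1f%% of %d decoys\n",
            100 * sc$decoy_false_accept, length(truth$decoy_ids)))
jsonlite::write_json(sc, "results/discover/recovery.json",
                     auto_unbox = TRUE, digits = NA)
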