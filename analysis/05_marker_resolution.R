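#!/usr/bin/env Rscript
# Cross-marker resolution comparison: how the fine COI clusters collapse
# under 18S sequence identity, and matching of metabarcode-style OTU
# subfragments back to the Sanger 18S references.

suppressPackageStartupMessages(library(plectax))

coi_truth <- utils::read.delim("results/fixtures/truth_groups.tsv",
                               colClasses = "character")
truth_part <- stats::setNames(coi_truth$group, coi_truth$nid)
ssu <- read_alignment("results/fixtures/ssu.fasta")

s <- alignment_strings(ssu)
coarse <- stats::setNames(paste0("ssu_class_", as.integer(factor(s))),
                          names(s))
rep <- compare_partitions(truth_part, coarse)
print(rep)

sink("results/marker_resolution.txt")
print(rep)
sink()

# OTU matching: one 360-nt subfragment per distinct 18S sequence,
# mimicking the metabarcode amplicon being nested in the Sanger region
refs <- stats::setNames(unique(s), paste0("ref_", seq_along(unique(s))))
otus <- stats::setNames(substr(refs, 101, 460),
                        paste0("otu_", seq_along(refs)))
matches <- match_otus(otus, refs, min_identity = 0.99)
utils::write.table(matches, "results/otu_matches.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d/%d OTUs matched a Sanger reference at >= 99%% identity\n",
            sum(!is.na(matches$ref)), nrow(matches)))
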