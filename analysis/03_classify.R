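#!/usr/bin/env Rscript

# Classify every quantifiable intron's retention trajectory with the
# five-rule scheme (retention cutoff 0.1, change cutoff 0.1, |Pearson|
# cutoff 0.7 against the monotone reference), and score the calls against
# the simulator's ground truth.

suppressMessages(library(iridyn))

if (!dir.exists("scratch/bundle")) stop("run analysis/01_simulate.R first")
bundle <- read_fixture_bundle("scratch/bundle")

shared_list <- lapply(bundle$models, compute_shared_regions)
records <- do.call(rbind, lapply(shared_list, build_intron_records))
rownames(records) <- NULL
filt <- apply_iri_filters(
  build_iri_matrix(bundle$tracks, records, bundle$design))
ct <- classify_all(filt$matrix, "timeseries")

counts <- attr(ct, "counts")
cat("Label counts:",
    paste(names(counts), counts, sep = "=", collapse = ", "), "\n")

truth <- bundle$truth
m <- merge(truth[, c("intron_id", "label")],
           as.data.frame(ct)[, c("intron_id", "label")],
           by = "intron_id", suffixes = c("_true", "_called"))
conf <- table(true = m$label_true, called = m$label_called)
print(conf)
ud <- m$label_true %in% c("up_IR", "down_IR")
cat(sprintf("Recovery of true up/down introns: %.1f%% (%d/%d classified)\n",
            100 * mean(m$label_called[ud] == m$label_true[ud]),
            sum(ud), sum(truth$label %in% c("up_IR", "down_IR"))))

utils::write.table(as.data.frame(ct), "results/03_classification.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(as.data.frame(conf), "results/03_confusion.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Classification in results/03_classification.tsv;",
    "confusion table in results/03_confusion.tsv\n")
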