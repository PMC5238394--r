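#!/usr/bin/env Rscript
# Step 7 — subspecies-specific high-frequency SNPs: per-category alternate
# allele frequencies, the >80% contrast scan between fastigiata and hypogaea
# (with wild sharing reported separately), and the restriction to SNPs with
# moderate (missense) or high (nonsense-like) predicted effect.

source("analysis/_common.R")

manifest <- read.delim(file.path(RESULTS, "manifest.tsv"))
gm <- read_genotypes(file.path(SIM_DIR, "genotypes.tsv"), snps = manifest)
qc <- sample_qc(gm, min_call_rate = STUDY_PARAMS$qc_min_call_rate)

freqs <- category_frequencies(qc$passed)
scan <- specific_high_frequency_scan(freqs,
                                     threshold = STUDY_PARAMS$scan_threshold,
                                     snps = manifest)
message(sprintf(
  "specific high-frequency SNPs (threshold > %.2f): %d total = %d fastigiata + %d hypogaea (%d of the hypogaea set shared with wild)",
  STUDY_PARAMS$scan_threshold, scan$counts$total_specific,
  scan$counts$fastigiata_specific, scan$counts$hypogaea_specific,
  scan$counts$hypogaea_shared_with_wild))

eff <- read.delim(file.path(RESULTS, "effects.tsv"))
hits <- scan_effect_filter(scan$snps, eff)
message(sprintf("%d specific SNPs with moderate/high effect in %d genes",
                nrow(hits$snps), length(hits$genes)))

out <- merge(scan$snps, freqs, by = "snp_id")
out$pseudomolecule <- manifest$pseudomolecule[match(out$snp_id, manifest$snp_id)]
write_tsv(out[order(out$snp_id), ], file.path(RESULTS, "scan.tsv"))
write_tsv(hits$snps, file.path(RESULTS, "scan_effect_hits.tsv"))
jsonlite::write_json(scan$counts[setdiff(names(scan$counts),
                                         "per_pseudomolecule")],
                     file.path(RESULTS, "scan_counts.json"),
                     auto_unbox = TRUE, pretty = TRUE)
message("wrote scan.tsv, scan_effect_hits.tsv, scan_counts.json")
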