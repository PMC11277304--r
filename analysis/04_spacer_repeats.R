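#!/usr/bin/env Rscript
# Stage 4: tandem-repeat decomposition of the longest intergenic
# spacer and detection of degenerate tRNA remnants inside it.

suppressMessages(library(mitorearr))
stopifnot(file.exists("results/derived.gb"))

rec <- parse_genbank("results/derived.gb")
jr <- junction_report(rec)
sp <- extract_spacer(rec, jr$longest_spacer$left, jr$longest_spacer$right)
print(sp)

decomp <- decompose_tandem(sp$seq)[[1]]
print(decomp)
hits <- scan_remnants(sp, trna_library(rec))
print(hits)
tru <- annotate_trus(decomp, hits, sp$seq)
print(tru)

write.table(remnants_to_bed(hits, sp, genome_id = rec$id),
            "results/remnants.bed", sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
jsonlite::write_json(
  list(spacer = list(left = sp$left_gene, right = sp$right_gene,
                     length = sp$length, start = sp$start, end = sp$end),
       period = decomp$period, copy_number = decomp$copy_number,
       partial_unit_length = decomp$partial_unit_length,
       consensus = decomp$consensus,
       per_copy_mismatches = vapply(decomp$copy_alignments, `[[`, 0L,
                                    "mismatches"),
       remnant_hits = hits,
       n_remnant_copies = tru$n_remnant_copies,
       remnant_length = unname(tru$remnant_span[["length"]]),
       linker_length = tru$linker_length,
       linkers_identical = tru$linkers_identical),
  "results/spacer_repeats.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("spacer %s..%s (%d bp): %d x %d bp units + %d bp partial; %d/%d units carry a %d bp remnant\n",
            sp$left_gene, sp$right_gene, sp$length, decomp$copy_number,
            decomp$period, decomp$partial_unit_length,
            tru$n_remnant_copies, decomp$copy_number,
            unname(tru$remnant_span[["length"]])))
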