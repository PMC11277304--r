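#!/usr/bin/env Rscript
# Stage 3: circular gene order, junction accounting, and rearrangement
# classification against the ancestral insect arrangement.

suppressMessages(library(mitorearr))
stopifnot(file.exists("results/derived.gb"))

rec <- parse_genbank("results/derived.gb")
jr <- junction_report(rec)
print(jr)

ord <- extract_gene_order(rec)
call <- compare_orders(ord, ancestral_insect_order())
print(call)

jsonlite::write_json(
  list(observed_order = format_gene_order(ord),
       ancestral_order = format_gene_order(ancestral_insect_order()),
       status = call$status,
       affected_genes = call$affected_genes,
       window = call$window,
       breakpoint_count = call$breakpoint_count,
       n_overlaps = jr$n_overlaps,
       overlap_range = jr$overlap_range,
       n_spacers = jr$n_spacers,
       longest_spacer = jr$longest_spacer),
  "results/gene_order.json", auto_unbox = TRUE, digits = NA)
write.table(jr$junctions, "results/junctions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("rearrangement: %s of %s within window %s..%s\n",
            call$status, paste(call$affected_genes, collapse = "/"),
            call$window[1], call$window[2]))
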