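#!/usr/bin/env Rscript
# Stage 5: tandem duplication-random loss scenarios for the observed
# local rearrangement, ranked by the remnant evidence found in stage 4.

suppressMessages(library(mitorearr))
stopifnot(file.exists("results/spacer_repeats.json"))

info <- jsonlite::read_json("results/spacer_repeats.json",
                            simplifyVector = TRUE)
n_remnants <- info$n_remnant_copies
remnant_gene <- info$remnant_hits$source_gene[1]

scen <- enumerate_scenarios(c("trnW", "trnC"), c("trnC", "trnW"),
                            max_copies = 12L)
ranked <- rank_by_remnants(scen, rep(remnant_gene, n_remnants))
top <- ranked[[1]]
print(top)
pathway <- render_scenario(c("trnW", "trnC"), top)
cat(pathway, sep = "\n")

writeLines(pathway, "results/tdrl_pathway.txt")
jsonlite::write_json(
  list(observed_remnants = rep(remnant_gene, n_remnants),
       n_scenarios = length(scen),
       top = list(block = top$block, copy_count = top$copy_count,
                  event_count = top$event_count,
                  retained = as.list(top$retained),
                  predicted_order = top$predicted_order,
                  predicted_remnants = top$predicted_remnants,
                  remnants_match = top$remnants_match)),
  "results/tdrl.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("\n%d remnants of %s => minimal consistent expansion: %d tandem copies (single TDRL event)\n",
            n_remnants, remnant_gene, top$copy_count))
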