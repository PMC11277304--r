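#!/usr/bin/env Rscript
# Stage 6: map the trnW/trnC rearrangement as a binary character on
# the ototretine backbone phylogeny by Fitch parsimony and test
# whether it is a synapomorphy of the Oculogryphus + Stenocladius
# clade.

suppressMessages(library(mitorearr))
dir.create("results", showWarnings = FALSE)

tree <- read_newick(paste0(
  "(((Oculogryphus_chenghoiyanae,(Stenocladius_bicoloripes,",
  "Stenocladius_sp)),Ototretadrilus_sp),Drilaster_axillaris);"))
states <- c(Oculogryphus_chenghoiyanae = "1",
            Stenocladius_bicoloripes = "1",
            Stenocladius_sp = "1",
            Ototretadrilus_sp = "?",     # no mitogenome available
            Drilaster_axillaris = "0")

cm <- fitch_map(tree, states)
print(cm)

jsonlite::write_json(
  list(tree = ape::write.tree(tree),
       leaf_states = as.list(cm$leaf_states),
       min_changes = cm$min_changes,
       synapomorphy_of = cm$is_synapomorphy_of),
  "results/character_map.json", auto_unbox = TRUE, digits = NA)

if (!is.null(cm$is_synapomorphy_of)) {
  cat(sprintf("single origin: the rearrangement is a synapomorphy of (%s)\n",
              paste(cm$is_synapomorphy_of, collapse = ", ")))
} else {
  cat(sprintf("%d state changes required; not a clean synapomorphy\n",
              cm$min_changes))
}
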