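#' Run the full mitogenome characterization pipeline on one record
#'
#' Stages, in order: composition and strand skews; junction
#' (overlap/spacer) accounting; gene-order extraction and comparison to
#' the reference arrangement; tandem-repeat decomposition and remnant
#' scan of the longest spacer; TDRL scenario enumeration ranked by the
#' observed remnants; optionally Nei-Gojobori Ka against a reference
#' record and Fitch mapping of the rearrangement on a phylogeny.
#' Optional stages degrade gracefully: a failure is logged as a warning
#' and the corresponding report slot left `NULL`.
#'
#' @param record A [mitogenome_record()].
#' @param reference Optional [mitogenome_record()] for the Ka stage.
#' @param tree Optional `phylo` (or newick string/path) for character
#'   mapping.
#' @param tip_states Optional named leaf states for [fitch_map()].
#' @param reference_order `gene_order` to compare against (default
#'   [ancestral_insect_order()]).
#' @param tdrl_max_copies Maximum TDRL copy count to enumerate.
#' @param repeat_params,remnant_params Named lists of overrides passed
#'   to [decompose_tandem()] / [scan_remnants()].
#' @return An object of class `analysis_report` (a nested list; see
#'   [report_to_json()]).
#' @export
run_full_analysis <- function(record, reference = NULL, tree = NULL,
                              tip_states = NULL,
                              reference_order = ancestral_insect_order(),
                              tdrl_max_copies = 10L,
                              repeat_params = list(),
                              remnant_params = list()) {
  validate_record(record)
  comp <- base_composition(record$sequence)
  junctions <- junction_report(record)
  order_obs <- extract_gene_order(record)
  call <- compare_orders(order_obs, reference_order)

  spacer <- NULL; decomp <- NULL; hits <- NULL; trus <- NULL
  scenarios <- NULL
  if (!is.null(junctions$longest_spacer)) {
    spacer <- extract_spacer(record, junctions$longest_spacer$left,
                             junctions$longest_spacer$right)
    decomps <- do.call(decompose_tandem,
                       c(list(spacer$seq), repeat_params))
    decomp <- if (length(decomps)) decomps[[1]] else NULL
    hits <- do.call(scan_remnants,
                    c(list(spacer, trna_library(record)), remnant_params))
    if (!is.null(decomp) && nrow(hits))
      trus <- annotate_trus(decomp, hits, spacer$seq)
  }
  if (call$status %in% c("adjacent_swap", "block_transposition")) {
    win <- .rearranged_window(order_obs, reference_order, call)
    scen <- tryCatch(
      enumerate_scenarios(win$ancestral, win$derived,
                          max_copies = tdrl_max_copies),
      error = function(e) { warning("TDRL stage failed: ",
                                    conditionMessage(e)); NULL })
    if (!is.null(scen)) {
      ev <- if (!is.null(hits) && nrow(hits)) hits else NULL
      if (!is.null(ev) && !is.null(decomp)) {
        # one remnant per full repeat unit: a fragment inside the
        # trailing partial unit restates the partial repeat, not an
        # additional lost gene copy
        cs <- decomp$start + (seq_len(decomp$copy_number) - 1L) * decomp$period
        ce <- cs + decomp$period - 1L
        inside <- vapply(seq_len(nrow(ev)), function(i)
          any(cs <= ev$spacer_offset[i] &
              ev$spacer_offset[i] + ev$length[i] - 1L <= ce), logical(1))
        ev <- ev[inside, , drop = FALSE]
      }
      observed_remnants <- if (!is.null(ev) && nrow(ev))
        ev$source_gene[order(ev$spacer_offset)] else character()
      scenarios <- rank_by_remnants(scen, observed_remnants)
    }
  }
  ka <- NULL
  if (!is.null(reference))
    ka <- tryCatch(ka_against_reference(record, reference),
                   error = function(e) { warning("Ka stage failed: ",
                                                 conditionMessage(e)); NULL })
  cmap <- NULL
  if (!is.null(tree) && !is.null(tip_states)) {
    if (is.character(tree)) tree <- read_newick(tree)
    cmap <- tryCatch(fitch_map(tree, tip_states),
                     error = function(e) { warning("mapping stage failed: ",
                                                   conditionMessage(e)); NULL })
  }
  structure(list(id = record$id,
                 genome_length = genome_length(record),
                 composition = comp,
                 junctions = junctions,
                 gene_order = order_obs,
                 rearrangement = call,
                 spacer = spacer,
                 tandem = decomp,
                 remnants = hits,
                 tru = trus,
                 tdrl = scenarios,
                 ka = ka,
                 character_map = cmap),
            class = "analysis_report")
}

# local ancestral/derived windows over the rearranged span only; the
# flanking genes are fixed and take no part in the duplication, so
# they are excluded from the enumeration window
.rearranged_window <- function(observed, reference, call) {
  anchor <- intersect(reference$name, observed$name)[1]
  o <- rotate_order(observed, anchor)$name
  r <- rotate_order(reference, anchor)$name
  first <- which(o != r)[1]
  last <- tail(which(o != r), 1)
  list(ancestral = r[first:last], derived = o[first:last])
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %s (%d bp)\n", x$id, x$genome_length))
  print(x$composition)
  print(x$junctions)
  print(x$rearrangement)
  if (!is.null(x$tandem)) print(x$tandem)
  if (!is.null(x$remnants))
    cat(sprintf("  %d remnant hit(s)\n", nrow(x$remnants)))
  if (!is.null(x$tdrl) && length(x$tdrl)) print(x$tdrl[[1]])
  if (!is.null(x$ka)) print(x$ka$concatenated)
  if (!is.null(x$character_map)) print(x$character_map)
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Flattens the report into plain lists (dropping sequences longer
#' than `max_seq` characters) and writes JSON; rerunning the pipeline
#' on identical inputs yields byte-identical output.
#'
#' @param report An `analysis_report`.
#' @param file Optional output path.
#' @param max_seq Longest sequence string to embed (default 0: none).
#' @return The JSON string, invisibly when writing to file.
#' @export
report_to_json <- function(report, file = NULL, max_seq = 0L) {
  strip <- function(x) {
    if (inherits(x, "tandem_decomposition"))
      x$copy_alignments <- lapply(x$copy_alignments, unclass)
    if (is.list(x)) {
      x <- lapply(unclass(x), strip)
      x[vapply(x, is.null, TRUE)] <- NULL
      return(x)
    }
    if (is.character(x) && length(x) == 1L && nchar(x) > max_seq &&
        grepl("^[ACGTN-]+$", x)) return(NULL)
    x
  }
  js <- jsonlite::toJSON(strip(report), auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (!is.null(file)) { writeLines(js, file); return(invisible(js)) }
  js
}
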