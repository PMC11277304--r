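#' Construct a gene feature table
#'
#' @param name Canonical gene tokens (or raw labels flagged non-canonical).
#' @param gene_class One of `PCG`, `tRNA`, `rRNA`, `control_region` per row.
#' @param strand `"J"` (majority) or `"N"` (minority) per row.
#' @param start,end 1-based inclusive coordinates on the J strand.
#' @param wraps_origin Logical; `TRUE` for features spanning the circular
#'   origin (then `start > end` is permitted).
#' @return A `data.frame` with one row per feature, sorted by `start`.
#' @export
gene_features <- function(name, gene_class, strand, start, end,
                          wraps_origin = FALSE) {
  n <- length(name)
  df <- data.frame(
    name = as.character(name),
    gene_class = as.character(gene_class),
    strand = as.character(strand),
    start = as.integer(start),
    end = as.integer(end),
    wraps_origin = rep_len(as.logical(wraps_origin), n),
    stringsAsFactors = FALSE)
  df[order(df$start), , drop = FALSE]
}

#' Construct an annotated mitogenome record
#'
#' The central container of the package: a (usually circular) DNA sequence
#' plus an ordered table of typed, stranded gene features.
#'
#' @param id Accession-like identifier.
#' @param sequence IUPAC DNA string (J strand).
#' @param features A feature table as built by [gene_features()].
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `mitogenome_record`.
#' @export
mitogenome_record <- function(id, sequence, features, topology = "circular") {
  rec <- structure(
    list(id = as.character(id),
         sequence = toupper(as.character(sequence)),
         topology = match.arg(topology, c("circular", "linear")),
         features = features),
    class = "mitogenome_record")
  validate_record(rec)
  rec
}

#' Validate a mitogenome record's invariants
#'
#' Checks the sequence alphabet, coordinate bounds, origin-wrap
#' consistency and feature ordering.
#'
#' @param record A `mitogenome_record`.
#' @return The record, invisibly; errors on violation.
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "mitogenome_record"))
  L <- nchar(record$sequence)
  bad <- setdiff(unique(chars(record$sequence)), IUPAC_DNA)
  if (length(bad))
    stop("sequence contains non-IUPAC characters: ",
         paste(bad, collapse = ", "))
  f <- record$features
  if (nrow(f)) {
    if (any(f$start < 1L | f$start > L | f$end < 1L | f$end > L))
      stop("feature coordinates outside [1, ", L, "]")
    if (any(!f$wraps_origin & f$start > f$end))
      stop("start > end for a non-wrapping feature: ",
           f$name[which(!f$wraps_origin & f$start > f$end)[1]])
    if (any(f$wraps_origin) && record$topology != "circular")
      stop("origin-wrapping feature on a linear record")
    if (!all(f$strand %in% c("J", "N")))
      stop("strand must be J or N")
    if (is.unsorted(f$start))
      stop("features must be sorted by start")
  }
  invisible(record)
}

#' @export
print.mitogenome_record <- function(x, ...) {
  cat(sprintf("<mitogenome_record> %s: %d bp, %s, %d features\n",
              x$id, nchar(x$sequence), x$topology, nrow(x$features)))
  invisible(x)
}

#' Genome length of a record
#' @param record A `mitogenome_record`.
#' @return Length in bp.
#' @export
genome_length <- function(record) nchar(record$sequence)

#' Extract the sequence of a feature, strand- and origin-aware
#'
#' J-strand features return the forward substring; N-strand features its
#' reverse complement; origin-wrapping features are read through the
#' circular origin before strand handling.
#'
#' @param record A `mitogenome_record`.
#' @param feature A single row of the record's feature table, or a gene
#'   name (the first feature with that name is used).
#' @return DNA string in the gene's reading orientation.
#' @export
extract_feature_seq <- function(record, feature) {
  if (is.character(feature)) {
    i <- match(feature, record$features$name)
    if (is.na(i)) stop("no feature named ", feature)
    feature <- record$features[i, ]
  }
  s <- if (feature$wraps_origin)
    circular_substr(record$sequence, feature$start, feature$end)
  else
    substr(record$sequence, feature$start, feature$end)
  if (feature$strand == "N") revcomp(s) else s
}

#' Whole-record reverse complement
#'
#' Reverse-complements the sequence and remaps every feature's
#' coordinates and strand accordingly; used for strand-symmetry checks.
#'
#' @param record A `mitogenome_record`.
#' @return A new `mitogenome_record`.
#' @export
revcomp_record <- function(record) {
  L <- genome_length(record)
  f <- record$features
  new_start <- ifelse(f$wraps_origin, L - f$end + 1L, L - f$end + 1L)
  new_end <- L - f$start + 1L
  f2 <- gene_features(f$name, f$gene_class,
                      ifelse(f$strand == "J", "N", "J"),
                      new_start, new_end, f$wraps_origin)
  mitogenome_record(record$id, revcomp(record$sequence), f2,
                    record$topology)
}
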