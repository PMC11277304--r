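# GenBank flat-file reader/writer for single annotated mitogenome
# records.  Only the feature keys that matter for mitogenomes are
# interpreted (CDS, tRNA, rRNA, D-loop/misc_feature); coordinates are
# kept 1-based inclusive externally, per GenBank convention.

.GB_CLASS_TO_KEY <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                      control_region = "D-loop")

#' Parse a single-record GenBank flat file
#'
#' Reads LOCUS (length, topology), the feature table (CDS, tRNA, rRNA,
#' D-loop and misc_feature entries) and the ORIGIN sequence.  Gene names
#' from `/gene=` (falling back to `/product=`) are normalized with
#' [canonical_gene_name()]; unknown names are retained with a warning.
#' `complement(...)` maps to the N strand and `join(a..L,1..b)` locations
#' spanning the origin set `wraps_origin`.
#'
#' @param text GenBank content: a file path or a character vector of lines.
#' @return A [mitogenome_record()].
#' @export
parse_genbank <- function(text) {
  lines <- .as_lines(text)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("malformed GenBank file: no LOCUS line")
  locus <- lines[locus_i[1]]
  lf <- strsplit(trimws(locus), "\\s+")[[1]]
  id <- lf[2]
  topology <- if (any(grepl("circular", locus))) "circular" else "linear"

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (!length(orig_i)) stop("malformed GenBank file: no ORIGIN section")
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[1] else length(lines) + 1L

  seq_lines <- lines[(orig_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("malformed GenBank file: empty ORIGIN")

  feats <- list()
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1L):(orig_i[1] - 1L)]
    cur <- NULL
    for (k in seq_along(block)) {
      ln <- block[k]
      if (grepl("^ {5}\\S", ln)) {           # new feature line
        if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        if (length(parts) < 2L)
          stop("malformed feature line ", k + feat_i[1], ": ", ln)
        cur <- list(key = parts[1], loc = parts[2], quals = character())
      } else if (grepl("^ {21}", ln) && !is.null(cur)) {
        q <- trimws(ln)
        if (startsWith(q, "/")) cur$quals <- c(cur$quals, q)
        else if (length(cur$quals))           # continuation line
          cur$quals[length(cur$quals)] <-
            paste0(cur$quals[length(cur$quals)], " ", q)
        else cur$loc <- paste0(cur$loc, q)    # wrapped location
      }
    }
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  }

  rows <- list()
  for (ft in feats) {
    if (!ft$key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature"))
      next
    loc <- .parse_location(ft$loc, nchar(sequence))
    label <- .qual_value(ft$quals, "gene") %||%
      .qual_value(ft$quals, "product") %||%
      (if (ft$key == "D-loop") "control_region" else NA_character_)
    if (ft$key == "misc_feature" &&
        !grepl("control|A\\+?T.rich", label %||% "", ignore.case = TRUE))
      next
    if (is.na(label)) next
    name <- canonical_gene_name(label)
    non_can <- attr(name, "non_canonical")
    name <- as.character(name)
    if (non_can)
      warning("non-canonical gene name retained: ", label)
    cls <- switch(ft$key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                  "control_region")
    rows[[length(rows) + 1L]] <- data.frame(
      name = name, gene_class = cls, strand = loc$strand,
      start = loc$start, end = loc$end, wraps_origin = loc$wraps,
      stringsAsFactors = FALSE)
  }
  f <- if (length(rows)) do.call(rbind, rows) else
    gene_features(character(), character(), character(), integer(), integer())
  f <- f[order(f$start), , drop = FALSE]
  rownames(f) <- NULL
  mitogenome_record(id, sequence, f, topology)
}

.as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    readLines(text)
  else if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
  else text
}

.qual_value <- function(quals, name) {
  pat <- paste0("^/", name, "=")
  hit <- quals[grepl(pat, quals)]
  if (!length(hit)) return(NULL)
  gsub('^"|"$', "", sub(pat, "", hit[1]))
}

.parse_location <- function(loc, L) {
  strand <- "J"
  raw <- loc
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wraps <- FALSE
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    segs <- strsplit(inner, ",", fixed = TRUE)[[1]]
    ranges <- lapply(segs, .parse_simple_range, raw = raw)
    if (length(ranges) == 2L && ranges[[2]]$start == 1L &&
        ranges[[1]]$end == L) {
      wraps <- TRUE
      return(list(start = ranges[[1]]$start, end = ranges[[2]]$end,
                  strand = strand, wraps = TRUE))
    }
    stop("unsupported join() location: ", raw)
  }
  r <- .parse_simple_range(loc, raw = raw)
  list(start = r$start, end = r$end, strand = strand, wraps = wraps)
}

.parse_simple_range <- function(txt, raw) {
  m <- regmatches(txt, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", txt))[[1]]
  if (!length(m)) stop("malformed location: ", raw)
  list(start = as.integer(m[2]), end = as.integer(m[3]))
}

#' Serialize a mitogenome record to GenBank flat-file text
#'
#' @param record A [mitogenome_record()].
#' @param file Optional path; if given, the text is written there.
#' @return Character vector of GenBank lines (invisibly when writing).
#' @export
write_genbank <- function(record, file = NULL) {
  L <- genome_length(record)
  lines <- c(sprintf("LOCUS       %-16s %d bp    DNA     %-8s INV",
                     record$id, L, record$topology),
             sprintf("DEFINITION  %s mitochondrial genome.", record$id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", L))
  f <- record$features
  for (i in seq_len(nrow(f))) {
    key <- .GB_CLASS_TO_KEY[[f$gene_class[i]]] %||% "misc_feature"
    loc <- if (f$wraps_origin[i])
      sprintf("join(%d..%d,1..%d)", f$start[i], L, f$end[i])
    else sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] == "N") loc <- sprintf("complement(%s)", loc)
    lines <- c(lines, sprintf("     %-15s %s", key, loc))
    if (f$gene_class[i] != "control_region")
      lines <- c(lines, sprintf('                     /gene="%s"', f$name[i]))
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(record$sequence)
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    seg <- substr(s, p, min(p + 59L, L))
    blocks <- substring(seg, seq(1, nchar(seg), 10), pmin(seq(10, nchar(seg) + 9, 10), nchar(seg)))
    lines <- c(lines, sprintf("%9d %s", p, paste(blocks, collapse = " ")))
  }
  lines <- c(lines, "//")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Read a feature-table TSV plus FASTA into a mitogenome record
#'
#' The TSV must have columns `name`, `class`, `strand`, `start`, `end`
#' and may have a logical `wraps_origin` column.
#'
#' @param tsv Path to (or lines of) the tab-separated feature table.
#' @param fasta Path to a single-sequence FASTA file.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return A [mitogenome_record()].
#' @export
parse_feature_table <- function(tsv, fasta, topology = "circular") {
  dss <- Biostrings::readDNAStringSet(fasta)
  if (length(dss) != 1L) stop("FASTA must contain exactly one sequence")
  sequence <- as.character(dss[[1]])
  id <- sub("\\s.*", "", names(dss)[1])
  tab <- if (is.data.frame(tsv)) tsv else
    read.delim(.tsv_con(tsv), stringsAsFactors = FALSE)
  need <- c("name", "class", "strand", "start", "end")
  if (!all(need %in% names(tab)))
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  L <- nchar(sequence)
  if (nrow(tab) && any(tab$start < 1 | tab$end < 1 | tab$start > L | tab$end > L))
    stop("feature coordinate outside the sequence [1, ", L, "]")
  wraps <- if ("wraps_origin" %in% names(tab)) as.logical(tab$wraps_origin)
           else rep(FALSE, nrow(tab))
  if (nrow(tab) && any(!wraps & tab$start > tab$end))
    stop("start > end without wraps_origin for: ",
         tab$name[which(!wraps & tab$start > tab$end)[1]])
  name <- canonical_gene_name(tab$name)
  dup <- name[duplicated(name) & !name %in%
                c("trnL1", "trnL2", "trnS1", "trnS2")]
  if (length(dup))
    warning("duplicate canonical gene name(s): ",
            paste(unique(dup), collapse = ", "))
  f <- gene_features(as.character(name), tab$class, tab$strand,
                     tab$start, tab$end, wraps)
  mitogenome_record(id, sequence, f, topology)
}

.tsv_con <- function(tsv) {
  if (length(tsv) == 1L && !grepl("\n", tsv) && file.exists(tsv)) tsv
  else textConnection(paste(tsv, collapse = "\n"))
}

#' Write the feature table of a record as TSV
#'
#' Column order: `name`, `class`, `strand`, `start`, `end`,
#' `wraps_origin`; coordinates 1-based inclusive.
#'
#' @param record A [mitogenome_record()].
#' @param file Output path.
#' @export
write_feature_table <- function(record, file) {
  f <- record$features
  out <- data.frame(name = f$name, class = f$gene_class, strand = f$strand,
                    start = f$start, end = f$end,
                    wraps_origin = f$wraps_origin)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a record's sequence as FASTA
#'
#' @param record A [mitogenome_record()].
#' @param file Output path.
#' @export
write_fasta <- function(record, file) {
  dss <- Biostrings::DNAStringSet(setNames(record$sequence, record$id))
  Biostrings::writeXStringSet(dss, file)
  invisible(file)
}
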