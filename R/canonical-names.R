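#' Canonical mitochondrial gene vocabulary
#'
#' The closed token vocabulary used throughout the package: 13
#' protein-coding genes, 22 tRNAs (leucine/serine paralogs
#' distinguished by anticodon family: trnL1 = CUN, trnL2 = UUR,
#' trnS1 = AGN, trnS2 = UCN), 2 rRNAs, and `control_region`.
#'
#' @format Character vectors of canonical gene tokens.
#' @name canonical_vocabulary
NULL

#' @rdname canonical_vocabulary
#' @export
CANONICAL_PCGS <- c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
                    "COX1", "COX2", "COX3", "CYTB", "ATP6", "ATP8")

#' @rdname canonical_vocabulary
#' @export
CANONICAL_TRNAS <- c("trnA", "trnR", "trnN", "trnD", "trnC", "trnE", "trnQ",
                     "trnG", "trnH", "trnI", "trnL1", "trnL2", "trnK", "trnM",
                     "trnF", "trnP", "trnS1", "trnS2", "trnT", "trnW", "trnY",
                     "trnV")

#' @rdname canonical_vocabulary
#' @export
CANONICAL_RRNAS <- c("rrnL", "rrnS")

#' @rdname canonical_vocabulary
#' @export
CANONICAL_GENES <- c(CANONICAL_PCGS, CANONICAL_TRNAS, CANONICAL_RRNAS,
                     "control_region")

# amino-acid letter -> canonical tRNA token (unambiguous paralogs only)
.TRNA_BY_AA <- c(A = "trnA", R = "trnR", N = "trnN", D = "trnD", C = "trnC",
                 E = "trnE", Q = "trnQ", G = "trnG", H = "trnH", I = "trnI",
                 K = "trnK", M = "trnM", F = "trnF", P = "trnP", T = "trnT",
                 W = "trnW", Y = "trnY", V = "trnV")

.AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Glu = "E",
          Gln = "Q", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
          Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
          Tyr = "Y", Val = "V")

# anticodon (DNA, as written in labels like trnL-uag) -> paralog index
.LEU_SER_ANTICODONS <- c(
  tag = "trnL1", uag = "trnL1",            # Leu CUN family
  taa = "trnL2", uaa = "trnL2",            # Leu UUR family
  tct = "trnS1", ucu = "trnS1", gct = "trnS1", gcu = "trnS1",  # Ser AGN
  tga = "trnS2", uga = "trnS2")            # Ser UCN

.PCG_SYNONYMS <- c(
  nd1 = "ND1", nad1 = "ND1", nd2 = "ND2", nad2 = "ND2", nd3 = "ND3",
  nad3 = "ND3", nd4 = "ND4", nad4 = "ND4", nd4l = "ND4L", nad4l = "ND4L",
  nd5 = "ND5", nad5 = "ND5", nd6 = "ND6", nad6 = "ND6",
  cox1 = "COX1", coi = "COX1", co1 = "COX1", coxi = "COX1",
  cox2 = "COX2", coii = "COX2", co2 = "COX2", coxii = "COX2",
  cox3 = "COX3", coiii = "COX3", co3 = "COX3", coxiii = "COX3",
  cytb = "CYTB", cob = "CYTB", cb = "CYTB",
  atp6 = "ATP6", atpase6 = "ATP6", atp8 = "ATP8", atpase8 = "ATP8")

.RNA_SYNONYMS <- c(
  rrnl = "rrnL", `16s` = "rrnL", `16srrna` = "rrnL", lrrna = "rrnL",
  lsu = "rrnL", rrns = "rrnS", `12s` = "rrnS", `12srrna` = "rrnS",
  srrna = "rrnS", ssu = "rrnS",
  controlregion = "control_region", dloop = "control_region",
  atrichregion = "control_region", atrich = "control_region",
  putativecontrolregion = "control_region")

#' Normalize a free-text gene label to the canonical vocabulary
#'
#' Maps the common synonym forms found in GenBank records ("tRNA-Trp",
#' "trnW-UCA", "COI", "l-rRNA", "16S ribosomal RNA", "D-loop", ...) onto a
#' closed vocabulary of 37 gene tokens plus `control_region`.  The two
#' leucine and serine tRNA paralogs are resolved by anticodon when one is
#' present in the label; a bare "tRNA-Leu"/"tRNA-Ser" cannot be resolved
#' and is returned non-canonical.
#'
#' @param raw Character vector of gene labels.
#' @return Character vector of the same length; canonical tokens where a
#'   mapping exists, otherwise the input unchanged with attribute
#'   `non_canonical` (a logical vector) marking unmapped entries.
#' @export
canonical_gene_name <- function(raw) {
  out <- vapply(raw, .canonical_one, character(1), USE.NAMES = FALSE)
  attr(out, "non_canonical") <- !(out %in% CANONICAL_GENES)
  out
}

.canonical_one <- function(raw) {
  if (is.na(raw) || !nzchar(raw)) return(raw)
  if (raw %in% CANONICAL_GENES) return(raw)
  key <- tolower(gsub("[^A-Za-z0-9]", "", raw))
  if (key %in% names(.PCG_SYNONYMS)) return(unname(.PCG_SYNONYMS[key]))
  # strip common rRNA decorations
  rkey <- sub("ribosomalrna", "rrna", key)
  if (rkey %in% names(.RNA_SYNONYMS)) return(unname(.RNA_SYNONYMS[rkey]))
  # tRNA forms: trnX, trnX-<anticodon>, tRNA-Xxx, tRNA-Xxx(nnn), tX, X
  low <- tolower(raw)
  m <- regmatches(low, regexec("^t?rna[-_ ]?([a-z]{3})[ (]?([acgut]{3})?\\)?$", low))[[1]]
  if (length(m)) {
    aa3 <- paste0(toupper(substr(m[2], 1, 1)), substr(m[2], 2, 3))
    if (aa3 %in% names(.AA3)) {
      aa <- .AA3[[aa3]]
      anti <- m[3]
      return(.trna_token(aa, anti, raw))
    }
  }
  m <- regmatches(key, regexec("^trn([a-z])([0-9]?)([acgut]{3})?$", key))[[1]]
  if (length(m)) {
    aa <- toupper(m[2])
    if (m[3] %in% c("1", "2") && aa %in% c("L", "S"))
      return(paste0("trn", aa, m[3]))
    return(.trna_token(aa, m[4], raw))
  }
  # two-letter shorthand like "TW"
  if (grepl("^t[a-z]$", key)) {
    aa <- toupper(substr(key, 2, 2))
    if (aa %in% names(.TRNA_BY_AA)) return(unname(.TRNA_BY_AA[aa]))
  }
  raw
}

.trna_token <- function(aa, anticodon, raw) {
  if (aa %in% names(.TRNA_BY_AA)) return(unname(.TRNA_BY_AA[aa]))
  if (aa %in% c("L", "S")) {
    if (!is.na(anticodon) && nzchar(anticodon)) {
      key <- tolower(anticodon)
      if (key %in% names(.LEU_SER_ANTICODONS))
        return(unname(.LEU_SER_ANTICODONS[key]))
    }
    return(raw)  # unresolvable paralog
  }
  raw
}

#' Gene class of a canonical token
#'
#' @param name Character vector of canonical tokens.
#' @return One of `"PCG"`, `"tRNA"`, `"rRNA"`, `"control_region"` per
#'   element, or `NA` for non-canonical names.
#' @export
gene_class_of <- function(name) {
  ifelse(name %in% CANONICAL_PCGS, "PCG",
  ifelse(name %in% CANONICAL_TRNAS, "tRNA",
  ifelse(name %in% CANONICAL_RRNAS, "rRNA",
  ifelse(name == "control_region", "control_region", NA_character_))))
}
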