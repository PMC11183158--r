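#' @include setcore.R
NULL

# Synthetic reconstructions of the published worked examples. The region
# structure below reproduces the counts printed in the article text; the
# element identifiers themselves (except the three named ASVs and the named
# target genes) are synthetic, and regions the text does not pin down are
# empty (Cases I/III) or filled with fixed documented values (Case II).

.fillRegion <- function(membership, sets, count, prefix) {
  if (count == 0) return(membership)
  ids <- sprintf("%s%04d", prefix, seq_len(count))
  add <- rep(list(sets), count)
  names(add) <- ids
  c(membership, add)
}

#' Synthetic five-set differential-metabolite collection
#'
#' Reconstruction of the five-part metabolite comparison: 119 metabolites
#' common to all five sets FS1-FS5; unique counts 2, 5, 1, 0 and 4; and
#' pairwise-only overlaps FS1&FS2 = 0, FS2&FS3 = 0, FS3&FS4 = 1,
#' FS4&FS5 = 7. Every other region is empty. Metabolite IDs are synthetic.
#'
#' @return a [SetCollection-class] with sets FS1..FS5.
#' @export
caseMetaboliteCollection <- function() {
  s <- paste0("FS", 1:5)
  m <- list()
  m <- .fillRegion(m, s, 119L, "Mcore")
  uq <- c(2L, 5L, 1L, 0L, 4L)
  for (i in 1:5) m <- .fillRegion(m, s[i], uq[i], sprintf("Mu%d_", i))
  m <- .fillRegion(m, c("FS3", "FS4"), 1L, "Mp34_")
  m <- .fillRegion(m, c("FS4", "FS5"), 7L, "Mp45_")
  SetCollection(m, setLabels = s)
}

#' Synthetic seven-regulator ChIP-seq target collection
#'
#' Reconstruction of the seven-regulator target comparison: 3411 genes
#' bound by all seven regulators (Sox2, Nanog, Klf4, Esrrb, H3K27ac, Med1,
#' H3K4me1), 475 genes bound by the six regulators excluding H3K27ac, and
#' no regulator with unique targets. Gene IDs are synthetic.
#'
#' @return a [SetCollection-class] with the seven regulator sets.
#' @export
caseRegulatorCollection <- function() {
  s <- c("Sox2", "Nanog", "Klf4", "Esrrb", "H3K27ac", "Med1", "H3K4me1")
  m <- list()
  m <- .fillRegion(m, s, 3411L, "g7x")
  m <- .fillRegion(m, setdiff(s, "H3K27ac"), 475L, "g6x")
  SetCollection(m, setLabels = s)
}

#' Synthetic 18-group microbiome OTU collection
#'
#' Reconstruction of the 18-group OTU comparison: 413 ASVs shared by all
#' groups (six replicates each of knock-out, wild-type and overexpression),
#' and exactly three groups with a unique ASV: ASV_942 in WT3, ASV_1022 in
#' OE1 and ASV_1201 in KO3. The remaining 15 groups have no unique
#' elements. Core ASV IDs are synthetic.
#'
#' @return a [SetCollection-class] with 18 group sets.
#' @export
caseOtuCollection <- function() {
  s <- c(paste0("KO", 1:6), paste0("WT", 1:6), paste0("OE", 1:6))
  m <- list()
  m <- .fillRegion(m, s, 413L, "ASV_core")
  m[["ASV_942"]] <- "WT3"
  m[["ASV_1022"]] <- "OE1"
  m[["ASV_1201"]] <- "KO3"
  SetCollection(m, setLabels = s)
}

#' Synthetic three-set DE-gene intersection count table
#'
#' Count-matrix input ("&" signatures, TAB separated, header line) for the
#' three-cell-type Euler example: the NCCIT-unique region holds 666 genes
#' (the largest region) and the three-way intersection 15 (the smallest).
#' The remaining region counts are synthetic fixed values chosen between
#' those two extremes.
#'
#' @return length-1 character: the TSV text.
#' @export
caseEulerCountsText <- function() {
  paste(
    "Intersection\tCount",
    "NCCIT\t666",
    "eRMS\t420",
    "GBM\t350",
    "NCCIT&eRMS\t86",
    "NCCIT&GBM\t63",
    "eRMS&GBM\t42",
    "NCCIT&eRMS&GBM\t15",
    sep = "\n")
}

#' Synthetic GO biological-process membership for the network example
#'
#' The named target genes and their four biological processes: one gene
#' (IMPTAPA2N19692_1) participates in all four processes, six genes link
#' the monocarboxylic-acid-biosynthetic and multicellular-organismal
#' processes, and one gene is specific to organonitrogen compound
#' biosynthesis.
#'
#' @return a [SetCollection-class] with four process sets.
#' @export
caseGoCollection <- function() {
  mono <- "monocarboxylic acid biosynthetic process"
  amino <- "cellular amino acid metabolic process"
  organo <- "organonitrogen compound biosynthetic process"
  multi <- "multicellular organismal process"
  pair <- c("IMPTAPA2N21328_1", "IMPTAPA2N31674_1", "IMPTAPA2N40577_1",
            "IMPTAPA2N11277_1", "IMPTAPA2N33800_1", "IMPTAPA2N22367_1")
  m <- c(
    list(IMPTAPA2N19692_1 = c(mono, amino, organo, multi)),
    structure(rep(list(c(mono, multi)), length(pair)), names = pair),
    list(IMPTAPA2N33400_1 = organo))
  SetCollection(m, setLabels = c(mono, amino, organo, multi))
}
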