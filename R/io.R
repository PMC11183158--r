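#' @include setcore.R
NULL

# Resolve an input argument that may be a file path or literal text.
.asLines <- function(input) {
  if (length(input) == 1L && !grepl("[\n\t]", input) && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else {
    strsplit(paste(input, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
}

# Split TAB-separated lines into exactly two trimmed tokens; error with the
# 1-based line number otherwise. Trailing blank lines are dropped.
.twoColumnRows <- function(lines) {
  keep <- !grepl("^\\s*$", lines)
  # drop only trailing blanks; an interior blank line is a format error
  lastData <- max(c(0L, which(keep)))
  lines <- lines[seq_len(lastData)]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    tok <- trimws(tok)
    if (length(tok) != 2L)
      stop("line ", i, ": expected 2 TAB-separated columns, found ",
           length(tok))
    if (any(tok == ""))
      stop("line ", i, ": empty token in two-column input")
    rows[[i]] <- tok
  }
  rows
}

#' Read a two-column membership table
#'
#' The standardized long-format input: column 1 holds element IDs, column 2
#' the set each element belongs to, one membership per row, separated by a
#' single TAB. Duplicated (element, set) rows collapse to one membership.
#' Set order is the order of first appearance in column 2.
#'
#' @param input a file path or the raw text itself.
#' @param hasHeader treat the first line as a header (explicit flag, never
#'   inferred).
#' @return a [SetCollection-class].
#' @examples
#' readTwoColumn("id\tset\ng1\tA\ng1\tB\ng2\tA", hasHeader = TRUE)
#' @export
readTwoColumn <- function(input, hasHeader = FALSE) {
  lines <- .asLines(input)
  if (hasHeader) {
    if (!length(lines)) stop("header expected but input is empty")
    lines <- lines[-1]
  }
  rows <- .twoColumnRows(lines)
  el <- vapply(rows, `[`, character(1), 1L)
  st <- vapply(rows, `[`, character(1), 2L)
  setLabels <- unique(st)
  membership <- lapply(split(st, factor(el, levels = unique(el))), unique)
  SetCollection(membership, setLabels = setLabels)
}

#' Read per-set pasted element lists
#'
#' Each block is the pasted content of one set: element tokens separated by
#' newlines and/or commas. Blank tokens are dropped and within-set
#' duplicates collapsed. Set order is block order.
#'
#' @param blocks named list (or named character vector) of raw text, one
#'   entry per set; names are the set labels.
#' @return a [SetCollection-class].
#' @examples
#' readElementLists(list(A = "x\ny", B = "y"))
#' @export
readElementLists <- function(blocks) {
  nm <- names(blocks)
  if (is.null(nm) || any(trimws(nm) == ""))
    stop("every block must carry a non-empty set name")
  nm <- trimws(nm)
  if (anyDuplicated(nm)) stop("duplicate set names in blocks")
  perSet <- lapply(blocks, function(txt) {
    tok <- trimws(strsplit(paste(txt, collapse = "\n"), "[\n,]")[[1]])
    unique(tok[tok != ""])
  })
  names(perSet) <- nm
  el <- unlist(perSet, use.names = FALSE)
  st <- rep(nm, lengths(perSet))
  membership <- lapply(split(st, factor(el, levels = unique(el))), unique)
  SetCollection(membership, setLabels = nm)
}

#' Read an "&"-signature intersection count table
#'
#' Column 1 is a signature of set names joined by "&" (surrounding spaces
#' tolerated), column 2 a non-negative integer count, TAB separated.
#' Signatures are canonicalized against the set order given by first
#' appearance within a signature; the set universe is the sorted union of
#' names seen in any row, so parsing is invariant under row permutation.
#'
#' @param input a file path or the raw text itself.
#' @param hasHeader treat the first line (e.g. "Intersection\\tCount") as a
#'   header.
#' @param semantics how the counts are to be read: "exclusive" region sizes
#'   (default) or "inclusive" intersection cardinalities.
#' @return an [IntersectionCountTable-class].
#' @examples
#' readIntersectionCounts("Intersection\tCount\nA\t10\nA&B\t3", hasHeader = TRUE)
#' @export
readIntersectionCounts <- function(input, hasHeader = FALSE,
                                   semantics = c("exclusive", "inclusive")) {
  semantics <- match.arg(semantics)
  lines <- .asLines(input)
  if (hasHeader) {
    if (!length(lines)) stop("header expected but input is empty")
    lines <- lines[-1]
  }
  rows <- .twoColumnRows(lines)
  sig <- vapply(rows, `[`, character(1), 1L)
  cntTok <- vapply(rows, `[`, character(1), 2L)
  bad <- !grepl("^[0-9]+$", cntTok)
  if (any(bad))
    stop("line ", which(bad)[1], ": count '", cntTok[bad][1],
         "' is not a non-negative integer")
  counts <- as.integer(cntTok)
  names(counts) <- sig
  # universe order is the sorted union of names, so the parsed table is
  # invariant under row permutation
  universe <- sort(unique(trimws(unlist(strsplit(sig, "&", fixed = TRUE)))),
                   method = "radix")  # C-locale order, independent of LC_COLLATE
  IntersectionCountTable(counts, semantics = semantics, setLabels = universe)
}

#' Serialize a collection back to two-column text
#'
#' Inverse of [readTwoColumn()]: one TAB-separated membership row per
#' (element, set) pair. Rows are grouped by set in collection order, so
#' re-reading reproduces the set order exactly.
#'
#' @param collection a [SetCollection-class].
#' @param hasHeader prepend an "ID\\tSet" header line.
#' @return length-1 character of TSV text.
#' @export
writeTwoColumn <- function(collection, hasHeader = TRUE) {
  stopifnot(is(collection, "SetCollection"))
  memb <- collection@membership
  rows <- unlist(lapply(collection@setLabels, function(s) {
    el <- names(memb)[vapply(memb, function(m) s %in% m, logical(1))]
    if (length(el)) paste(el, s, sep = "\t") else character(0)
  }), use.names = FALSE)
  paste(c(if (hasHeader) "ID\tSet", rows), collapse = "\n")
}

# RFC 4180 field quoting
.csvField <- function(x) {
  need <- grepl('[",\r\n]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

#' Write per-region element lists as CSV
#'
#' One column per non-empty region; the header cell is the region's
#' signature and the rows below it list the member element IDs. Ordering is
#' deterministic: signatures by degree then set order, elements
#' lexicographic. The dialect is RFC 4180 (comma separator, quoting only
#' where needed).
#'
#' @param partition a [RegionPartition-class] with element lists.
#' @param file optional path; when given the text is also written there.
#' @return the CSV text, invisibly when \code{file} is given.
#' @export
writeRegionCSV <- function(partition, file = NULL) {
  stopifnot(is(partition, "RegionPartition"))
  if (partition@countsOnly)
    stop("counts-only partition has no element lists to write")
  sigs <- names(partition@counts)
  sigs <- sigs[signatureOrder(sigs, partition@setLabels)]
  cols <- lapply(sigs, function(s) sort(partition@elements[[s]], method = "radix"))
  depth <- if (length(cols)) max(lengths(cols)) else 0L
  lines <- paste(.csvField(sigs), collapse = ",")
  if (depth > 0) {
    body <- vapply(seq_len(depth), function(i) {
      paste(.csvField(vapply(cols, function(cl) {
        if (i <= length(cl)) cl[i] else ""
      }, character(1))), collapse = ",")
    }, character(1))
    lines <- c(lines, body)
  }
  txt <- paste0(paste(lines, collapse = "\r\n"), "\r\n")
  if (!is.null(file)) {
    writeChar(txt, file, eos = NULL)
    return(invisible(txt))
  }
  txt
}
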