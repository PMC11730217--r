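## Sequence-level analysis: scanning for the conserved acidic-residue/
## tyrosine acceptor consensus ([E/D]Y) and per-column conservation of an
## alignment.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Scan a sequence for acceptor-tyrosine motifs
#'
#' Reports every tyrosine whose immediately preceding residue is glutamate
#' or aspartate (the acceptor consensus).  Overlapping motifs are each
#' reported.  Indices honour \code{firstIndex}, so the engineered tail
#' SGSEYS numbered from 371 yields a single hit at acceptor index 375.
#'
#' @param seq an ungapped amino-acid sequence (character string,
#'   \code{AAString}, or a length-1 \code{AAStringSet}).
#' @param firstIndex 1-based index of the first residue.
#' @return data.frame with columns \code{acceptor_index},
#'   \code{preceding}, \code{site_class} (\code{"E-type"} or
#'   \code{"D-type"}) and \code{context} (the +/- 5-residue window);
#'   zero rows when there is no hit.
#' @export
scanAcceptorMotifs <- function(seq, firstIndex = 1L) {
  if (is(seq, "XStringSet")) {
    stopifnot(length(seq) == 1L)
    seq <- as.character(seq[[1L]])
  }
  seq <- as.character(seq)
  if (grepl("-", seq, fixed = TRUE))
    stop("gapped sequence: remove alignment gaps before motif scanning")
  s <- strsplit(seq, "")[[1L]]
  hits <- which(s == "Y" & c("", head(s, -1L)) %in% c("E", "D"))
  if (length(hits) == 0L)
    return(data.frame(acceptor_index = integer(), preceding = character(),
                      site_class = character(), context = character()))
  ctx <- vapply(hits, function(i)
    paste(s[max(1L, i - 5L):min(length(s), i + 5L)], collapse = ""),
    character(1L))
  pre <- s[hits - 1L]
  data.frame(acceptor_index = hits + as.integer(firstIndex) - 1L,
             preceding = pre,
             site_class = paste0(pre, "-type"),
             context = ctx)
}

#' Per-column conservation of an alignment
#'
#' For each column: residue frequencies over non-gap symbols, the modal
#' (consensus) residue, and a conservation score equal to the modal
#' frequency (1 iff the column is invariant, 0 for all-gap columns).
#' Ties are broken alphabetically and flagged.
#'
#' @param alignment an aligned \code{AAStringSet} or character vector of
#'   equal-length sequences (at least 2); gaps are \code{"-"}.
#' @return A \code{\linkS4class{ConservationProfile}}.
#' @export
columnConservation <- function(alignment) {
  if (is(alignment, "XStringSet")) alignment <- as.character(alignment)
  if (length(alignment) < 2L)
    stop("an alignment of at least 2 sequences is required")
  if (length(unique(nchar(alignment))) != 1L)
    stop("ragged alignment: all records must have equal length")
  m <- do.call(rbind, strsplit(alignment, ""))
  nc <- ncol(m)
  symbols <- sort(unique(c(.AA20, as.vector(m))))
  symbols <- setdiff(symbols, "-")
  freq <- matrix(0, nrow = length(symbols), ncol = nc,
                 dimnames = list(symbols, NULL))
  consensus <- character(nc)
  score <- numeric(nc)
  tie <- logical(nc)
  for (j in seq_len(nc)) {
    col <- m[, j]
    col <- col[col != "-"]
    if (length(col) == 0L) {
      consensus[j] <- "-"
      next
    }
    tab <- table(col)
    freq[names(tab), j] <- as.numeric(tab) / length(col)
    mx <- max(tab)
    winners <- sort(names(tab)[tab == mx])
    consensus[j] <- winners[1L]
    score[j] <- mx / length(col)
    tie[j] <- length(winners) > 1L
  }
  new("ConservationProfile", frequencies = freq, consensus = consensus,
      score = score, tie = tie)
}

#' Classify an acceptor column pair of a conservation profile
#'
#' Given the column of a consensus acceptor tyrosine, types the site from
#' the consensus of the preceding column: E gives \code{"E-type"}, D gives
#' \code{"D-type"}; a tie or any other residue gives \code{"mixed"}.
#'
#' @param profile a \code{\link{columnConservation}} result.
#' @param acceptorColumn 1-based column index whose consensus must be Y.
#' @return \code{"E-type"}, \code{"D-type"} or \code{"mixed"}.
#' @export
classifyHormonogenicColumnPair <- function(profile, acceptorColumn) {
  stopifnot(is(profile, "ConservationProfile"))
  nc <- length(profile@consensus)
  if (acceptorColumn < 2L || acceptorColumn > nc)
    stop("acceptor column must have a predecessor within the alignment")
  if (profile@consensus[acceptorColumn] != "Y")
    stop(sprintf("consensus of column %d is '%s', not the acceptor tyrosine Y",
                 acceptorColumn, profile@consensus[acceptorColumn]))
  pre <- profile@consensus[acceptorColumn - 1L]
  if (profile@tie[acceptorColumn - 1L]) return("mixed")
  switch(pre, E = "E-type", D = "D-type", "mixed")
}
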