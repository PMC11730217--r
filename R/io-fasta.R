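## Sequence and table input.  FASTA goes through Biostrings; the species
## free-energy tables used by the thermodynamic ledger are plain TSV.

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around \code{Biostrings::readAAStringSet} that tolerates an
#' empty file (returning an empty set) and rejects sequence data appearing
#' before the first header.
#'
#' @param path path to a (plain or aligned) FASTA file.
#' @return An \code{\link[Biostrings]{AAStringSet}}; gaps in aligned input
#'   are preserved.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(Biostrings::AAStringSet())
  if (!startsWith(lines[1L], ">"))
    stop(sprintf("parse error in %s: sequence data before the first '>' header",
                 path))
  Biostrings::readAAStringSet(path)
}

#' Write sequences to FASTA
#'
#' @param seqs an \code{AAStringSet} (or named character vector).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path) {
  if (!is(seqs, "XStringSet")) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a species free-energy table
#'
#' Tab-separated table with columns \code{species}, \code{energy}
#' (kcal/mol), \code{charge} and \code{spin} (one of \code{closed-shell},
#' \code{radical}, \code{diradical}).  Lines starting with \code{#} are
#' comments.
#'
#' @param path path to the TSV file.
#' @return A data.frame of species energies.
#' @seealso \code{\link{makeEnergyTable}} for generating synthetic tables.
#' @export
readSpeciesEnergies <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("species", "energy", "charge", "spin")
  if (!all(need %in% names(d)))
    stop(sprintf("species table %s must have columns: %s", path,
                 paste(need, collapse = ", ")))
  if (!all(is.finite(d$energy))) stop("species energies must be finite")
  d
}
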