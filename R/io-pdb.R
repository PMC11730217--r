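## PDB input/output.  Fixed-width ATOM/HETATM records plus MODEL/ENDMDL
## blocks are read and written directly so that multi-model ensembles and
## the non-standard TYD/IYR residues (iodines named I1/I2) survive a round
## trip exactly; coordinates carry the format's native 1e-3 A precision.

.parseAtomLine <- function(line, lineno) {
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  line <- pad(line, 80)
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  resid <- suppressWarnings(as.integer(substr(line, 23, 26)))
  if (any(is.na(xyz)) || is.na(resid))
    stop(sprintf("malformed ATOM/HETATM record at line %d: '%s'",
                 lineno, trimws(line)))
  occ <- suppressWarnings(as.numeric(substr(line, 55, 60)))
  element <- trimws(substr(line, 77, 78))
  name <- trimws(substr(line, 13, 16))
  if (element == "") {
    ## fall back on the name prefix (digit-stripped first letter)
    element <- sub("^[0-9]*", "", name)
    element <- substr(element, 1, 1)
  }
  list(element = element,
       name = name,
       altloc = substr(line, 17, 17),
       resname = trimws(substr(line, 18, 20)),
       chain = substr(line, 22, 22),
       resid = resid,
       x = xyz[1L], y = xyz[2L], z = xyz[3L],
       occ = if (is.na(occ)) 1 else occ)
}

.atomsFromLines <- function(lines, linenos) {
  recs <- mapply(.parseAtomLine, lines, linenos, SIMPLIFY = FALSE)
  a <- do.call(rbind, lapply(recs, function(r)
    data.frame(element = r$element, name = r$name, altloc = r$altloc,
               resname = r$resname, chain = r$chain, resid = r$resid,
               x = r$x, y = r$y, z = r$z, occ = r$occ,
               stringsAsFactors = FALSE)))
  ## alternate locations: keep the highest-occupancy copy of each atom
  if (any(a$altloc != " ")) {
    key <- paste(a$chain, a$resid, a$name)
    keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(i)
      i[which.max(a$occ[i])]), use.names = FALSE)
    a <- a[sort(keep), , drop = FALSE]
  }
  a$altloc <- NULL
  a$occ <- NULL
  rownames(a) <- NULL
  a
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM and HETATM records.  Of a multi-model file only the first
#' model is returned; alternate locations are reduced to the
#' highest-occupancy copy.
#'
#' @param path path to a PDB file.
#' @return A \code{\linkS4class{ProteinStructure}}.
#' @seealso \code{\link{writeStructure}}, \code{\link{readEnsembleFrames}}
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !any(grepl("^(ATOM  |HETATM)", lines)))
    stop(sprintf("empty input: no ATOM/HETATM records in %s", path))
  endm <- grep("^ENDMDL", lines)
  if (length(endm) > 0L) lines <- lines[seq_len(endm[1L] - 1L)]
  sel <- grep("^(ATOM  |HETATM)", lines)
  title <- sub("^TITLE +", "", grep("^TITLE", lines, value = TRUE)[1L])
  if (is.na(title)) title <- basename(path)
  proteinStructure(.atomsFromLines(lines[sel], sel), title = title)
}

.formatAtomName <- function(name, element) {
  ## names of <4 characters for 1-letter elements start in column 14
  if (nchar(name) >= 4L || nchar(element) == 2L)
    formatC(name, width = 4L, flag = "-")
  else
    formatC(paste0(" ", name), width = 4L, flag = "-")
}

.atomLines <- function(atoms, serial0 = 0L) {
  n <- nrow(atoms)
  vapply(seq_len(n), function(i)
    sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial0 + i,
            .formatAtomName(atoms$name[i], atoms$element[i]),
            atoms$resname[i], atoms$chain[i], atoms$resid[i],
            atoms$x[i], atoms$y[i], atoms$z[i], 1, 0,
            formatC(atoms$element[i], width = 2L)),
    character(1L))
}

#' Write a structure to a PDB file
#'
#' @param x a \code{ProteinStructure}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeStructure <- function(x, path) {
  stopifnot(is(x, "ProteinStructure"))
  if (nAtoms(x) == 0L) stop("refusing to write an empty structure")
  lines <- c(if (nzchar(x@title)) sprintf("TITLE     %s", x@title),
             .atomLines(x@atoms), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a conformer ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, frame order preserved; each model is
#' the full structure with the frame's mobile-atom coordinates substituted.
#'
#' @param ens a \code{\linkS4class{ConformerEnsemble}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeEnsemble <- function(ens, path) {
  stopifnot(is(ens, "ConformerEnsemble"))
  if (nFrames(ens) == 0L) stop("refusing to write an empty ensemble")
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(ens@structure@title))
    writeLines(sprintf("TITLE     %s", ens@structure@title), con)
  writeLines(sprintf("REMARK   6 CONDITION %s SEED %d", ens@condition, ens@seed),
             con)
  a <- ens@structure@atoms
  for (i in seq_len(nFrames(ens))) {
    xyz <- frameCoords(ens, i)
    a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
    writeLines(c(sprintf("MODEL %8d", i), .atomLines(a), "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read the frames of a multi-model PDB file
#'
#' @param path path to a (possibly multi-model) PDB file.
#' @return A list with elements \code{structure} (a
#'   \code{ProteinStructure} built from the first model) and \code{coords}
#'   (a list of n x 3 coordinate matrices, one per model).
#' @export
readEnsembleFrames <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  sel <- grep("^(ATOM  |HETATM)", lines)
  if (length(sel) == 0L) stop(sprintf("empty input: no ATOM/HETATM records in %s", path))
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0L) { starts <- 0L; ends <- length(lines) + 1L }
  if (length(starts) != length(ends))
    stop("unbalanced MODEL/ENDMDL blocks")
  frames <- lapply(seq_along(starts), function(k) {
    s <- sel[sel > starts[k] & sel < ends[k]]
    .atomsFromLines(lines[s], s)
  })
  nref <- nrow(frames[[1L]])
  if (!all(vapply(frames, nrow, integer(1L)) == nref))
    stop("models differ in atom count")
  structure0 <- proteinStructure(frames[[1L]], title = basename(path))
  list(structure = structure0,
       coords = lapply(frames, function(f)
         unname(as.matrix(f[, c("x", "y", "z")]))))
}
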