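## Structure / trajectory input and the Cas9 domain map. PDB and DCD
## parsing is delegated to bio3d; this layer enforces the package's
## conventions (first model, first altloc, author residue numbering,
## solvent skipped, nucleic chains retained).

.solventResnames <- c("HOH", "WAT", "TIP3", "SOL", "NA", "CL", "K", "MG")

#' Read a structure from a PDB file
#'
#' Reads ATOM/HETATM records in file order via bio3d. Only the first MODEL
#' is kept; alternate locations are resolved deterministically to the first
#' altloc; solvent and ion records are skipped; nucleic-acid chains are
#' retained. Residue numbering is the 1-based author numbering of the file.
#'
#' @param path PDB file path.
#' @param keepHetero keep non-solvent HETATM records (default FALSE).
#' @return a \code{\link{Structure}}.
#' @export
readStructure <- function(path, keepHetero = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  .checkPDBLines(path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  .structureFromBio3d(pdb, keepHetero = keepHetero)
}

# Cheap format pre-check so a malformed ATOM record is reported with its
# line number rather than as an opaque parser failure.
.checkPDBLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  bad <- which(rec & nchar(lines) < 54)
  if (!length(bad)) {
    coords <- substr(lines[rec], 31, 54)
    ok <- grepl("^[-+ .0-9]+$", coords)
    if (all(ok)) return(invisible(TRUE))
    bad <- which(rec)[!ok]
  }
  stop(sprintf("malformed ATOM record at line %d of %s", bad[1], path))
}

.structureFromBio3d <- function(pdb, keepHetero = FALSE) {
  a <- pdb$atom
  keep <- !(a$resid %in% .solventResnames)
  if (!keepHetero) keep <- keep & a$type == "ATOM"
  # first altloc only: keep records whose alt is blank or the first seen
  # for that (chain, resno, atom name)
  alt <- a$alt
  alt[is.na(alt)] <- ""
  key <- paste(a$chain, a$resno, a$elety)
  firstAlt <- !duplicated(key)
  keep <- keep & (alt == "" | firstAlt)
  a <- a[keep, , drop = FALSE]
  ch <- a$chain
  ch[is.na(ch)] <- "A"
  new("Structure", atoms = data.frame(
    name = a$elety, resid = a$resno, resname = a$resid, chain = ch,
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE))
}

#' Read a trajectory
#'
#' Reads one or more trajectory files against a topology. Multi-model PDB
#' is the mandatory dialect; DCD is supported as the binary dialect via
#' bio3d's reader. Frames are kept in the order given.
#'
#' @param paths character vector of trajectory files (.pdb or .dcd).
#' @param topology a \code{\link{Structure}} with matching atom count.
#' @param frameStride ns per frame (default 1, one frame per ns).
#' @return a \code{\link{TrajectoryEnsemble}}.
#' @export
readTrajectory <- function(paths, topology, frameStride = 1) {
  nat <- nrow(atoms(topology))
  frames <- list()
  for (p in paths) {
    if (grepl("\\.dcd$", p, ignore.case = TRUE)) {
      xyz <- bio3d::read.dcd(p, verbose = FALSE)
    } else {
      pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
      xyz <- pdb$xyz
      # read.pdb applies no solvent filter; align with the topology
      # convention by selecting the atoms retained by readStructure
      s <- .structureFromBio3d(pdb)
      if (nrow(atoms(s)) != ncol(xyz) / 3) {
        keep <- !(pdb$atom$resid %in% .solventResnames) & pdb$atom$type == "ATOM"
        idx <- which(keep)
        xyz <- xyz[, as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx)),
                   drop = FALSE]
      }
    }
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    for (f in seq_len(nrow(xyz))) {
      m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      if (nrow(m) != nat)
        stop(sprintf("frame %d of %s has %d atoms; topology has %d",
                     f, p, nrow(m), nat))
      frames[[length(frames) + 1]] <- m
    }
  }
  new("TrajectoryEnsemble", topology = topology, frames = frames,
      frameStride = frameStride)
}

#' Write a structure or trajectory as (multi-model) PDB
#'
#' Fixture-grade PDB writer: one MODEL/ENDMDL block per frame, coordinates
#' at the format's 0.001 A precision, so generated trajectories can be
#' consumed through the standard reader path.
#'
#' @param x a \code{Structure} or \code{TrajectoryEnsemble}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePDB <- function(x, path) {
  if (is(x, "Structure")) {
    topo <- x
    frameList <- list(as.matrix(atoms(x)[, c("x", "y", "z")]))
    multi <- FALSE
  } else {
    topo <- topology(x)
    frameList <- frames(x)
    multi <- length(frameList) > 1
  }
  a <- atoms(topo)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frameList)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    m <- frameList[[f]]
    # PDB fixed columns: name left-padded per convention for <4-char names
    nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
    lines <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                     seq_len(nrow(a)) %% 100000, nm, a$resname,
                     substr(a$chain, 1, 1), a$resid %% 10000,
                     m[, 1], m[, 2], m[, 3])
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Construct a domain map
#'
#' @param ... named arguments, each a character vector of inclusive
#'   "start-end" residue ranges, e.g. \code{HNH = "779-906"}.
#' @return a \code{\link{DomainMap}}.
#' @export
domainMap <- function(...) {
  entries <- list(...)
  if (length(entries) == 1 && is.list(entries[[1]]) && is.null(names(entries)[1]))
    entries <- entries[[1]]
  rows <- list()
  for (lab in names(entries)) {
    for (rg in entries[[lab]]) {
      parts <- as.integer(strsplit(rg, "-", fixed = TRUE)[[1]])
      if (length(parts) != 2 || anyNA(parts))
        stop("malformed range '", rg, "' for label ", lab)
      rows[[length(rows) + 1]] <- data.frame(label = lab, start = parts[1],
                                             end = parts[2])
    }
  }
  new("DomainMap", ranges = do.call(rbind, rows))
}

#' The five-domain Cas9 map used throughout
#'
#' SpCas9 domain boundaries (author numbering): HNH 779-906; RuvC 1-59,
#' 718-764 and 917-1098; L1 linker 765-778; L2 linker 907-916; bridge
#' helix 60-93.
#'
#' @return a \code{\link{DomainMap}}.
#' @export
cas9DomainMap <- function() {
  domainMap(RuvC = c("1-59", "718-764", "917-1098"),
            Bridge = "60-93",
            L1 = "765-778",
            HNH = "779-906",
            L2 = "907-916")
}

#' Classify a residue into a domain
#'
#' @param map a \code{\link{DomainMap}}.
#' @param resid 1-based residue index (vectorized).
#' @return character label per residue, \code{"unassigned"} when the
#'   residue falls in no range.
#' @export
classifyResidue <- function(map, resid) {
  r <- map@ranges
  vapply(resid, function(i) {
    hit <- which(r$start <= i & i <= r$end)
    if (length(hit)) r$label[hit[1]] else "unassigned"
  }, character(1))
}

#' Domain composition of a residue list
#'
#' Percentage of the input residues falling in each domain, rounded half-up
#' to one decimal. Invariant under permutation of the input.
#'
#' @param resids non-empty vector of 1-based residue indices.
#' @param map a \code{\link{DomainMap}} (default \code{cas9DomainMap()}).
#' @param dropUnassigned drop the "unassigned" share from the table
#'   (default FALSE).
#' @return named numeric vector of percentages.
#' @examples
#' ticaResids <- c(718, 719, 765, 768, 773, 774, 777, 779, 825, 826, 842,
#'                 864, 892, 899, 901, 907, 913, 917, 974, 976, 983, 1001)
#' domainComposition(ticaResids)  # RuvC 31.8, HNH 36.4, L1 22.7, L2 9.1
#' @export
domainComposition <- function(resids, map = cas9DomainMap(),
                              dropUnassigned = FALSE) {
  if (length(resids) == 0) stop("resids must be non-empty")
  lab <- classifyResidue(map, resids)
  tab <- table(lab)
  pct <- roundHalfUp(100 * as.numeric(tab) / length(resids), 1)
  names(pct) <- names(tab)
  if (dropUnassigned) pct <- pct[names(pct) != "unassigned"]
  pct[order(-pct)]
}

#' Select atoms from a structure
#'
#' @param structure a \code{\link{Structure}}.
#' @param selection one of \code{"calpha"}, \code{"backbone"} (N, CA, C, O),
#'   a residue range given as \code{c(start, end)}, or a character vector of
#'   atom names.
#' @param residRange optional residue range filter combined with the
#'   selection.
#' @return ascending integer atom indices; empty selections warn.
#' @export
selectAtoms <- function(structure, selection = "calpha", residRange = NULL) {
  a <- atoms(structure)
  if (is.character(selection) && length(selection) == 1 &&
      selection %in% c("calpha", "backbone")) {
    wanted <- if (selection == "calpha") "CA" else c("N", "CA", "C", "O")
    idx <- which(a$name %in% wanted)
  } else if (is.numeric(selection) && length(selection) == 2) {
    idx <- which(a$resid >= selection[1] & a$resid <= selection[2])
  } else {
    idx <- which(a$name %in% selection)
  }
  if (!is.null(residRange))
    idx <- idx[a$resid[idx] >= residRange[1] & a$resid[idx] <= residRange[2]]
  if (!length(idx)) warning("atom selection is empty")
  sort(idx)
}
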