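## structure_prep: 3D embedding, minimization, charging, per-atom properties.
#' @importClassesFrom ChemmineR SDF SDFset
NULL

##
## Geometry generation, MMFF94 minimization and Gasteiger charging are
## delegated to Open Babel (obabel); the resulting structures are parsed into
## Conformer objects carrying coordinates, charges, vdW radii and the five
## similarity-index property weights.

.obabelPath <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("Open Babel (obabel) not found on PATH")
  p
}

.runObabel <- function(args) {
  out <- suppressWarnings(system2(.obabelPath(), args,
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("obabel failed (", paste(args, collapse = " "), "): ",
         paste(utils::tail(out, 3), collapse = " / "))
  invisible(out)
}

# distance of every bonded atom pair (Angstrom)
bondLengths <- function(conf) {
  b <- conf@bonds
  if (nrow(b) == 0L) return(numeric(0))
  xyz <- as.matrix(conf@atoms[, c("x", "y", "z")])
  sqrt(rowSums((xyz[b[, "from"], , drop = FALSE] -
                xyz[b[, "to"], , drop = FALSE])^2))
}

# Parse a (possibly multi-molecule) mol2 file into raw atom/bond tables.
# mol2 is emitted by obabel and carries, per atom, the SYBYL atom type
# (element + hybridization/aromaticity) and the computed partial charge.
.parseMol2 <- function(lines) {
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    blk <- lines[starts[i]:ends[i]]
    name <- trimws(blk[2])
    sec <- function(tag) {
      s <- grep(paste0("^@<TRIPOS>", tag), blk)
      if (!length(s)) return(character(0))
      e <- grep("^@<TRIPOS>", blk)
      e <- e[e > s[1]]
      blk[(s[1] + 1L):(if (length(e)) e[1] - 1L else length(blk))]
    }
    at <- strsplit(trimws(sec("ATOM")), "\\s+")
    at <- at[lengths(at) >= 9]
    bd <- strsplit(trimws(sec("BOND")), "\\s+")
    bd <- bd[lengths(bd) >= 4]
    type <- vapply(at, `[[`, "", 6L)
    list(name = name,
      atoms = data.frame(
        element = sub("\\..*$", "", type),
        type = type,
        x = as.numeric(vapply(at, `[[`, "", 3L)),
        y = as.numeric(vapply(at, `[[`, "", 4L)),
        z = as.numeric(vapply(at, `[[`, "", 5L)),
        charge = as.numeric(vapply(at, `[[`, "", 9L)),
        stringsAsFactors = FALSE),
      bonds = cbind(
        from = as.integer(vapply(bd, `[[`, "", 2L)),
        to = as.integer(vapply(bd, `[[`, "", 3L)),
        # mol2 bond type: 1/2/3, "ar" (aromatic -> 4), "am" (amide -> 1)
        order = vapply(bd, function(f)
          switch(f[[4L]], ar = 4L, am = 1L, un = 1L,
                 as.integer(f[[4L]])), 1L)))
  })
}

#' Van der Waals parameter table
#'
#' Element-typed Lennard-Jones parameters (radius in Angstrom, well depth in
#' kcal/mol) used for the steric field and the steric similarity weights.
#'
#' @return data.frame with columns \code{element}, \code{radius},
#'   \code{epsilon}.
#' @export
vdwParams <- function() {
  utils::read.csv(.extdata("vdw_params.csv"), comment.char = "#",
                  stringsAsFactors = FALSE)
}

.vdwLookup <- function(elements) {
  tab <- vdwParams()
  i <- match(elements, tab$element)
  if (anyNA(i))
    stop("no van der Waals parameters for element(s): ",
         paste(unique(elements[is.na(i)]), collapse = ", "))
  tab[i, c("radius", "epsilon")]
}

# Coarse atomic log P increments (octanol/water), a simplified
# Ghose-Crippen-style typing by element, aromaticity and bonding context.
.hydrophobicIncrement <- function(atoms, bonds) {
  el <- atoms$element
  w <- numeric(length(el))
  aromatic <- grepl("\\.ar$", atoms$type)
  w[el == "C"] <- 0.05
  w[el == "C" & grepl("\\.3$", atoms$type)] <- 0.14
  w[el == "C" & aromatic] <- 0.29
  w[el == "N"] <- -0.60
  w[el == "O"] <- -0.38
  w[el == "O" & grepl("\\.2$", atoms$type)] <- -0.12  # carbonyl oxygen
  w[el == "S"] <- 0.65
  w[el == "Br"] <- 0.86
  # hydrogens: mildly lipophilic on carbon, polar on heteroatoms
  hvyOf <- .attachedHeavy(el, bonds)
  isH <- el == "H"
  w[isH] <- ifelse(el[hvyOf[isH]] %in% c("N", "O"), -0.30, 0.12)
  w
}

# for each atom, index of a bonded neighbour that is a heavy atom (for H);
# arbitrary (self) for heavy atoms
.attachedHeavy <- function(el, bonds) {
  out <- seq_along(el)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, "from"]; j <- bonds[k, "to"]
    if (el[i] == "H" && el[j] != "H") out[i] <- j
    if (el[j] == "H" && el[i] != "H") out[j] <- i
  }
  out
}

#' Populate per-atom property weights of a conformer
#'
#' Fills vdW radii and the five similarity-field weights: steric = r_vdw^3,
#' electrostatic = partial charge, hydrophobic = atomic log P increment,
#' donor / acceptor = 0/1 typing flags (N-H and O-H hydrogens donate through
#' their heavy atom; N and O accept).
#'
#' @param conf a \code{\link{Conformer}}.
#' @return the conformer with weight columns populated.
#' @export
assignPropertyWeights <- function(conf) {
  a <- conf@atoms
  vdw <- .vdwLookup(a$element)
  a$radius <- vdw$radius
  a$steric <- a$radius^3
  a$electro <- a$charge
  a$hydrophobic <- .hydrophobicIncrement(a, conf@bonds)
  hasH <- rep(FALSE, nrow(a))
  b <- conf@bonds
  for (k in seq_len(nrow(b))) {
    i <- b[k, "from"]; j <- b[k, "to"]
    if (a$element[i] == "H") hasH[j] <- TRUE
    if (a$element[j] == "H") hasH[i] <- TRUE
  }
  a$donor <- as.numeric(a$element %in% c("N", "O") & hasH)
  a$acceptor <- as.numeric(a$element %in% c("N", "O"))
  conf@atoms <- a
  validObject(conf)
  conf
}

.newConformer <- function(id, atoms, bonds, smiles = NA_character_,
                          netCharge = 0) {
  for (col in c("radius", "steric", "electro", "hydrophobic",
                "donor", "acceptor"))
    if (is.null(atoms[[col]])) atoms[[col]] <- rep(NA_real_, nrow(atoms))
  if (is.null(atoms$charge)) atoms$charge <- rep(NA_real_, nrow(atoms))
  new("Conformer", compoundId = as.character(id), atoms = atoms,
      bonds = bonds, smiles = smiles, netCharge = netCharge)
}

#' Construct a conformer from raw atom data
#'
#' Convenience constructor, mainly for toy systems and tests; real structures
#' come from \code{\link{embedConformers}} or \code{\link{readConformerSDF}}.
#'
#' @param elements character vector of element symbols.
#' @param xyz numeric n x 3 coordinate matrix (Angstrom).
#' @param charge per-atom partial charges (e), or \code{NA}.
#' @param bonds matrix with columns \code{from}, \code{to}, \code{order};
#'   default none.
#' @param id compound identifier.
#' @param netCharge net molecular charge (e); defaults to the rounded charge
#'   sum.
#' @param weights if \code{TRUE} (default), populate radii and property
#'   weights via \code{\link{assignPropertyWeights}}.
#' @return a \code{\link{Conformer}}.
#' @export
conformer <- function(elements, xyz, charge = NA_real_, bonds = NULL,
                      id = "toy", netCharge = NULL, weights = TRUE) {
  xyz <- matrix(xyz, ncol = 3)
  atoms <- data.frame(element = elements, type = elements,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charge, length(elements)), stringsAsFactors = FALSE)
  if (is.null(bonds))
    bonds <- matrix(integer(), 0, 3,
                    dimnames = list(NULL, c("from", "to", "order")))
  if (is.null(netCharge))
    netCharge <- if (all(is.na(atoms$charge))) 0 else round(sum(atoms$charge))
  cf <- .newConformer(id, atoms, bonds, netCharge = netCharge)
  if (weights && nrow(atoms) > 0) cf <- assignPropertyWeights(cf)
  cf
}

#' Embed, minimize and charge a set of structures
#'
#' Builds a single 3D conformer per input SMILES: rule-based 3D generation
#' followed by MMFF94 minimization (energy convergence \code{crit}, at most
#' \code{steps} iterations) and Gasteiger partial charges, all through Open
#' Babel. The whole procedure is deterministic, so repeated calls with the
#' same inputs (any \code{seed}) give identical coordinates; \code{seed} is
#' recorded for provenance.
#'
#' @param smiles named character vector of SMILES (names = compound ids).
#' @param seed integer, recorded in the result attributes.
#' @param steps maximum minimization iterations.
#' @param crit energy convergence criterion (kcal/mol).
#' @return list of \code{\link{Conformer}} objects, one per input, with
#'   property weights populated; attribute \code{seed}.
#' @export
embedConformers <- function(smiles, seed = 1L, steps = 2000L, crit = 1e-6) {
  if (is.null(names(smiles))) names(smiles) <- as.character(seq_along(smiles))
  td <- tempfile("embed"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  smi <- file.path(td, "in.smi"); raw <- file.path(td, "raw.sdf")
  minf <- file.path(td, "min.sdf"); m2 <- file.path(td, "out.mol2")
  writeLines(paste(smiles, names(smiles)), smi)
  .runObabel(c(smi, "-O", raw, "--gen3d"))
  .runObabel(c(raw, "-O", minf, "--minimize", "--ff", "MMFF94",
               "--steps", format(steps), "--crit", format(crit)))
  .runObabel(c(minf, "-O", m2, "--partialcharge", "gasteiger"))
  mols <- .parseMol2(readLines(m2))
  if (length(mols) != length(smiles)) {
    got <- vapply(mols, `[[`, "", "name")
    stop("embedding failed for compound id(s): ",
         paste(setdiff(names(smiles), got), collapse = ", "))
  }
  confs <- lapply(seq_along(mols), function(i) {
    m <- mols[[i]]
    if (nrow(m$atoms) == 0L)
      stop("embedding produced no atoms for compound id ", names(smiles)[i])
    cf <- assignPropertyWeights(
      .newConformer(names(smiles)[i], m$atoms, m$bonds, smiles[[i]]))
    d <- bondLengths(cf)
    if (length(d) && any(d < 0.6 | d > 2.6))
      stop("minimization left implausible bonded distances for compound id ",
           names(smiles)[i])
    cf
  })
  names(confs) <- names(smiles)
  attr(confs, "seed") <- as.integer(seed)
  confs
}

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Conformer", function(x) nrow(x@atoms))

#' @rdname atomCoords
#' @export
setMethod("atomCoords", "Conformer", function(x)
  as.matrix(x@atoms[, c("x", "y", "z")]))

#' @rdname atomCoords-set
#' @export
setMethod("atomCoords<-", "Conformer", function(x, value) {
  x@atoms[, c("x", "y", "z")] <- value
  validObject(x)
  x
})

#' @rdname atomCharges
#' @export
setMethod("atomCharges", "Conformer", function(x) x@atoms$charge)

setMethod("show", "Conformer", function(object) {
  cat("Conformer", object@compoundId, "-", nAtoms(object), "atoms,",
      nrow(object@bonds), "bonds\n")
  if (!is.na(object@smiles)) cat("  SMILES:", object@smiles, "\n")
})

#' Write conformers to an SDF V2000 file
#'
#' Partial charges are carried in a \code{PARTIAL_CHARGES} data field
#' (semicolon-separated, atom order).
#'
#' @param confs list of \code{\link{Conformer}} objects.
#' @param path output file.
#' @export
writeConformerSDF <- function(confs, path) {
  sdfs <- lapply(confs, function(cf) {
    a <- cf@atoms
    xyz <- as.matrix(a[, c("x", "y", "z")])
    ab <- cbind(xyz, matrix(0, nrow(a), 13))
    rownames(ab) <- paste(a$element, seq_len(nrow(a)), sep = "_")
    colnames(ab) <- c("C1", "C2", "C3", paste0("C", 4:16))
    bb <- cbind(cf@bonds[, c("from", "to", "order"), drop = FALSE],
                matrix(0, nrow(cf@bonds), 4))
    rownames(bb) <- as.character(seq_len(nrow(bb)))
    colnames(bb) <- paste0("C", 1:7)
    new("SDF",
      header = c(Molecule_Name = cf@compoundId, Source = "fieldQSAR",
                 Comment = "",
                 Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                       nrow(a), nrow(bb))),
      atomblock = ab, bondblock = bb,
      datablock = c(PARTIAL_CHARGES = paste(sprintf("%.6f", a$charge),
                                            collapse = ";"),
                    SMILES = ifelse(is.na(cf@smiles), "", cf@smiles)))
  })
  sdfset <- methods::as(sdfs, "SDFset")
  ChemmineR::cid(sdfset) <- vapply(confs, methods::slot, "", "compoundId")
  ChemmineR::write.SDF(sdfset, file = path)
  invisible(path)
}

#' Read conformers from an SDF V2000 file
#'
#' Inverse of \code{\link{writeConformerSDF}}: charges are restored from the
#' \code{PARTIAL_CHARGES} data field when present. Property weights are left
#' unpopulated (V2000 does not carry the hybridization typing they need);
#' run \code{\link{assignPropertyWeights}} to refill all but the
#' aromaticity-dependent hydrophobic increments.
#'
#' @param path SDF file.
#' @return list of \code{\link{Conformer}} objects.
#' @export
readConformerSDF <- function(path) {
  sdfset <- ChemmineR::read.SDFset(path)
  ChemmineR::cid(sdfset) <- ChemmineR::sdfid(sdfset)
  out <- lapply(seq_along(ChemmineR::cid(sdfset)), function(i) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    el <- sub("_.*$", "", rownames(ab))
    atoms <- data.frame(element = el,
      type = el,   # hybridization typing not preserved in V2000
      x = ab[, 1], y = ab[, 2], z = ab[, 3],
      charge = NA_real_, stringsAsFactors = FALSE)
    db <- ChemmineR::datablock(sdf)
    if ("PARTIAL_CHARGES" %in% names(db))
      atoms$charge <- as.numeric(strsplit(db[["PARTIAL_CHARGES"]], ";")[[1]])
    smi <- if ("SMILES" %in% names(db) && nzchar(db[["SMILES"]]))
      db[["SMILES"]] else NA_character_
    bonds <- cbind(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
    .newConformer(ChemmineR::cid(sdfset)[i], atoms, bonds, smi)
  })
  names(out) <- ChemmineR::cid(sdfset)
  out
}
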