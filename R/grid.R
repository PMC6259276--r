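## grid_fields: lattice construction and CoMFA / CoMSIA field evaluation.
##
## CoMFA probes the aligned molecules with an sp3 carbon of charge +1e on a
## regular 1 Angstrom lattice extending 4 Angstrom beyond the union bounding
## box: steric = Lennard-Jones 6-12 energy (truncated at +30 kcal/mol),
## electrostatic = Coulomb energy with distance-dependent dielectric D(r) = r
## (clamped to +/-30 kcal/mol; values at sterically truncated points are
## replaced by the column mean over compounds). CoMSIA evaluates Gaussian
## similarity indices A(q) = -sum_i w_probe w_i exp(-alpha r_iq^2) with
## attenuation factor alpha = 0.3 for five property channels; the kernel has
## no singularity, so no truncation is applied.

#' Probe atom specification
#'
#' The CoMFA probe is an sp3 carbon carrying +1e; the CoMSIA probe has radius
#' 1 Angstrom, charge +1 and unit hydrophobic, donor and acceptor weights.
#'
#' @param charge probe charge (e).
#' @param radius CoMSIA probe radius (Angstrom).
#' @param element probe element for the Lennard-Jones parameters.
#' @return list with the probe parameters, including the LJ \code{radius} and
#'   \code{epsilon} of the probe element and unit CoMSIA weights.
#' @export
probeSpec <- function(charge = 1.0, radius = 1.0, element = "C") {
  vdw <- .vdwLookup(element)
  list(element = element, charge = charge, comsiaRadius = radius,
       ljRadius = vdw$radius, ljEpsilon = vdw$epsilon,
       steric = radius^3, electro = charge,
       hydrophobic = 1.0, donor = 1.0, acceptor = 1.0)
}

#' The seven standard field channels
#' @return character vector of channel labels.
#' @export
fieldChannels <- function() {
  c("comfa_steric", "comfa_elec",
    "comsia_steric", "comsia_elec", "comsia_hydrophobic",
    "comsia_donor", "comsia_acceptor")
}

#' Build the field lattice around an aligned conformer set
#'
#' Smallest world-axis-aligned regular lattice such that every atom of every
#' conformer lies at least \code{margin} inside the box faces. The box is the
#' union bounding box extended by \code{margin} on every side, with the upper
#' faces rounded up to a whole number of spacings; the result is independent
#' of conformer order.
#'
#' @param confs list of aligned \code{\link{Conformer}} objects.
#' @param spacing lattice spacing (Angstrom), default 1.
#' @param margin box extension beyond the bounding box (Angstrom), default 4.
#' @return a \code{\link{GridSpec}}.
#' @export
makeGrid <- function(confs, spacing = 1.0, margin = 4.0) {
  if (length(confs) == 0L) stop("empty conformer set")
  if (spacing <= 0) stop("spacing must be positive")
  xyz <- do.call(rbind, lapply(confs, atomCoords))
  lo <- unname(apply(xyz, 2, min)) - margin
  hi <- unname(apply(xyz, 2, max)) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing - 1e-9)) + 1L
  new("GridSpec", origin = lo, spacing = spacing, dims = dims,
      margin = margin)
}

#' @rdname gridPoints
#' @export
setMethod("gridPoints", "GridSpec", function(x) {
  ax <- lapply(1:3, function(k)
    x@origin[k] + x@spacing * (seq_len(x@dims[k]) - 1L))
  # x-fastest enumeration
  cbind(
    rep(ax[[1]], times = x@dims[2] * x@dims[3]),
    rep(rep(ax[[2]], each = x@dims[1]), times = x@dims[3]),
    rep(ax[[3]], each = x@dims[1] * x@dims[2]))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d x %d points, spacing %.2f A, origin (%.2f, %.2f, %.2f)\n",
    object@dims[1], object@dims[2], object@dims[3], object@spacing,
    object@origin[1], object@origin[2], object@origin[3]))
})

# squared distances grid-points x atoms
.dist2 <- function(pts, xyz) {
  outer(rowSums(pts^2), rep(1, nrow(xyz))) +
    outer(rep(1, nrow(pts)), rowSums(xyz^2)) - 2 * tcrossprod(pts, xyz)
}

#' CoMFA steric field of one conformer
#'
#' Lennard-Jones 6-12 probe-atom energy summed over all atoms,
#' E = sum_i eps_i [ (R*_i / r_i)^12 - 2 (R*_i / r_i)^6 ] with
#' R*_i = R_probe + R_atom and eps_i = sqrt(eps_probe eps_atom), truncated at
#' +\code{cutoff} kcal/mol.
#'
#' @param conf a \code{\link{Conformer}} with radii populated.
#' @param grid a \code{\link{GridSpec}}.
#' @param probe a \code{\link{probeSpec}}.
#' @param cutoff truncation energy (kcal/mol), default 30.
#' @return list with \code{energy} (per grid point, kcal/mol) and
#'   \code{clamped} (logical, points where the truncation engaged).
#' @export
comfaSteric <- function(conf, grid, probe = probeSpec(), cutoff = 30) {
  if (any(is.na(conf@atoms$radius)))
    stop("conformer lacks vdW radii; run assignPropertyWeights()")
  vdw <- .vdwLookup(conf@atoms$element)
  rstar <- probe$ljRadius + vdw$radius
  eps <- sqrt(probe$ljEpsilon * vdw$epsilon)
  d2 <- .dist2(gridPoints(grid), atomCoords(conf))
  d2 <- pmax(d2, 1e-12)
  s6 <- sweep(1 / d2, 2, rstar^2, "*")^3        # (R*/r)^6
  e <- as.numeric((sweep(s6^2, 2, eps, "*") - 2 * sweep(s6, 2, eps, "*")) %*%
                  rep(1, length(eps)))
  clamped <- e > cutoff
  e[clamped] <- cutoff
  list(energy = e, clamped = clamped)
}

#' CoMFA electrostatic field of one conformer
#'
#' Coulomb probe-atom energy with distance-dependent dielectric D(r) = r:
#' E = sum_i 332.0636 q_i q_probe / r_i^2 (kcal/mol with charges in e and
#' distances in Angstrom), clamped to +/-\code{cutoff}. A constant dielectric
#' (D = \code{dielectric}, energy ~ 1/r) may be selected instead.
#'
#' @param conf a \code{\link{Conformer}} with charges assigned.
#' @param grid a \code{\link{GridSpec}}.
#' @param probe a \code{\link{probeSpec}}.
#' @param cutoff clamp magnitude (kcal/mol), default 30.
#' @param dielectric \code{"distance"} (default) or a positive constant.
#' @return numeric vector of per-point energies (kcal/mol).
#' @export
comfaElectrostatic <- function(conf, grid, probe = probeSpec(), cutoff = 30,
                               dielectric = "distance") {
  q <- atomCharges(conf)
  if (anyNA(q)) stop("conformer lacks partial charges")
  d2 <- .dist2(gridPoints(grid), atomCoords(conf))
  d2 <- pmax(d2, 1e-12)
  denom <- if (identical(dielectric, "distance")) d2
           else sqrt(d2) * as.numeric(dielectric)
  e <- as.numeric((332.0636 * probe$charge / denom) %*% q)
  pmin(pmax(e, -cutoff), cutoff)
}

#' CoMSIA similarity-index field of one conformer
#'
#' Gaussian-kernel similarity index
#' A(q) = -sum_i w_probe w_i exp(-alpha r_iq^2), finite everywhere.
#'
#' @param conf a \code{\link{Conformer}} with property weights populated.
#' @param grid a \code{\link{GridSpec}}.
#' @param probe a \code{\link{probeSpec}}.
#' @param property one of \code{"steric"}, \code{"electro"},
#'   \code{"hydrophobic"}, \code{"donor"}, \code{"acceptor"}.
#' @param alpha attenuation factor (1/Angstrom^2), default 0.3.
#' @return numeric vector of per-point indices (dimensionless).
#' @export
comsiaField <- function(conf, grid, probe = probeSpec(), property, alpha = 0.3) {
  ok <- c("steric", "electro", "hydrophobic", "donor", "acceptor")
  if (!property %in% ok)
    stop("unknown CoMSIA channel '", property, "'; use one of: ",
         paste(ok, collapse = ", "))
  w <- conf@atoms[[property]]
  if (anyNA(w))
    stop("property weights for '", property,
         "' not populated; run assignPropertyWeights()")
  if (nAtoms(conf) == 0L) return(numeric(prod(grid@dims)))
  d2 <- .dist2(gridPoints(grid), atomCoords(conf))
  as.numeric(-(probe[[property]] * exp(-alpha * d2)) %*% w)
}

#' Evaluate all field channels for an aligned conformer set
#'
#' Assembles the compounds x (points * channels) descriptor block: the two
#' CoMFA channels followed by the five CoMSIA channels (or any subset), each
#' block enumerating grid points x-fastest. Electrostatic CoMFA values at
#' sterically truncated points are replaced by the column mean over the
#' remaining compounds (set \code{elecAtClamped = "keep"} to disable).
#'
#' @param confs list of aligned \code{\link{Conformer}} objects.
#' @param grid a \code{\link{GridSpec}}; default builds one with 1 A spacing
#'   and 4 A margin.
#' @param probe a \code{\link{probeSpec}}.
#' @param channels channel labels, see \code{\link{fieldChannels}}.
#' @param cutoff CoMFA truncation (kcal/mol).
#' @param alpha CoMSIA attenuation factor.
#' @param elecAtClamped \code{"column_mean"} (default) or \code{"keep"}.
#' @return a \code{\link{FieldMatrix}}.
#' @export
assembleFieldMatrix <- function(confs, grid = makeGrid(confs),
    probe = probeSpec(), channels = fieldChannels(), cutoff = 30,
    alpha = 0.3, elecAtClamped = c("column_mean", "keep")) {
  elecAtClamped <- match.arg(elecAtClamped)
  bad <- setdiff(channels, fieldChannels())
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  n <- length(confs)
  np <- prod(grid@dims)
  needClamp <- any(c("comfa_steric", "comfa_elec") %in% channels)
  steric <- clamp <- NULL
  if (needClamp) {
    st <- lapply(confs, comfaSteric, grid = grid, probe = probe,
                 cutoff = cutoff)
    steric <- do.call(rbind, lapply(st, `[[`, "energy"))
    clamp <- do.call(rbind, lapply(st, `[[`, "clamped"))
  }
  blocks <- lapply(channels, function(ch) {
    if (ch == "comfa_steric") return(steric)
    if (ch == "comfa_elec") {
      e <- do.call(rbind, lapply(confs, comfaElectrostatic, grid = grid,
                                 probe = probe, cutoff = cutoff))
      if (elecAtClamped == "column_mean" && any(clamp)) {
        e[clamp] <- NA_real_
        cm <- colMeans(e, na.rm = TRUE)
        cm[is.nan(cm)] <- 0
        idx <- which(is.na(e), arr.ind = TRUE)
        e[idx] <- cm[idx[, 2]]
      }
      return(e)
    }
    prop <- sub("^comsia_", "", ch)
    prop <- c(steric = "steric", elec = "electro", hydrophobic = "hydrophobic",
              donor = "donor", acceptor = "acceptor")[[prop]]
    do.call(rbind, lapply(confs, comsiaField, grid = grid, probe = probe,
                          property = prop, alpha = alpha))
  })
  vals <- do.call(cbind, blocks)
  ids <- names(confs)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  new("FieldMatrix", values = vals, channels = channels, grid = grid,
      compoundIds = ids)
}

#' @rdname channelOfColumn
#' @export
setMethod("channelOfColumn", "FieldMatrix", function(x)
  rep(x@channels, each = prod(x@grid@dims)))

#' @rdname channels
#' @export
setMethod("channels", "FieldMatrix", function(x) x@channels)

#' @rdname fieldValues
#' @export
setMethod("fieldValues", "FieldMatrix", function(x) x@values)

#' @rdname fieldSubset
#' @export
setMethod("fieldSubset", "FieldMatrix", function(x, keep) {
  bad <- setdiff(keep, x@channels)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  keepCols <- channelOfColumn(x) %in% keep
  new("FieldMatrix", values = x@values[, keepCols, drop = FALSE],
      channels = x@channels[x@channels %in% keep], grid = x@grid,
      compoundIds = x@compoundIds)
})

setMethod("show", "FieldMatrix", function(object) {
  cat(sprintf("FieldMatrix: %d compounds x %d grid points x %d channels\n",
    nrow(object@values), prod(object@grid@dims), length(object@channels)))
  cat("  channels:", paste(object@channels, collapse = ", "), "\n")
})

#' Persist a field matrix as CSV values + JSON metadata
#' @param fm a \code{\link{FieldMatrix}}.
#' @param basename output path without extension; writes
#'   \code{<basename>.csv} and \code{<basename>.json}.
#' @export
writeFieldMatrix <- function(fm, basename) {
  utils::write.csv(data.frame(id = fm@compoundIds, fm@values,
                              check.names = FALSE),
                   paste0(basename, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(channels = fm@channels,
    grid = list(origin = fm@grid@origin, spacing = fm@grid@spacing,
                dims = fm@grid@dims, margin = fm@grid@margin)),
    paste0(basename, ".json"), digits = NA)
  invisible(basename)
}
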