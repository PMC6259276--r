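#' @import methods
#' @importFrom stats sd cor var coef predict
NULL

#' Conformer: a 3D molecular structure with per-atom properties
#'
#' Holds one conformer of one compound: elements, Cartesian coordinates
#' (Angstrom), partial charges (e), van der Waals radii (Angstrom), the five
#' similarity-index property weights (steric, electrostatic, hydrophobic,
#' H-bond donor, H-bond acceptor), and the bond list.
#'
#' @slot compoundId character(1), identifier of the compound.
#' @slot atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{charge}, \code{radius}, \code{steric}, \code{electro},
#'   \code{hydrophobic}, \code{donor}, \code{acceptor}.
#' @slot bonds integer matrix with columns \code{from}, \code{to},
#'   \code{order} (1-based atom indices; order 4 encodes aromatic).
#' @slot smiles character(1), the line notation the conformer was built from
#'   (may be \code{NA}).
#' @slot netCharge numeric(1), net molecular charge (e); partial charges must
#'   sum to it.
#' @export
setClass("Conformer",
  representation(compoundId = "character", atoms = "data.frame",
                 bonds = "matrix", smiles = "character",
                 netCharge = "numeric"),
  prototype(compoundId = NA_character_, smiles = NA_character_,
            netCharge = 0))

setValidity("Conformer", function(object) {
  a <- object@atoms
  need <- c("element", "x", "y", "z", "charge", "radius",
            "steric", "electro", "hydrophobic", "donor", "acceptor")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@bonds) > 0) {
    if (!all(c("from", "to", "order") %in% colnames(object@bonds)))
      return("bonds must have columns from, to, order")
    if (max(object@bonds[, c("from", "to")]) > nrow(a))
      return("bond indices exceed atom count")
  }
  if (!all(is.na(a$charge)) && abs(sum(a$charge) - object@netCharge) > 1e-3)
    return("partial charges do not sum to the net molecular charge (1e-3 e)")
  TRUE
})

#' GridSpec: a rectangular field lattice
#'
#' World-axis-aligned regular lattice. Points are enumerated x-fastest, then
#' y, then z (see \code{\link{gridPoints}}).
#'
#' @slot origin numeric(3), coordinates of the first lattice point (Angstrom).
#' @slot spacing numeric(1), lattice spacing (Angstrom).
#' @slot dims integer(3), number of points along x, y, z.
#' @slot margin numeric(1), the margin (Angstrom) the grid was built with.
#' @export
setClass("GridSpec",
  representation(origin = "numeric", spacing = "numeric",
                 dims = "integer", margin = "numeric"))

setValidity("GridSpec", function(object) {
  if (length(object@origin) != 3L) return("origin must be length 3")
  if (length(object@dims) != 3L || any(object@dims < 1L))
    return("dims must be 3 positive integers")
  if (object@spacing <= 0) return("spacing must be positive")
  TRUE
})

#' FieldMatrix: compounds x grid-points x channels descriptor block
#'
#' Field values are stored as a compounds-by-columns matrix; the columns are
#' grouped into contiguous channel blocks, each block enumerating the grid
#' x-fastest. CoMFA channels are interaction energies in kcal/mol bounded to
#' the truncation interval; CoMSIA channels are dimensionless similarity
#' indices.
#'
#' @slot values numeric matrix, compounds x (points * channels).
#' @slot channels character vector of channel labels, in block order.
#' @slot grid a \code{\link{GridSpec}}.
#' @slot compoundIds character, row identifiers.
#' @export
setClass("FieldMatrix",
  representation(values = "matrix", channels = "character",
                 grid = "GridSpec", compoundIds = "character"))

setValidity("FieldMatrix", function(object) {
  np <- prod(object@grid@dims)
  if (ncol(object@values) != np * length(object@channels))
    return("ncol(values) must equal n_points * n_channels")
  if (nrow(object@values) != length(object@compoundIds))
    return("nrow(values) must equal length(compoundIds)")
  comfa <- grepl("^comfa", channelOfColumn(object))
  if (any(comfa)) {
    v <- object@values[, comfa, drop = FALSE]
    if (any(is.finite(v) & (v < -30 - 1e-9 | v > 30 + 1e-9)))
      return("CoMFA channel values outside the [-30, +30] kcal/mol truncation interval")
  }
  if (any(!is.finite(object@values)))
    return("field values must be finite")
  TRUE
})

#' PLSModel: a fitted latent-variable regression
#'
#' NIPALS partial least squares fit of activity on a descriptor matrix, after
#' column filtering and block scaling. Coefficients are stored both in the
#' internal scaled representation and mapped back to the original column
#' units, so that \code{predict} works on raw descriptor rows.
#'
#' @slot ncomp integer(1), number of latent components.
#' @slot columnMask logical, which original columns were retained.
#' @slot columnMeans,columnScales numeric, centring/scaling of retained columns.
#' @slot coefficients numeric, regression coefficients per retained column in
#'   original units.
#' @slot coefScaled numeric, coefficients in the scaled representation.
#' @slot intercept numeric(1).
#' @slot channelOfColumn character, channel label per original column.
#' @slot fitted numeric, fitted values on the training rows.
#' @slot y numeric, training response.
#' @export
setClass("PLSModel",
  representation(ncomp = "integer", columnMask = "logical",
    columnMeans = "numeric", columnScales = "numeric",
    coefficients = "numeric", coefScaled = "numeric", intercept = "numeric",
    channelOfColumn = "character", fitted = "numeric", y = "numeric"))

setValidity("PLSModel", function(object) {
  k <- sum(object@columnMask)
  if (length(object@coefficients) != k)
    return("one coefficient per retained column required")
  if (object@ncomp < 1L) return("ncomp must be >= 1")
  TRUE
})

#' LooResult: leave-one-out cross-validation profile
#'
#' @slot q2 numeric, cross-validated r2 (q2) by component count.
#' @slot press numeric, PRESS by component count.
#' @slot onc integer(1), optimal number of components (argmax q2, ties to
#'   the smaller count).
#' @export
setClass("LooResult",
  representation(q2 = "numeric", press = "numeric", onc = "integer"))

setValidity("LooResult", function(object) {
  if (length(object@q2) != length(object@press))
    return("q2 and press must have equal length")
  if (object@onc < 1L || object@onc > length(object@q2))
    return("onc out of range")
  qs <- object@q2
  if (abs(qs[object@onc] - max(qs)) > 1e-12 ||
      any(abs(qs[seq_len(object@onc - 1L)] - max(qs)) < 1e-15))
    return("onc must be the smallest component count attaining max q2")
  TRUE
})

#' ContourField: a STDEV*COEFF field with contour levels
#'
#' @slot channel character(1) channel label.
#' @slot values numeric, one value per grid point (zero at filtered columns).
#' @slot favoredLevel,disfavoredLevel numeric(1) contour thresholds.
#' @slot grid a \code{\link{GridSpec}}.
#' @export
setClass("ContourField",
  representation(channel = "character", values = "numeric",
    favoredLevel = "numeric", disfavoredLevel = "numeric", grid = "GridSpec"))

setValidity("ContourField", function(object) {
  if (length(object@values) != prod(object@grid@dims))
    return("one value per grid point required")
  if (!is.finite(object@favoredLevel) || !is.finite(object@disfavoredLevel))
    return("contour levels must be finite")
  if (object@favoredLevel < 0 || object@disfavoredLevel > 0)
    return("favoredLevel must be >= 0 and disfavoredLevel <= 0")
  TRUE
})
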