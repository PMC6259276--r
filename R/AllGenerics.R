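#' Number of atoms in a conformer
#' @param x a \code{\link{Conformer}}
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Atom coordinates
#' @param x a \code{\link{Conformer}}
#' @return numeric matrix, atoms x 3
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' Replace atom coordinates
#' @param x a \code{\link{Conformer}}
#' @param value atoms x 3 numeric matrix
#' @export
setGeneric("atomCoords<-", function(x, value) standardGeneric("atomCoords<-"))

#' Partial charges
#' @param x a \code{\link{Conformer}}
#' @export
setGeneric("atomCharges", function(x) standardGeneric("atomCharges"))

#' Grid point coordinates, x-fastest order
#' @param x a \code{\link{GridSpec}} (or object carrying one)
#' @return numeric matrix, points x 3
#' @export
setGeneric("gridPoints", function(x) standardGeneric("gridPoints"))

#' Channel label of every column of a field matrix
#' @param x a \code{\link{FieldMatrix}} or \code{\link{PLSModel}}
#' @export
setGeneric("channelOfColumn", function(x) standardGeneric("channelOfColumn"))

#' Channel labels
#' @param x a \code{\link{FieldMatrix}}
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' Field values as a plain matrix
#' @param x a \code{\link{FieldMatrix}}
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' Subset a field matrix by channel
#' @param x a \code{\link{FieldMatrix}}
#' @param keep character, channel labels to retain
#' @export
setGeneric("fieldSubset", function(x, keep) standardGeneric("fieldSubset"))

#' Optimal number of components
#' @param x a \code{\link{LooResult}} or \code{\link{PLSModel}}
#' @export
setGeneric("onc", function(x) standardGeneric("onc"))

#' Cross-validated r2 profile
#' @param x a \code{\link{LooResult}}
#' @export
setGeneric("q2", function(x) standardGeneric("q2"))
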