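## contour_export: STDEV*COEFF fields and contour-by-contribution levels,
## exported as OpenDX grids.

#' STDEV*COEFF contour field of one channel
#'
#' Per grid point, the product of the column standard deviation (across
#' training compounds) and the model coefficient in original units; columns
#' removed by the column filter contribute zero. Positive values mark
#' regions where increasing the field raises predicted activity.
#'
#' @param model a \code{\link{PLSModel}} fitted on \code{X}.
#' @param X the training \code{\link{FieldMatrix}}.
#' @param channel channel label present in \code{X}.
#' @return a \code{\link{ContourField}} with levels from
#'   \code{\link{contourLevels}} applied at the default 80/20 split.
#' @export
stdevCoeffField <- function(model, X, channel) {
  if (!is(X, "FieldMatrix")) stop("X must be a FieldMatrix")
  if (!channel %in% channels(X))
    stop("unknown channel '", channel, "'; available: ",
         paste(channels(X), collapse = ", "))
  cols <- channelOfColumn(X) == channel
  sds <- apply(fieldValues(X)[, cols, drop = FALSE], 2, sd)
  coefFull <- numeric(length(model@columnMask))
  coefFull[model@columnMask] <- model@coefficients
  vals <- sds * coefFull[cols]
  vals[!model@columnMask[cols]] <- 0
  lv <- contourLevels(vals)
  new("ContourField", channel = channel, values = vals,
      favoredLevel = lv[["favored"]], disfavoredLevel = lv[["disfavored"]],
      grid = X@grid)
}

#' Contour levels by cumulative contribution
#'
#' The favored level is set so that the grid points above it carry the top
#' (100 - favoredPct) percent of the total positive STDEV*COEFF mass (the
#' contour-by-contribution convention: an "80 percent contribution" contour
#' encloses the strongest 20 percent of the favourable mass). The
#' disfavored level symmetrically bounds the top \code{disfavoredPct}
#' percent of the negative mass (by magnitude). An all-zero field yields
#' (0, 0); a one-signed field yields 0 for the missing side.
#'
#' @param values numeric field values (or a \code{\link{ContourField}}).
#' @param favoredPct,disfavoredPct percentage conventions, defaults 80 / 20.
#' @return named numeric: \code{favored} (>= 0), \code{disfavored} (<= 0).
#' @export
contourLevels <- function(values, favoredPct = 80, disfavoredPct = 20) {
  if (is(values, "ContourField")) values <- values@values
  massLevel <- function(v, frac) {
    # smallest value among the top-|mass| fraction of v (v > 0)
    if (!length(v) || sum(v) <= 0) return(0)
    s <- sort(v, decreasing = TRUE)
    cum <- cumsum(s)
    k <- which(cum >= frac * sum(s) - 1e-12)[1]
    s[k]
  }
  pos <- values[values > 0]
  neg <- -values[values < 0]
  c(favored = massLevel(pos, (100 - favoredPct) / 100),
    disfavored = -massLevel(neg, disfavoredPct / 100))
}

setMethod("show", "ContourField", function(object) {
  cat(sprintf("ContourField '%s': %d points, levels [%.4g, %.4g]\n",
    object@channel, length(object@values),
    object@disfavoredLevel, object@favoredLevel))
})

#' Write a scalar grid field as an OpenDX file
#'
#' Standard OpenDX regular-grid scalar format (as consumed by PyMOL, VMD and
#' Chimera). OpenDX enumerates data z-fastest, so the package's x-fastest
#' values are permuted on output; \code{\link{readOpenDX}} inverts this.
#' Contour levels are recorded as comments in the header.
#'
#' @param field a \code{\link{ContourField}}, or a numeric vector together
#'   with \code{grid}.
#' @param path output file.
#' @param grid a \code{\link{GridSpec}} (required when \code{field} is a bare
#'   vector).
#' @export
writeOpenDX <- function(field, path, grid = NULL) {
  if (is(field, "ContourField")) {
    grid <- field@grid
    vals <- field@values
    hdr <- sprintf("# channel %s ; favored_level %.10g ; disfavored_level %.10g",
                   field@channel, field@favoredLevel, field@disfavoredLevel)
  } else {
    if (is.null(grid)) stop("grid required for a bare value vector")
    vals <- field
    hdr <- "# scalar field"
  }
  d <- grid@dims
  stopifnot(length(vals) == prod(d))
  # x-fastest -> z-fastest
  arr <- array(vals, dim = d)
  zfast <- as.numeric(aperm(arr, c(3, 2, 1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr,
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid@origin[1], grid@origin[2], grid@origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid@spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid@spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid@spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  chunks <- split(zfast, ceiling(seq_along(zfast) / 3))
  writeLines(vapply(chunks, function(x)
    paste(sprintf("%.10e", x), collapse = " "), ""), con)
  writeLines(c('attribute "dep" string "positions"',
    'object "regular positions regular connections" class field',
    'component "positions" value 1',
    'component "connections" value 2',
    'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar grid file
#'
#' @param path OpenDX file written by \code{\link{writeOpenDX}} (or any
#'   regular-grid scalar DX file with uniform axis-aligned deltas).
#' @return list with \code{values} (x-fastest order) and \code{grid}
#'   (a \code{\link{GridSpec}}).
#' @export
readOpenDX <- function(path) {
  lines <- readLines(path)
  num <- function(rx) as.numeric(strsplit(trimws(
    sub(rx, "", grep(rx, lines, value = TRUE)[1])), "\\s+")[[1]])
  cnt <- num("^object 1 class gridpositions counts")
  origin <- num("^origin")
  deltas <- t(vapply(grep("^delta", lines, value = TRUE),
    function(l) as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1]]),
    numeric(3)))
  spacing <- max(deltas)
  start <- grep("data follows", lines)[1] + 1L
  end <- grep('^attribute "dep"', lines)[1] - 1L
  zfast <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "\\s+")))
  d <- as.integer(cnt)
  arr <- array(zfast, dim = rev(d))
  list(values = as.numeric(aperm(arr, c(3, 2, 1))),
       grid = new("GridSpec", origin = origin, spacing = spacing,
                  dims = d, margin = NA_real_))
}
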