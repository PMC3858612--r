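#' @import methods
NULL

#' Trajectory: an ordered series of telemetry fixes for one individual
#'
#' A `Trajectory` holds the time-stamped planar locations ("fixes") of one
#' radio-tracked individual, either for a single night's focal follow or
#' pooled across nights. Coordinates are planar meters on a local study
#' grid; no geodesy is applied anywhere in the package.
#'
#' @slot id character(1), individual identifier.
#' @slot sex character(1), `"M"`, `"F"` or `NA`.
#' @slot night character(1), night identifier or `"pooled"`.
#' @slot t numeric, fix times in seconds (strictly increasing).
#' @slot x,y numeric, planar coordinates in meters.
#' @slot inSight logical, whether the animal was in sight at the fix
#'   (defaults to `TRUE` when absent from input files).
#'
#' @seealso [Trajectory()], [subsampleFixes()], [pathLength()],
#'   [alignDyad()]
#' @export
setClass("Trajectory",
  representation(
    id = "character", sex = "character", night = "character",
    t = "numeric", x = "numeric", y = "numeric", inSight = "logical"
  ),
  prototype(
    id = NA_character_, sex = NA_character_, night = "pooled",
    t = numeric(0), x = numeric(0), y = numeric(0), inSight = logical(0)
  )
)

setValidity("Trajectory", function(object) {
  n <- length(object@t)
  if (length(object@x) != n || length(object@y) != n ||
      length(object@inSight) != n)
    return("t, x, y and inSight must have equal length")
  if (n > 0) {
    if (!all(is.finite(object@x)) || !all(is.finite(object@y)))
      return("coordinates must be finite")
    if (any(diff(object@t) <= 0))
      return("fix times must be strictly increasing")
  }
  if (!object@sex %in% c("M", "F", NA_character_))
    return("sex must be 'M', 'F' or NA")
  TRUE
})

#' DyadSeries: time-aligned simultaneous fixes of a male-female dyad
#'
#' Each entry pairs one fix of the male with the nearest-in-time fix of the
#' female (or vice versa), within an alignment tolerance. All
#' dynamic-interaction tests operate on this container.
#'
#' @slot maleId,femaleId character(1), identifiers of the two partners.
#' @slot t numeric, alignment times in seconds (strictly increasing).
#' @slot mx,my numeric, male coordinates (m) at each aligned time.
#' @slot fx,fy numeric, female coordinates (m) at each aligned time.
#'
#' @seealso [alignDyad()], [dyadDistances()], [doncasterTest()],
#'   [proximityTime()]
#' @export
setClass("DyadSeries",
  representation(
    maleId = "character", femaleId = "character",
    t = "numeric", mx = "numeric", my = "numeric",
    fx = "numeric", fy = "numeric"
  ),
  prototype(
    maleId = NA_character_, femaleId = NA_character_,
    t = numeric(0), mx = numeric(0), my = numeric(0),
    fx = numeric(0), fy = numeric(0)
  )
)

setValidity("DyadSeries", function(object) {
  n <- length(object@t)
  if (any(vapply(list(object@mx, object@my, object@fx, object@fy),
                 length, 0L) != n))
    return("t, mx, my, fx, fy must have equal length")
  if (n > 1 && any(diff(object@t) <= 0))
    return("alignment times must be strictly increasing")
  TRUE
})

#' UtilizationDistribution: a gridded kernel density of space use
#'
#' The utilization distribution (UD) is the probability density of an
#' animal's use of space, estimated here by a fixed bivariate Gaussian
#' kernel on a regular grid. The density integrates to one over the grid
#' (cell Riemann sum).
#'
#' @slot xg,yg numeric, cell-center coordinates (m) of the grid columns and
#'   rows; equally spaced.
#' @slot cell numeric(1), cell side length (m).
#' @slot z matrix, density values (per m^2), `length(xg)` rows by
#'   `length(yg)` columns.
#' @slot h numeric(1), kernel bandwidth (m, standard deviation of the
#'   Gaussian kernel).
#'
#' @seealso [kernelUD()], [isopleth()]
#' @export
setClass("UtilizationDistribution",
  representation(xg = "numeric", yg = "numeric", cell = "numeric",
                 z = "matrix", h = "numeric")
)

setValidity("UtilizationDistribution", function(object) {
  if (object@h <= 0) return("bandwidth h must be > 0")
  if (object@cell <= 0) return("cell size must be > 0")
  if (nrow(object@z) != length(object@xg) ||
      ncol(object@z) != length(object@yg))
    return("density matrix dimensions must match the grid")
  if (any(object@z < 0)) return("density must be nonnegative")
  mass <- sum(object@z) * object@cell^2
  if (abs(mass - 1) > 1e-6)
    return(sprintf("density must integrate to 1 (got %.8f)", mass))
  TRUE
})

#' RangePolygon: an isopleth home-range polygon with its area
#'
#' The polygon(s) enclosing the smallest set of UD cells whose cumulative
#' probability reaches the isopleth level (conventionally 0.95), or a
#' minimum convex polygon. Areas are reported in hectares.
#'
#' @slot id character(1), individual identifier.
#' @slot level numeric(1), isopleth level in (0, 1]; 1 for an MCP.
#' @slot rings list of two-column matrices (x, y in m), the closed rings.
#' @slot areaHa numeric(1), enclosed area in hectares.
#' @slot h numeric(1), bandwidth used (m); `NA` for an MCP.
#'
#' @seealso [isopleth()], [mcpPolygon()], [percentOverlap()]
#' @export
setClass("RangePolygon",
  representation(id = "character", level = "numeric", rings = "list",
                 areaHa = "numeric", h = "numeric"),
  prototype(id = NA_character_, h = NA_real_)
)

setValidity("RangePolygon", function(object) {
  if (object@level <= 0 || object@level > 1)
    return("isopleth level must be in (0, 1]")
  if (!length(object@rings)) return("at least one ring required")
  for (r in object@rings) {
    if (!is.matrix(r) || ncol(r) != 2 || nrow(r) < 3)
      return("each ring must be a matrix with >= 3 rows and 2 columns")
  }
  if (!is.finite(object@areaHa) || object@areaHa <= 0)
    return("area must be positive")
  TRUE
})

#' @describeIn Trajectory-class number of fixes
#' @param x a `Trajectory` or `DyadSeries`
#' @export
setGeneric("nFixes", function(x) standardGeneric("nFixes"))

#' @rdname Trajectory-class
#' @export
setMethod("nFixes", "Trajectory", function(x) length(x@t))

#' @rdname DyadSeries-class
#' @aliases nFixes,DyadSeries-method
#' @param x a `DyadSeries`
#' @export
setMethod("nFixes", "DyadSeries", function(x) length(x@t))

#' @describeIn Trajectory-class fix coordinates as an n x 2 matrix
#' @param object a `Trajectory`
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @rdname Trajectory-class
#' @export
setMethod("coords", "Trajectory", function(object)
  cbind(x = object@x, y = object@y))

#' @describeIn Trajectory-class fix times in seconds
#' @export
setGeneric("fixTimes", function(object) standardGeneric("fixTimes"))

#' @rdname Trajectory-class
#' @export
setMethod("fixTimes", "Trajectory", function(object) object@t)

#' @describeIn RangePolygon-class area in hectares
#' @export
setGeneric("areaHa", function(object) standardGeneric("areaHa"))

#' @rdname RangePolygon-class
#' @param object a `RangePolygon`
#' @export
setMethod("areaHa", "RangePolygon", function(object) object@areaHa)

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory '%s' (%s), night %s: %d fixes",
              object@id, object@sex, object@night, length(object@t)))
  if (length(object@t) > 1)
    cat(sprintf(", %.0f s span, path %.1f m",
                diff(range(object@t)), pathLength(object)))
  cat("\n")
})

setMethod("show", "DyadSeries", function(object) {
  cat(sprintf("DyadSeries %s x %s: %d aligned fixes",
              object@maleId, object@femaleId, length(object@t)))
  if (length(object@t))
    cat(sprintf(", median distance %.1f m",
                stats::median(dyadDistances(object))))
  cat("\n")
})

setMethod("show", "UtilizationDistribution", function(object) {
  cat(sprintf(
    "UtilizationDistribution: %d x %d grid, cell %.2f m, h = %.2f m\n",
    length(object@xg), length(object@yg), object@cell, object@h))
})

setMethod("show", "RangePolygon", function(object) {
  cat(sprintf("RangePolygon '%s': %.0f%% isopleth, %d ring(s), %.4f ha\n",
              object@id, 100 * object@level, length(object@rings),
              object@areaHa))
})
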