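#' 4D lung displacement field
#'
#' Container for a per-subject displacement field: a 3-vector of tissue
#' displacement (in voxel units, relative to end-exhalation at phase 1) at
#' every voxel of a regular lattice, resolved over `n_phases` inspiratory
#' phase points, together with a binary lung mask and the voxel spacing.
#'
#' @param u Numeric array of dimension `c(shape, 3, n_phases)`: displacement
#'   component `k` at phase `p` for voxel `(i,j,l)` is `u[i,j,l,k,p]`.
#'   Phase 1 (end-exhalation reference) must be identically zero.
#' @param mask Logical array of dimension `shape`; `TRUE` marks lung interior.
#' @param voxel_spacing_mm Numeric length-3 vector of voxel edge lengths in mm.
#'
#' @return An object of class `displacement_field` with elements `u`, `mask`,
#'   `shape`, `n_phases`, `voxel_spacing_mm`.
#' @export
displacement_field <- function(u, mask, voxel_spacing_mm = c(1, 1, 1)) {
  du <- dim(u)
  if (length(du) != 5L || du[4] != 3L) {
    stop("`u` must be a 5-D array with dimension c(shape, 3, n_phases)")
  }
  shape <- du[1:3]
  n_phases <- du[5]
  if (n_phases < 2L) stop("a displacement field needs at least 2 phases")
  if (!is.logical(mask) || !identical(dim(mask), as.integer(shape))) {
    stop("`mask` must be a logical array matching the spatial shape of `u`")
  }
  if (!any(mask)) stop("mask is empty")
  if (!all(is.finite(u))) stop("displacements must be finite")
  if (any(u[, , , , 1] != 0)) {
    stop("displacement at phase 1 (end-exhalation reference) must be zero")
  }
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0)) {
    stop("`voxel_spacing_mm` must be 3 positive reals")
  }
  structure(
    list(
      u = u, mask = mask, shape = as.integer(shape),
      n_phases = as.integer(n_phases),
      voxel_spacing_mm = as.numeric(voxel_spacing_mm)
    ),
    class = "displacement_field"
  )
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(
    "<displacement_field> ", paste(x$shape, collapse = "x"),
    " lattice, ", x$n_phases, " phases, ",
    sum(x$mask), " lung voxels\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.displacement_field <- function(x) x$shape
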