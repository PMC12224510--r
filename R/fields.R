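#' Scalar field on the lung mask
#'
#' A derived scalar quantity (expansion, flow, or oscillation) defined on a
#' subset of lung voxels (the support).
#'
#' @param values Numeric vector, one value per support voxel.
#' @param support Integer vector of linear voxel indices into the lattice.
#' @param shape Integer length-3 lattice dimensions.
#' @param field_kind `"expansion"`, `"flow"`, or `"oscillation"`.
#' @param id Interval id (flow) or variant id (oscillation); `NA` for expansion.
#' @return A `scalar_field` object.
#' @export
scalar_field <- function(values, support, shape,
                         field_kind = c("expansion", "flow", "oscillation"),
                         id = NA_integer_) {
  field_kind <- match.arg(field_kind)
  stopifnot(length(values) == length(support), length(support) > 0)
  if (!all(is.finite(values))) stop("scalar field values must be finite")
  structure(
    list(values = values, support = as.integer(support),
         shape = as.integer(shape), field_kind = field_kind,
         id = as.integer(id)),
    class = "scalar_field"
  )
}

#' @export
print.scalar_field <- function(x, ...) {
  cat("<scalar_field:", x$field_kind,
      if (!is.na(x$id)) paste0("#", x$id) else "",
      "> ", length(x$values), " voxels\n", sep = "")
  invisible(x)
}

# Shift a 3-D array by +1/-1 along one axis, padding with `fill`.
.shift3 <- function(a, axis, by, fill = NA_real_) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- lapply(d, seq_len)
  if (by == 1L) {        # out[i] = a[i + 1]
    src[[axis]] <- 2:d[axis]; dst[[axis]] <- 1:(d[axis] - 1L)
  } else {               # out[i] = a[i - 1]
    src[[axis]] <- 1:(d[axis] - 1L); dst[[axis]] <- 2:d[axis]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Mask-aware partial derivative of a 3-D volume along one axis: central
# differences where both neighbours are inside the mask, one-sided at the
# mask boundary, NA where the full stencil leaves the mask.
.masked_deriv <- function(vol, mask, axis) {
  mnum <- array(as.numeric(mask), dim(mask))
  fp <- .shift3(vol, axis, 1L); mp <- .shift3(mnum, axis, 1L, 0) > 0
  fm <- .shift3(vol, axis, -1L); mm <- .shift3(mnum, axis, -1L, 0) > 0
  d <- array(NA_real_, dim(vol))
  both <- mask & mp & mm
  fwd <- mask & mp & !mm
  bwd <- mask & !mp & mm
  d[both] <- (fp[both] - fm[both]) / 2
  d[fwd] <- fp[fwd] - vol[fwd]
  d[bwd] <- vol[bwd] - fm[bwd]
  d
}

.check_mask_extent <- function(mask) {
  for (ax in 1:3) {
    present <- apply(mask, ax, any)
    if (sum(present) < 3L) {
      stop("gradient undefined: mask thinner than 3 voxels along axis ", ax)
    }
  }
  invisible(TRUE)
}

#' Local lung expansion from the displacement field
#'
#' Finite-strain fractional volume change at one breath phase:
#' `e(x) = det(I + grad u(x, phase)) - 1`, with the displacement gradient by
#' central differences on interior voxels and one-sided differences at the
#' mask boundary. Voxels whose full difference stencil leaves the mask are
#' excluded from the support.
#'
#' @param field A [displacement_field()].
#' @param phase Phase index, 0-based (`0` to `n_phases - 1`); defaults to the
#'   final phase (full inspiration).
#' @return A [scalar_field()] of kind `"expansion"`.
#' @export
compute_expansion <- function(field, phase = field$n_phases - 1L) {
  stopifnot(inherits(field, "displacement_field"))
  if (phase < 0 || phase >= field$n_phases) stop("invalid `phase`")
  .check_mask_extent(field$mask)
  J <- vector("list", 9L)
  for (k in 1:3) {
    vol <- field$u[, , , k, phase + 1L]
    dim(vol) <- field$shape
    for (a in 1:3) J[[(k - 1L) * 3L + a]] <- .masked_deriv(vol, field$mask, a)
  }
  # det(I + J) - 1, expanded elementwise over the 3x3 Jacobian
  j11 <- J[[1]]; j12 <- J[[2]]; j13 <- J[[3]]
  j21 <- J[[4]]; j22 <- J[[5]]; j23 <- J[[6]]
  j31 <- J[[7]]; j32 <- J[[8]]; j33 <- J[[9]]
  det <- (1 + j11) * ((1 + j22) * (1 + j33) - j23 * j32) -
    j12 * (j21 * (1 + j33) - j23 * j31) +
    j13 * (j21 * j32 - (1 + j22) * j31)
  e <- det - 1
  support <- which(field$mask & is.finite(e))
  scalar_field(e[support], support, field$shape, "expansion")
}

#' The canonical flow time intervals
#'
#' For a 7-phase breath these are the 6 consecutive inter-phase steps plus
#' the first half (0-3), second half (3-6), and whole breath (0-6). Phase
#' indices are 0-based.
#'
#' @param n_phases Number of phase points.
#' @param consecutive_only If `TRUE`, only the consecutive inter-phase steps.
#' @return Tibble with columns `id`, `phase_lo`, `phase_hi`.
#' @export
interval_specs <- function(n_phases = 7L, consecutive_only = FALSE) {
  n_phases <- as.integer(n_phases)
  last <- n_phases - 1L
  lo <- 0:(last - 1L); hi <- 1:last
  if (!consecutive_only && n_phases >= 3L) {
    mid <- last %/% 2L
    extra <- unique(list(c(0L, mid), c(mid, last), c(0L, last)))
    for (e in extra) {
      dup <- any(lo == e[1] & hi == e[2])
      if (!dup) { lo <- c(lo, e[1]); hi <- c(hi, e[2]) }
    }
  }
  tibble::tibble(id = seq_along(lo), phase_lo = lo, phase_hi = hi)
}

#' Expansion rate (flow) over a time interval
#'
#' Inter-phase change in local expansion per unit time:
#' `f(x) = (e(x, hi) - e(x, lo)) / (hi - lo)` in normalized phase units
#' (one phase step = 1). Physical seconds-per-phase only rescales all flow
#' fields by a constant.
#'
#' @param field A [displacement_field()].
#' @param interval One row of [interval_specs()] (or a list with `id`,
#'   `phase_lo`, `phase_hi`).
#' @return A [scalar_field()] of kind `"flow"`.
#' @export
compute_flow <- function(field, interval) {
  lo <- interval$phase_lo; hi <- interval$phase_hi
  if (is.null(lo) || is.null(hi) || lo < 0 || hi <= lo || hi >= field$n_phases) {
    stop("invalid interval")
  }
  e_lo <- compute_expansion(field, lo)
  e_hi <- compute_expansion(field, hi)
  stopifnot(identical(e_lo$support, e_hi$support))
  f <- (e_hi$values - e_lo$values) / (hi - lo)
  scalar_field(f, e_lo$support, field$shape, "flow", id = interval$id)
}

#' Direction-reversal (oscillation) index
#'
#' Per voxel, the fraction of consecutive inter-phase increment pairs whose
#' dot product is negative, i.e. how often the local motion reverses
#' direction over the inspiratory phase. Variants: 1 = displacement
#' increments; 2 = velocity vectors (increments per unit time); 3 and 4 =
#' the element-wise signed square (`v * |v|`) of variants 1 and 2, which
#' preserves direction while emphasizing large excursions.
#'
#' @param field A [displacement_field()].
#' @param variant Integer 1-4.
#' @return A [scalar_field()] of kind `"oscillation"` with values in `[0, 1]`.
#' @export
compute_oscillation <- function(field, variant = 1L) {
  stopifnot(inherits(field, "displacement_field"))
  if (field$n_phases < 3L) stop("oscillation needs at least 3 phases")
  if (!variant %in% 1:4) stop("`variant` must be 1..4")
  np <- field$n_phases
  idx <- which(field$mask)
  nm <- length(idx)
  nvox <- prod(field$shape)
  # increments v[voxel, axis, step]
  v <- array(0, c(nm, 3L, np - 1L))
  for (p in seq_len(np - 1L)) {
    for (ax in 1:3) {
      off <- (ax - 1L) * nvox
      v[, ax, p] <- field$u[idx + off + p * 3L * nvox] -
        field$u[idx + off + (p - 1L) * 3L * nvox]
    }
  }
  dt <- 1 # normalized phase step
  if (variant %in% c(2L, 4L)) v <- v / dt
  if (variant %in% c(3L, 4L)) v <- v * abs(v)
  neg <- matrix(0, nm, np - 2L)
  for (p in seq_len(np - 2L)) {
    dots <- v[, 1, p] * v[, 1, p + 1] + v[, 2, p] * v[, 2, p + 1] +
      v[, 3, p] * v[, 3, p + 1]
    neg[, p] <- as.numeric(dots < 0)
  }
  scalar_field(rowMeans(neg), idx, field$shape, "oscillation", id = variant)
}

#' Derive the full set of scalar fields for one subject
#'
#' Computes the expansion field at full inspiration, one flow field per time
#' interval, and the four oscillation variants. With the default 7-phase
#' intervals this yields 14 scalar fields (1 + 9 + 4).
#'
#' @param field A [displacement_field()].
#' @param intervals Interval table (defaults to [interval_specs()] for the
#'   field's phase count).
#' @return A named list of [scalar_field()]s of class `derived_field_set`:
#'   `expansion`, `flow_i<1..>`, `osc_v<1..4>`.
#' @export
derive_all <- function(field, intervals = interval_specs(field$n_phases)) {
  # expansion at every phase once; flow intervals reuse these
  e_by_phase <- lapply(0:(field$n_phases - 1L), function(p) {
    compute_expansion(field, p)
  })
  out <- list(expansion = e_by_phase[[field$n_phases]])
  for (r in seq_len(nrow(intervals))) {
    iv <- intervals[r, ]
    e_lo <- e_by_phase[[iv$phase_lo + 1L]]
    e_hi <- e_by_phase[[iv$phase_hi + 1L]]
    f <- (e_hi$values - e_lo$values) / (iv$phase_hi - iv$phase_lo)
    out[[paste0("flow_i", iv$id)]] <-
      scalar_field(f, e_lo$support, field$shape, "flow", id = iv$id)
  }
  for (v in 1:4) out[[paste0("osc_v", v)]] <- compute_oscillation(field, v)
  structure(out, class = "derived_field_set")
}
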