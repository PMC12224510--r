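# Fixture builders and independent oracles shared across the suite.

# displacement field u(x, p) = coef_p * (x - centre), exact linear fields:
# finite differences recover the gradient exactly, so expansion has a
# closed form det((1 + coef_p) I) - 1 on every voxel (incl. boundaries).
make_scaling_field <- function(coefs, shape = c(10L, 10L, 10L),
                               mask = array(TRUE, shape)) {
  n_phases <- length(coefs) + 1L
  ctr <- (shape + 1) / 2
  co <- as.matrix(expand.grid(
    x = seq_len(shape[1]) - ctr[1],
    y = seq_len(shape[2]) - ctr[2],
    z = seq_len(shape[3]) - ctr[3]
  ))
  u <- array(0, c(shape, 3L, n_phases))
  for (p in seq_along(coefs)) {
    for (ax in 1:3) u[, , , ax, p + 1L] <- array(coefs[p] * co[, ax], shape)
  }
  displacement_field(u, mask)
}

# random smooth displacement field: sums of low-frequency sinusoids
make_smooth_field <- function(shape = c(8L, 8L, 8L), n_phases = 3L,
                              amp = 0.05, seed = 1) {
  withr::with_seed(seed, {
    ctr <- (shape + 1) / 2
    gx <- (seq_len(shape[1]) - ctr[1]) / shape[1]
    gy <- (seq_len(shape[2]) - ctr[2]) / shape[2]
    gz <- (seq_len(shape[3]) - ctr[3]) / shape[3]
    u <- array(0, c(shape, 3L, n_phases))
    for (p in 2:n_phases) {
      for (ax in 1:3) {
        ph <- runif(3, 0, 2 * pi)
        fr <- sample(1:2, 3, replace = TRUE)
        vol <- amp * (p - 1) * (
          outer(outer(sin(fr[1] * pi * gx + ph[1]),
                      cos(fr[2] * pi * gy + ph[2])), sin(fr[3] * pi * gz + ph[3]))
        )
        u[, , , ax, p] <- vol
      }
    }
    displacement_field(u, array(TRUE, shape))
  })
}

# Brute-force expansion oracle: per voxel, assemble the 3x3 Jacobian from
# explicit difference quotients (central inside, one-sided at the array
# edge) and evaluate det(I + J) - 1 with base determinant code.
oracle_expansion <- function(field, phase) {
  sh <- field$shape
  out <- array(NA_real_, sh)
  for (i in seq_len(sh[1])) for (j in seq_len(sh[2])) for (l in seq_len(sh[3])) {
    J <- matrix(0, 3, 3)
    for (k in 1:3) {
      for (a in 1:3) {
        lo <- c(i, j, l); hi <- c(i, j, l)
        lo[a] <- lo[a] - 1L; hi[a] <- hi[a] + 1L
        ok_lo <- lo[a] >= 1L; ok_hi <- hi[a] <= sh[a]
        uk <- function(v) field$u[v[1], v[2], v[3], k, phase + 1L]
        J[k, a] <- if (ok_lo && ok_hi) {
          (uk(hi) - uk(lo)) / 2
        } else if (ok_hi) {
          uk(hi) - uk(c(i, j, l))
        } else {
          uk(c(i, j, l)) - uk(lo)
        }
      }
    }
    out[i, j, l] <- det(diag(3) + J) - 1
  }
  out
}

# Brute-force oscillation oracle: per voxel, enumerate consecutive increment
# pairs of the requested variant and count negative dot products.
oracle_oscillation <- function(field, variant) {
  np <- field$n_phases
  idx <- which(field$mask)
  pos <- arrayInd(idx, field$shape)
  vapply(seq_along(idx), function(t) {
    v <- sapply(seq_len(np - 1L), function(p) {
      field$u[pos[t, 1], pos[t, 2], pos[t, 3], , p + 1L] -
        field$u[pos[t, 1], pos[t, 2], pos[t, 3], , p]
    })
    if (variant %in% c(2L, 4L)) v <- v / 1
    if (variant %in% c(3L, 4L)) v <- v * abs(v)
    cnt <- 0
    for (p in seq_len(np - 2L)) {
      if (sum(v[, p] * v[, p + 1]) < 0) cnt <- cnt + 1
    }
    cnt / (np - 2L)
  }, numeric(1))
}

# Pairwise Mann-Whitney AUC oracle
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  sp <- scores[labels]; sn <- scores[!labels]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Small two-group cohort on a reduced lattice for fast module tests,
# built once per session.
.test_cohort_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.test_cohort_env$cb)) {
    .test_cohort_env$cb <- cohort_biomarkers(
      list(control = 8L, copd_gold12 = 8L),
      master_seed = 4242L, shape = c(16L, 16L, 16L)
    )
  }
  .test_cohort_env$cb
}

# Heterogeneity-sensitive catalogue entries: the statistics a planted
# lesion/lag/reversal effect is expected to move (dispersion and shape of
# expansion and flow; level and spread of oscillation).
planted_biomarkers <- function(bank = enumerate_bank()) {
  het <- c("sd", "iqr", "skewness", "kurtosis", "shannon_entropy",
           "pct_low", "pct_high", "max")
  osc <- c("mean", "sum", "sd", "pct_high")
  bank$name[(bank$source %in% c("expansion", "flow") & bank$statistic %in% het) |
              (bank$source == "oscillation" & bank$statistic %in% osc)]
}
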