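# Fixed constants of the simulator. BASE_AMP gives ~10% linear dilatation at
# full inspiration for unit compliance (expansion 1.1^3 - 1 = 0.331);
# AMP_SD is the between-subject log-normal spread of global inflation
# amplitude (applied only when noise_sd > 0, so a noiseless subject is fully
# deterministic); CHANNEL_SD is the log-normal spread of the per-subject
# severity realized in each pathology channel (compliance, lag, reversal);
# EMPH_BOOST is the compliance gain in emphysematous voxels; OSC_AMP the
# amplitude (voxels) of the alternating increments in reversal-flagged voxels.
.xv_const <- list(
  base_amp = 0.1,
  amp_sd = 0.12,
  channel_sd = 0.5,
  emph_boost = 0.5,
  osc_amp = 0.25
)

#' Phenotype configuration for the synthetic cohort generator
#'
#' Bundles the generative parameters of one simulated phenotype. `severity`
#' scales all pathological effects: the effective lesion compliance contrast,
#' per-lesion phase lag, reversal probability, and emphysema fraction are the
#' nominal values multiplied by a per-subject severity realization, so
#' `severity = 0` with `noise_sd = 0` reproduces the deterministic control
#' template exactly.
#'
#' @param group_label One of `"control"`, `"copd_gold12"`, `"copd_gold34"`,
#'   `"drcb"`.
#' @param severity Disease severity in `[0, 1]`.
#' @param n_blobs Number of low-compliance (lesion) blobs.
#' @param blob_radius_vox Lesion radius in voxels.
#' @param compliance_contrast Fractional compliance reduction inside lesions
#'   at severity 1, in `[0, 1]`.
#' @param phase_lag_max Maximum lesion inflation delay in phase units at
#'   severity 1.
#' @param reversal_prob Per-voxel probability of oscillatory increments at
#'   severity 1, in `[0, 1]`.
#' @param emphysema_frac Fraction of lung voxels with elevated compliance at
#'   severity 1 (advanced-COPD emphysema analogue), in `[0, 1]`.
#' @param noise_sd Gaussian displacement noise, voxel units.
#' @param seed Integer RNG seed for the subject.
#' @return A `phenotype_config` list.
#' @export
phenotype_config <- function(group_label = c("control", "copd_gold12", "copd_gold34", "drcb"),
                             severity = 0,
                             n_blobs = 0L,
                             blob_radius_vox = 3,
                             compliance_contrast = 0,
                             phase_lag_max = 0,
                             reversal_prob = 0,
                             emphysema_frac = 0,
                             noise_sd = 0,
                             seed = 1L) {
  group_label <- match.arg(group_label)
  stopifnot(
    severity >= 0, severity <= 1,
    n_blobs >= 0,
    blob_radius_vox > 0,
    compliance_contrast >= 0, compliance_contrast <= 1,
    phase_lag_max >= 0,
    reversal_prob >= 0, reversal_prob <= 1,
    emphysema_frac >= 0, emphysema_frac <= 1,
    noise_sd >= 0
  )
  structure(
    list(
      group_label = group_label, severity = severity,
      n_blobs = as.integer(n_blobs), blob_radius_vox = blob_radius_vox,
      compliance_contrast = compliance_contrast,
      phase_lag_max = phase_lag_max, reversal_prob = reversal_prob,
      emphysema_frac = emphysema_frac, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "phenotype_config"
  )
}

#' Default phenotype configurations
#'
#' The frozen generative settings for the four simulated groups. Controls
#' carry mild residual heterogeneity (low severity); the two COPD-like grades
#' differ in severity and in the presence of an emphysema channel; the
#' constrictive-bronchiolitis-like (DR-CB) phenotype has many small lesions
#' dominated by phase lag and flow-direction reversals rather than compliance
#' loss, mirroring small-airways disease with relatively preserved spirometry.
#'
#' @return Named list of [phenotype_config()] objects, one per group.
#' @export
default_phenotypes <- function() {
  list(
    control = phenotype_config(
      "control",
      severity = 0.18, n_blobs = 5L, blob_radius_vox = 3,
      compliance_contrast = 0.7, phase_lag_max = 3.0, reversal_prob = 0.25,
      emphysema_frac = 0, noise_sd = 0.02
    ),
    copd_gold12 = phenotype_config(
      "copd_gold12",
      severity = 0.32, n_blobs = 6L, blob_radius_vox = 3,
      compliance_contrast = 0.7, phase_lag_max = 3.0, reversal_prob = 0.25,
      emphysema_frac = 0, noise_sd = 0.02
    ),
    copd_gold34 = phenotype_config(
      "copd_gold34",
      severity = 0.65, n_blobs = 8L, blob_radius_vox = 3.5,
      compliance_contrast = 0.8, phase_lag_max = 3.0, reversal_prob = 0.25,
      emphysema_frac = 0.25, noise_sd = 0.02
    ),
    drcb = phenotype_config(
      "drcb",
      severity = 0.35, n_blobs = 12L, blob_radius_vox = 2,
      compliance_contrast = 0.45, phase_lag_max = 4.5, reversal_prob = 0.50,
      emphysema_frac = 0, noise_sd = 0.02
    )
  )
}

#' Normalized inflation curve over breath phases
#'
#' Logistic-in-phase inflation profile: the fraction of full inspiration
#' reached at each phase point. With `lag = 0` the curve runs from exactly 0
#' to exactly 1; a positive lag shifts the logistic midpoint toward later
#' phases so a lagged region inflates later and reaches a lower fraction by
#' end-inspiration (gas-trapping analogue). The curve is always monotone
#' non-decreasing and deterministic.
#'
#' @param n_phases Number of phase points (at least 2).
#' @param lag Inflation delay in phase units, `>= 0`.
#' @return Numeric vector of length `n_phases` in `[0, 1]`.
#' @export
inflation_curve <- function(n_phases, lag = 0) {
  if (n_phases < 2) stop("`n_phases` must be at least 2")
  if (lag < 0) stop("`lag` must be non-negative")
  p <- seq_len(n_phases) - 1
  m <- (n_phases - 1) / 2
  s <- (n_phases - 1) / 6
  raw <- stats::plogis(p - m - lag, scale = s)
  lo <- stats::plogis(0 - m - lag, scale = s)
  # normalize by the lag-0 dynamic range so lag only ever removes inflation
  rng <- stats::plogis(n_phases - 1 - m, scale = s) - stats::plogis(-m, scale = s)
  pmin((raw - lo) / rng, 1)
}

# Spherical lung mask centered on the lattice.
.lung_mask <- function(shape) {
  ctr <- (shape + 1) / 2
  r <- min(shape) / 2 - 2
  ax <- (seq_len(shape[1]) - ctr[1])^2
  ay <- (seq_len(shape[2]) - ctr[2])^2
  az <- (seq_len(shape[3]) - ctr[3])^2
  outer(outer(ax, ay, "+"), az, "+") <= r^2
}

# Voxel-center coordinates relative to the lattice centroid, one matrix
# column per axis, rows in array (column-major) order.
.radial_coords <- function(shape) {
  ctr <- (shape + 1) / 2
  g <- expand.grid(
    x = seq_len(shape[1]) - ctr[1],
    y = seq_len(shape[2]) - ctr[2],
    z = seq_len(shape[3]) - ctr[3]
  )
  as.matrix(g)
}

#' Simulate one subject's displacement field and clinical record
#'
#' Generates a seeded 4D tidal-breathing displacement field
#' `u(x, p) = a * c(x) * g_p(x) * r(x) + osc + noise`, where `r(x)` is the
#' radial direction from the lung centroid scaled by distance (uniform
#' dilatation baseline), `c(x)` a compliance map reduced inside lesion blobs
#' and elevated in emphysematous voxels, `g_p(x)` the logistic inflation
#' curve with per-lesion phase lag, `osc` alternating-sign increments in
#' reversal-flagged voxels, and Gaussian voxel noise. A simulated FEV1
#' percent-predicted covariate is drawn negatively correlated with severity
#' for the COPD-like groups and preserved (non-obstructive) for controls and
#' the DR-CB-like group.
#'
#' @param cfg A [phenotype_config()].
#' @param shape Integer length-3 lattice dimensions.
#' @param n_phases Number of breath phases (default 7).
#' @param subject_id Subject identifier string.
#' @return List with elements `field` (a [displacement_field()]), `record`
#'   (one-row tibble: subject_id, group_label, fev1_pct_pred, severity, seed),
#'   and `detail` (generative ground truth: lesion/compliance/lag/reversal
#'   maps over the masked voxels and the realized per-channel severities).
#' @export
simulate_subject <- function(cfg, shape = c(24L, 24L, 24L), n_phases = 7L,
                             subject_id = "subj") {
  stopifnot(inherits(cfg, "phenotype_config"))
  shape <- as.integer(shape)
  if (2 * cfg$blob_radius_vox >= min(shape)) {
    stop("lattice shape too small for `blob_radius_vox`")
  }
  k <- .xv_const
  withr::with_seed(cfg$seed, {
    mask <- .lung_mask(shape)
    idx_mask <- which(mask)
    nm <- length(idx_mask)
    coords <- .radial_coords(shape)

    # per-subject realized severity per pathology channel
    sev <- cfg$severity * exp(rnorm(3, 0, k$channel_sd))
    sev <- pmin(pmax(sev, 0), 1)
    sev_comp <- sev[1]; sev_lag <- sev[2]; sev_rev <- sev[3]

    amp <- k$base_amp
    if (cfg$noise_sd > 0) amp <- amp * exp(rnorm(1, 0, k$amp_sd))

    # compliance and lag maps over masked voxels
    comp <- rep(1, nm)
    lagv <- rep(0, nm)
    lesion <- rep(FALSE, nm)
    if (cfg$n_blobs > 0) {
      centers <- idx_mask[sample.int(nm, cfg$n_blobs, replace = FALSE)]
      blob_lags <- runif(cfg$n_blobs, 0.25, 1) * cfg$phase_lag_max * sev_lag
      cmask <- coords[idx_mask, , drop = FALSE]
      for (b in seq_len(cfg$n_blobs)) {
        cb <- coords[centers[b], ]
        d2 <- (cmask[, 1] - cb[1])^2 + (cmask[, 2] - cb[2])^2 + (cmask[, 3] - cb[3])^2
        inb <- d2 <= cfg$blob_radius_vox^2
        lesion <- lesion | inb
        comp[inb] <- pmin(comp[inb], 1 - cfg$compliance_contrast * sev_comp)
        lagv[inb] <- pmax(lagv[inb], blob_lags[b])
      }
    }
    if (cfg$emphysema_frac > 0) {
      n_emph <- round(cfg$emphysema_frac * sev_comp * nm)
      cand <- which(!lesion)
      if (n_emph > 0 && length(cand) > 0) {
        picked <- cand[sample.int(length(cand), min(n_emph, length(cand)))]
        comp[picked] <- 1 + k$emph_boost
      }
    }

    # inflation profiles: one curve per distinct lag value
    lag_levels <- sort(unique(lagv))
    curves <- vapply(lag_levels, function(l) inflation_curve(n_phases, l),
                     numeric(n_phases))
    gmat <- t(curves)[match(lagv, lag_levels), , drop = FALSE] # nm x n_phases

    # reversal-flagged voxels get alternating-sign radial increments
    rev_flag <- runif(nm) < cfg$reversal_prob * sev_rev
    osc_step <- (seq_len(n_phases) - 1) %% 2 # 0,1,0,1,...

    rmask <- coords[idx_mask, , drop = FALSE]
    rnorms <- sqrt(rowSums(rmask^2))
    rhat <- rmask / pmax(rnorms, 1e-9)

    u <- array(0, dim = c(shape, 3L, n_phases))
    nvox <- prod(shape)
    for (p in seq_len(n_phases)) {
      base_p <- amp * comp * gmat[, p]
      for (ax in 1:3) {
        vals <- base_p * rmask[, ax]
        if (any(rev_flag) && osc_step[p] > 0) {
          vals[rev_flag] <- vals[rev_flag] +
            k$osc_amp * osc_step[p] * rhat[rev_flag, ax]
        }
        u[idx_mask + (ax - 1L) * nvox + (p - 1L) * 3L * nvox] <- vals
      }
    }
    if (cfg$noise_sd > 0 && n_phases > 1) {
      for (p in 2:n_phases) {
        for (ax in 1:3) {
          u[idx_mask + (ax - 1L) * nvox + (p - 1L) * 3L * nvox] <-
            u[idx_mask + (ax - 1L) * nvox + (p - 1L) * 3L * nvox] +
            rnorm(nm, 0, cfg$noise_sd)
        }
      }
    }

    fev1 <- if (cfg$group_label %in% c("copd_gold12", "copd_gold34")) {
      max(25, 100 - 55 * cfg$severity + rnorm(1, 0, 8))
    } else {
      max(60, rnorm(1, 95, 10))
    }

    list(
      field = displacement_field(u, mask),
      record = tibble::tibble(
        subject_id = subject_id,
        group_label = cfg$group_label,
        fev1_pct_pred = fev1,
        severity = cfg$severity,
        seed = cfg$seed
      ),
      # generative ground truth, for validation and effect-recovery checks
      detail = list(
        mask_idx = idx_mask, lesion = lesion, compliance = comp,
        lag = lagv, reversal = rev_flag, amplitude = amp,
        severity_channels = c(compliance = sev_comp, lag = sev_lag,
                              reversal = sev_rev)
      )
    )
  })
}

# Deterministic per-subject seed from the master seed and (group, index).
.subject_seed <- function(master_seed, group, index) {
  h <- sum(utf8ToInt(group) * seq_along(utf8ToInt(group)))
  as.integer((as.numeric(master_seed) + 131 * h + 7919 * index) %% 2147483647)
}

# Expand a cohort request into one row per subject with its config.
.cohort_plan <- function(n_per_group, master_seed, phenotypes = default_phenotypes()) {
  stopifnot(all(names(n_per_group) %in% names(phenotypes)),
            all(unlist(n_per_group) >= 0))
  rows <- list()
  for (g in names(n_per_group)) {
    n <- n_per_group[[g]]
    if (n == 0) next
    for (i in seq_len(n)) {
      cfg <- phenotypes[[g]]
      cfg$seed <- .subject_seed(master_seed, g, i)
      rows[[length(rows) + 1L]] <- list(
        subject_id = sprintf("%s_%03d", g, i), group = g, cfg = cfg
      )
    }
  }
  rows
}

#' Simulate a multi-group cohort
#'
#' Generates displacement fields and clinical records for the requested
#' number of subjects per group, with per-subject seeds derived
#' deterministically from `master_seed` so the same call reproduces the same
#' cohort while subjects remain mutually independent.
#'
#' @param n_per_group Named list/vector, e.g. `list(control = 20, copd_gold12 = 20)`.
#' @param master_seed Integer master seed.
#' @param shape,n_phases Lattice dimensions and phase count per subject.
#' @param phenotypes Named list of [phenotype_config()]s (defaults to
#'   [default_phenotypes()]).
#' @return List with `fields` (named list of [displacement_field()]) and
#'   `records` (tibble of subject covariates).
#' @export
simulate_cohort <- function(n_per_group, master_seed = 1L,
                            shape = c(24L, 24L, 24L), n_phases = 7L,
                            phenotypes = default_phenotypes()) {
  plan <- .cohort_plan(n_per_group, master_seed, phenotypes)
  fields <- vector("list", length(plan))
  recs <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    s <- simulate_subject(plan[[i]]$cfg, shape, n_phases, plan[[i]]$subject_id)
    fields[[i]] <- s$field
    recs[[i]] <- s$record
  }
  names(fields) <- vapply(plan, `[[`, "", "subject_id")
  list(fields = fields, records = do.call(rbind, recs))
}
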