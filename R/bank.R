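#' The eleven spatially resolved statistics
#'
#' Fixed, ordered identifiers of the summary statistics computed over each
#' scalar field: mean, median, sd, iqr, skewness, kurtosis (excess),
#' shannon_entropy (64-bin, bits), pct_low, pct_high (percentage of voxels
#' below/above reference cut-offs), max, sum.
#'
#' @return Character vector of length 11.
#' @export
statistic_ids <- function() {
  c("mean", "median", "sd", "iqr", "skewness", "kurtosis",
    "shannon_entropy", "pct_low", "pct_high", "max", "sum")
}

#' Summarize a scalar field with one statistic
#'
#' Degenerate-distribution conventions: sd, iqr, entropy, skewness and
#' kurtosis are 0 for constant (zero-variance) fields. Entropy uses a 64-bin
#' histogram over the field's own `[min, max]` range, in bits. `pct_low` and
#' `pct_high` report the percentage of voxels below `thresholds$low` /
#' above `thresholds$high`; when no reference thresholds are supplied the
#' field's own 10th and 90th percentiles are used (so a field scored against
#' itself gives ~10% on each side).
#'
#' @param field A [scalar_field()] or bare numeric vector.
#' @param statistic One of [statistic_ids()].
#' @param thresholds Optional list with elements `low` and `high`: reference
#'   cut-off values (typically pooled-control 10th/90th percentiles).
#' @param entropy_bins Number of histogram bins for `shannon_entropy`.
#' @return A single numeric value.
#' @export
summarize_field <- function(field, statistic, thresholds = NULL,
                            entropy_bins = 64L) {
  x <- if (inherits(field, "scalar_field")) field$values else as.numeric(field)
  if (length(x) == 0) stop("field support is empty")
  statistic <- match.arg(statistic, statistic_ids())
  switch(statistic,
    mean = mean(x),
    median = median(x),
    sd = if (length(x) < 2) 0 else sd(x),
    iqr = unname(diff(quantile(x, c(0.25, 0.75), type = 7))),
    skewness = .moment_skewness(x),
    kurtosis = .moment_kurtosis(x),
    shannon_entropy = .shannon_entropy(x, entropy_bins),
    pct_low = {
      lo <- if (is.null(thresholds)) quantile(x, 0.10, type = 7) else thresholds$low
      100 * mean(x < lo)
    },
    pct_high = {
      hi <- if (is.null(thresholds)) quantile(x, 0.90, type = 7) else thresholds$high
      100 * mean(x > hi)
    },
    max = max(x),
    sum = sum(x)
  )
}

# Moment-based skewness, 0 for zero-variance input.
.moment_skewness <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# Moment-based excess kurtosis, 0 for zero-variance input.
.moment_kurtosis <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}

# Histogram Shannon entropy in bits; 0 for constant fields.
.shannon_entropy <- function(x, bins = 64L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  cnt <- tabulate(findInterval(x, brk, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log2(p))
}

#' Enumerate the biomarker catalogue
#'
#' Builds the ordered catalogue of biomarker definitions: every statistic
#' crossed with every source field (one expansion field, one flow field per
#' time interval, one oscillation field per variant). The default
#' configuration (11 statistics, 9 intervals, 4 variants) yields the
#' 154-entry bank: 11 expansion + 99 flow + 44 oscillation.
#'
#' @param statistics Character vector of statistic ids.
#' @param n_intervals Number of flow time intervals.
#' @param n_variants Number of oscillation variants.
#' @return Tibble with columns `biomarker_id` (1-based, stable),
#'   `source` (`expansion`/`flow`/`oscillation`), `source_id` (interval or
#'   variant id, `NA` for expansion), `statistic`, and `name`
#'   (`<source>_<interval/variant>_<statistic>`).
#' @export
enumerate_bank <- function(statistics = statistic_ids(),
                           n_intervals = 9L, n_variants = 4L) {
  if (anyDuplicated(statistics)) stop("duplicate statistic ids")
  statistics <- vapply(statistics, match.arg, "", choices = statistic_ids())
  src <- rbind(
    data.frame(source = "expansion", source_id = NA_integer_,
               field = "expansion"),
    if (n_intervals > 0) data.frame(
      source = "flow", source_id = seq_len(n_intervals),
      field = paste0("flow_i", seq_len(n_intervals))),
    if (n_variants > 0) data.frame(
      source = "oscillation", source_id = seq_len(n_variants),
      field = paste0("osc_v", seq_len(n_variants)))
  )
  out <- do.call(rbind, lapply(seq_len(nrow(src)), function(i) {
    data.frame(source = src$source[i], source_id = src$source_id[i],
               field = src$field[i], statistic = statistics,
               stringsAsFactors = FALSE)
  }))
  out$biomarker_id <- seq_len(nrow(out))
  out$name <- ifelse(
    out$source == "expansion",
    paste0("expansion_", out$statistic),
    paste0(out$field, "_", out$statistic)
  )
  tibble::as_tibble(out[, c("biomarker_id", "source", "source_id",
                            "field", "statistic", "name")])
}

#' Pooled-control reference thresholds for pct_low / pct_high
#'
#' Pools the voxel values of each source field across the supplied (control)
#' subjects and returns the per-field quantile cut-offs against which
#' `pct_low` / `pct_high` are scored for every subject.
#'
#' @param field_sets List of `derived_field_set`s from control subjects.
#' @param probs Length-2 vector of low/high quantiles (default 10th/90th).
#' @return Named list (one element per source field) of `list(low=, high=)`.
#' @export
reference_thresholds <- function(field_sets, probs = c(0.10, 0.90)) {
  stopifnot(length(field_sets) > 0)
  fields <- names(field_sets[[1]])
  out <- lapply(fields, function(f) {
    pooled <- unlist(lapply(field_sets, function(s) s[[f]]$values),
                     use.names = FALSE)
    q <- quantile(pooled, probs, type = 7)
    list(low = unname(q[1]), high = unname(q[2]))
  })
  names(out) <- fields
  out
}

#' Extract one subject's biomarker vector
#'
#' Evaluates every catalogue entry on the subject's derived fields, in
#' catalogue order.
#'
#' @param field_set A `derived_field_set` from [derive_all()].
#' @param bank Catalogue from [enumerate_bank()].
#' @param thresholds Per-field reference thresholds from
#'   [reference_thresholds()], or `NULL` for self-referenced percentiles.
#' @param entropy_bins Histogram bins for the entropy statistic.
#' @return Named numeric vector of length `nrow(bank)`.
#' @export
extract_vector <- function(field_set, bank = enumerate_bank(),
                           thresholds = NULL, entropy_bins = 64L) {
  missing <- setdiff(unique(bank$field), names(field_set))
  if (length(missing) > 0) {
    stop("missing source field(s): ", paste(missing, collapse = ", "))
  }
  vals <- vapply(seq_len(nrow(bank)), function(i) {
    f <- bank$field[i]
    summarize_field(field_set[[f]], bank$statistic[i],
                    thresholds = thresholds[[f]], entropy_bins = entropy_bins)
  }, numeric(1))
  names(vals) <- bank$name
  vals
}

#' Build a cohort biomarker table
#'
#' Simulates (or accepts) per-subject displacement fields, derives the scalar
#' fields, anchors the `pct_low`/`pct_high` cut-offs to the pooled control
#' distribution, and assembles the subjects-by-biomarkers table used by the
#' composite search.
#'
#' @param n_per_group Named list of subject counts per group (as in
#'   [simulate_cohort()]).
#' @param master_seed Integer master seed.
#' @param shape,n_phases Lattice dimensions and phase count.
#' @param phenotypes Named list of [phenotype_config()]s.
#' @param bank Catalogue from [enumerate_bank()].
#' @return List with `cohort` (tibble: subject_id, group_label,
#'   fev1_pct_pred, severity, then one column per biomarker), `bank`, and
#'   `thresholds`.
#' @export
cohort_biomarkers <- function(n_per_group, master_seed = 1L,
                              shape = c(24L, 24L, 24L), n_phases = 7L,
                              phenotypes = default_phenotypes(),
                              bank = enumerate_bank()) {
  plan <- .cohort_plan(n_per_group, master_seed, phenotypes)
  field_sets <- vector("list", length(plan))
  recs <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    s <- simulate_subject(plan[[i]]$cfg, shape, n_phases, plan[[i]]$subject_id)
    field_sets[[i]] <- derive_all(s$field)
    recs[[i]] <- s$record
  }
  records <- do.call(rbind, recs)
  ctrl <- which(records$group_label == "control")
  ref <- if (length(ctrl) > 0) field_sets[ctrl] else field_sets
  thresholds <- reference_thresholds(ref)
  mat <- t(vapply(field_sets, extract_vector, numeric(nrow(bank)),
                  bank = bank, thresholds = thresholds))
  cohort <- tibble::as_tibble(cbind(records, tibble::as_tibble(mat)))
  list(cohort = cohort, bank = bank, thresholds = thresholds)
}

#' Named biomarkers of the 4DH analyses
#'
#' Maps the named composite-constituent biomarkers onto catalogue entries:
#' VhiP (high ventilation volume percentage) = expansion pct_high; OVIhi
#' (oscillation ventilation index, high region) = oscillation-v2 pct_high;
#' SumFH (sum of flow heterogeneity) = whole-breath flow sd; VDS
#' (ventilation distribution skewness) = expansion skewness; FHmax = whole-
#' breath flow max; FDE (Shannon entropy of airflow distribution) =
#' whole-breath flow entropy; OVI_g1 / OVI_g2 = oscillation-v2 skewness /
#' kurtosis; SumF_muIQR = product of whole-breath flow mean and iqr.
#'
#' @return Named list; each element is a character vector of one or two
#'   catalogue `name`s (two = product).
#' @export
named_biomarker_map <- function() {
  list(
    VhiP = "expansion_pct_high",
    OVIhi = "osc_v2_pct_high",
    SumFH = "flow_i9_sd",
    VDS = "expansion_skewness",
    FHmax = "flow_i9_max",
    FDE = "flow_i9_shannon_entropy",
    OVI_g1 = "osc_v2_skewness",
    OVI_g2 = "osc_v2_kurtosis",
    SumF_muIQR = c("flow_i9_mean", "flow_i9_iqr")
  )
}

#' Resolve a named biomarker on a cohort table
#'
#' @param name One of the names in [named_biomarker_map()].
#' @param cohort Cohort tibble from [cohort_biomarkers()].
#' @return Numeric vector, one value per subject (product of the two
#'   catalogue columns for `SumF_muIQR`).
#' @export
resolve_named <- function(name, cohort) {
  map <- named_biomarker_map()
  if (!name %in% names(map)) stop("unknown named biomarker: ", name)
  cols <- map[[name]]
  if (!all(cols %in% names(cohort))) {
    stop("cohort table lacks column(s): ", paste(cols, collapse = ", "))
  }
  if (length(cols) == 1L) cohort[[cols]] else cohort[[cols[1]]] * cohort[[cols[2]]]
}
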