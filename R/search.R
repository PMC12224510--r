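#' Binary contrast specification
#'
#' @param positive_group,negative_group Group labels; the positive group is
#'   the disease class scored as 1.
#' @return A `contrast_spec` list.
#' @export
contrast_spec <- function(positive_group, negative_group) {
  if (identical(positive_group, negative_group)) {
    stop("contrast groups must be disjoint")
  }
  structure(list(positive = positive_group, negative = negative_group),
            class = "contrast_spec")
}

#' ROC area under the curve
#'
#' Mann-Whitney convention: the probability that a random positive scores
#' above a random negative, with ties counted half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) class labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignments: n x repeats matrix of fold ids 1..k, each
# repeat shuffled with its own derived seed, class proportions preserved.
.make_folds <- function(y, k, repeats, seed) {
  n <- length(y)
  folds <- matrix(0L, n, repeats)
  for (r in seq_len(repeats)) {
    withr::with_seed(as.integer((seed + r) %% 2147483647), {
      for (cls in c(TRUE, FALSE)) {
        idx <- which(y == cls)
        idx <- idx[sample.int(length(idx))]
        folds[idx, r] <- rep_len(seq_len(k), length(idx))
      }
    })
  }
  folds
}

# Extract the contrast design from a cohort table: rows sorted by subject_id
# (so CV is invariant to input row order), labels, and the feature matrix.
.contrast_design <- function(cohort, contrast, feature_names) {
  stopifnot(inherits(contrast, "contrast_spec"))
  keep <- cohort$group_label %in% c(contrast$positive, contrast$negative)
  sub <- cohort[keep, , drop = FALSE]
  sub <- sub[order(sub$subject_id), , drop = FALSE]
  y <- sub$group_label == contrast$positive
  if (sum(y) == 0 || sum(!y) == 0) stop("both contrast groups must be present")
  missing <- setdiff(feature_names, names(sub))
  if (length(missing) > 0) {
    stop("cohort lacks feature column(s): ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(sub[, feature_names, drop = FALSE])
  list(data = sub, y = y, X = X)
}

# Map integer biomarker ids to catalogue column names; pass names through.
.feature_names <- function(features, bank) {
  if (is.numeric(features)) bank$name[match(features, bank$biomarker_id)]
  else as.character(features)
}

#' Repeated stratified cross-validated AUC of a biomarker subset
#'
#' For each repeat, subjects are reshuffled with a repeat-specific derived
#' seed and split into `k` class-stratified folds; a ridge-penalized logistic
#' decision boundary is fitted on the training folds (features standardized
#' with training-fold means/sds only) and scored by ROC AUC on the held-out
#' fold. Returns all `k * repeats` fold-level AUCs.
#'
#' @param cohort Cohort tibble (see [cohort_biomarkers()]).
#' @param features Biomarker column names, or integer catalogue ids.
#' @param contrast A [contrast_spec()].
#' @param k Number of folds (default 3).
#' @param repeats Number of CV repeats (default 100).
#' @param seed Integer seed.
#' @param lambda Ridge penalty on standardized slopes (default 1e-4).
#' @param bank Catalogue used to resolve integer ids.
#' @return List with `auc_mean`, `auc_sd`, `fold_aucs`.
#' @export
cv_auc <- function(cohort, features, contrast, k = 3L, repeats = 100L,
                   seed = 1L, lambda = 1e-4, bank = enumerate_bank()) {
  stopifnot(k >= 2, repeats >= 1)
  fn <- .feature_names(features, bank)
  des <- .contrast_design(cohort, contrast, fn)
  if (min(sum(des$y), sum(!des$y)) < k) {
    stop("each class needs at least k subjects for stratified ", k, "-fold CV")
  }
  folds <- .make_folds(des$y, k, repeats, seed)
  aucs <- .cv_fold_aucs_cpp(des$X, as.numeric(des$y), folds, k, lambda)
  list(auc_mean = mean(aucs), auc_sd = stats::sd(aucs), fold_aucs = aucs)
}

#' Count the composite-biomarker candidate space
#'
#' `sum_{r=1..max_dim} C(n, r)` in exact integer arithmetic. For the default
#' 154-biomarker bank and dimension 4 this is 23,141,965.
#'
#' @param n Number of individual biomarkers.
#' @param max_dim Maximum composite dimension.
#' @return The exact count (numeric; integer-valued).
#' @export
count_composites <- function(n, max_dim) {
  if (n < 1 || max_dim < 1 || max_dim > n) stop("invalid arguments")
  sum(choose(n, seq_len(max_dim)))
}

# Rank candidate results: auc_mean desc, then smaller dimension, then
# lexicographic biomarker ids.
.rank_candidates <- function(dims, ids_list, auc_mean) {
  key <- vapply(ids_list, function(v) paste(sprintf("%05d", v), collapse = "-"), "")
  order(-auc_mean, dims, key)
}

#' Search composite biomarkers by cross-validated AUC
#'
#' Ranks feature subsets of dimension up to `max_dim` by the mean fold-level
#' CV AUC of their logistic decision boundary. When the full candidate space
#' is no larger than `budget` the search is exhaustive; otherwise a staged
#' beam search screens all singletons, then repeatedly expands the top
#' `beam` subsets of each dimension by one feature.
#'
#' @inheritParams cv_auc
#' @param max_dim Maximum composite dimension (1-4).
#' @param budget Exhaustive-enumeration cap on candidate count.
#' @param beam Beam width of the staged search.
#' @param top Number of ranked composites to return.
#' @param screen_repeats CV repeats used while screening beam-expansion
#'   candidates in the staged search; survivors (the top candidates of each
#'   dimension) are then confirmed at the full `repeats` before ranking.
#'   Singletons are always evaluated at full `repeats`, and the exhaustive
#'   mode never screens.
#' @return Tibble of class `composite_search`: `rank`, `dim`,
#'   `biomarker_ids` (list-column of catalogue ids), `features`
#'   (collapsed names), `auc_mean`, `auc_sd`. Attributes `n_evaluated` and
#'   `candidate_space` record the search scale.
#' @export
search_composites <- function(cohort, contrast, max_dim = 4L, k = 3L,
                              repeats = 100L, seed = 1L, lambda = 1e-4,
                              budget = 20000L, beam = 25L, top = 200L,
                              screen_repeats = 15L,
                              bank = enumerate_bank()) {
  stopifnot(max_dim >= 1, max_dim <= 4)
  feat <- intersect(bank$name, names(cohort))
  P <- length(feat)
  if (P < 1) stop("no catalogue features found in cohort")
  if (budget < P) stop("`budget` must cover at least the ", P, " singletons")
  des <- .contrast_design(cohort, contrast, feat)
  if (min(sum(des$y), sum(!des$y)) < k) {
    stop("each class needs at least k subjects for stratified ", k, "-fold CV")
  }
  screen_repeats <- min(screen_repeats, repeats)
  folds <- .make_folds(des$y, k, repeats, seed)
  yv <- as.numeric(des$y)

  eval_cands <- function(id_list, n_rep) {
    cm <- matrix(0L, max_dim, length(id_list))
    for (i in seq_along(id_list)) cm[seq_along(id_list[[i]]), i] <- id_list[[i]]
    .cv_eval_many_cpp(des$X, yv, cm, folds[, seq_len(n_rep), drop = FALSE],
                      k, lambda)
  }

  space <- count_composites(P, max_dim)
  exhaustive <- space <= budget
  n_screened <- 0L
  if (exhaustive) {
    cand <- unlist(lapply(seq_len(max_dim), function(d) {
      combn(P, d, simplify = FALSE)
    }), recursive = FALSE)
    final_ids <- cand
    final_res <- eval_cands(cand, repeats)
    n_screened <- length(cand)
  } else {
    # full-repeat evaluation of every singleton
    singles <- lapply(seq_len(P), function(i) i)
    res1 <- eval_cands(singles, repeats)
    n_screened <- P
    # staged beam expansion at screening repeats
    frontier <- singles[order(-res1[, 1])][seq_len(min(beam, P))]
    screened_ids <- list(); screened_res <- NULL
    d <- 1L
    while (d < max_dim) {
      d <- d + 1L
      cand_env <- new.env(parent = emptyenv())
      cand <- list()
      for (s in frontier) {
        for (j in setdiff(seq_len(P), s)) {
          ids <- sort(c(s, j))
          key <- paste(ids, collapse = "-")
          if (is.null(cand_env[[key]])) {
            cand_env[[key]] <- TRUE
            cand[[length(cand) + 1L]] <- ids
          }
        }
      }
      res_d <- eval_cands(cand, screen_repeats)
      screened_ids <- c(screened_ids, cand)
      screened_res <- rbind(screened_res, res_d)
      n_screened <- n_screened + length(cand)
      frontier <- cand[order(-res_d[, 1])][seq_len(min(beam, length(cand)))]
    }
    # confirm survivors at full repeats: the overall top plus the best of
    # each dimension, so the final ranking never rests on screening AUCs
    sdims <- lengths(screened_ids)
    pick <- order(-screened_res[, 1])[seq_len(min(top, length(screened_ids)))]
    for (d in unique(sdims)) {
      idx_d <- which(sdims == d)
      pick <- union(pick, idx_d[order(-screened_res[idx_d, 1])][
        seq_len(min(10L, length(idx_d)))])
    }
    confirm_ids <- screened_ids[pick]
    confirm_res <- if (screen_repeats == repeats) {
      screened_res[pick, , drop = FALSE]
    } else {
      eval_cands(confirm_ids, repeats)
    }
    final_ids <- c(singles, confirm_ids)
    final_res <- rbind(res1, confirm_res)
  }

  dims <- lengths(final_ids)
  ord <- .rank_candidates(dims, final_ids, final_res[, 1])
  keep <- ord[seq_len(min(top, length(ord)))]
  bank_ids <- bank$biomarker_id[match(feat, bank$name)]
  out <- tibble::tibble(
    rank = seq_along(keep),
    dim = dims[keep],
    biomarker_ids = lapply(final_ids[keep], function(v) bank_ids[v]),
    features = vapply(final_ids[keep], function(v) paste(feat[v], collapse = " + "), ""),
    auc_mean = final_res[keep, 1],
    auc_sd = final_res[keep, 2]
  )
  attr(out, "n_evaluated") <- n_screened
  # full singleton ranking (always evaluated at full repeats)
  sing <- which(dims == 1L)
  sing <- sing[order(-final_res[sing, 1])]
  attr(out, "singletons") <- tibble::tibble(
    feature = feat[unlist(final_ids[sing])],
    auc_mean = final_res[sing, 1],
    auc_sd = final_res[sing, 2]
  )
  attr(out, "best_by_dim") <- tibble::tibble(
    dim = seq_len(max_dim),
    best_auc_mean = vapply(seq_len(max_dim), function(d) {
      if (any(dims == d)) max(final_res[dims == d, 1]) else NA_real_
    }, numeric(1))
  )
  attr(out, "candidate_space") <- space
  attr(out, "exhaustive") <- exhaustive
  attr(out, "contrast") <- contrast
  class(out) <- c("composite_search", class(out))
  out
}

#' Fit the final 4DH decision boundary and score subjects
#'
#' Refits the ridge-penalized logistic decision boundary of a selected
#' composite on all contrast subjects (features standardized on the full
#' contrast data) and returns the four-dimensional ventilation heterogeneity
#' (4DH) score for every subject: the linear predictor `w . z + b` on
#' standardized biomarkers. The default abnormality threshold is the
#' Youden-optimal point of the full-data ROC; pass `threshold` to override
#' (e.g. an externally chosen operating point).
#'
#' @inheritParams cv_auc
#' @param threshold Optional fixed threshold; scores above it are called
#'   abnormal.
#' @return List with `features`, `weights` (named, standardized scale),
#'   `intercept`, `center`, `scale`, `threshold`, `auc` (full-data), and
#'   `scores`: tibble (subject_id, group_label, score, abnormal).
#' @export
fit_4dh <- function(cohort, features, contrast, threshold = NULL,
                    lambda = 1e-4, bank = enumerate_bank()) {
  fn <- .feature_names(features, bank)
  des <- .contrast_design(cohort, contrast, fn)
  ctr <- colMeans(des$X)
  scl <- apply(des$X, 2, stats::sd)
  scl[scl <= 0] <- 1
  Z <- sweep(sweep(des$X, 2, ctr), 2, scl, "/")
  beta <- .ridge_logistic_cpp(Z, as.numeric(des$y), lambda)
  intercept <- beta[1]
  weights <- beta[-1]
  names(weights) <- fn
  score <- as.numeric(intercept + Z %*% weights)
  if (is.null(threshold)) threshold <- .youden_threshold(score, des$y)
  tibble_scores <- tibble::tibble(
    subject_id = des$data$subject_id,
    group_label = des$data$group_label,
    score = score,
    abnormal = score > threshold
  )
  list(features = fn, weights = weights, intercept = intercept,
       center = ctr, scale = scl, threshold = threshold,
       auc = roc_auc(score, des$y), scores = tibble_scores)
}

# Youden-optimal threshold: midpoint cut maximizing sensitivity +
# specificity - 1, calling scores strictly above the threshold abnormal.
.youden_threshold <- function(score, y) {
  s <- sort(unique(score))
  cuts <- c(min(s) - 1, (head(s, -1) + s[-1]) / 2)
  j <- vapply(cuts, function(t) {
    mean(score[y] > t) + mean(score[!y] <= t) - 1
  }, numeric(1))
  cuts[which.max(j)]
}

#' Score new subjects with a fitted 4DH model
#'
#' @param model Result of [fit_4dh()].
#' @param cohort Cohort tibble containing the model's feature columns.
#' @param threshold Optional override of the model's threshold.
#' @return Tibble (subject_id, group_label, score, abnormal).
#' @export
score_4dh <- function(model, cohort, threshold = model$threshold) {
  X <- as.matrix(cohort[, model$features, drop = FALSE])
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  score <- as.numeric(model$intercept + Z %*% model$weights)
  tibble::tibble(
    subject_id = cohort$subject_id,
    group_label = cohort$group_label,
    score = score,
    abnormal = score > threshold
  )
}
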