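#' PCA of a subjects-by-features score matrix
#'
#' Principal component analysis of standardized biomarker (or composite
#' score) columns, returning per-subject coordinates on the leading
#' components and the explained-variance fractions.
#'
#' @param x Numeric matrix or data frame, subjects in rows, features in
#'   columns; no missing values.
#' @param n_components Number of components to return (default 2).
#' @param scale Scale columns to unit variance before decomposition
#'   (default `TRUE`; constant columns are dropped).
#' @return List with `coords` (matrix, subjects x components),
#'   `explained_variance` (fractions, non-increasing), and `sdev`.
#' @export
pca_top <- function(x, n_components = 2L, scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 3 || ncol(x) < 2) stop("PCA needs at least 3 subjects and 2 features")
  if (any(!is.finite(x))) stop("score matrix must have no missing values")
  keep <- apply(x, 2, stats::sd) > 0
  if (sum(keep) < 2) stop("score matrix is constant; PCA undefined")
  p <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = scale)
  ev <- p$sdev^2 / sum(p$sdev^2)
  nc <- min(n_components, ncol(p$x))
  list(coords = p$x[, seq_len(nc), drop = FALSE],
       explained_variance = ev[seq_len(nc)],
       sdev = p$sdev)
}

#' Two-sample comparison of scores between groups
#'
#' Classical two-sided Student's t-test (pooled variance by default,
#' Welch optional).
#'
#' @param scores Numeric vector.
#' @param groups Two-level grouping vector aligned with `scores`.
#' @param welch Use the Welch (unequal-variance) form.
#' @return List with `statistic`, `p_value`, `df`, `group_means`.
#' @export
group_compare <- function(scores, groups, welch = FALSE) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (any(table(groups) < 2)) stop("each group needs at least 2 subjects")
  tt <- t.test(scores ~ groups, var.equal = !welch)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       group_means = tapply(scores, groups, mean))
}

#' Pearson correlation with r-squared
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, non-zero variance.
#' @return List with `r`, `r_squared`, `p_value`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_value = ct$p.value)
}

#' Write the analysis report for a completed search
#'
#' Produces the standard analysis surfaces as CSV tables plus rendered
#' figures: PCA of the top individual biomarkers and of the top composite
#' scores, best CV-AUC by composite dimension, 4DH score distributions per
#' group, and 4DH score against FEV1 percent predicted. CSVs are
#' deterministic for a fixed cohort and search result.
#'
#' @param cohort Cohort tibble from [cohort_biomarkers()].
#' @param search_results A `composite_search` result.
#' @param out_dir Output directory (created if needed).
#' @param top_n Number of top biomarkers/composites entering the PCAs.
#' @param render_figures Also write PNG figures (default `TRUE`).
#' @return Named list of written file paths (the manifest), invisibly a
#'   list also carrying the computed summary statistics.
#' @export
report_results <- function(cohort, search_results, out_dir, top_n = 20L,
                           render_figures = TRUE) {
  if (nrow(search_results) == 0) stop("empty search results")
  contrast <- attr(search_results, "contrast")
  if (is.null(contrast)) stop("search results lack a contrast attribute")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  des <- .contrast_design(cohort, contrast,
                          intersect(enumerate_bank()$name, names(cohort)))
  sub <- des$data
  manifest <- list()

  # PCA of top individual biomarkers (ranked by their singleton CV AUC)
  singles <- attr(search_results, "singletons")
  feat1 <- if (!is.null(singles)) {
    head(singles$feature, top_n)
  } else {
    head(search_results$features[search_results$dim == 1], top_n)
  }
  pca1 <- pca_top(sub[, feat1, drop = FALSE])
  t1 <- tibble::tibble(
    subject_id = sub$subject_id, group_label = sub$group_label,
    pc1 = pca1$coords[, 1], pc2 = pca1$coords[, 2]
  )
  manifest$pca_single <- file.path(out_dir, "pca_single.csv")
  readr::write_csv(t1, manifest$pca_single)

  # PCA of top composite scores (one fitted linear score per composite)
  comps <- head(search_results, top_n)
  comp_scores <- vapply(seq_len(nrow(comps)), function(i) {
    m <- fit_4dh(cohort, comps$biomarker_ids[[i]], contrast)
    m$scores$score[match(sub$subject_id, m$scores$subject_id)]
  }, numeric(nrow(sub)))
  colnames(comp_scores) <- paste0("composite_", seq_len(ncol(comp_scores)))
  pca2 <- pca_top(comp_scores)
  t2 <- tibble::tibble(
    subject_id = sub$subject_id, group_label = sub$group_label,
    pc1 = pca2$coords[, 1], pc2 = pca2$coords[, 2]
  )
  manifest$pca_composite <- file.path(out_dir, "pca_composite.csv")
  readr::write_csv(t2, manifest$pca_composite)

  # best CV AUC at each composite dimension (over all evaluated candidates)
  auc_dim <- attr(search_results, "best_by_dim")
  if (is.null(auc_dim)) {
    dims <- seq_len(max(search_results$dim))
    auc_dim <- tibble::tibble(
      dim = dims,
      best_auc_mean = vapply(dims, function(d) {
        max(search_results$auc_mean[search_results$dim == d], -Inf)
      }, numeric(1))
    )
  }
  manifest$auc_by_dim <- file.path(out_dir, "auc_by_dim.csv")
  readr::write_csv(auc_dim, manifest$auc_by_dim)

  # 4DH scores from the top-ranked composite
  model <- fit_4dh(cohort, search_results$biomarker_ids[[1]], contrast)
  sc <- model$scores
  sc$fev1_pct_pred <- sub$fev1_pct_pred[match(sc$subject_id, sub$subject_id)]
  manifest$fourdh_scores <- file.path(out_dir, "fourdh_scores.csv")
  readr::write_csv(sc, manifest$fourdh_scores)

  cmp <- group_compare(sc$score, sc$group_label)
  cor_fev1 <- correlate(sc$score, sc$fev1_pct_pred)
  summary <- list(
    contrast = unclass(contrast),
    top_composite = search_results$features[1],
    top_auc_mean = search_results$auc_mean[1],
    threshold = model$threshold,
    t_statistic = cmp$statistic, t_p_value = cmp$p_value,
    fev1_r = cor_fev1$r, fev1_r_squared = cor_fev1$r_squared,
    pca_single_explained = pca1$explained_variance,
    pca_composite_explained = pca2$explained_variance
  )
  manifest$summary <- file.path(out_dir, "report_summary.json")
  jsonlite::write_json(summary, manifest$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  if (render_figures) {
    manifest <- c(manifest, .render_figures(t1, t2, auc_dim, sc, out_dir))
  }
  invisible(c(manifest, list(stats = summary)))
}

.render_figures <- function(t1, t2, auc_dim, sc, out_dir) {
  gg_save <- function(p, name) {
    path <- file.path(out_dir, name)
    ggplot2::ggsave(path, p, width = 5, height = 4, dpi = 120)
    path
  }
  pca_plot <- function(d, title) {
    ggplot2::ggplot(d, ggplot2::aes(.data$pc1, .data$pc2,
                                    colour = .data$group_label)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(title = title, x = "PC1", y = "PC2") +
      ggplot2::theme_minimal()
  }
  list(
    fig_pca_single = gg_save(pca_plot(t1, "Top individual biomarkers"),
                             "pca_single.png"),
    fig_pca_composite = gg_save(pca_plot(t2, "Top composite biomarkers"),
                                "pca_composite.png"),
    fig_auc_by_dim = gg_save(
      ggplot2::ggplot(auc_dim, ggplot2::aes(.data$dim, .data$best_auc_mean)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::labs(x = "composite dimension", y = "best CV AUC") +
        ggplot2::theme_minimal(),
      "auc_by_dim.png"),
    fig_fourdh_violin = gg_save(
      ggplot2::ggplot(sc, ggplot2::aes(.data$group_label, .data$score,
                                       fill = .data$group_label)) +
        ggplot2::geom_violin(alpha = 0.6) +
        ggplot2::geom_jitter(width = 0.08, size = 1.5) +
        ggplot2::labs(x = NULL, y = "4DH score") +
        ggplot2::theme_minimal() +
        ggplot2::theme(legend.position = "none"),
      "fourdh_violin.png"),
    fig_fourdh_fev1 = gg_save(
      ggplot2::ggplot(sc, ggplot2::aes(.data$fev1_pct_pred, .data$score,
                                       colour = .data$group_label)) +
        ggplot2::geom_point(size = 2) +
        ggplot2::labs(x = "FEV1 % predicted", y = "4DH score") +
        ggplot2::theme_minimal(),
      "fourdh_vs_fev1.png")
  )
}
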