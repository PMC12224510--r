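test_that("degenerate and tiny fields obey the statistic conventions", {
  cst <- rep(2.5, 100)
  expect_equal(summarize_field(cst, "sd"), 0)
  expect_equal(summarize_field(cst, "iqr"), 0)
  expect_equal(summarize_field(cst, "shannon_entropy"), 0)
  expect_equal(summarize_field(cst, "skewness"), 0)
  expect_equal(summarize_field(cst, "kurtosis"), 0)
  x <- c(1, 2, 3, 4, 5)
  expect_equal(summarize_field(x, "mean"), 3)
  expect_equal(summarize_field(x, "median"), 3)
  expect_equal(summarize_field(x, "max"), 5)
  expect_equal(summarize_field(x, "sum"), 15)
  expect_error(summarize_field(numeric(0), "mean"), "empty")
})

test_that("all eleven statistics match direct-formula oracles", {
  withr::with_seed(77, x <- c(rnorm(800), rexp(200)))
  n <- length(x)
  m <- mean(x)
  oracle <- list(
    mean = sum(x) / n,
    median = sort(x)[c(n / 2, n / 2 + 1)] |> mean(),
    sd = sqrt(sum((x - m)^2) / (n - 1)),
    iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)),
    skewness = (sum((x - m)^3) / n) / (sum((x - m)^2) / n)^1.5,
    kurtosis = (sum((x - m)^4) / n) / (sum((x - m)^2) / n)^2 - 3,
    max = max(x),
    sum = sum(x)
  )
  for (stat in names(oracle)) {
    expect_equal(summarize_field(x, stat), oracle[[stat]], tolerance = 1e-10,
                 label = stat)
  }
  # moment statistics also agree with e1071's moment-based (type 1) forms
  expect_equal(summarize_field(x, "skewness"), e1071::skewness(x, type = 1),
               tolerance = 1e-10)
  expect_equal(summarize_field(x, "kurtosis"), e1071::kurtosis(x, type = 1),
               tolerance = 1e-10)
  # entropy against an independent histogram implementation, same binning
  h <- hist(x, breaks = seq(min(x), max(x), length.out = 65), plot = FALSE)
  p <- h$counts[h$counts > 0] / n
  expect_equal(summarize_field(x, "shannon_entropy"), -sum(p * log2(p)),
               tolerance = 1e-10)
  # tail percentages against direct counting with explicit thresholds
  thr <- list(low = -1, high = 1.5)
  expect_equal(summarize_field(x, "pct_low", thr), 100 * sum(x < -1) / n)
  expect_equal(summarize_field(x, "pct_high", thr), 100 * sum(x > 1.5) / n)
})

test_that("tail percentages are self-consistent", {
  withr::with_seed(8, x <- rnorm(1000))
  pl <- summarize_field(x, "pct_low")
  ph <- summarize_field(x, "pct_high")
  expect_lte(pl + ph, 100)
  expect_equal(pl, 10, tolerance = 1)
  expect_equal(ph, 10, tolerance = 1)
})

test_that("statistics are permutation-invariant over voxels", {
  withr::with_seed(13, {
    x <- rnorm(500)
    xp <- sample(x)
  })
  thr <- list(low = -1, high = 1)
  for (stat in statistic_ids()) {
    expect_identical(summarize_field(x, stat, thr),
                     summarize_field(xp, stat, thr), label = stat)
  }
})

test_that("the catalogue enumerates 154 biomarkers with the 11/99/44 split", {
  bank <- enumerate_bank()
  expect_equal(nrow(bank), 154L)
  expect_equal(sum(bank$source == "expansion"), 11L)
  expect_equal(sum(bank$source == "flow"), 99L)
  expect_equal(sum(bank$source == "oscillation"), 44L)
  expect_identical(bank$biomarker_id, seq_len(154L))
  expect_equal(anyDuplicated(bank$name), 0L)
  # identical on re-enumeration (stable ids)
  expect_identical(bank, enumerate_bank())
})

test_that("catalogue size follows S * (1 + I + V) for reduced configs", {
  expect_equal(nrow(enumerate_bank(statistics = "mean")), 14L)
  expect_equal(nrow(enumerate_bank(n_intervals = 2L, n_variants = 1L)), 44L)
  withr::with_seed(3, {
    for (rep in 1:5) {
      S <- sample(1:11, 1); I <- sample(0:9, 1); V <- sample(0:4, 1)
      b <- enumerate_bank(statistics = sample(statistic_ids(), S),
                          n_intervals = I, n_variants = V)
      expect_equal(nrow(b), S * (1 + I + V))
    }
  })
  expect_error(enumerate_bank(statistics = c("mean", "mean")), "duplicate")
})

test_that("extraction is pure and matches closed forms", {
  f <- make_scaling_field(c(0.05, 0.1))
  fs <- derive_all(f, intervals = interval_specs(3))
  bank <- enumerate_bank(n_intervals = nrow(interval_specs(3)))
  v1 <- extract_vector(fs, bank)
  v2 <- extract_vector(fs, bank)
  expect_identical(v1, v2)
  expect_length(v1, nrow(bank))
  expect_equal(unname(v1["expansion_mean"]), 1.1^3 - 1, tolerance = 1e-12)
  expect_error(extract_vector(fs["expansion"], bank), "missing source")
})

test_that("full-bank subject vectors have length 154", {
  cb <- small_cohort()
  expect_equal(ncol(cb$cohort) - 5L, 154L) # 5 covariate columns
  expect_true(all(vapply(cb$cohort[, cb$bank$name],
                         function(x) all(is.finite(x)), TRUE)))
})

test_that("named biomarkers resolve onto the catalogue", {
  cb <- small_cohort()
  map <- named_biomarker_map()
  for (nm in names(map)) {
    expect_true(all(is.finite(resolve_named(nm, cb$cohort))), label = nm)
  }
  toy <- tibble::tibble(flow_i9_mean = c(2, -1), flow_i9_iqr = c(3, 4))
  expect_equal(resolve_named("SumF_muIQR", toy), c(6, -4))
  expect_error(resolve_named("nope", toy), "unknown named biomarker")
  # VhiP on its own reference distribution sits near the cut quantile
  ctrl <- cb$cohort$group_label == "control"
  expect_equal(mean(resolve_named("VhiP", cb$cohort)[ctrl]), 10, tolerance = 5)
})

test_that("planted emphysema produces a right-skewed expansion field", {
  cfg <- phenotype_config("copd_gold34", severity = 1, n_blobs = 0L,
                          emphysema_frac = 0.15, noise_sd = 0, seed = 5L)
  s <- simulate_subject(cfg)
  e <- compute_expansion(s$field)
  expect_gt(summarize_field(e, "skewness"), 0)
})
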