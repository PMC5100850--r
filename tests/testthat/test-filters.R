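# Crossover and marker quality-control filters.

test_that("probability filter uses a strict threshold", {
  calls <- toy_calls(probability = c(0.4, 0.5, 0.51, 0.9),
                     meiosis = c("m1", "m2", "m3", "m4"))
  res <- filter_low_probability_calls(calls)
  expect_equal(res$calls$probability, c(0.51, 0.9))
  expect_equal(res$report$n_removed + res$report$n_surviving, res$report$n_in)

  all_one <- toy_calls(probability = rep(1, 5), meiosis = paste0("m", 1:5))
  expect_equal(filter_low_probability_calls(all_one)$report$n_removed, 0L)

  expect_error(filter_low_probability_calls(data.frame(chrom = "chr1")),
               "probability")
})

test_that("probability filter removes exactly the below-threshold subset", {
  set.seed(21)
  p <- c(runif(90, 0.51, 1), runif(10, 0, 0.49))
  calls <- toy_calls(probability = p, meiosis = sprintf("m%03d", 1:100))
  res <- filter_low_probability_calls(calls)
  expect_equal(res$report$n_removed, 10L)
  expect_true(all(res$calls$probability > 0.5))
})

test_that("blacklist filter removes overlapping records only", {
  cfg0 <- filter_config(blacklist_regions = NULL)
  calls <- toy_calls(probability = 0.9, meiosis = c("m1", "m2"),
                     left = c(1e6, 2e6), right = c(1.5e6, 2.5e6))
  expect_equal(nrow(filter_blacklist_regions(calls, cfg0)$calls), 2L)

  cfg <- filter_config(blacklist_regions = data.frame(
    chrom = "chr1", start = 10.3e6, end = 11e6))
  hit <- toy_calls(probability = 0.9, left = 10.2e6, right = 10.4e6)
  expect_equal(nrow(filter_blacklist_regions(hit, cfg)$calls), 0L)

  # exhaustive-oracle comparison on a random fixture
  set.seed(22)
  n <- 20L
  l <- runif(n, 0, 9e7); r <- l + runif(n, 1e4, 1e6)
  calls2 <- toy_calls(probability = 0.9, meiosis = sprintf("m%02d", 1:n),
                      left = l, right = r)
  bl <- data.frame(chrom = "chr1",
                   start = c(1e7, 4e7, 7e7), end = c(1.2e7, 4.5e7, 7.05e7))
  manual_hit <- vapply(seq_len(n), function(i) {
    any(l[i] < bl$end & r[i] > bl$start)
  }, logical(1L))
  res <- filter_blacklist_regions(calls2, filter_config(blacklist_regions = bl))
  expect_equal(nrow(res$calls), sum(!manual_hit))
  expect_setequal(res$report$removed_ids, which(manual_hit))
})

test_that("clustered double crossovers are removed only with shared boundaries", {
  pair <- function(m, par, base) {
    toy_calls(probability = 0.9, meiosis = rep(m, 2), parent = par,
              left = c(base, base + 3e5), right = c(base + 1e5, base + 4e5))
  }
  # two children of one parent share boundary coordinates: all 4 removed
  both <- rbind(pair("m1", "P", 10.4e6), pair("m2", "P", 10.4e6))
  res <- filter_clustered_double_crossovers(both)
  expect_equal(res$report$n_removed, 4L)
  expect_equal(nrow(res$calls), 0L)

  # a single meiosis with a clustered pair is retained
  single <- pair("m1", "P", 10.4e6)
  expect_equal(filter_clustered_double_crossovers(single)$report$n_removed, 0L)

  # clustered pairs of one parent without shared boundaries are retained
  nosh <- rbind(pair("m1", "P", 10.4e6), pair("m2", "P", 30.0e6))
  expect_equal(filter_clustered_double_crossovers(nosh)$report$n_removed, 0L)

  # pairs separated by more than the clustering distance are not flagged
  far <- rbind(
    toy_calls(probability = 0.9, meiosis = rep("m1", 2), parent = "P",
              left = c(1e6, 4e6), right = c(1.1e6, 4.1e6)),
    toy_calls(probability = 0.9, meiosis = rep("m2", 2), parent = "P",
              left = c(1e6, 4e6), right = c(1.1e6, 4.1e6)))
  expect_equal(filter_clustered_double_crossovers(far)$report$n_removed, 0L)
})

test_that("double-crossover filter is sensitive and specific on synthetic truth", {
  cfg <- small_sim_config(seed = 23L, n = 30L, chroms = 3L)
  tr <- simulate_crossovers(cfg)
  obs <- censor_informative_spans(tr, cfg)
  calls <- inject_artifacts(obs$calls, cfg, meioses = tr$meioses,
                            n_clusters = 6L, n_outliers = 0L)
  res <- filter_clustered_double_crossovers(calls)
  removed <- calls[calls$call_id %in% res$report$removed_ids, ]
  art <- calls[!calls$genuine, ]
  sens <- sum(!removed$genuine) / nrow(art)
  false_rate <- sum(removed$genuine) / sum(calls$genuine)
  expect_gte(sens, 0.95)
  expect_lte(false_rate, 0.01)
})

test_that("robust MAD outlier filter matches the hand computation", {
  b <- outlier_bounds(c(12, 13, 13, 14, 15, 30))
  expect_equal(unname(b["median"]), 13.5)
  expect_equal(unname(b["sd"]), 1.4826)
  expect_equal(unname(b["lower"]), 13.5 - 4 * 1.4826)
  expect_equal(unname(b["upper"]), 13.5 + 4 * 1.4826)

  counts <- c(12, 13, 13, 14, 15, 30)
  calls <- do.call(rbind, lapply(seq_along(counts), function(i) {
    toy_calls(probability = 0.9,
              meiosis = rep(sprintf("m%d", i), counts[i]),
              left = seq(1e6, by = 2e6, length.out = counts[i]),
              right = seq(1.1e6, by = 2e6, length.out = counts[i]))
  }))
  res <- filter_outlier_meioses(calls)
  expect_equal(res$report$details$female$excluded$meiosis_id, "m6")
  expect_equal(res$report$n_removed, 30L)
})

test_that("equal counts exclude nothing and MAD = 0 falls back gracefully", {
  calls <- do.call(rbind, lapply(1:5, function(i) {
    toy_calls(probability = 0.9, meiosis = rep(sprintf("m%d", i), 10),
              left = seq(1e6, by = 2e6, length.out = 10),
              right = seq(1.1e6, by = 2e6, length.out = 10))
  }))
  res <- filter_outlier_meioses(calls)
  expect_equal(res$report$n_removed, 0L)

  expect_warning(filter_outlier_meioses(toy_calls(probability = 0.9)),
                 "fewer than 2")
})

test_that("genotype QC excludes missingness, Mendelian and error-flag markers", {
  mk <- data.frame(marker_id = sprintf("snp%03d", 1:10),
                   missing_fraction = c(0.051, 0.050, rep(0.01, 8)),
                   error_prob = c(rep(0, 9), 0.95))
  duo <- data.frame(marker_id = c("snp003", "snp004"),
                    duo_id = "d1",
                    parent_gt = c("AA", "AB"), child_gt = c("BB", "BB"))
  res <- genotype_qc(mk, duo)
  expect_setequal(res$exclude, c("snp001", "snp003", "snp010"))

  # planted-truth oracle on a larger panel
  set.seed(24)
  n <- 1000L
  mk2 <- data.frame(marker_id = sprintf("m%04d", seq_len(n)),
                    missing_fraction = 0.0)
  bad <- sample.int(n, 30L)
  duo2 <- data.frame(marker_id = mk2$marker_id[bad], duo_id = "d1",
                     parent_gt = "AA", child_gt = "BB")
  res2 <- genotype_qc(mk2, duo2)
  expect_setequal(res2$exclude, mk2$marker_id[bad])
})

test_that("filters are idempotent and probability/blacklist commute", {
  cfg <- small_sim_config(seed = 25L, n = 20L, chroms = 2L)
  ds <- simulate_dataset(cfg)
  fc <- filter_config(blacklist_regions = data.frame(
    chrom = "chr1", start = 3e7, end = 3.3e7))

  f1 <- filter_low_probability_calls(ds$calls, fc)
  f1b <- filter_low_probability_calls(f1$calls, fc)
  expect_equal(f1b$calls, f1$calls)

  f2 <- filter_clustered_double_crossovers(ds$calls, fc)
  f2b <- filter_clustered_double_crossovers(f2$calls, fc)
  expect_equal(f2b$calls, f2$calls)

  f3 <- filter_outlier_meioses(ds$calls, fc)
  f3b <- filter_outlier_meioses(f3$calls, fc)
  expect_equal(f3b$calls, f3$calls)

  ab <- filter_blacklist_regions(filter_low_probability_calls(ds$calls, fc)$calls, fc)
  ba <- filter_low_probability_calls(filter_blacklist_regions(ds$calls, fc)$calls, fc)
  expect_equal(ab$calls[order(ab$calls$call_id), ],
               ba$calls[order(ba$calls$call_id), ])
})

test_that("an injected outlier meiosis is removed end to end", {
  cfg <- small_sim_config(seed = 26L, n = 30L, chroms = 3L)
  tr <- simulate_crossovers(cfg)
  obs <- censor_informative_spans(tr, cfg)
  calls <- inject_artifacts(obs$calls, cfg, meioses = tr$meioses,
                            n_clusters = 0L, n_outliers = 1L)
  out_id <- unique(calls$meiosis_id[!calls$genuine])
  expect_length(out_id, 1L)
  res <- filter_outlier_meioses(calls)
  expect_false(out_id %in% res$calls$meiosis_id)
})
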