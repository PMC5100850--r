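# Interference likelihoods and model fitting.

test_that("genetic-scale placement integrates the map correctly", {
  u <- uniform_map(len_bp = 1e8, rate = 1)      # 1 cM/Mb, 100 cM total
  calls <- toy_calls(probability = 1, left = 4.9e7, right = 5.1e7)
  xs <- to_genetic_scale(calls, u)
  expect_equal(xs$events$pos, 0.5)              # midpoint 50 Mb -> 0.5 Morgans
  expect_equal(xs$seqs$L, 1)

  two <- genetic_map(data.frame(chrom = "chr1", start = c(0, 5e7),
                                end = c(5e7, 1e8), cM = c(100, 1e-9)))
  calls2 <- toy_calls(probability = 1, left = 7.4e7, right = 7.6e7)
  xs2 <- to_genetic_scale(calls2, two)
  expect_equal(xs2$events$pos, 1.0, tolerance = 1e-6)

  # zero-event meioses are retained as k = 0 sequences
  roster <- data.frame(meiosis_id = c("P1_C1", "P2_C2"),
                       parent_sex = "female")
  xs3 <- to_genetic_scale(calls, u, meioses = roster)
  expect_equal(nrow(xs3$seqs), 2L)
  expect_equal(sort(xs3$seqs$k), c(0L, 1L))
})

test_that("gamma likelihood reduces to the Poisson process at nu = 1", {
  xs0 <- xo_sequences(data.frame(seq_id = "a", L = 1))
  expect_equal(gamma_loglik(xs0, 1), -1.0, tolerance = 1e-9)

  xs2 <- xo_sequences(data.frame(seq_id = "a", L = 1),
                      data.frame(seq_id = c("a", "a"), pos = c(0.11, 0.83)))
  expect_equal(gamma_loglik(xs2, 1), -1.0, tolerance = 1e-9)

  set.seed(51)
  for (i in 1:10) {
    xs <- random_sequences()
    expect_equal(gamma_loglik(xs, 1), -sum(xs$seqs$L), tolerance = 1e-9)
  }
})

test_that("gamma-escape likelihood degenerates correctly at p = 0 and p = 1", {
  set.seed(52)
  for (i in 1:25) {
    xs <- random_sequences()
    nu <- exp(runif(1, log(0.5), log(40)))
    expect_equal(gamma_escape_loglik(xs, nu, 0), gamma_loglik(xs, nu),
                 tolerance = 1e-9)
  }
  xs0 <- xo_sequences(data.frame(seq_id = "a", L = 1))
  expect_equal(gamma_escape_loglik(xs0, 5, 1), -1.0, tolerance = 1e-9)
  # escape superposed on a nu = 1 pathway is still the unit Poisson process
  xs <- random_sequences()
  expect_equal(gamma_escape_loglik(xs, 1, 0.4), -sum(xs$seqs$L),
               tolerance = 1e-9)
})

test_that("the enumeration cap raises an informative error", {
  xs <- xo_sequences(data.frame(seq_id = "a", L = 10),
                     data.frame(seq_id = "a", pos = seq(0.1, 9.9, length.out = 25)))
  expect_error(gamma_escape_loglik(xs, 5, 0.1), "enumeration cap")
})

test_that("likelihood is a proper density on short intervals", {
  for (par in list(c(1, 0), c(4.5, 0), c(4.5, 0.1), c(12, 0.05))) {
    nu <- par[1]; p <- par[2]
    L <- 0.05
    lik1 <- function(x) {
      vapply(x, function(xi) {
        exp(gamma_escape_loglik(
          xo_sequences(data.frame(seq_id = "s", L = L),
                       data.frame(seq_id = "s", pos = xi)), nu, p))
      }, numeric(1L))
    }
    lik2_inner <- function(xi) {
      stats::integrate(function(y) {
        vapply(y, function(yi) {
          exp(gamma_escape_loglik(
            xo_sequences(data.frame(seq_id = "s", L = L),
                         data.frame(seq_id = c("s", "s"), pos = c(xi, yi))),
            nu, p))
        }, numeric(1L))
      }, xi, L)$value
    }
    p0 <- exp(gamma_escape_loglik(
      xo_sequences(data.frame(seq_id = "s", L = L)), nu, p))
    p1 <- stats::integrate(lik1, 0, L)$value
    p2 <- stats::integrate(function(x) vapply(x, lik2_inner, numeric(1L)),
                           0, L)$value
    expect_lt(abs(p0 + p1 + p2 - 1), 1e-4)
  }
})

test_that("simulated inter-crossover spacings match the model density", {
  set.seed(53)
  nu <- 5
  arr <- canrec:::renewal_arrivals(400, nu, 2 * nu)
  xo <- arr[stats::rbinom(length(arr), 1L, 0.5) == 1L]
  gaps <- diff(xo)
  cdf <- function(q) canrec:::thinned_cdf(q, nu, 2 * nu,
                                          canrec:::mixture_terms(nu, 2 * nu, max(q)))
  ks <- suppressWarnings(stats::ks.test(gaps, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("BIC follows its definition and model comparison uses it", {
  xs <- xo_sequences(
    data.frame(seq_id = sprintf("s%02d", 1:50),
               meiosis_id = sprintf("m%02d", 1:50), L = rep(0.8, 50)),
    data.frame(seq_id = "s01", pos = 0.4))
  f <- fit_interference(xs, "gamma", bootstrap_n = 0)
  expect_equal(f$bic, -2 * f$logL + log(50))

  fake_g <- structure(list(model = "gamma", bic = -2 * (-100) + 1 * log(50),
                           n = 50L), class = "interference_fit")
  fake_e <- structure(list(model = "gamma_escape",
                           bic = -2 * (-100) + 2 * log(50), n = 50L),
                      class = "interference_fit")
  expect_equal(fake_e$bic, 200 + 2 * log(50))   # 207.824
  cmpr <- compare_models(fake_g, fake_e)
  expect_equal(cmpr$preferred, "gamma")          # same logL: fewer params win
  fake_e$n <- 40L
  expect_error(compare_models(fake_g, fake_e), "different numbers")
})

test_that("the gamma MLE recovers the generating shape", {
  cfg <- sim_config(n_meioses_per_sex = c(female = 120, male = 0),
                    chrom_lengths = canfam_autosomes()[1:8, ],
                    total_cM = c(female = 700, male = 600),
                    nu = 5, p_escape = 0,
                    telomere_bias = list(window_bp = 5e6, female = NA, male = NA),
                    censor_fraction = 0, seed = 54L)
  xs <- true_sequences(simulate_crossovers(cfg))
  fit <- fit_interference(xs, "gamma", bootstrap_n = 0)
  expect_lt(abs(fit$nu - 5) / 5, 0.25)

  # bootstrap CI brackets the point estimate and the truth at this seed
  fit_b <- fit_interference(xs, "gamma", bootstrap_n = 30, seed = 55L)
  expect_true(fit_b$ci$nu[1] <= fit_b$nu && fit_b$nu <= fit_b$ci$nu[2])
  expect_true(fit_b$ci$nu[1] <= 5 && 5 <= fit_b$ci$nu[2])
})

test_that("joint escape-model MLE recovers both parameters approximately", {
  cfg <- sim_config(n_meioses_per_sex = c(female = 90, male = 0),
                    chrom_lengths = canfam_autosomes()[1:8, ],
                    total_cM = c(female = 700, male = 600),
                    nu = 10, p_escape = 0.1,
                    telomere_bias = list(window_bp = 5e6, female = NA, male = NA),
                    censor_fraction = 0, seed = 56L)
  xs <- true_sequences(simulate_crossovers(cfg))
  fit <- fit_interference(xs, "gamma_escape", bootstrap_n = 0)
  expect_gt(fit$nu, 5); expect_lt(fit$nu, 25)
  expect_gt(fit$p, 0.02); expect_lt(fit$p, 0.25)
  # the fitted likelihood cannot be below the likelihood at the truth
  expect_gte(fit$logL, gamma_escape_loglik(xs, 10, 0.1) - 1e-6)
})

test_that("stratified fits split by labels and by quantile bins", {
  cfg <- sim_config(n_meioses_per_sex = c(female = 60, male = 0),
                    chrom_lengths = canfam_autosomes()[1:6, ],
                    total_cM = c(female = 500, male = 400),
                    nu = c(female = 3, male = 3), p_escape = 0,
                    telomere_bias = list(window_bp = 5e6, female = NA, male = NA),
                    censor_fraction = 0, seed = 57L)
  xs <- true_sequences(simulate_crossovers(cfg))
  mids <- unique(xs$seqs$meiosis_id)

  one <- setNames(rep("all", length(mids)), mids)
  s1 <- stratified_fit(xs, one, model = "gamma", bootstrap_n = 0)
  f <- fit_interference(xs, "gamma", bootstrap_n = 0)
  expect_equal(s1$all$nu, f$nu, tolerance = 1e-6)

  ages <- setNames(seq_along(mids), mids)
  s7 <- suppressWarnings(stratified_fit(xs, ages, n_bins = 3L,
                                        min_meioses = 5L,
                                        model = "gamma", bootstrap_n = 0))
  expect_equal(length(s7), 3L)
  expect_true(all(vapply(s7, function(x) x$nu > 0, logical(1L))))

  tiny <- setNames(c("a", rep("b", length(mids) - 1L)), mids)
  expect_warning(stratified_fit(xs, tiny, min_meioses = 5L,
                                model = "gamma", bootstrap_n = 0),
                 "skipped")
})

test_that("strata with different interference strengths are distinguished", {
  mk <- function(nu, seed, tag) {
    cfg <- sim_config(n_meioses_per_sex = c(female = 70, male = 0),
                      chrom_lengths = canfam_autosomes()[1:6, ],
                      total_cM = c(female = 500, male = 400),
                      nu = nu, p_escape = 0,
                      telomere_bias = list(window_bp = 5e6, female = NA, male = NA),
                      censor_fraction = 0, seed = seed)
    xs <- true_sequences(simulate_crossovers(cfg))
    xs$seqs$meiosis_id <- paste0(tag, xs$seqs$meiosis_id)
    xs$seqs$seq_id <- paste0(tag, xs$seqs$seq_id)
    xs$events$seq_id <- paste0(tag, xs$events$seq_id)
    xs
  }
  lo <- mk(2, 58L, "lo_"); hi <- mk(25, 59L, "hi_")
  xs <- xo_sequences(rbind(lo$seqs[, c("seq_id", "meiosis_id", "sex", "chrom", "L")],
                           hi$seqs[, c("seq_id", "meiosis_id", "sex", "chrom", "L")]),
                     rbind(lo$events, hi$events))
  lab <- setNames(sub("_.*", "", unique(xs$seqs$meiosis_id)),
                  unique(xs$seqs$meiosis_id))
  fits <- stratified_fit(xs, lab, model = "gamma", bootstrap_n = 0,
                         min_meioses = 5L)
  expect_lt(fits$lo$nu, fits$hi$nu)
})
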