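# Landscape statistics: telomere proportions, concentration curves,
# feature profiles, CpG thinning, marker-framework thinning and expansion.

test_that("telomere proportion is window-proportional for uniform maps", {
  u <- uniform_map(len_bp = 5e7)
  expect_equal(telomere_proportion(u, 5e6), 0.1)

  # rate 9 in the telomeric half, 1 in the interior half
  toy <- genetic_map(data.frame(chrom = "chr1", start = c(0, 5e5),
                                end = c(5e5, 1e6), cM = c(1, 9)))
  expect_equal(telomere_proportion(toy, 5e5), 0.9)

  # window and its complement partition the total
  m <- grid_map(c(1, 4, 2, 6, 3))
  tel <- telomere_proportion(m, 2e6)
  head_part <- sum(m$cM[1:3]) / sum(m$cM)
  expect_equal(tel + head_part, 1)

  expect_warning(telomere_proportion(uniform_map(len_bp = 3e6), 5e6),
                 "exceeds the length")
})

test_that("concentration curve matches closed forms", {
  u <- grid_map(rep(1, 10))
  cu <- concentration_curve(u, bootstrap_n = 0)
  expect_equal(sequence_fraction_at(cu, 0.8), 0.8)
  expect_equal(sequence_fraction_at(cu, c(0.2, 0.5)), c(0.2, 0.5))

  toy <- genetic_map(data.frame(chrom = "chr1", start = c(0, 5e5),
                                end = c(5e5, 1e6), cM = c(9, 1)))
  ct <- concentration_curve(toy, bootstrap_n = 0)
  expect_equal(sequence_fraction_at(ct, 0.8), 0.8 / 0.9 * 0.5)

  expect_error(concentration_curve(grid_map(rep(0, 4)), bootstrap_n = 0),
               "no recombination")
})

test_that("concentration curve dominates the identity line (Lorenz property)", {
  set.seed(41)
  for (i in 1:5) {
    m <- grid_map(rexp(30, 1))
    pts <- concentration_curve(m, bootstrap_n = 0)$points
    expect_true(all(pts$gen_prop >= pts$phys_prop - 1e-12))
    expect_equal(pts$gen_prop[nrow(pts)], 1)
    expect_equal(pts$phys_prop[nrow(pts)], 1)
    expect_true(!is.unsorted(pts$gen_prop))
  }
})

test_that("long map gaps are excluded before sorting", {
  m <- genetic_map(data.frame(chrom = "chr1",
                              start = c(0, 1e6, 4e6), end = c(1e6, 4e6, 5e6),
                              cM = c(1, 0.1, 1)))
  cc <- concentration_curve(m, gap_bp = 1e6, bootstrap_n = 0)
  expect_equal(cc$n_intervals, 2L)
})

test_that("bootstrap bands contain the point estimate", {
  set.seed(42)
  cM <- rexp(60, 1)
  m <- genetic_map(data.frame(
    chrom = rep(sprintf("chr%d", 1:6), each = 10),
    start = rep((0:9) * 1e6, 6), end = rep((1:10) * 1e6, 6), cM = cM))
  cc <- concentration_curve(m, bootstrap_n = 200, seed = 7)
  est <- approx(c(0, cc$points$phys_prop), c(0, cc$points$gen_prop),
                xout = cc$bands$phys_prop)$y
  expect_true(all(est >= cc$bands$lower - 1e-9))
  expect_true(all(est <= cc$bands$upper + 1e-9))
})

test_that("profiles around anchors are flat for uniform maps", {
  u <- uniform_map(len_bp = 1e8, rate = 1.7)
  anchors <- data.frame(chrom = "chr1", pos = c(2e7, 5e7, 8e7),
                        strand = c("+", "-", "+"))
  pr <- profile_around_anchors(u, anchors, bin_bp = 1e4, flank_bp = 1e5)
  expect_true(all(abs(pr$rate - 1.7) < 1e-9))
  expect_error(profile_around_anchors(u, anchors[0, ]), "no anchors")
})

test_that("planted rate elevation is recovered at the anchor bins", {
  anchors <- data.frame(chrom = "chr1", pos = c(2e7, 5e7, 8e7), strand = "+")
  rows <- list(data.frame(chrom = "chr1", start = 0, end = 1e8, cM = NA))
  # rate 5 inside +/- 10 kb of each anchor, 1 elsewhere
  bk <- sort(c(0, 1e8, anchors$pos - 1e4, anchors$pos + 1e4))
  seg <- data.frame(chrom = "chr1", start = bk[-length(bk)], end = bk[-1L])
  inside <- vapply(seq_len(nrow(seg)), function(i) {
    any(seg$start[i] >= anchors$pos - 1e4 & seg$end[i] <= anchors$pos + 1e4)
  }, logical(1L))
  seg$cM <- ifelse(inside, 5, 1) * (seg$end - seg$start) / 1e6
  m <- genetic_map(seg)
  pr <- profile_around_anchors(m, anchors, bin_bp = 1e4, flank_bp = 1e5)
  centre <- pr$rate[pr$offset %in% c(-1e4, 0)]
  flank <- pr$rate[abs(pr$offset) >= 5e4]
  expect_true(all(abs(centre - 5) < 1e-9))
  expect_true(all(abs(flank - 1) < 1e-9))
})

test_that("minus-strand anchors mirror their offsets", {
  seg <- genetic_map(data.frame(chrom = "chr1", start = c(0, 5e7),
                                end = c(5e7, 1e8), cM = c(50, 200)))
  a_plus <- data.frame(chrom = "chr1", pos = 5e7, strand = "+")
  a_minus <- data.frame(chrom = "chr1", pos = 5e7, strand = "-")
  p1 <- profile_around_anchors(seg, a_plus, bin_bp = 1e4, flank_bp = 5e4)
  p2 <- profile_around_anchors(seg, a_minus, bin_bp = 1e4, flank_bp = 5e4)
  expect_equal(p1$rate, rev(p2$rate))
})

test_that("CpG island thinning caps windows and is seed-reproducible", {
  isl <- data.frame(chrom = "chr1",
                    start = c(seq(1e5, 3e5, by = 1e5),          # window 0: 3
                              seq(5.1e5, 6.2e5, by = 1e4)),      # window 1: 12
                    end = NA)
  isl$end <- isl$start + 500
  th <- thin_cpg_islands(isl, seed = 9)
  tab <- table(floor(th$start / 5e5))
  expect_equal(unname(tab[["0"]]), 3L)
  expect_equal(unname(tab[["1"]]), 5L)
  expect_identical(thin_cpg_islands(isl, seed = 9), th)
})

test_that("marker-framework thinning matches the reference spacing", {
  set.seed(43)
  ref <- data.frame(chrom = "chr1",
                    pos_bp = cumsum(rexp(600, rate = log(2) / 102000)))
  expect_identical(thin_marker_framework(ref, ref), ref)

  dup <- data.frame(chrom = "chr1", pos_bp = sort(c(ref$pos_bp, ref$pos_bp + 1)))
  th_dup <- thin_marker_framework(dup, ref, seed = 2)
  med_ref <- median(diff(ref$pos_bp))
  expect_lt(abs(median(diff(th_dup$pos_bp)) - med_ref) / med_ref, 0.05)

  dense <- data.frame(chrom = "chr1",
                      pos_bp = cumsum(rexp(2100, rate = log(2) / 30000)))
  th <- thin_marker_framework(dense, ref, seed = 3)
  expect_lt(abs(median(diff(th$pos_bp)) - med_ref) / med_ref, 0.05)
  expect_lt(canrec:::max_cdf_distance(diff(th$pos_bp), diff(ref$pos_bp)), 0.08)
})

test_that("crossover expansion snaps boundaries outward to the framework", {
  fw <- data.frame(chrom = "chr1", pos_bp = c(100, 130, 200))
  calls <- toy_calls(probability = 1, left = 105, right = 120)
  ex <- expand_crossovers_to_framework(calls, fw)
  expect_equal(ex$left_bp, 100)
  expect_equal(ex$right_bp, 130)

  already <- toy_calls(probability = 1, left = 100, right = 130)
  ex2 <- expand_crossovers_to_framework(already, fw)
  expect_equal(ex2$left_bp, 100)
  expect_equal(ex2$right_bp, 130)

  outside <- toy_calls(probability = 1, left = 50, right = 80)
  expect_warning(ex3 <- expand_crossovers_to_framework(outside, fw), "dropped")
  expect_equal(nrow(ex3), 0L)

  # intervals only widen, for any random fixture
  set.seed(44)
  fw2 <- data.frame(chrom = "chr1", pos_bp = sort(runif(50, 0, 1e6)))
  l <- runif(20, 1e5, 8e5); r <- l + runif(20, 1e3, 5e4)
  calls2 <- toy_calls(probability = 1, meiosis = sprintf("m%d", 1:20),
                      left = l, right = r)
  suppressWarnings(ex4 <- expand_crossovers_to_framework(calls2, fw2))
  orig <- calls2[match(ex4$meiosis_id, calls2$meiosis_id), ]
  expect_true(all(ex4$left_bp <= orig$left_bp))
  expect_true(all(ex4$right_bp >= orig$right_bp))
  expect_gte(median(ex4$right_bp - ex4$left_bp),
             median(orig$right_bp - orig$left_bp))
})
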