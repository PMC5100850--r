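## Broad- and fine-scale recombination landscape statistics.

#' Proportion of recombination near the telomeric chromosome ends
#'
#' Sums the genetic length falling within `window_bp` of each chromosome's
#' distal (telomeric) end and divides by the total genetic length, pooled
#' genome-wide. Dog autosomes are acrocentric, so each chromosome contributes
#' a single telomeric window at its distal coordinate; chromosomes stored in
#' reverse orientation should be mirrored first (see
#' [reverse_chromosomes()]).
#'
#' @param map a [genetic_map()].
#' @param window_bp telomeric window size (default 5 Mb).
#' @param chrom_lengths optional data frame `chrom`, `length_bp`; defaults to
#'   each chromosome's maximal map coordinate.
#' @return proportion of total map length in the telomeric windows.
#' @export
telomere_proportion <- function(map, window_bp = 5e6, chrom_lengths = NULL) {
  total <- sum(map$cM)
  if (total <= 0) stop("map has zero total genetic length")
  tel <- 0
  for (cc in unique(map$chrom)) {
    m <- map[map$chrom == cc, , drop = FALSE]
    len <- if (!is.null(chrom_lengths)) {
      chrom_lengths$length_bp[match(cc, chrom_lengths$chrom)]
    } else max(m$end)
    if (window_bp >= len) {
      warning(sprintf("telomeric window exceeds the length of %s; whole chromosome counted", cc))
    }
    w0 <- len - window_bp
    ov <- pmin(m$end, len) - pmax(m$start, w0)
    frac <- pmax(0, ov) / (m$end - m$start)
    tel <- tel + sum(m$cM * pmin(1, frac))
  }
  tel / total
}

#' Concentration curve of recombination
#'
#' Sorts map intervals by recombination rate in descending order and
#' accumulates genetic against physical proportion, quantifying how
#' concentrated recombination is in a small fraction of sequence
#' (a Lorenz-type curve, read from the high-rate end). Intervals longer than
#' `gap_bp` (large physical gaps without markers, e.g. around centromeres)
#' are removed before sorting. Confidence bands come from resampling
#' chromosomes with replacement.
#'
#' @param map a [genetic_map()].
#' @param gap_bp drop intervals with physical length above this value.
#' @param bootstrap_n number of chromosome bootstrap resamples (0 disables
#'   bands).
#' @param seed optional seed for the bootstrap.
#' @param grid_n number of physical-proportion grid points for the bands.
#' @return object of class `concentration_curve`: list with `points`
#'   (`phys_prop`, `gen_prop`), optional `bands` (`phys_prop`, `lower`,
#'   `upper`), and the number of intervals used.
#' @export
concentration_curve <- function(map, gap_bp = 1e6, bootstrap_n = 1000,
                                seed = NULL, grid_n = 101L) {
  m <- as.data.frame(map)
  m <- m[(m$end - m$start) <= gap_bp, , drop = FALSE]
  if (nrow(m) == 0L || sum(m$cM) <= 0) {
    stop("map has no recombination after gap removal; cannot build a concentration curve")
  }
  pts <- curve_points(m)
  bands <- NULL
  if (bootstrap_n > 0L) {
    if (!is.null(seed)) set.seed(seed)
    chroms <- unique(m$chrom)
    grid <- seq(0, 1, length.out = grid_n)
    boot <- matrix(NA_real_, nrow = bootstrap_n, ncol = grid_n)
    for (b in seq_len(bootstrap_n)) {
      cc <- sample(chroms, length(chroms), replace = TRUE)
      mb <- do.call(rbind, lapply(cc, function(ch) m[m$chrom == ch, ]))
      if (sum(mb$cM) <= 0) next
      pb <- curve_points(mb)
      boot[b, ] <- approx(c(0, pb$phys_prop), c(0, pb$gen_prop),
                          xout = grid, rule = 2L)$y
    }
    qs <- apply(boot, 2L, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    bands <- data.frame(phys_prop = grid, lower = qs[1L, ], upper = qs[2L, ])
  }
  structure(list(points = pts, bands = bands, n_intervals = nrow(m)),
            class = "concentration_curve")
}

curve_points <- function(m) {
  o <- order(m$rate_cM_per_Mb, decreasing = TRUE)
  len <- (m$end - m$start)[o]
  cm <- m$cM[o]
  data.frame(phys_prop = cumsum(len) / sum(len),
             gen_prop = cumsum(cm) / sum(cm))
}

#' @export
print.concentration_curve <- function(x, ...) {
  cat(sprintf(
    "Concentration curve over %d intervals; 80%% of recombination in %.1f%% of sequence\n",
    x$n_intervals, 100 * sequence_fraction_at(x, 0.8)))
  invisible(x)
}

#' Minimal sequence fraction holding a given share of recombination
#'
#' Reads the concentration curve at genetic proportion `q`: the smallest
#' physical proportion of the genome containing a fraction `q` of total
#' recombination.
#'
#' @param curve a [concentration_curve()].
#' @param q genetic proportion(s) in `(0, 1]`.
#' @return physical proportion(s).
#' @export
sequence_fraction_at <- function(curve, q) {
  pts <- curve$points
  approx(c(0, pts$gen_prop), c(0, pts$phys_prop), xout = q, ties = min)$y
}

#' Recombination rate profile around genomic anchors
#'
#' Physical-length-weighted mean recombination rate in non-overlapping bins
#' of `bin_bp` at signed offsets from a set of anchor points (transcription
#' start sites, CpG island midpoints, or generic BED features). Anchors on
#' the minus strand have their offsets mirrored so that negative offsets are
#' always upstream.
#'
#' @param map a [genetic_map()].
#' @param anchors data frame with `chrom`, `pos` (anchor coordinate, 0-based)
#'   and optional `strand` ("+"/"-"); or a `GRanges` whose start (strand
#'   aware) is used.
#' @param bin_bp bin width (default 10 kb).
#' @param flank_bp half-width of the profiled region.
#' @return object of class `feature_profile`: data frame with `offset`
#'   (bin start relative to the anchor) and `rate`, plus an `n_anchors`
#'   attribute.
#' @export
profile_around_anchors <- function(map, anchors, bin_bp = 1e4, flank_bp = 5e5) {
  if (methods::is(anchors, "GRanges")) {
    anchors <- granges_anchors(anchors)
  }
  assert_columns(anchors, c("chrom", "pos"), "anchor table")
  if (nrow(anchors) == 0L) stop("no anchors supplied")
  strand <- anchors$strand %||% rep("+", nrow(anchors))
  strand[is.na(strand) | !(strand %in% c("+", "-"))] <- "+"
  n_bins <- 2L * ceiling(flank_bp / bin_bp)
  offsets <- (seq_len(n_bins) - 1L - n_bins %/% 2L) * bin_bp
  num <- numeric(n_bins); den <- numeric(n_bins)
  for (cc in unique(anchors$chrom)) {
    m <- map[map$chrom == cc, , drop = FALSE]
    if (nrow(m) == 0L) next
    a <- anchors[anchors$chrom == cc, , drop = FALSE]
    st <- strand[anchors$chrom == cc]
    for (r in seq_len(nrow(a))) {
      for (bi in seq_len(n_bins)) {
        off <- offsets[bi]
        if (st[r] == "+") {
          w1 <- a$pos[r] + off; w2 <- w1 + bin_bp
        } else {
          w2 <- a$pos[r] - off; w1 <- w2 - bin_bp
        }
        ov <- pmin(m$end, w2) - pmax(m$start, w1)
        pos <- ov > 0
        if (any(pos)) {
          num[bi] <- num[bi] + sum(ov[pos] * m$rate_cM_per_Mb[pos])
          den[bi] <- den[bi] + sum(ov[pos])
        }
      }
    }
  }
  out <- data.frame(offset = offsets,
                    rate = ifelse(den > 0, num / den, NA_real_))
  structure(out, n_anchors = nrow(anchors),
            class = c("feature_profile", "data.frame"))
}

granges_anchors <- function(gr) {
  st <- as.character(BiocGenerics::strand(gr))
  pos <- ifelse(st == "-", BiocGenerics::end(gr), BiocGenerics::start(gr) - 1L)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = pos, strand = ifelse(st == "*", "+", st),
             stringsAsFactors = FALSE)
}

#' Thin CpG islands to a uniform genomic density
#'
#' Retains at most `max_per_window` islands per non-overlapping window,
#' chosen uniformly at random, to control for CpG clustering when profiling
#' recombination around islands.
#'
#' @param islands data frame `chrom`, `start`, `end`.
#' @param window_bp window size (default 500 kb).
#' @param max_per_window cap per window.
#' @param seed optional seed for reproducible subsampling.
#' @return the thinned island table, sorted by position.
#' @export
thin_cpg_islands <- function(islands, window_bp = 5e5, max_per_window = 5L,
                             seed = NULL) {
  assert_columns(islands, c("chrom", "start", "end"), "island table")
  if (!is.null(seed)) set.seed(seed)
  win <- paste(islands$chrom, floor(islands$start / window_bp))
  keep <- unlist(lapply(split(seq_len(nrow(islands)), win), function(i) {
    if (length(i) <= max_per_window) i else sample(i, max_per_window)
  }), use.names = FALSE)
  out <- islands[sort(keep), , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Thin a dense marker set to match a reference marker spacing
#'
#' Iteratively removes random markers from regions where the dense set's
#' inter-marker gaps cluster more tightly than in the reference set, until
#' the median inter-marker distances agree within `tolerance` and the
#' empirical gap distributions are close (maximal CDF difference below
#' `cdf_tolerance`). Removal targets gap-size bins (bounded by reference gap
#' quantiles) in which the dense set holds more gaps than the reference, so
#' only the over-represented spacings are thinned. Used to reduce a
#' higher-resolution dataset (e.g. a human SNP framework) to the resolution
#' of a sparser one before comparing maps.
#'
#' @param dense,reference data frames `chrom`, `pos_bp`.
#' @param tolerance relative tolerance on the median gap (default 5%).
#' @param cdf_tolerance maximal allowed CDF difference between the gap
#'   distributions; the default reflects the two-sample noise floor at
#'   typical framework sizes plus the residual distortion marker removal
#'   (which can only merge gaps) leaves behind.
#' @param max_iter iteration cap; exceeded iterations raise an error with
#'   diagnostics.
#' @param removal_prob base per-iteration removal probability; halved
#'   adaptively whenever a proposed step would overshoot the median band.
#' @param seed optional seed.
#' @return the thinned marker table.
#' @export
thin_marker_framework <- function(dense, reference, tolerance = 0.05,
                                  cdf_tolerance = 0.08, max_iter = 100L,
                                  removal_prob = 0.3, seed = NULL) {
  assert_columns(dense, c("chrom", "pos_bp"), "dense marker table")
  assert_columns(reference, c("chrom", "pos_bp"), "reference marker table")
  if (!is.null(seed)) set.seed(seed)
  dense <- dense[order(dense$chrom, dense$pos_bp), ]
  reference <- reference[order(reference$chrom, reference$pos_bp), ]
  ref_gaps <- marker_gaps(reference)
  ref_med <- median(ref_gaps)
  breaks <- c(-Inf, unique(quantile(ref_gaps, seq(0.05, 0.95, by = 0.05))), Inf)
  n_ref <- as.numeric(table(cut(ref_gaps, breaks)))
  step_scale <- 1
  for (it in seq_len(max_iter + 1L)) {
    gaps <- marker_gaps(dense)
    med <- median(gaps)
    ks <- max_cdf_distance(gaps, ref_gaps)
    if (abs(med - ref_med) / ref_med < tolerance && ks < cdf_tolerance) {
      rownames(dense) <- NULL
      return(dense)
    }
    if (it > max_iter || med >= ref_med * (1 + tolerance)) {
      stop(sprintf(
        paste0("marker thinning did not converge (iteration %d): median gap ",
               "%.0f vs reference %.0f (rel. diff %.3f), max CDF distance %.3f"),
        it, med, ref_med, abs(med - ref_med) / ref_med, ks))
    }
    ## per-bin excess of dense gaps over the reference's gap counts; the
    ## removal weight of a gap is the fraction of its bin that is excess
    bin_all <- cut(gaps, breaks)
    n_dense <- as.numeric(table(bin_all))
    w_bin <- pmax(0, n_dense - n_ref) / pmax(n_dense, 1)
    p_eff <- step_scale * removal_prob
    drop <- logical(nrow(dense))
    best_cand <- NA_integer_; best_w <- 0
    for (cc in unique(dense$chrom)) {
      i <- which(dense$chrom == cc)
      if (length(i) < 3L) next
      g <- diff(dense$pos_bp[i])
      wg <- w_bin[as.integer(cut(g, breaks))]
      inner <- 2:(length(i) - 1L)
      w_mark <- pmax(c(0, wg)[inner], c(wg, 0)[inner])
      sel <- runif(length(inner)) < p_eff * w_mark
      ## removing two adjacent markers at once merges three gaps and
      ## inflates the right tail; forbid adjacent removals within a pass
      for (j in which(sel)) if (j > 1L && sel[j - 1L]) sel[j] <- FALSE
      drop[i[inner[sel]]] <- TRUE
      if (any(w_mark > best_w)) {
        best_w <- max(w_mark)
        best_cand <- i[inner[which.max(w_mark)]]
      }
    }
    if (!any(drop)) {
      if (!is.finite(best_cand) || best_w <= 0) {
        stop(sprintf(
          paste0("marker thinning stalled (iteration %d): no over-represented ",
                 "gaps left but max CDF distance is %.3f"), it, ks))
      }
      drop[best_cand] <- TRUE   # force minimal progress on an empty draw
    }
    proposal <- dense[!drop, , drop = FALSE]
    if (median(marker_gaps(proposal)) >= ref_med * (1 + tolerance)) {
      ## revert a step that would overshoot the median band and retry finer
      step_scale <- step_scale / 2
      if (step_scale < 1e-4) {
        stop("marker thinning cannot step without overshooting the median band")
      }
      next
    }
    dense <- proposal
  }
}

marker_gaps <- function(markers) {
  unlist(lapply(split(markers$pos_bp, markers$chrom), diff), use.names = FALSE)
}

max_cdf_distance <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
}

#' Expand crossover intervals to a thinned marker framework
#'
#' Moves each call's left boundary to the nearest framework marker at or
#' below it and the right boundary to the nearest framework marker at or
#' above it, so intervals only widen. Calls with no flanking framework
#' marker on one side are dropped with a warning.
#'
#' @param calls crossover call table.
#' @param framework data frame `chrom`, `pos_bp` of retained markers.
#' @return the call table with expanded boundaries.
#' @export
expand_crossovers_to_framework <- function(calls, framework) {
  assert_columns(framework, c("chrom", "pos_bp"), "framework table")
  assert_columns(calls, c("chrom", "left_bp", "right_bp"), "call table")
  drop <- logical(nrow(calls))
  for (cc in unique(calls$chrom)) {
    i <- which(calls$chrom == cc)
    fw <- sort(framework$pos_bp[framework$chrom == cc])
    if (length(fw) == 0L) { drop[i] <- TRUE; next }
    li <- findInterval(calls$left_bp[i], fw)
    ri <- findInterval(calls$right_bp[i], fw, left.open = TRUE) + 1L
    ok <- li >= 1L & ri <= length(fw)
    drop[i[!ok]] <- TRUE
    j <- i[ok]
    calls$left_bp[j] <- fw[li[ok]]
    calls$right_bp[j] <- fw[ri[ok]]
  }
  if (any(drop)) {
    warning(sprintf("%d call(s) had no flanking framework marker and were dropped",
                    sum(drop)))
  }
  calls[!drop, , drop = FALSE]
}
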