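## Genetic map construction: effective meioses, Haldane's map function,
## per-interval recombination fractions, sex averaging and map comparisons.
##
## A genetic map is a data frame (class "genetic_map") with columns
##   chrom, start, end   -- 0-based half-open physical interval (bp)
##   cM                  -- genetic length of the interval
##   rate_cM_per_Mb      -- cM / physical Mb
##   cum_cM              -- cumulative cM at the interval end, per chromosome
## and a "sex" attribute ("female", "male" or "sex-averaged").

#' Construct a genetic map object
#'
#' @param df data frame with columns `chrom`, `start`, `end` and `cM`
#'   (interval genetic length in centimorgans). Coordinates are 0-based
#'   half-open base pairs.
#' @param sex map label: `"female"`, `"male"` or `"sex-averaged"`.
#' @return A `genetic_map` data frame with derived `rate_cM_per_Mb` and
#'   `cum_cM` columns, sorted by chromosome and position.
#' @export
genetic_map <- function(df, sex = "sex-averaged") {
  assert_columns(df, c("chrom", "start", "end", "cM"), "genetic map")
  if (any(df$end <= df$start)) stop("genetic map intervals must have end > start")
  if (any(df$cM < 0)) stop("genetic map interval cM must be non-negative")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  for (cc in unique(df$chrom)) {
    i <- which(df$chrom == cc)
    if (length(i) > 1L && any(df$start[i][-1] < df$end[i][-length(i)])) {
      stop(sprintf("overlapping intervals on chromosome %s", cc))
    }
  }
  df$rate_cM_per_Mb <- df$cM / ((df$end - df$start) / 1e6)
  df$cum_cM <- stats::ave(df$cM, df$chrom, FUN = cumsum)
  rownames(df) <- NULL
  structure(df, sex = sex, class = c("genetic_map", "data.frame"))
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic map (%s): %d intervals on %d chromosome(s), total %.1f cM\n",
              attr(x, "sex") %||% "?", nrow(x),
              length(unique(x$chrom)), map_total_cM(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Total genetic length of a map in centimorgans
#' @param map a [genetic_map()].
#' @param by_chrom return a named per-chromosome vector instead of the total.
#' @export
map_total_cM <- function(map, by_chrom = FALSE) {
  tot <- tapply(map$cM, map$chrom, sum)
  if (by_chrom) tot[unique(map$chrom)] else sum(map$cM)
}

## Interpolation knots of the cumulative map for one chromosome; requires
## contiguous intervals (true for maps built on a marker grid).
map_knots <- function(map, chrom) {
  m <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0L) stop(sprintf("chromosome %s not present in map", chrom))
  list(bp = c(m$start[1L], m$end), cM = c(0, cumsum(m$cM)))
}

#' Convert physical positions to cumulative genetic positions (and back)
#'
#' Piecewise-linear interpolation of the cumulative map. `cM_to_bp()` requires
#' a strictly monotone (everywhere positive rate) map; a map with zero-rate
#' intervals is not invertible.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome name.
#' @param bp,cM positions to convert.
#' @return numeric vector of converted positions.
#' @export
bp_to_cM <- function(map, chrom, bp) {
  k <- map_knots(map, chrom)
  if (any(bp < k$bp[1L] - 1e-9) || any(bp > k$bp[length(k$bp)] + 1e-9)) {
    stop(sprintf("position outside map support on %s", chrom))
  }
  approx(k$bp, k$cM, xout = bp, rule = 2L)$y
}

#' @rdname bp_to_cM
#' @export
cM_to_bp <- function(map, chrom, cM) {
  k <- map_knots(map, chrom)
  if (any(diff(k$cM) <= 0)) {
    stop(sprintf(
      "map is not invertible on %s: cumulative genetic position must be strictly increasing",
      chrom))
  }
  approx(k$cM, k$bp, xout = cM, rule = 2L)$y
}

#' Haldane's map function and its inverse
#'
#' Converts a recombination fraction to a genetic distance assuming no
#' interference between the two loci: `d = -1/2 log(1 - 2 r)` Morgans, with
#' inverse `r = (1 - exp(-2 d)) / 2`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d genetic distance(s) in Morgans.
#' @return `haldane()` returns Morgans; `haldane_inv()` returns fractions.
#' @examples
#' haldane(0.25)          # 0.3466 Morgans
#' haldane_inv(0.5)       # 0.3161
#' @export
haldane <- function(r) {
  if (any(r < 0) || any(r >= 0.5)) {
    stop("recombination fraction must lie in [0, 0.5): distance is infinite at r >= 0.5")
  }
  -0.5 * log1p(-2 * r)
}

#' @rdname haldane
#' @export
haldane_inv <- function(d) {
  if (any(d < 0)) stop("genetic distance must be non-negative")
  0.5 * (1 - exp(-2 * d))
}

#' Marker intervals from marker positions
#'
#' @param markers data frame with columns `chrom`, `pos_bp` (sorted within
#'   chromosome or sortable).
#' @return data frame `chrom`, `start`, `end` of consecutive-marker intervals.
#' @export
marker_intervals <- function(markers) {
  assert_columns(markers, c("chrom", "pos_bp"), "marker table")
  markers <- markers[order(markers$chrom, markers$pos_bp), ]
  out <- lapply(split(markers$pos_bp, markers$chrom), function(p) {
    p <- unique(p)
    if (length(p) < 2L) return(NULL)
    data.frame(start = p[-length(p)], end = p[-1L])
  })
  keep <- !vapply(out, is.null, logical(1L))
  res <- do.call(rbind, Map(function(cc, d) cbind(chrom = cc, d),
                            names(out)[keep], out[keep]))
  rownames(res) <- NULL
  res
}

#' Effective number of meioses per marker interval
#'
#' At each marker interval, the effective number of meioses is the number of
#' parent-child duos whose informative span (first to last heterozygous
#' parental marker) fully contains the interval. It replaces the fixed duo
#' count in recombination-fraction estimation, correcting for regions where
#' homozygosity makes crossovers invisible.
#'
#' @param spans data frame with columns `meiosis_id`, `chrom`,
#'   `first_het_bp`, `last_het_bp` (one row per duo per chromosome).
#' @param intervals marker intervals from [marker_intervals()].
#' @return `intervals` with an added `n_eff` column.
#' @export
effective_meioses <- function(spans, intervals) {
  assert_columns(intervals, c("chrom", "start", "end"), "interval table")
  intervals$n_eff <- 0
  if (is.null(spans) || nrow(spans) == 0L) {
    warning("no informative spans supplied: effective meioses are zero everywhere")
    return(intervals)
  }
  assert_columns(spans, c("meiosis_id", "chrom", "first_het_bp", "last_het_bp"),
                 "informative span table")
  for (cc in unique(intervals$chrom)) {
    ii <- which(intervals$chrom == cc)
    s <- spans[spans$chrom == cc, , drop = FALSE]
    if (nrow(s) == 0L) next
    starts <- intervals$start[ii]
    ends <- intervals$end[ii]
    ## intervals are sorted and contiguous-or-disjoint; a span covers the
    ## contiguous index range of intervals fully inside [first, last].
    delta <- integer(length(ii) + 1L)
    for (r in seq_len(nrow(s))) {
      lo <- which(starts >= s$first_het_bp[r] & ends <= s$last_het_bp[r])
      if (length(lo) == 0L) next
      delta[lo[1L]] <- delta[lo[1L]] + 1L
      delta[lo[length(lo)] + 1L] <- delta[lo[length(lo)] + 1L] - 1L
    }
    intervals$n_eff[ii] <- cumsum(delta[-length(delta)])
  }
  intervals
}

#' Build a genetic map from filtered crossover calls
#'
#' Each crossover contributes one unit of mass, distributed over the marker
#' intervals intersecting its bounding interval proportionally to physical
#' overlap (`assign = "overlap"`, default) or assigned wholly to the interval
#' containing its midpoint (`assign = "midpoint"`). Per-interval recombination
#' fractions `mass / n_eff` are converted to genetic distances with Haldane's
#' map function.
#'
#' @param calls crossover call table (0-based half-open `left_bp`, `right_bp`).
#' @param neff marker intervals with an `n_eff` column, from
#'   [effective_meioses()]; alternatively marker intervals plus `n_fixed` to
#'   use a constant meiosis count.
#' @param sex label for the resulting map; if not `NULL`, calls are subset to
#'   `parent_sex == sex` ("female"/"male", accepting "F"/"M").
#' @param assign crossover mass assignment mode.
#' @param n_fixed optional fixed meiosis count overriding `n_eff`.
#' @return a [genetic_map()].
#' @export
build_map <- function(calls, neff, sex = NULL, assign = c("overlap", "midpoint"),
                      n_fixed = NULL) {
  assign <- match.arg(assign)
  assert_columns(neff, c("chrom", "start", "end"), "interval table")
  if (!is.null(n_fixed)) {
    neff$n_eff <- n_fixed
  }
  assert_columns(neff, c("chrom", "start", "end", "n_eff"), "interval table")
  if (!is.null(sex)) {
    sx <- norm_sex(sex)
    calls <- calls[norm_sex(calls$parent_sex) == sx, , drop = FALSE]
  } else {
    sx <- "sex-averaged"
  }
  if (nrow(calls) > 0L) {
    assert_columns(calls, c("chrom", "left_bp", "right_bp"), "call table")
  }
  neff <- neff[order(neff$chrom, neff$start), ]
  neff$mass <- 0
  for (cc in unique(neff$chrom)) {
    ii <- which(neff$chrom == cc)
    s <- neff$start[ii]; e <- neff$end[ii]
    cl <- calls[calls$chrom == cc, , drop = FALSE]
    if (nrow(cl) == 0L) next
    mass <- numeric(length(ii))
    for (r in seq_len(nrow(cl))) {
      l <- cl$left_bp[r]; rr <- cl$right_bp[r]
      if (assign == "midpoint") {
        mid <- (l + rr) / 2
        j <- findInterval(mid, s)
        if (j >= 1L && j <= length(s) && mid < e[j]) mass[j] <- mass[j] + 1
        next
      }
      ov <- pmin(e, rr) - pmax(s, l)
      ov[ov < 0] <- 0
      tot <- sum(ov)
      if (tot > 0) mass <- mass + ov / tot
    }
    neff$mass[ii] <- mass
  }
  bad <- neff$mass > 0 & neff$n_eff <= 0
  if (any(bad)) {
    stop(sprintf(
      "%d interval(s) carry crossover mass but have zero effective meioses; inconsistent inputs",
      sum(bad)))
  }
  r_hat <- ifelse(neff$n_eff > 0, neff$mass / neff$n_eff, 0)
  ## intervals observed in very few meioses can yield fractions at or above
  ## 1/2, where the map distance diverges; cap them and report it
  over <- r_hat >= 0.5
  if (any(over)) {
    warning(sprintf(
      "%d interval(s) had recombination fraction >= 0.5 (few effective meioses); capped at 0.49",
      sum(over)))
    r_hat[over] <- 0.49
  }
  d_cM <- 100 * haldane(r_hat)
  out <- data.frame(chrom = neff$chrom, start = neff$start, end = neff$end,
                    cM = d_cM)
  genetic_map(out, sex = sx)
}

norm_sex <- function(x) {
  x <- tolower(as.character(x))
  out <- ifelse(x %in% c("f", "female", "2"), "female",
                ifelse(x %in% c("m", "male", "1"), "male", x))
  out
}

#' Sex-averaged genetic map
#'
#' Per-interval arithmetic mean of the female and male genetic distances.
#' The two maps must be built on identical interval grids.
#'
#' @param map_f,map_m female and male [genetic_map()]s.
#' @return a sex-averaged [genetic_map()].
#' @export
sex_average <- function(map_f, map_m) {
  if (nrow(map_f) != nrow(map_m) ||
      !all(map_f$chrom == map_m$chrom) ||
      !all(map_f$start == map_m$start) ||
      !all(map_f$end == map_m$end)) {
    stop("sex_average requires identical interval grids")
  }
  out <- data.frame(chrom = map_f$chrom, start = map_f$start, end = map_f$end,
                    cM = (map_f$cM + map_m$cM) / 2)
  genetic_map(out, sex = "sex-averaged")
}

#' Mirror chromosome coordinates
#'
#' Reverses the physical orientation of the named chromosomes (`x -> L - x`),
#' as needed when a reference assembly stores a chromosome in the reverse
#' orientation (dog chromosomes 27 and 32). Applying the operation twice
#' restores the input.
#'
#' @param x a [genetic_map()], a crossover call table (`left_bp`/`right_bp`),
#'   or an informative span table (`first_het_bp`/`last_het_bp`).
#' @param chroms chromosomes to reverse.
#' @param chrom_lengths data frame `chrom`, `length_bp`.
#' @return object of the same type with mirrored coordinates.
#' @export
reverse_chromosomes <- function(x, chroms, chrom_lengths) {
  assert_columns(chrom_lengths, c("chrom", "length_bp"), "chromosome length table")
  unknown <- setdiff(chroms, chrom_lengths$chrom)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown chromosome(s): %s", paste(unknown, collapse = ", ")))
  }
  len <- setNames(chrom_lengths$length_bp, chrom_lengths$chrom)
  if (inherits(x, "genetic_map")) {
    sex <- attr(x, "sex")
    df <- as.data.frame(x)
    for (cc in chroms) {
      i <- df$chrom == cc
      if (!any(i)) next
      ns <- len[[cc]] - df$end[i]
      ne <- len[[cc]] - df$start[i]
      df$start[i] <- ns; df$end[i] <- ne
    }
    return(genetic_map(df[, c("chrom", "start", "end", "cM")], sex = sex))
  }
  cols <- if (all(c("left_bp", "right_bp") %in% names(x))) {
    c("left_bp", "right_bp")
  } else if (all(c("first_het_bp", "last_het_bp") %in% names(x))) {
    c("first_het_bp", "last_het_bp")
  } else stop("cannot reverse: unrecognized table type")
  for (cc in chroms) {
    i <- x$chrom == cc
    if (!any(i)) next
    a <- len[[cc]] - x[[cols[2L]]][i]
    b <- len[[cc]] - x[[cols[1L]]][i]
    x[[cols[1L]]][i] <- a
    x[[cols[2L]]][i] <- b
  }
  x
}

## Length-weighted mean rate of a map in fixed non-overlapping windows.
## Returns data frame chrom, win_start, rate, coverage.
windowed_rates <- function(map, window_bp) {
  out <- list()
  for (cc in unique(map$chrom)) {
    m <- map[map$chrom == cc, , drop = FALSE]
    wmax <- ceiling(max(m$end) / window_bp)
    num <- numeric(wmax); den <- numeric(wmax)
    for (r in seq_len(nrow(m))) {
      w1 <- floor(m$start[r] / window_bp) + 1L
      w2 <- ceiling(m$end[r] / window_bp)
      for (w in w1:w2) {
        ov <- min(m$end[r], w * window_bp) - max(m$start[r], (w - 1) * window_bp)
        if (ov > 0) {
          num[w] <- num[w] + ov * m$rate_cM_per_Mb[r]
          den[w] <- den[w] + ov
        }
      }
    }
    keep <- den > 0
    if (any(keep)) {
      out[[cc]] <- data.frame(chrom = cc,
                              win_start = (which(keep) - 1L) * window_bp,
                              rate = num[keep] / den[keep],
                              coverage = den[keep])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Windowed correlation between two genetic maps
#'
#' Rates are averaged (physical-length-weighted) within non-overlapping
#' windows and the Pearson correlation is computed over windows covered by
#' both maps.
#'
#' @param map_a,map_b [genetic_map()]s sharing chromosome names.
#' @param window_bp window size (default 5 Mb).
#' @return Pearson correlation coefficient.
#' @export
smooth_and_correlate <- function(map_a, map_b, window_bp = 5e6) {
  wa <- windowed_rates(map_a, window_bp)
  wb <- windowed_rates(map_b, window_bp)
  key_a <- paste(wa$chrom, wa$win_start)
  key_b <- paste(wb$chrom, wb$win_start)
  shared <- intersect(key_a, key_b)
  if (length(shared) < 3L) stop("fewer than 3 shared windows between maps")
  cor(wa$rate[match(shared, key_a)], wb$rate[match(shared, key_b)],
      method = "pearson")
}
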