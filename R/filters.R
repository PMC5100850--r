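## Quality-control filters for crossover calls and genotype summaries.

#' Filter configuration
#'
#' Thresholds for the crossover- and marker-level filters: calls are retained
#' when their posterior probability is strictly greater than
#' `min_call_probability`; clustered double crossovers are removed when two
#' crossovers of one meiosis lie within `double_xo_cluster_bp` of each other
#' and a second meiosis of the same parent carries a clustered pair sharing a
#' boundary coordinate; meioses whose autosome-wide crossover count falls
#' outside the sex-specific median plus/minus `sd_multiplier` robust standard
#' deviations (`mad_constant` times the median absolute deviation) are
#' excluded; markers are excluded for missingness above
#' `max_missing_fraction`, duo Mendelian conflicts, or an error probability
#' above `marker_error_probability`.
#'
#' @param min_call_probability retain calls with probability strictly above
#'   this value.
#' @param double_xo_cluster_bp clustering distance between the inner
#'   boundaries of successive crossover intervals.
#' @param mad_constant consistency constant converting MAD to a standard
#'   deviation under normality.
#' @param sd_multiplier half-width of the outlier band in robust SD units.
#' @param max_missing_fraction marker missingness threshold (strict).
#' @param marker_error_probability marker error-probability threshold (strict).
#' @param blacklist_regions data frame `chrom`, `start`, `end` (0-based
#'   half-open) of regions whose overlapping records are removed.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_call_probability = 0.5,
                          double_xo_cluster_bp = 1e6,
                          mad_constant = 1.4826,
                          sd_multiplier = 4,
                          max_missing_fraction = 0.05,
                          marker_error_probability = 0.9,
                          blacklist_regions = NULL) {
  assert_scalar_number(min_call_probability, "min_call_probability", 0, 1)
  assert_scalar_number(double_xo_cluster_bp, "double_xo_cluster_bp", 0,
                       strict_lower = TRUE)
  assert_scalar_number(sd_multiplier, "sd_multiplier", 0, strict_lower = TRUE)
  assert_scalar_number(max_missing_fraction, "max_missing_fraction", 0, 1)
  if (!is.null(blacklist_regions)) {
    assert_columns(blacklist_regions, c("chrom", "start", "end"),
                   "blacklist_regions")
    if (any(blacklist_regions$end < blacklist_regions$start)) {
      stop("blacklist regions must have end >= start")
    }
  }
  structure(list(min_call_probability = min_call_probability,
                 double_xo_cluster_bp = double_xo_cluster_bp,
                 mad_constant = mad_constant,
                 sd_multiplier = sd_multiplier,
                 max_missing_fraction = max_missing_fraction,
                 marker_error_probability = marker_error_probability,
                 blacklist_regions = blacklist_regions),
            class = "filter_config")
}

new_filter_report <- function(rule, n_in, removed_ids, details = NULL) {
  structure(list(rule = rule, n_in = n_in, n_removed = length(removed_ids),
                 n_surviving = n_in - length(removed_ids),
                 removed_ids = removed_ids, details = details),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter '%s': %d in, %d removed, %d surviving\n",
              x$rule, x$n_in, x$n_removed, x$n_surviving))
  invisible(x)
}

ensure_call_ids <- function(calls) {
  if (is.null(calls$call_id)) calls$call_id <- seq_len(nrow(calls))
  calls
}

#' Remove low-probability crossover calls
#'
#' Retains calls whose posterior probability is strictly greater than the
#' configured threshold (default 0.5).
#'
#' @param calls crossover call table with a `probability` column.
#' @param config a [filter_config()].
#' @return list with filtered `calls` and a `report`.
#' @export
filter_low_probability_calls <- function(calls, config = filter_config()) {
  if (is.null(calls$probability)) {
    stop("call table has no `probability` column")
  }
  calls <- ensure_call_ids(calls)
  drop <- !(calls$probability > config$min_call_probability)
  list(calls = calls[!drop, , drop = FALSE],
       report = new_filter_report("low_probability", nrow(calls),
                                  calls$call_id[drop]))
}

#' Remove records overlapping blacklist regions
#'
#' Any record whose interval overlaps a configured blacklist region (such as
#' segmental duplications or misassembled contigs) is removed. Works on call
#' tables (`left_bp`/`right_bp`) and marker tables (`pos_bp`).
#'
#' @param x call or marker table.
#' @param config a [filter_config()] with `blacklist_regions` set (an empty
#'   or `NULL` blacklist is the identity).
#' @return list with filtered table (`calls`) and a `report`.
#' @export
filter_blacklist_regions <- function(x, config = filter_config()) {
  bl <- config$blacklist_regions
  x <- ensure_call_ids(x)
  if (is.null(bl) || nrow(bl) == 0L) {
    return(list(calls = x, report = new_filter_report("blacklist", nrow(x),
                                                      integer(0))))
  }
  if (all(c("left_bp", "right_bp") %in% names(x))) {
    s <- x$left_bp; e <- x$right_bp
  } else if ("pos_bp" %in% names(x)) {
    s <- x$pos_bp; e <- x$pos_bp + 1
  } else stop("cannot locate intervals: need left_bp/right_bp or pos_bp")
  drop <- logical(nrow(x))
  for (cc in unique(bl$chrom)) {
    b <- bl[bl$chrom == cc, , drop = FALSE]
    i <- which(x$chrom == cc)
    if (length(i) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = s[i] + 1, end = e[i]),
      IRanges::IRanges(start = b$start + 1, end = b$end))
    drop[i[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  list(calls = x[!drop, , drop = FALSE],
       report = new_filter_report("blacklist", nrow(x), x$call_id[drop]))
}

#' Remove clustered double crossovers with shared boundaries
#'
#' Within each meiosis and chromosome, successive crossover pairs whose
#' bounding intervals lie within `double_xo_cluster_bp` (measured between the
#' inner boundaries) are flagged as clustered. A clustered pair is removed
#' when at least one other meiosis transmitted from the same parent carries a
#' clustered pair sharing an identical interval-boundary coordinate -- the
#' signature of a genotyping error at a shared SNP rather than genuine gene
#' conversion.
#'
#' @param calls crossover call table.
#' @param config a [filter_config()].
#' @return list with filtered `calls` and a `report`.
#' @export
filter_clustered_double_crossovers <- function(calls, config = filter_config()) {
  calls <- ensure_call_ids(calls)
  n_in <- nrow(calls)
  if (n_in == 0L) {
    return(list(calls = calls,
                report = new_filter_report("double_xo_cluster", 0L, integer(0))))
  }
  o <- order(calls$meiosis_id, calls$chrom, calls$left_bp, calls$right_bp)
  calls_o <- calls[o, ]
  ## flag successive pairs within a meiosis x chromosome
  pairs <- list()
  grp <- paste(calls_o$meiosis_id, calls_o$chrom)
  idx <- split(seq_len(nrow(calls_o)), grp)
  for (g in idx) {
    if (length(g) < 2L) next
    for (j in seq_len(length(g) - 1L)) {
      a <- g[j]; b <- g[j + 1L]
      gap <- calls_o$left_bp[b] - calls_o$right_bp[a]
      if (gap <= config$double_xo_cluster_bp) {
        pairs[[length(pairs) + 1L]] <- list(
          parent = calls_o$parent_id[a], meiosis = calls_o$meiosis_id[a],
          rows = c(a, b),
          bounds = c(calls_o$left_bp[a], calls_o$right_bp[a],
                     calls_o$left_bp[b], calls_o$right_bp[b]))
      }
    }
  }
  removed_rows <- integer(0)
  if (length(pairs) >= 2L) {
    parents <- vapply(pairs, `[[`, character(1L), "parent")
    meio <- vapply(pairs, `[[`, character(1L), "meiosis")
    for (i in seq_along(pairs)) {
      mates <- which(parents == parents[i] & meio != meio[i])
      for (k in mates) {
        if (length(intersect(pairs[[i]]$bounds, pairs[[k]]$bounds)) > 0L) {
          removed_rows <- c(removed_rows, pairs[[i]]$rows)
          break
        }
      }
    }
  }
  removed_rows <- unique(removed_rows)
  removed_ids <- calls_o$call_id[removed_rows]
  keep <- !(calls$call_id %in% removed_ids)
  list(calls = calls[keep, , drop = FALSE],
       report = new_filter_report("double_xo_cluster", n_in, removed_ids))
}

#' Robust outlier bounds for crossover counts
#'
#' Median plus/minus `sd_multiplier` robust standard deviations, where the SD
#' is estimated as `mad_constant * median(|count - median|)`. A zero MAD
#' falls back to the sample standard deviation; if that is also zero the
#' bounds are infinite (nothing excluded).
#'
#' @param counts integer vector of per-meiosis crossover counts.
#' @param config a [filter_config()].
#' @return named vector `c(lower, upper, median, sd)`.
#' @export
outlier_bounds <- function(counts, config = filter_config()) {
  m <- median(counts)
  mad_raw <- median(abs(counts - m))
  sd_star <- config$mad_constant * mad_raw
  if (sd_star == 0) sd_star <- sd(counts)
  if (is.na(sd_star) || sd_star == 0) {
    return(c(lower = -Inf, upper = Inf, median = m, sd = 0))
  }
  c(lower = m - config$sd_multiplier * sd_star,
    upper = m + config$sd_multiplier * sd_star,
    median = m, sd = sd_star)
}

#' Remove meioses with biologically abnormal crossover counts
#'
#' Computes per-meiosis autosome-wide crossover counts separately by parental
#' sex and removes entire meioses whose count falls outside the robust
#' outlier bounds (see [outlier_bounds()]).
#'
#' @param calls crossover call table with `parent_sex`.
#' @param config a [filter_config()].
#' @return list with filtered `calls` and a `report`; the report `details`
#'   holds per-sex bounds and the excluded meioses with their counts.
#' @export
filter_outlier_meioses <- function(calls, config = filter_config()) {
  calls <- ensure_call_ids(calls)
  n_in <- nrow(calls)
  drop_mei <- character(0)
  details <- list()
  for (sx in unique(norm_sex(calls$parent_sex))) {
    i <- norm_sex(calls$parent_sex) == sx
    counts <- table(calls$meiosis_id[i])
    if (length(counts) < 2L) {
      warning(sprintf("fewer than 2 meioses for sex '%s'; outlier filter skipped", sx))
      next
    }
    b <- outlier_bounds(as.numeric(counts), config)
    out <- names(counts)[as.numeric(counts) < b["lower"] |
                         as.numeric(counts) > b["upper"]]
    drop_mei <- c(drop_mei, out)
    details[[sx]] <- list(bounds = b,
                          excluded = data.frame(
                            meiosis_id = out,
                            count = as.numeric(counts[out])))
  }
  drop <- calls$meiosis_id %in% drop_mei
  list(calls = calls[!drop, , drop = FALSE],
       report = new_filter_report("outlier_meioses", n_in,
                                  calls$call_id[drop], details = details))
}

#' Marker-level genotype quality control
#'
#' Excludes markers with (i) missing genotypes in more than
#' `max_missing_fraction` of samples, (ii) any duo Mendelian inconsistency
#' (parent homozygous for one allele, child homozygous for the other), or
#' (iii) a per-marker error probability above `marker_error_probability`.
#'
#' @param markers data frame with `marker_id` and optional `missing_fraction`
#'   and `error_prob` columns.
#' @param duo_genotypes optional long-format data frame `marker_id`,
#'   `duo_id`, `parent_gt`, `child_gt` with genotypes coded "AA"/"AB"/"BB"
#'   (NA for missing).
#' @param config a [filter_config()].
#' @return list with `exclude` (marker ids) and a per-rule `report` data
#'   frame.
#' @export
genotype_qc <- function(markers, duo_genotypes = NULL,
                        config = filter_config()) {
  assert_columns(markers, "marker_id", "marker table")
  excl_missing <- excl_mendel <- excl_error <- character(0)
  if (!is.null(markers$missing_fraction)) {
    excl_missing <- markers$marker_id[
      markers$missing_fraction > config$max_missing_fraction]
  }
  if (!is.null(duo_genotypes)) {
    assert_columns(duo_genotypes, c("marker_id", "parent_gt", "child_gt"),
                   "duo genotype table")
    viol <- (duo_genotypes$parent_gt == "AA" & duo_genotypes$child_gt == "BB") |
            (duo_genotypes$parent_gt == "BB" & duo_genotypes$child_gt == "AA")
    viol[is.na(viol)] <- FALSE
    excl_mendel <- unique(duo_genotypes$marker_id[viol])
  }
  if (!is.null(markers$error_prob)) {
    excl_error <- markers$marker_id[
      !is.na(markers$error_prob) &
        markers$error_prob > config$marker_error_probability]
  }
  exclude <- unique(c(excl_missing, excl_mendel, excl_error))
  list(exclude = exclude,
       report = data.frame(
         rule = c("missingness", "mendelian", "error_probability", "total"),
         n_excluded = c(length(excl_missing), length(excl_mendel),
                        length(excl_error), length(exclude))))
}

#' Apply the full crossover filter chain
#'
#' Probability, blacklist, clustered double-crossover and outlier-meiosis
#' filters in sequence, mirroring the study's filtering flow.
#'
#' @param calls crossover call table.
#' @param config a [filter_config()].
#' @return list with filtered `calls` and a list of `reports`.
#' @export
apply_crossover_filters <- function(calls, config = filter_config()) {
  reports <- list()
  st <- filter_low_probability_calls(calls, config)
  reports$low_probability <- st$report
  st2 <- filter_blacklist_regions(st$calls, config)
  reports$blacklist <- st2$report
  st3 <- filter_clustered_double_crossovers(st2$calls, config)
  reports$double_xo_cluster <- st3$report
  st4 <- filter_outlier_meioses(st3$calls, config)
  reports$outlier_meioses <- st4$report
  list(calls = st4$calls, reports = reports)
}
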