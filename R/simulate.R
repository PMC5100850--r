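## Synthetic meiosis simulator.
##
## Crossovers are placed on the genetic scale by a two-pathway process:
## an interfering pathway -- a stationary renewal process of chiasmata with
## gamma(shape nu, rate 2 nu (1 - p)) inter-arrivals, each chiasma retained
## with probability 1/2 (chromatid thinning) -- plus an escape pathway, a
## homogeneous Poisson process with rate p per Morgan. The expected crossover
## count per meiosis and chromosome equals the genetic length in Morgans for
## any nu. Genetic positions are mapped to base pairs through the inverse of
## the supplied per-sex truth map.

#' canFam3.1 autosome lengths
#'
#' Physical lengths of the 38 dog autosomes in the canFam3.1 assembly,
#' shipped as a plain-text chromosome-sizes table.
#'
#' @return data frame with columns `chrom` and `length_bp`.
#' @export
canfam_autosomes <- function() {
  read_tsv(system.file("extdata", "canfam3.1_autosomes.tsv",
                       package = "canrec", mustWork = TRUE))
}

#' Simulation configuration
#'
#' Defaults reproduce the design of the dog pedigree dataset: 204 meioses per
#' sex over the 38 canFam3.1 autosomes, sex-specific autosomal map totals of
#' 2162 cM (female) and 1816 cM (male) distributed proportionally to physical
#' length, interference parameters from the gamma-escape model fits
#' (female nu = 30.64, p = 0.035; male nu = 14.05, p = 0.055), a male
#' telomeric concentration of 38.2% of recombination within 5 Mb of the
#' distal end (9.7% in females), a 100-kb marker grid (102-kb median
#' crossover interval), and artifact rates matching the observed fractions of
#' clustered false double crossovers (~1% of calls) and outlier meioses
#' (~1.5% of meioses).
#'
#' @param n_meioses_per_sex meioses per sex; scalar or named
#'   `c(female =, male =)` vector (0 disables a sex).
#' @param chrom_lengths data frame `chrom`, `length_bp`.
#' @param genetic_lengths optional data frame `chrom`, `female_cM`, `male_cM`;
#'   by default sex totals are split proportionally to physical length.
#' @param total_cM named vector of autosomal totals used when
#'   `genetic_lengths` is `NULL`.
#' @param nu interference shape (> 0); scalar or per-sex named vector.
#' @param p_escape escape proportion in `[0, 1]`; scalar or per-sex.
#' @param telomere_bias list with `window_bp` and per-sex fractions of each
#'   chromosome's genetic length placed in the distal window (male telomeric
#'   bias); set fractions to `NA` for uniform maps.
#' @param censor_fraction expected fraction of each chromosome lacking
#'   informative markers (split between the two ends).
#' @param marker_spacing_bp marker grid spacing; the bounding interval of an
#'   observed crossover has this median width.
#' @param prob_shape shape of the Beta(shape, 1) call-probability draw for
#'   genuine events (near 1 for large shape).
#' @param artifact_rates list: `cluster_rate` (expected shared-boundary
#'   double-crossover cluster groups per meiosis), `outlier_rate` (probability
#'   a meiosis is an outlier), `outlier_factor` (range of the count
#'   multiplier for outliers).
#' @param children_per_parent pedigree fan-out (controls how many meioses
#'   share a parent).
#' @param seed integer seed; identical seeds give byte-identical datasets.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_meioses_per_sex = c(female = 204, male = 204),
                       chrom_lengths = canfam_autosomes(),
                       genetic_lengths = NULL,
                       total_cM = c(female = 2162, male = 1816),
                       nu = c(female = 30.64, male = 14.05),
                       p_escape = c(female = 0.035, male = 0.055),
                       telomere_bias = list(window_bp = 5e6,
                                            female = 0.097, male = 0.382),
                       censor_fraction = 0.05,
                       marker_spacing_bp = 1e5,
                       prob_shape = 20,
                       artifact_rates = list(cluster_rate = 0.005,
                                             outlier_rate = 0.0145,
                                             outlier_factor = c(3, 8)),
                       children_per_parent = 4,
                       seed = 1L) {
  assert_columns(chrom_lengths, c("chrom", "length_bp"), "chrom_lengths")
  if (any(chrom_lengths$length_bp <= 0)) stop("chromosome lengths must be > 0")
  for (sx in c("female", "male")) {
    assert_scalar_number(sex_param(nu, sx, "nu"), "nu", lower = 0,
                         strict_lower = TRUE)
    assert_scalar_number(sex_param(p_escape, sx, "p_escape"), "p_escape",
                         lower = 0, upper = 1)
  }
  assert_scalar_number(censor_fraction, "censor_fraction", lower = 0, upper = 0.9)
  if (length(n_meioses_per_sex) == 1L && is.null(names(n_meioses_per_sex))) {
    n_meioses_per_sex <- c(female = n_meioses_per_sex, male = n_meioses_per_sex)
  }
  cfg <- list(n_meioses_per_sex = n_meioses_per_sex,
              chrom_lengths = chrom_lengths,
              genetic_lengths = genetic_lengths,
              total_cM = total_cM,
              nu = nu, p_escape = p_escape,
              telomere_bias = telomere_bias,
              censor_fraction = censor_fraction,
              marker_spacing_bp = marker_spacing_bp,
              prob_shape = prob_shape,
              artifact_rates = artifact_rates,
              children_per_parent = children_per_parent,
              seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

## Per-sex per-chromosome genetic lengths (cM) implied by the config.
config_genetic_lengths <- function(config) {
  if (!is.null(config$genetic_lengths)) {
    gl <- config$genetic_lengths
    assert_columns(gl, c("chrom", "female_cM", "male_cM"), "genetic_lengths")
    return(gl)
  }
  P <- config$chrom_lengths$length_bp
  data.frame(chrom = config$chrom_lengths$chrom,
             female_cM = config$total_cM[["female"]] * P / sum(P),
             male_cM = config$total_cM[["male"]] * P / sum(P))
}

#' Ground-truth genetic maps implied by a simulation configuration
#'
#' Each chromosome gets a two-segment map: a distal telomeric window holding
#' the configured fraction of the chromosome's genetic length, and a uniform
#' interior. With `telomere_bias` fractions set to `NA` the map is uniform.
#'
#' @param config a [sim_config()].
#' @return list with `female` and `male` [genetic_map()]s.
#' @export
sim_truth_maps <- function(config) {
  gl <- config_genetic_lengths(config)
  tb <- config$telomere_bias
  out <- list()
  for (sx in c("female", "male")) {
    frac <- tb[[sx]]
    rows <- list()
    for (i in seq_len(nrow(gl))) {
      P <- config$chrom_lengths$length_bp[i]
      cc <- gl$chrom[i]
      L <- gl[[paste0(sx, "_cM")]][i]
      w <- min(tb$window_bp %||% 5e6, P / 2)
      if (is.null(frac) || is.na(frac)) {
        rows[[i]] <- data.frame(chrom = cc, start = 0, end = P, cM = L)
      } else {
        rows[[i]] <- data.frame(chrom = cc,
                                start = c(0, P - w), end = c(P - w, P),
                                cM = c((1 - frac) * L, frac * L))
      }
    }
    out[[sx]] <- genetic_map(do.call(rbind, rows), sex = sx)
  }
  out
}

## Stationary gamma renewal process on [0, L): arrivals of a renewal process
## with gamma(nu, rate) inter-arrivals, started 20 mean inter-arrivals before
## the origin so the process is at equilibrium at 0.
renewal_arrivals <- function(L, nu, rate) {
  mu <- nu / rate
  t0 <- -20 * mu
  n0 <- max(16L, ceiling((L - t0) / mu * 1.4) + 8L)
  arr <- t0 + cumsum(rgamma(n0, shape = nu, rate = rate))
  while (arr[length(arr)] < L) {
    arr <- c(arr, arr[length(arr)] + cumsum(rgamma(n0, shape = nu, rate = rate)))
  }
  arr[arr >= 0 & arr < L]
}

#' Simulate true crossover events
#'
#' Draws crossovers for every meiosis and chromosome under the two-pathway
#' interference model (see the package vignette) and maps genetic positions
#' to base pairs through the inverse of the truth map.
#'
#' @param config a [sim_config()]; `config$seed` is applied when not `NULL`.
#' @return object of class `true_crossover_set`: list with `events`
#'   (meiosis_id, parent_id, child_id, parent_sex, chrom, pos_M, pos_bp,
#'   pathway, genuine), `meioses`, `maps` (truth maps) and `config`.
#' @export
simulate_crossovers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  maps <- sim_truth_maps(config)
  gl <- config_genetic_lengths(config)
  meioses <- sim_pedigree(config)
  ev <- list()
  for (sx in c("female", "male")) {
    mm <- meioses[meioses$parent_sex == sx, , drop = FALSE]
    if (nrow(mm) == 0L) next
    nu <- sex_param(config$nu, sx, "nu")
    p <- sex_param(config$p_escape, sx, "p_escape")
    map <- maps[[sx]]
    for (i in seq_len(nrow(mm))) {
      for (ci in seq_len(nrow(gl))) {
        cc <- gl$chrom[ci]
        L <- gl[[paste0(sx, "_cM")]][ci] / 100  # Morgans
        pos <- numeric(0); path <- character(0)
        if (p < 1) {
          chiasma <- renewal_arrivals(L, nu, rate = 2 * nu * (1 - p))
          keep <- rbinom(length(chiasma), 1L, 0.5) == 1L
          pos <- chiasma[keep]
          path <- rep("interference", length(pos))
        }
        n_esc <- rpois(1L, p * L)
        if (n_esc > 0L) {
          pos <- c(pos, runif(n_esc, 0, L))
          path <- c(path, rep("escape", n_esc))
        }
        if (length(pos) == 0L) next
        o <- order(pos)
        pos <- pos[o]; path <- path[o]
        bp <- cM_to_bp(map, cc, 100 * pos)
        ev[[length(ev) + 1L]] <- data.frame(
          meiosis_id = mm$meiosis_id[i], parent_id = mm$parent_id[i],
          child_id = mm$child_id[i], parent_sex = sx, chrom = cc,
          pos_M = pos, pos_bp = bp, pathway = path, genuine = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(meiosis_id = character(0), parent_id = character(0),
               child_id = character(0), parent_sex = character(0),
               chrom = character(0), pos_M = numeric(0), pos_bp = numeric(0),
               pathway = character(0), genuine = logical(0))
  rownames(events) <- NULL
  structure(list(events = events, meioses = meioses, maps = maps,
                 config = config),
            class = "true_crossover_set")
}

#' @export
print.true_crossover_set <- function(x, ...) {
  cat(sprintf("True crossover set: %d events across %d meioses (%d female, %d male)\n",
              nrow(x$events), nrow(x$meioses),
              sum(x$meioses$parent_sex == "female"),
              sum(x$meioses$parent_sex == "male")))
  invisible(x)
}

## Minimal FAM-style pedigree: founder parents, each with children_per_parent
## offspring; one meiosis per parent-child duo.
sim_pedigree <- function(config) {
  out <- list()
  for (sx in c("female", "male")) {
    n <- config$n_meioses_per_sex[[sx]]
    if (is.na(n) || n <= 0) next
    fan <- max(1L, config$children_per_parent)
    n_par <- ceiling(n / fan)
    parent <- sprintf("%s%03d", ifelse(sx == "female", "DAM", "SIRE"),
                      rep(seq_len(n_par), each = fan)[seq_len(n)])
    child <- sprintf("CH%s%03d", ifelse(sx == "female", "F", "M"), seq_len(n))
    out[[sx]] <- data.frame(
      meiosis_id = paste(parent, child, sep = "_"),
      parent_id = parent, child_id = child, parent_sex = sx,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Marker grid per chromosome: fixed spacing, anchored at 0, chromosome end
## appended so the whole chromosome is observable when censoring is off.
sim_markers <- function(config) {
  out <- lapply(seq_len(nrow(config$chrom_lengths)), function(i) {
    P <- config$chrom_lengths$length_bp[i]
    p <- unique(c(seq(0, P, by = config$marker_spacing_bp), P))
    data.frame(chrom = config$chrom_lengths$chrom[i], pos_bp = p)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Censor events to informative spans and report bounded call intervals
#'
#' Each duo and chromosome receives a random informative span (the region
#' between the parent's first and last heterozygous markers); events outside
#' the span are invisible. Retained events are reported as the marker
#' interval bounding the true position, with a call probability drawn near 1
#' for genuine events.
#'
#' @param truth a `true_crossover_set` from [simulate_crossovers()].
#' @param config the [sim_config()] used to generate it.
#' @return list with `calls` (observed crossover-call table), `spans`
#'   (informative spans per duo and chromosome) and `markers`.
#' @export
censor_informative_spans <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "true_crossover_set"))
  markers <- sim_markers(config)
  cl <- config$chrom_lengths
  meioses <- truth$meioses
  cf <- config$censor_fraction
  spans <- list()
  for (ci in seq_len(nrow(cl))) {
    P <- cl$length_bp[ci]
    cc <- cl$chrom[ci]
    mpos <- markers$pos_bp[markers$chrom == cc]
    left_cut <- runif(nrow(meioses), 0, cf * P)
    right_cut <- P - runif(nrow(meioses), 0, cf * P)
    ## smallest marker >= left_cut
    first_het <- mpos[pmin(length(mpos),
                           findInterval(left_cut, mpos, left.open = TRUE) + 1L)]
    ## largest marker <= right_cut
    last_het <- mpos[pmax(1L, findInterval(right_cut, mpos))]
    bad <- first_het >= last_het
    if (any(bad)) { first_het[bad] <- mpos[1L]; last_het[bad] <- mpos[length(mpos)] }
    spans[[ci]] <- data.frame(meiosis_id = meioses$meiosis_id, chrom = cc,
                              first_het_bp = first_het, last_het_bp = last_het,
                              stringsAsFactors = FALSE)
  }
  spans <- do.call(rbind, spans)
  rownames(spans) <- NULL

  ev <- truth$events
  key <- paste(ev$meiosis_id, ev$chrom)
  skey <- paste(spans$meiosis_id, spans$chrom)
  si <- match(key, skey)
  inside <- ev$pos_bp > spans$first_het_bp[si] & ev$pos_bp < spans$last_het_bp[si]
  obs <- ev[inside, , drop = FALSE]
  if (nrow(obs) > 0L) {
    left <- right <- numeric(nrow(obs))
    for (cc in unique(obs$chrom)) {
      i <- which(obs$chrom == cc)
      mpos <- markers$pos_bp[markers$chrom == cc]
      j <- findInterval(obs$pos_bp[i], mpos)
      j <- pmin(pmax(j, 1L), length(mpos) - 1L)
      left[i] <- mpos[j]
      right[i] <- mpos[j + 1L]
    }
    calls <- data.frame(
      meiosis_id = obs$meiosis_id, parent_id = obs$parent_id,
      child_id = obs$child_id, parent_sex = obs$parent_sex,
      chrom = obs$chrom, left_bp = left, right_bp = right,
      probability = rbeta(nrow(obs), config$prob_shape, 1),
      genuine = TRUE, artifact = NA_character_,
      stringsAsFactors = FALSE)
  } else {
    calls <- empty_calls()
  }
  calls <- calls[order(calls$meiosis_id, calls$chrom, calls$left_bp), ]
  calls$call_id <- seq_len(nrow(calls))
  rownames(calls) <- NULL
  list(calls = calls, spans = spans, markers = markers)
}

empty_calls <- function() {
  data.frame(meiosis_id = character(0), parent_id = character(0),
             child_id = character(0), parent_sex = character(0),
             chrom = character(0), left_bp = numeric(0), right_bp = numeric(0),
             probability = numeric(0), genuine = logical(0),
             artifact = character(0), stringsAsFactors = FALSE)
}

#' Inject genotyping-error artifacts into an observed call table
#'
#' Adds (i) clustered false double crossovers: pairs of calls within 1 Mb
#' whose interval boundaries are shared across two meioses of the same parent
#' (the signature of a genotyping error at a common SNP), and (ii) outlier
#' meioses with abnormally inflated crossover counts. All injected records
#' carry `genuine = FALSE` and an `artifact` label so that filter sensitivity
#' and specificity are measurable.
#'
#' @param calls observed call table from [censor_informative_spans()].
#' @param config the [sim_config()]; `artifact_rates` of zero make this a
#'   no-op.
#' @param meioses meiosis roster (defaults to the duos present in `calls`).
#' @param n_clusters,n_outliers optional exact artifact counts overriding the
#'   Poisson/Bernoulli draws (used for constructed test fixtures).
#' @return the call table with artifact records appended.
#' @export
inject_artifacts <- function(calls, config, meioses = NULL,
                             n_clusters = NULL, n_outliers = NULL) {
  ar <- config$artifact_rates
  if (is.null(meioses)) {
    meioses <- unique(calls[, c("meiosis_id", "parent_id", "child_id",
                                "parent_sex")])
  }
  n_mei <- nrow(meioses)
  if (is.null(n_clusters)) {
    n_clusters <- if ((ar$cluster_rate %||% 0) > 0)
      rpois(1L, ar$cluster_rate * n_mei) else 0L
  }
  if (is.null(n_outliers)) {
    n_outliers <- if ((ar$outlier_rate %||% 0) > 0)
      rbinom(1L, n_mei, ar$outlier_rate) else 0L
  }
  if (n_clusters == 0L && n_outliers == 0L) return(calls)

  cl <- config$chrom_lengths
  spacing <- config$marker_spacing_bp
  new_rows <- list()

  ## (i) shared-boundary clustered double crossovers
  multi <- split(meioses$meiosis_id, meioses$parent_id)
  multi <- multi[vapply(multi, length, integer(1L)) >= 2L]
  for (g in seq_len(n_clusters)) {
    if (length(multi) == 0L) break
    par <- sample(names(multi), 1L)
    mids <- sample(multi[[par]], 2L)
    ci <- sample.int(nrow(cl), 1L)
    P <- cl$length_bp[ci]
    ## keep the false cluster clear of genuine calls in the chosen meioses so
    ## that the pair structure is unambiguously the injected error signature
    occupied <- calls[calls$meiosis_id %in% mids & calls$chrom == cl$chrom[ci], ]
    b <- NA_real_
    for (try in 1:25) {
      cand <- round(runif(1L, 0.1 * P, 0.9 * P) / spacing) * spacing
      if (nrow(occupied) == 0L ||
          all(abs((occupied$left_bp + occupied$right_bp) / 2 - cand) > 2e6)) {
        b <- cand
        break
      }
    }
    if (is.na(b)) next
    s <- spacing
    for (m in mids) {
      meta <- meioses[meioses$meiosis_id == m, ][1L, ]
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        meiosis_id = m, parent_id = meta$parent_id, child_id = meta$child_id,
        parent_sex = meta$parent_sex, chrom = cl$chrom[ci],
        left_bp = c(b - 2 * s, b + s), right_bp = c(b - s, b + 2 * s),
        probability = runif(2L, 0.6, 1),
        genuine = FALSE, artifact = "double_xo", stringsAsFactors = FALSE)
    }
  }

  ## (ii) outlier meioses with inflated counts
  if (n_outliers > 0L && nrow(calls) > 0L) {
    counts <- table(calls$meiosis_id)
    mean_count <- mean(counts)
    out_ids <- sample(meioses$meiosis_id, min(n_outliers, n_mei))
    for (m in out_ids) {
      meta <- meioses[meioses$meiosis_id == m, ][1L, ]
      fac <- runif(1L, ar$outlier_factor[1L], ar$outlier_factor[2L])
      cur <- sum(calls$meiosis_id == m)
      n_add <- max(0L, round(fac * mean_count) - cur)
      if (n_add == 0L) next
      ci <- sample.int(nrow(cl), n_add, replace = TRUE,
                       prob = cl$length_bp)
      pos <- floor(runif(n_add, 0, (cl$length_bp[ci] - spacing)) / spacing) * spacing
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        meiosis_id = m, parent_id = meta$parent_id, child_id = meta$child_id,
        parent_sex = meta$parent_sex, chrom = cl$chrom[ci],
        left_bp = pos, right_bp = pos + spacing,
        probability = runif(n_add, 0.6, 1),
        genuine = FALSE, artifact = "outlier", stringsAsFactors = FALSE)
    }
  }

  if (length(new_rows) == 0L) return(calls)
  add <- do.call(rbind, new_rows)
  out <- rbind(calls[, setdiff(names(calls), "call_id"), drop = FALSE], add)
  out <- out[order(out$meiosis_id, out$chrom, out$left_bp), ]
  out$call_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic dataset
#'
#' Runs [simulate_crossovers()], [censor_informative_spans()] and
#' [inject_artifacts()] under a single seed. The result is byte-identical
#' across runs with the same configuration.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset` with `truth`, `calls`, `spans`,
#'   `markers`, `maps`, `meioses` and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  truth <- simulate_crossovers(config)
  obs <- censor_informative_spans(truth, config)
  calls <- inject_artifacts(obs$calls, config, meioses = truth$meioses)
  structure(list(truth = truth, calls = calls, spans = obs$spans,
                 markers = obs$markers, maps = truth$maps,
                 meioses = truth$meioses, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic dataset: %d observed calls (%d genuine, %d artifact) / %d true events\n",
    nrow(x$calls), sum(x$calls$genuine), sum(!x$calls$genuine),
    nrow(x$truth$events)))
  invisible(x)
}
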