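## Crossover interference: likelihood inference under the gamma renewal and
## Housworth-Stahl gamma-escape models.
##
## The chiasma process on the four-strand bundle is a stationary renewal
## process on the genetic scale with gamma(shape nu, rate beta) inter-arrival
## distances; each chiasma involves a given chromatid with probability 1/2
## (chromatid thinning), so the observed crossover process is the renewal
## process thinned independently by 1/2. Under thinning, the inter-crossover
## density is the geometric mixture
##     f(x) = sum_{j >= 1} (1/2)^j gammaPDF(x; j nu, beta),
## truncated when (1/2)^j < 1e-12, with mean mu = 2 nu / beta. For the pure
## gamma model beta = 2 nu, giving one crossover per Morgan on average. The
## gamma-escape model superposes an independent homogeneous Poisson pathway
## with rate p per Morgan and slows the interfering pathway to
## beta = 2 nu (1 - p), preserving the total rate of 1 per Morgan.
##
## Sequence likelihoods use the full stationary-renewal form with end
## effects: the first event contributes the equilibrium forward-recurrence
## density S(x1)/mu, inner gaps contribute f, the right end contributes the
## survival S(L - xk), and an empty sequence contributes
## P(no event in [0, L]) = (mu - L + int_0^L F(u) du) / mu.

MAX_MIXTURE_TERMS <- 40L   # (1/2)^40 < 1e-12

## Number of mixture terms that carry mass below xmax (early truncation for
## strongly interfering processes on short chromosomes).
mixture_terms <- function(nu, beta, xmax) {
  j <- seq_len(MAX_MIXTURE_TERMS)
  pg <- pgamma(xmax, shape = j * nu, rate = beta)
  w <- which(pg * 0.5^j > 1e-17)
  if (length(w) == 0L) 1L else max(w)
}

## f, F, and int_0^L F for the thinned-renewal inter-arrival distribution.
thinned_pdf <- function(x, nu, beta, jmax) {
  out <- numeric(length(x))
  for (j in seq_len(jmax)) {
    out <- out + 0.5^j * dgamma(x, shape = j * nu, rate = beta)
  }
  out
}

thinned_cdf <- function(x, nu, beta, jmax) {
  out <- numeric(length(x))
  for (j in seq_len(jmax)) {
    out <- out + 0.5^j * pgamma(x, shape = j * nu, rate = beta)
  }
  out
}

## int_0^L F(u) du  via  int_0^L Fgamma(u; a, b) du
##   = L Fgamma(L; a, b) - (a / b) Fgamma(L; a + 1, b)
thinned_cdf_integral <- function(L, nu, beta, jmax) {
  out <- numeric(length(L))
  for (j in seq_len(jmax)) {
    a <- j * nu
    out <- out + 0.5^j * (L * pgamma(L, shape = a, rate = beta) -
                            (a / beta) * pgamma(L, shape = a + 1, rate = beta))
  }
  out
}

## log P(no observed event in [0, L]) for the stationary thinned process.
renewal_log_p0 <- function(L, nu, beta, jmax = NULL) {
  mu <- 2 * nu / beta
  if (is.null(jmax)) jmax <- mixture_terms(nu, beta, max(L))
  val <- (mu - L + thinned_cdf_integral(L, nu, beta, jmax)) / mu
  log(pmax(val, 1e-300))
}

#' Construct a set of crossover sequences
#'
#' A crossover sequence is one meiosis on one chromosome: the ordered event
#' positions on the genetic scale together with the observable genetic
#' length. Zero-event sequences are retained; they carry likelihood
#' information.
#'
#' @param seqs data frame with `seq_id`, `L` (Morgans) and optionally
#'   `meiosis_id`, `sex`, `chrom`.
#' @param events data frame with `seq_id` and `pos` (Morgans, within
#'   `[0, L]`); may have zero rows.
#' @return object of class `xo_sequences`.
#' @export
xo_sequences <- function(seqs, events = NULL) {
  assert_columns(seqs, c("seq_id", "L"), "sequence table")
  if (any(seqs$L <= 0)) stop("sequence genetic lengths must be > 0")
  if (anyDuplicated(seqs$seq_id)) stop("duplicated seq_id")
  if (is.null(events)) {
    events <- data.frame(seq_id = character(0), pos = numeric(0))
  }
  assert_columns(events, c("seq_id", "pos"), "event table")
  if (nrow(events) > 0L) {
    Lmatch <- seqs$L[match(events$seq_id, seqs$seq_id)]
    if (anyNA(Lmatch)) stop("event refers to unknown seq_id")
    if (any(events$pos < 0 | events$pos > Lmatch)) {
      stop("event positions must lie within [0, L]")
    }
    events <- events[order(match(events$seq_id, seqs$seq_id), events$pos), ]
  }
  seqs$k <- as.integer(table(factor(events$seq_id,
                                    levels = seqs$seq_id))[seqs$seq_id])
  rownames(seqs) <- rownames(events) <- NULL
  structure(list(seqs = seqs, events = events), class = "xo_sequences")
}

#' @export
print.xo_sequences <- function(x, ...) {
  cat(sprintf(
    "Crossover sequences: %d sequences, %d events, total genetic length %.1f Morgans\n",
    nrow(x$seqs), nrow(x$events), sum(x$seqs$L)))
  invisible(x)
}

## Precompute per-sequence quantities reused across likelihood evaluations.
sequence_layout <- function(xs) {
  seqs <- xs$seqs
  ev <- xs$events
  si <- match(ev$seq_id, seqs$seq_id)
  first <- !duplicated(si)
  last <- !duplicated(si, fromLast = TRUE)
  gap_ok <- c(FALSE, si[-1L] == si[-length(si)])
  list(
    L = seqs$L, k = seqs$k,
    x_first = ev$pos[first], L_minus_last = seqs$L[si[last]] - ev$pos[last],
    gaps = ev$pos[gap_ok] - ev$pos[which(gap_ok) - 1L],
    L_empty = seqs$L[seqs$k == 0L],
    si = si)
}

#' Log-likelihood under the gamma (thinned renewal) interference model
#'
#' Full stationary-renewal likelihood of crossover sequences under a chiasma
#' process with gamma(shape `nu`, rate `2 nu`) inter-arrivals thinned by 1/2
#' per chromatid, including first-arrival, inter-arrival, right-censoring
#' and zero-count terms. At `nu = 1` this is exactly the homogeneous Poisson
#' process with rate 1 per Morgan, with total log-likelihood `-sum(L)`
#' regardless of event placement.
#'
#' @param xs an [xo_sequences()] object.
#' @param nu interference shape (> 0).
#' @return total log-likelihood over sequences.
#' @export
gamma_loglik <- function(xs, nu) {
  stopifnot(inherits(xs, "xo_sequences"))
  assert_scalar_number(nu, "nu", lower = 0, strict_lower = TRUE)
  lay <- sequence_layout(xs)
  renewal_loglik_terms(lay, nu, beta = 2 * nu)
}

renewal_loglik_terms <- function(lay, nu, beta) {
  mu <- 2 * nu / beta
  xmax <- max(lay$L, 0)
  jmax <- mixture_terms(nu, beta, xmax)
  ll <- 0
  if (length(lay$L_empty) > 0L) {
    ll <- ll + sum(renewal_log_p0(lay$L_empty, nu, beta, jmax))
  }
  if (length(lay$x_first) > 0L) {
    s1 <- 1 - thinned_cdf(lay$x_first, nu, beta, jmax)
    s2 <- 1 - thinned_cdf(lay$L_minus_last, nu, beta, jmax)
    ll <- ll + sum(log(pmax(s1, 1e-300))) - length(lay$x_first) * log(mu) +
      sum(log(pmax(s2, 1e-300)))
  }
  if (length(lay$gaps) > 0L) {
    fg <- thinned_pdf(lay$gaps, nu, beta, jmax)
    ll <- ll + sum(log(pmax(fg, 1e-300)))
  }
  if (!is.finite(ll)) {
    stop(sprintf("log-likelihood is non-finite at nu = %g", nu))
  }
  ll
}

#' Log-likelihood under the gamma-escape (Housworth-Stahl) model
#'
#' Mixture of an interfering thinned gamma renewal pathway (inter-chiasma
#' gamma(`nu`, `2 nu (1 - p)`)) and a non-interfering homogeneous Poisson
#' "escape" pathway with rate `p` per Morgan. For each sequence the
#' likelihood sums over all `2^k` assignments of the observed events to the
#' two pathways. At `p = 0` this reduces exactly to [gamma_loglik()]; at
#' `p = 1` it is the pure Poisson process.
#'
#' @param xs an [xo_sequences()] object.
#' @param nu interference shape (> 0).
#' @param p escape proportion in `[0, 1]`.
#' @param enumeration_cap maximal per-sequence event count for the exact
#'   `2^k` enumeration; sequences beyond the cap raise an error advising
#'   exclusion.
#' @return total log-likelihood over sequences.
#' @export
gamma_escape_loglik <- function(xs, nu, p, enumeration_cap = 20L) {
  stopifnot(inherits(xs, "xo_sequences"))
  assert_scalar_number(nu, "nu", lower = 0, strict_lower = TRUE)
  assert_scalar_number(p, "p", lower = 0, upper = 1)
  if (any(xs$seqs$k > enumeration_cap)) {
    stop(sprintf(
      "sequence(s) with more than %d events exceed the escape enumeration cap; exclude them first",
      enumeration_cap))
  }
  if (p == 0) return(gamma_loglik(xs, nu))
  if (p > 1 - 1e-9) {
    ## pure Poisson with rate p ~ 1
    return(sum(xs$seqs$k * log(p)) - p * sum(xs$seqs$L))
  }
  beta <- 2 * nu * (1 - p)
  mu <- 2 * nu / beta
  jmax <- mixture_terms(nu, beta, max(xs$seqs$L))
  log_p <- log(p)
  ll <- 0
  ev_by_seq <- split(xs$events$pos,
                     factor(xs$events$seq_id, levels = xs$seqs$seq_id))
  for (i in seq_len(nrow(xs$seqs))) {
    L <- xs$seqs$L[i]
    x <- ev_by_seq[[i]]
    k <- length(x)
    lp0 <- renewal_log_p0(L, nu, beta, jmax)
    if (k == 0L) {
      ll <- ll + lp0 - p * L
      next
    }
    ## pairwise gap log-densities and end terms, reused across subsets
    logS_first <- log(pmax(1 - thinned_cdf(x, nu, beta, jmax), 1e-300)) - log(mu)
    logS_last <- log(pmax(1 - thinned_cdf(L - x, nu, beta, jmax), 1e-300))
    logf <- matrix(-Inf, k, k)
    if (k > 1L) {
      for (a in seq_len(k - 1L)) {
        logf[a, (a + 1L):k] <- log(pmax(
          thinned_pdf(x[(a + 1L):k] - x[a], nu, beta, jmax), 1e-300))
      }
    }
    terms <- numeric(2^k)
    for (mask in 0:(2^k - 1L)) {
      esc <- as.logical(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))))
      idx <- which(!esc)           # interference-pathway events
      s <- k - length(idx)
      lr <- if (length(idx) == 0L) lp0 else {
        v <- logS_first[idx[1L]] + logS_last[idx[length(idx)]]
        if (length(idx) > 1L) {
          v <- v + sum(logf[cbind(idx[-length(idx)], idx[-1L])])
        }
        v
      }
      terms[mask + 1L] <- s * log_p + lr
    }
    ll <- ll + log_sum_exp(terms) - p * L
  }
  if (!is.finite(ll)) stop(sprintf("log-likelihood non-finite at nu = %g, p = %g", nu, p))
  ll
}

#' Place crossover calls on the genetic scale
#'
#' Converts each call's physical midpoint to a cumulative genetic position
#' through the sex-matched map and assembles one crossover sequence per
#' meiosis and chromosome, with the chromosome's genetic length (or the
#' informative span's genetic length, when spans are provided) as the
#' observable length.
#'
#' @param calls filtered crossover call table.
#' @param map the sex-matched [genetic_map()].
#' @param meioses optional roster (`meiosis_id`, and optionally `parent_sex`)
#'   ensuring zero-event sequences are represented; defaults to the meioses
#'   present in `calls`.
#' @param spans optional informative spans; when given, each sequence is
#'   restricted to its span (positions re-expressed relative to the span
#'   start on the genetic scale).
#' @return an [xo_sequences()] object.
#' @export
to_genetic_scale <- function(calls, map, meioses = NULL, spans = NULL) {
  if (is.null(meioses)) {
    meioses <- unique(calls[, intersect(c("meiosis_id", "parent_sex"),
                                        names(calls)), drop = FALSE])
  }
  chroms <- unique(map$chrom)
  chrom_cM <- map_total_cM(map, by_chrom = TRUE)
  seq_rows <- list(); ev_rows <- list()
  for (cc in chroms) {
    span_c <- if (!is.null(spans)) spans[spans$chrom == cc, , drop = FALSE] else NULL
    for (mi in seq_len(nrow(meioses))) {
      mid <- meioses$meiosis_id[mi]
      sid <- paste(mid, cc, sep = "|")
      lo_cM <- 0; hi_cM <- chrom_cM[[cc]]
      if (!is.null(span_c)) {
        sr <- span_c[span_c$meiosis_id == mid, , drop = FALSE]
        if (nrow(sr) == 1L) {
          lo_cM <- bp_to_cM(map, cc, sr$first_het_bp)
          hi_cM <- bp_to_cM(map, cc, sr$last_het_bp)
        }
      }
      L <- (hi_cM - lo_cM) / 100
      if (L <= 0) next
      seq_rows[[length(seq_rows) + 1L]] <- data.frame(
        seq_id = sid, meiosis_id = mid,
        sex = if ("parent_sex" %in% names(meioses))
          norm_sex(meioses$parent_sex[mi]) else NA_character_,
        chrom = cc, L = L, stringsAsFactors = FALSE)
      cl <- calls[calls$meiosis_id == mid & calls$chrom == cc, , drop = FALSE]
      if (nrow(cl) > 0L) {
        mids_bp <- (cl$left_bp + cl$right_bp) / 2
        pos <- (bp_to_cM(map, cc, mids_bp) - lo_cM) / 100
        pos <- pmin(pmax(pos, 0), L)
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          seq_id = sid, pos = pos, stringsAsFactors = FALSE)
      }
    }
  }
  xo_sequences(do.call(rbind, seq_rows),
               if (length(ev_rows)) do.call(rbind, ev_rows) else NULL)
}

#' Crossover sequences from simulated ground truth
#'
#' Builds [xo_sequences()] directly from the true genetic-scale positions of
#' a simulated crossover set (no censoring or localization error), one
#' sequence per meiosis and chromosome.
#'
#' @param truth a `true_crossover_set` from [simulate_crossovers()].
#' @param sex optionally restrict to one parental sex.
#' @return an [xo_sequences()] object.
#' @export
true_sequences <- function(truth, sex = NULL) {
  stopifnot(inherits(truth, "true_crossover_set"))
  gl <- config_genetic_lengths(truth$config)
  meioses <- truth$meioses
  if (!is.null(sex)) {
    meioses <- meioses[meioses$parent_sex == norm_sex(sex), , drop = FALSE]
  }
  seq_rows <- list()
  for (sx in unique(meioses$parent_sex)) {
    mm <- meioses$meiosis_id[meioses$parent_sex == sx]
    Lc <- gl[[paste0(sx, "_cM")]] / 100
    seq_rows[[sx]] <- data.frame(
      seq_id = paste(rep(mm, each = nrow(gl)), gl$chrom, sep = "|"),
      meiosis_id = rep(mm, each = nrow(gl)),
      sex = sx, chrom = rep(gl$chrom, length(mm)),
      L = rep(Lc, length(mm)), stringsAsFactors = FALSE)
  }
  seqs <- do.call(rbind, seq_rows)
  ev <- truth$events
  ev <- ev[ev$meiosis_id %in% meioses$meiosis_id, , drop = FALSE]
  events <- data.frame(seq_id = paste(ev$meiosis_id, ev$chrom, sep = "|"),
                       pos = ev$pos_M, stringsAsFactors = FALSE)
  xo_sequences(seqs, events)
}

#' Fit a crossover-interference model by maximum likelihood
#'
#' Bounded maximum-likelihood estimation of the gamma model (shape `nu`) or
#' the gamma-escape model (`nu` and escape proportion `p`), with percentile
#' bootstrap confidence intervals obtained by resampling whole meioses with
#' replacement, and BIC computed with `n` equal to the number of
#' meiosis-by-chromosome sequences.
#'
#' @param xs an [xo_sequences()] object; at least one sequence must carry an
#'   event.
#' @param model `"gamma"` or `"gamma_escape"`.
#' @param bootstrap_n bootstrap resamples for the confidence intervals
#'   (0 disables the bootstrap).
#' @param seed optional seed for the bootstrap.
#' @param nu_bounds search bounds for `nu`.
#' @param enumeration_cap see [gamma_escape_loglik()]; sequences above the
#'   cap are excluded from the gamma-escape fit with a message.
#' @return object of class `interference_fit` with elements `model`, `nu`,
#'   `p`, `logL`, `bic`, `n`, `k_params`, `ci` and `boot`.
#' @export
fit_interference <- function(xs, model = c("gamma", "gamma_escape"),
                             bootstrap_n = 1000L, seed = NULL,
                             nu_bounds = c(0.1, 200),
                             enumeration_cap = 20L) {
  model <- match.arg(model)
  stopifnot(inherits(xs, "xo_sequences"))
  if (sum(xs$seqs$k) == 0L) stop("no crossover events: cannot fit an interference model")
  n_excluded <- 0L
  if (model == "gamma_escape") {
    over <- xs$seqs$k > enumeration_cap
    if (any(over)) {
      n_excluded <- sum(over)
      message(sprintf("excluding %d sequence(s) above the enumeration cap", n_excluded))
      keep <- xs$seqs$seq_id[!over]
      xs <- xo_sequences(xs$seqs[!over, , drop = FALSE],
                         xs$events[xs$events$seq_id %in% keep, , drop = FALSE])
    }
  }
  est <- fit_point(xs, model, nu_bounds, enumeration_cap)
  n <- nrow(xs$seqs)
  k_params <- if (model == "gamma") 1L else 2L
  bic <- -2 * est$logL + k_params * log(n)
  boot <- NULL; ci <- list(nu = c(NA_real_, NA_real_), p = c(NA_real_, NA_real_))
  if (bootstrap_n > 0L) {
    if (!is.null(seed)) set.seed(seed)
    mids <- unique(xs$seqs$meiosis_id)
    if (length(mids) == 0L || all(is.na(mids))) {
      stop("bootstrap requires meiosis_id on the sequences")
    }
    bnu <- bp <- numeric(bootstrap_n)
    for (b in seq_len(bootstrap_n)) {
      res <- resample_meioses(xs, sample(mids, length(mids), replace = TRUE))
      eb <- fit_point(res, model, nu_bounds, enumeration_cap)
      bnu[b] <- eb$nu; bp[b] <- eb$p
    }
    ci$nu <- unname(quantile(bnu, c(0.025, 0.975)))
    if (model == "gamma_escape") ci$p <- unname(quantile(bp, c(0.025, 0.975)))
    boot <- data.frame(nu = bnu, p = bp)
  }
  structure(list(model = model, nu = est$nu, p = est$p, logL = est$logL,
                 bic = bic, n = n, k_params = k_params, ci = ci, boot = boot,
                 n_excluded = n_excluded),
            class = "interference_fit")
}

fit_point <- function(xs, model, nu_bounds, enumeration_cap) {
  if (model == "gamma") {
    opt <- optimize(function(lnu) gamma_loglik(xs, exp(lnu)),
                    interval = log(nu_bounds), maximum = TRUE, tol = 1e-3)
    return(list(nu = exp(opt$maximum), p = 0, logL = opt$objective))
  }
  g <- optimize(function(lnu) gamma_loglik(xs, exp(lnu)),
                interval = log(nu_bounds), maximum = TRUE, tol = 1e-2)
  starts <- list(c(g$maximum, 0.05),
                 c(min(log(nu_bounds[2L]), g$maximum + log(4)), 0.05))
  best <- NULL
  for (s in starts) {
    o <- optim(s, function(par) {
      nu <- exp(par[1L]); p <- par[2L]
      if (p < 0 || p > 1 || nu < nu_bounds[1L] || nu > nu_bounds[2L]) return(1e10)
      -gamma_escape_loglik(xs, nu, p, enumeration_cap)
    }, method = "L-BFGS-B",
    lower = c(log(nu_bounds[1L]), 0), upper = c(log(nu_bounds[2L]), 1),
    control = list(factr = 1e9))
    if (o$convergence != 0) {
      stop(sprintf("gamma-escape optimizer failed to converge (code %d): %s",
                   o$convergence, o$message %||% ""))
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(nu = exp(best$par[1L]), p = best$par[2L], logL = -best$value)
}

resample_meioses <- function(xs, mids) {
  pieces_s <- list(); pieces_e <- list()
  ev_split <- split(xs$events, factor(xs$events$seq_id, levels = xs$seqs$seq_id))
  for (b in seq_along(mids)) {
    i <- which(xs$seqs$meiosis_id == mids[b])
    s <- xs$seqs[i, , drop = FALSE]
    new_ids <- paste0(s$seq_id, "#", b)
    e <- do.call(rbind, ev_split[s$seq_id])
    if (!is.null(e) && nrow(e) > 0L) {
      e$seq_id <- paste0(e$seq_id, "#", b)
      pieces_e[[b]] <- e
    }
    s$seq_id <- new_ids
    pieces_s[[b]] <- s
  }
  xo_sequences(do.call(rbind, pieces_s),
               if (length(pieces_e)) do.call(rbind, pieces_e) else NULL)
}

#' @export
print.interference_fit <- function(x, ...) {
  cat(sprintf("Interference fit (%s model): nu = %.3f", x$model, x$nu))
  if (!is.na(x$ci$nu[1L])) cat(sprintf(" (95%% CI %.2f-%.2f)", x$ci$nu[1L], x$ci$nu[2L]))
  if (x$model == "gamma_escape") {
    cat(sprintf(", p = %.4f", x$p))
    if (!is.na(x$ci$p[1L])) cat(sprintf(" (95%% CI %.3f-%.3f)", x$ci$p[1L], x$ci$p[2L]))
  }
  cat(sprintf("\n  logL = %.2f, BIC = %.1f, n = %d sequences\n", x$logL, x$bic, x$n))
  invisible(x)
}

#' Compare two interference model fits by BIC
#'
#' @param fit_gamma,fit_escape [fit_interference()] results on the same
#'   sequence set (equal `n`).
#' @return list with `preferred` (model name) and `delta_bic`
#'   (BIC of the gamma fit minus BIC of the escape fit).
#' @export
compare_models <- function(fit_gamma, fit_escape) {
  if (fit_gamma$n != fit_escape$n) {
    stop("fits use different numbers of sequences; refit on a common set")
  }
  delta <- fit_gamma$bic - fit_escape$bic
  list(preferred = if (fit_escape$bic < fit_gamma$bic) fit_escape$model
       else fit_gamma$model,
       delta_bic = delta)
}

#' Stratified interference fits
#'
#' Splits meioses into strata -- either explicit labels or equal-frequency
#' bins of a numeric covariate such as parental age -- and fits the chosen
#' model independently within each stratum.
#'
#' @param xs an [xo_sequences()] object.
#' @param strata named vector (names = meiosis ids) of labels, or numeric
#'   values to be cut into `n_bins` equal-frequency bins.
#' @param n_bins number of quantile bins for numeric strata.
#' @param min_meioses strata with fewer meioses are skipped with a warning.
#' @param ... passed to [fit_interference()].
#' @return named list of `interference_fit` objects.
#' @export
stratified_fit <- function(xs, strata, n_bins = 7L, min_meioses = 10L, ...) {
  mids <- unique(xs$seqs$meiosis_id)
  if (is.null(names(strata))) stop("`strata` must be named by meiosis_id")
  strata <- strata[mids]
  if (is.numeric(strata)) {
    br <- unique(quantile(strata, probs = seq(0, 1, length.out = n_bins + 1L),
                          na.rm = TRUE))
    lab <- cut(strata, breaks = br, include.lowest = TRUE)
  } else {
    lab <- factor(strata)
  }
  out <- list()
  for (lv in levels(lab)) {
    sel <- mids[!is.na(lab) & lab == lv]
    if (length(sel) < min_meioses) {
      warning(sprintf("stratum '%s' has %d meioses (< %d); skipped",
                      lv, length(sel), min_meioses))
      next
    }
    keep <- xs$seqs$meiosis_id %in% sel
    sub <- xo_sequences(xs$seqs[keep, , drop = FALSE],
                        xs$events[xs$events$seq_id %in%
                                    xs$seqs$seq_id[keep], , drop = FALSE])
    out[[lv]] <- fit_interference(sub, ...)
  }
  out
}
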