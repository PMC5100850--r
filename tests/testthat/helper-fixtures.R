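# Shared fixtures built in code: small configurations, toy maps and call
# tables used across test files.

small_sim_config <- function(seed = 1L, n = 10L, chroms = 3L, ...) {
  sim_config(n_meioses_per_sex = c(female = n, male = n),
             chrom_lengths = canfam_autosomes()[seq_len(chroms), ],
             seed = seed, ...)
}

uniform_map <- function(len_bp = 1e8, rate = 1, chrom = "chr1", sex = "female") {
  genetic_map(data.frame(chrom = chrom, start = 0, end = len_bp,
                         cM = rate * len_bp / 1e6), sex = sex)
}

# a map on a regular grid with per-interval cM values
grid_map <- function(cM, width = 1e6, chrom = "chr1", sex = "female") {
  n <- length(cM)
  genetic_map(data.frame(chrom = chrom, start = (0:(n - 1)) * width,
                         end = (1:n) * width, cM = cM), sex = sex)
}

toy_calls <- function(probability = 0.9, chrom = "chr1",
                      left = 1e6, right = 1.2e6,
                      meiosis = "P1_C1", parent = "P1", sex = "female") {
  n <- max(lengths(list(probability, left, right, meiosis)))
  data.frame(meiosis_id = rep_len(meiosis, n), parent_id = rep_len(parent, n),
             child_id = sub("^[^_]*_", "", rep_len(meiosis, n)),
             parent_sex = rep_len(sex, n), chrom = rep_len(chrom, n),
             left_bp = rep_len(left, n), right_bp = rep_len(right, n),
             probability = rep_len(probability, n),
             stringsAsFactors = FALSE)
}

# random sequence sets for likelihood property tests
random_sequences <- function(n_seq = 8L, lambda = 1.2, Lmax = 2) {
  L <- runif(n_seq, 0.3, Lmax)
  k <- rpois(n_seq, lambda)
  ev <- do.call(rbind, lapply(seq_len(n_seq), function(i) {
    if (k[i] == 0L) return(NULL)
    data.frame(seq_id = sprintf("s%02d", i),
               pos = sort(runif(k[i], 0, L[i])))
  }))
  xo_sequences(data.frame(seq_id = sprintf("s%02d", seq_len(n_seq)),
                          meiosis_id = sprintf("m%02d", seq_len(n_seq)),
                          L = L),
               ev)
}
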