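## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop unless a data frame has the required columns
#' @noRd
assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  ok_lower <- if (strict_lower) x > lower else x >= lower
  if (!ok_lower || x > upper) {
    stop(sprintf("`%s` = %g is outside its valid range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

## Per-sex parameter lookup: accepts a scalar (recycled) or a vector named
## with "female"/"male".
sex_param <- function(x, sex, name = deparse(substitute(x))) {
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  if (!all(c("female", "male") %in% names(x))) {
    stop(sprintf("`%s` must be a scalar or named with 'female' and 'male'",
                 name), call. = FALSE)
  }
  unname(x[[sex]])
}

## Stable numeric formatting for TSV output.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
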