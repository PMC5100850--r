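## Readers and writers for on-disk formats.
##
## Convention: crossover-call, span and map TSVs use 1-based inclusive
## coordinates on disk (linkage-community convention); BED files are 0-based
## half-open as the format mandates. Internally everything is 0-based
## half-open; conversion is confined to this file.

CALL_COLUMNS <- c("meiosis_id", "parent_id", "child_id", "parent_sex",
                  "chrom", "left_bp", "right_bp", "probability")

#' Read a crossover-call table
#'
#' Expects a TSV with columns `meiosis_id`, `parent_id`, `child_id`,
#' `parent_sex`, `chrom`, `left_bp`, `right_bp`, `probability` (1-based
#' inclusive coordinates on disk). Extra columns are preserved.
#'
#' @param path file path.
#' @param chrom_lengths optional data frame `chrom`, `length_bp` used to
#'   validate chromosome names and bounds.
#' @return validated call table with 0-based half-open coordinates and a
#'   `call_id` column.
#' @export
read_crossover_calls <- function(path, chrom_lengths = NULL) {
  df <- read_tsv(path)
  assert_columns(df, CALL_COLUMNS, sprintf("call table '%s'", path))
  bad <- which(df$left_bp >= df$right_bp)
  if (length(bad) > 0L) {
    stop(sprintf("%s: right_bp <= left_bp at line %d", path, bad[1L] + 1L))
  }
  bad_p <- which(df$probability < 0 | df$probability > 1)
  if (length(bad_p) > 0L) {
    stop(sprintf("%s: probability outside [0, 1] at line %d", path, bad_p[1L] + 1L))
  }
  if (!is.null(chrom_lengths)) {
    bad_c <- which(!(df$chrom %in% chrom_lengths$chrom))
    if (length(bad_c) > 0L) {
      stop(sprintf("%s: unknown chromosome '%s' at line %d",
                   path, df$chrom[bad_c[1L]], bad_c[1L] + 1L))
    }
  }
  df$left_bp <- df$left_bp - 1   # to 0-based half-open
  df$parent_sex <- norm_sex(df$parent_sex)
  df$call_id <- seq_len(nrow(df))
  df
}

#' @rdname read_crossover_calls
#' @param calls call table to write (internal 0-based coordinates).
#' @export
write_crossover_calls <- function(calls, path) {
  out <- calls[, c(CALL_COLUMNS,
                   intersect(c("genuine", "artifact"), names(calls))),
               drop = FALSE]
  out$left_bp <- out$left_bp + 1  # to 1-based inclusive
  write_tsv(out, path)
}

#' Read/write informative-span tables
#'
#' TSV with columns `meiosis_id`, `chrom`, `first_het_bp`, `last_het_bp`
#' (1-based positions on disk).
#'
#' @param path file path.
#' @return span table.
#' @export
read_informative_spans <- function(path) {
  df <- read_tsv(path)
  assert_columns(df, c("meiosis_id", "chrom", "first_het_bp", "last_het_bp"),
                 sprintf("span table '%s'", path))
  bad <- which(df$first_het_bp >= df$last_het_bp)
  if (length(bad) > 0L) {
    stop(sprintf("%s: last_het_bp <= first_het_bp at line %d", path, bad[1L] + 1L))
  }
  df$first_het_bp <- df$first_het_bp - 1
  df
}

#' @rdname read_informative_spans
#' @param spans span table to write.
#' @export
write_informative_spans <- function(spans, path) {
  out <- spans
  out$first_het_bp <- out$first_het_bp + 1
  write_tsv(out, path)
}

#' Read/write genetic map TSVs
#'
#' Columns `chrom`, `start`, `end`, `rate_cM_per_Mb`, `cum_cM` (1-based
#' inclusive intervals on disk), with the sex label in a `sex` column.
#'
#' @param path file path.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  df <- read_tsv(path)
  assert_columns(df, c("chrom", "start", "end", "cM"),
                 sprintf("map table '%s'", path))
  sex <- if ("sex" %in% names(df)) df$sex[1L] else "sex-averaged"
  genetic_map(data.frame(chrom = df$chrom, start = df$start - 1, end = df$end,
                         cM = df$cM),
              sex = sex)
}

#' @rdname read_genetic_map
#' @param map map to write.
#' @export
write_genetic_map <- function(map, path) {
  out <- as.data.frame(map)
  out$start <- out$start + 1
  out$sex <- attr(map, "sex")
  write_tsv(out, path)
}

#' Read a chromosome-sizes table
#'
#' Two-column TSV (`chrom`, `length_bp`), with or without a header.
#'
#' @param path file path.
#' @return data frame `chrom`, `length_bp`.
#' @export
read_chrom_sizes <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("chrom", first, fixed = TRUE)
  df <- read.table(path, sep = "\t", header = header,
                   stringsAsFactors = FALSE)
  names(df)[1:2] <- c("chrom", "length_bp")
  df[, c("chrom", "length_bp")]
}

#' Read PLINK text pedigree and marker files
#'
#' `read_plink_fam()` reads a whitespace-delimited `.fam` file (family id,
#' individual id, father id, mother id, sex code, phenotype);
#' `read_plink_map()` reads a `.map` file (chromosome, marker id, genetic
#' position, physical position).
#'
#' @param path file path.
#' @return data frame with standard column names.
#' @export
read_plink_fam <- function(path) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop(sprintf("%s: FAM files need 6 columns", path))
  names(df)[1:6] <- c("family_id", "individual_id", "father_id", "mother_id",
                      "sex_code", "phenotype")
  df
}

#' @rdname read_plink_fam
#' @export
read_plink_map <- function(path) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop(sprintf("%s: MAP files need 4 columns", path))
  names(df)[1:4] <- c("chrom", "marker_id", "genetic_pos", "pos_bp")
  df
}

#' Read feature annotations (BED or GTF)
#'
#' BED intervals are returned as-is (strand-aware when present). For GTF
#' input, transcript records can be reduced to protein-coding genes keeping
#' the longest isoform per gene, the convention used for TSS profiling.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @param protein_coding_only for GTF: keep only protein-coding genes when
#'   biotype information is present.
#' @param longest_isoform for GTF: keep the longest transcript per gene.
#' @return a `GRanges` of features (transcripts for GTF input).
#' @export
read_features <- function(path, format = c("auto", "bed", "gtf"),
                          protein_coding_only = TRUE, longest_isoform = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "bed"
  }
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e) {
                   stop(sprintf("failed to parse %s as %s: %s",
                                path, toupper(format), conditionMessage(e)))
                 })
  if (length(gr) == 0L) {
    warning(sprintf("%s contains no features", path))
    return(gr)
  }
  if (format == "gtf") {
    md <- S4Vectors::mcols(gr)
    if ("type" %in% names(md)) {
      tx <- gr[md$type %in% c("transcript", "mRNA")]
      if (length(tx) > 0L) gr <- tx
    }
    md <- S4Vectors::mcols(gr)
    if (protein_coding_only) {
      bt_col <- intersect(c("gene_biotype", "gene_type"), names(md))
      if (length(bt_col) > 0L) {
        gr <- gr[md[[bt_col[1L]]] %in% "protein_coding"]
        md <- S4Vectors::mcols(gr)
      }
    }
    if (longest_isoform && "gene_id" %in% names(md) && length(gr) > 0L) {
      w <- BiocGenerics::width(gr)
      keep <- unlist(lapply(split(seq_along(gr), md$gene_id), function(i) {
        i[which.max(w[i])]
      }), use.names = FALSE)
      gr <- gr[sort(keep)]
    }
  }
  gr
}

#' Convert feature GRanges to an anchor table
#'
#' Anchors are strand-aware start positions (TSS for transcripts) or, with
#' `at = "midpoint"`, interval midpoints (CpG islands).
#'
#' @param gr a `GRanges` (or a `chrom`/`start`/`end` data frame).
#' @param at `"start"` (strand-aware 5' end) or `"midpoint"`.
#' @return data frame `chrom`, `pos`, `strand` (0-based positions).
#' @export
feature_anchors <- function(gr, at = c("start", "midpoint")) {
  at <- match.arg(at)
  if (is.data.frame(gr)) {
    assert_columns(gr, c("chrom", "start", "end"), "feature table")
    pos <- if (at == "midpoint") (gr$start + gr$end) / 2 else gr$start
    return(data.frame(chrom = gr$chrom, pos = pos,
                      strand = gr$strand %||% "+", stringsAsFactors = FALSE))
  }
  st <- as.character(BiocGenerics::strand(gr))
  st[st == "*"] <- "+"
  pos <- if (at == "midpoint") {
    (BiocGenerics::start(gr) - 1 + BiocGenerics::end(gr)) / 2
  } else {
    ifelse(st == "-", BiocGenerics::end(gr), BiocGenerics::start(gr) - 1L)
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = pos, strand = st, stringsAsFactors = FALSE)
}

#' Write an interference fit as JSON
#' @param fit an `interference_fit`.
#' @param path output path.
#' @export
write_interference_fit <- function(fit, path) {
  jsonlite::write_json(list(model = fit$model, nu = fit$nu, p = fit$p,
                            logL = fit$logL, bic = fit$bic, n = fit$n,
                            ci_nu = fit$ci$nu, ci_p = fit$ci$p),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
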