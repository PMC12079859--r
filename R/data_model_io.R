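#' @importFrom stats pnorm qnorm lm glm coef vcov quantile median mad sd var
#'   rnorm rbinom runif complete.cases binomial resid setNames density
#' @importFrom utils head modifyList
NULL

#' Default column map for GWAS summary-statistic files
#'
#' Maps the internal field names to the column names expected in delimited
#' summary-statistic files. Override individual entries via the
#' `column_map` argument of [read_summary_stats()].
#'
#' @return Named character vector (internal name -> file column name).
#' @export
default_column_map <- function() {
  c(variant_id = "SNP", chrom = "CHR", pos = "BP",
    effect_allele = "EA", other_allele = "OA", eaf = "EAF",
    beta = "BETA", se = "SE", pval = "P", n = "N")
}

VARIANT_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                  "other_allele", "eaf", "beta", "se", "pval", "n")

#' Construct a table of variant records
#'
#' The variant table is the unit that flows through every pipeline stage:
#' one row per harmonizable GWAS summary-statistic record. Invalid rows are
#' dropped with a message; `validate = FALSE` skips the audit (for internal
#' use on already-validated tables).
#'
#' Invariants enforced: `se > 0`; `pval` in (0, 1]; `eaf` in (0, 1) when
#' present (missing EAF is permitted but flagged); effect and other allele
#' differ; alleles are upper-cased; `pval` agrees with the two-sided normal
#' p-value implied by `beta/se` within a factor of 2.
#'
#' @param df data.frame carrying the columns named in `VARIANT_COLS`.
#' @param validate drop rows violating the record invariants?
#' @return data.frame of class `variant_table`.
#' @export
variant_table <- function(df, validate = TRUE) {
  missing_cols <- setdiff(VARIANT_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[VARIANT_COLS]
  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) df[[col]] <- as.numeric(df[[col]])
  df$n <- as.integer(df$n)
  if (validate) {
    ok <- !is.na(df$se) & df$se > 0 &
      !is.na(df$pval) & df$pval > 0 & df$pval <= 1 &
      !is.na(df$beta) &
      df$effect_allele != df$other_allele &
      (is.na(df$eaf) | (df$eaf > 0 & df$eaf < 1)) &
      pval_consistent(df$beta, df$se, df$pval)
    ok[is.na(ok)] <- FALSE
    if (any(!ok)) {
      message(sum(!ok), " row(s) dropped: variant-record invariant violation")
      df <- df[ok, , drop = FALSE]
    }
    if (anyNA(df$eaf)) {
      message(sum(is.na(df$eaf)), " row(s) with missing EAF (kept, flagged)")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

# two-sided normal p implied by beta/se must agree with the stated p within
# a factor of 2 (compared on the log scale so extreme tails don't underflow)
pval_consistent <- function(beta, se, pval, factor = 2) {
  lz <- pnorm(abs(beta / se), lower.tail = FALSE, log.p = TRUE) + log(2)
  lp <- log(pval)
  # floored p-values (<= 1e-300) pass when the implied p is at least as small
  abs(lp - lz) <= log(factor) | (pval <= 1e-300 & lz <= lp + log(factor))
}

#' Read GWAS summary statistics from a delimited file
#'
#' Accepts tab- or comma-delimited text with a header row. Column names are
#' resolved through `column_map`; rows failing the variant-record
#' invariants are dropped with a logged count.
#'
#' @param path file path.
#' @param column_map named character vector overriding
#'   [default_column_map()] entries.
#' @return A `variant_table`.
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  cmap <- default_column_map()
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0) stop("empty input: no data rows in ", path)
  missing_cols <- setdiff(unname(cmap), names(dt))
  if (length(missing_cols) > 0) {
    stop("configuration error: column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  df <- dt[, unname(cmap)]
  names(df) <- names(cmap)
  variant_table(df)
}

#' Write a variant table to delimited text
#'
#' Inverse of [read_summary_stats()]: full-precision, lossless round-trip.
#'
#' @param variants a `variant_table`.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_summary_stats <- function(variants, path, sep = "\t") {
  cmap <- default_column_map()
  out <- as.data.frame(variants)[names(cmap)]
  names(out) <- unname(cmap)
  data.table::fwrite(out, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Construct gene annotations
#'
#' Internal coordinates are 1-based closed intervals. `term_ids` is a
#' list-column of character vectors (possibly empty) of ontology-term
#' labels attached to each gene.
#'
#' @param gene_id,chrom character vectors.
#' @param start,end 1-based closed interval bounds, `start <= end`.
#' @param term_ids list of character vectors, one per gene.
#' @return data.frame of class `gene_table`.
#' @export
gene_table <- function(gene_id, chrom, start, end, term_ids = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop("gene interval with start > end")
  if (is.null(term_ids)) term_ids <- replicate(length(gene_id), character(0), simplify = FALSE)
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   start = start, end = end, stringsAsFactors = FALSE)
  df$term_ids <- term_ids
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Read gene annotations from BED4 plus a term map
#'
#' The BED file is 0-based half-open (chrom, start, end, gene_id); it is
#' converted on read to the internal 1-based closed convention
#' (`start + 1`, `end`). The term map is two-column delimited text
#' (gene_id, term_id); genes absent from it get empty term sets.
#'
#' @param path BED4 file path.
#' @param term_map_path optional two-column (gene_id, term_id) file.
#' @return A `gene_table`.
#' @export
read_gene_bed <- function(path, term_map_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty input: ", path)
  fields <- strsplit(lines, "[\t ]+")
  bad <- which(vapply(fields, length, 1L) < 4)
  if (length(bad) > 0) stop("parse error at line ", bad[1], " of ", path)
  chrom <- vapply(fields, `[`, "", 1)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  if (anyNA(start0) || anyNA(end0)) {
    stop("parse error: malformed coordinate at line ",
         which(is.na(start0) | is.na(end0))[1], " of ", path)
  }
  gene_id <- vapply(fields, `[`, "", 4)
  term_ids <- NULL
  if (!is.null(term_map_path)) {
    tm <- data.table::fread(term_map_path, header = FALSE, data.table = FALSE,
                            col.names = c("gene_id", "term_id"))
    term_ids <- lapply(gene_id, function(g) {
      unique(as.character(tm$term_id[tm$gene_id == g]))
    })
  }
  gene_table(gene_id, chrom, start0 + 1L, end0, term_ids)
}

#' Write gene annotations to BED4 plus a term map
#'
#' @param genes a `gene_table`.
#' @param path BED4 output path (coordinates converted back to 0-based
#'   half-open).
#' @param term_map_path optional term-map output path.
#' @export
write_gene_bed <- function(genes, path, term_map_path = NULL) {
  bed <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id)
  data.table::fwrite(bed, path, sep = "\t", quote = FALSE, col.names = FALSE)
  if (!is.null(term_map_path)) {
    n_terms <- vapply(genes$term_ids, length, 1L)
    tm <- data.frame(gene_id = rep(genes$gene_id, n_terms),
                     term_id = unlist(genes$term_ids))
    data.table::fwrite(tm, term_map_path, sep = "\t", quote = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Validate a category configuration
#'
#' A category config maps category names (e.g. "renal", "vessel", or
#' negative-control labels like "dominant"/"recessive") to non-empty sets
#' of ontology-term ids.
#'
#' @param config named list of character vectors.
#' @return the validated config, invisibly classed `category_config`.
#' @export
category_config <- function(config) {
  if (is.null(names(config)) || anyDuplicated(names(config)) > 0 ||
      any(!nzchar(names(config)))) {
    stop("category names must be unique and non-empty")
  }
  if (any(vapply(config, length, 1L) == 0)) stop("category term sets must be non-empty")
  config <- lapply(config, as.character)
  class(config) <- "category_config"
  config
}

#' Bundle individual-level cohort data
#'
#' @param dosages numeric matrix (individuals x variants), values in
#'   `[0, 2]`, columns named by variant id and aligned to exposure effect
#'   alleles.
#' @param covariates data.frame of per-individual covariates.
#' @param phenotypes data.frame of per-individual phenotypes; binary
#'   phenotypes coded 0/1.
#' @return object of class `cohort_data`.
#' @export
cohort_data <- function(dosages, covariates, phenotypes) {
  dosages <- as.matrix(dosages)
  if (min(dosages) < 0 || max(dosages) > 2) stop("dosages must lie in [0, 2]")
  n <- nrow(dosages)
  if (nrow(covariates) != n || nrow(phenotypes) != n) {
    stop("cohort component row counts disagree")
  }
  for (ph in names(phenotypes)) {
    v <- phenotypes[[ph]]
    u <- unique(v[!is.na(v)])
    if (length(u) <= 2 && !all(u %in% c(0, 1))) {
      stop("binary phenotype '", ph, "' must be coded {0,1}")
    }
  }
  structure(list(dosages = dosages, covariates = as.data.frame(covariates),
                 phenotypes = as.data.frame(phenotypes)),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("cohort_data:", nrow(x$dosages), "individuals,",
      ncol(x$dosages), "variants,", ncol(x$phenotypes), "phenotype(s)\n")
  invisible(x)
}
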