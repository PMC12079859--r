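#' Build an LD-based genomic interval around a lead variant
#'
#' The interval runs from the most distant variant with r2 >= `min_r2`
#' upstream of the lead to the most distant such variant downstream,
#' searching at most `window_bp` in either direction. A lead with no
#' qualifying partner yields the degenerate interval `[pos, pos]`.
#'
#' @param lead lead variant id (must exist in `ld`).
#' @param ld an [ld_reference()].
#' @param min_r2 minimum r2 for interval membership (default 0.8).
#' @param window_bp maximum search distance either side (default 1 Mbp).
#' @return list of class `ld_interval` with fields `lead`, `chrom`,
#'   `start`, `end`, `members` (qualifying variant ids incl. the lead).
#' @export
build_ld_interval <- function(lead, ld, min_r2 = 0.8, window_bp = 1e6) {
  me <- ld_pos(ld, lead)
  p <- ld_partners(ld, lead)
  p <- p[p$chrom == me$chrom & abs(p$pos - me$pos) <= window_bp &
           p$r2 >= min_r2, , drop = FALSE]
  pos <- c(me$pos, p$pos)
  structure(list(lead = lead, chrom = me$chrom,
                 start = min(pos), end = max(pos),
                 members = c(lead, p$variant_id)),
            class = "ld_interval")
}

#' Genes overlapping an LD interval
#'
#' A gene is counted when its flanked span `[start - flank_bp, end +
#' flank_bp]` intersects the interval (closed-interval intersection, same
#' chromosome).
#'
#' @param interval an [build_ld_interval()] result.
#' @param genes a `gene_table`.
#' @param flank_bp flank added to each gene on both sides (default 1000).
#' @return character vector of gene ids.
#' @export
overlap_genes <- function(interval, genes, flank_bp = 1000) {
  hit <- genes$chrom == interval$chrom &
    genes$start - flank_bp <= interval$end &
    genes$end + flank_bp >= interval$start
  genes$gene_id[hit]
}

# n_intervals x n_genes logical overlap matrix for given interval bounds
interval_gene_overlap <- function(ichrom, istart, iend, genes, flank_bp) {
  gs <- genes$start - flank_bp
  ge <- genes$end + flank_bp
  same <- outer(ichrom, genes$chrom, `==`)
  same & outer(istart, ge, `<=`) & outer(iend, gs, `>=`)
}

#' Interval-based ontology-term enrichment by random relocation
#'
#' For each term, the observed statistic is the number of intervals
#' overlapping at least one (flanked) gene carrying that term. The null
#' relocates every interval, preserving its length, to a uniformly random
#' position on a chromosome drawn proportional to chromosome length, and
#' recounts; the empirical p-value is `(1 + #{null >= observed}) /
#' (n_perm + 1)`.
#'
#' @param intervals list of [build_ld_interval()] results.
#' @param genes a `gene_table`.
#' @param genome_length_map named numeric vector: chromosome -> length.
#' @param n_perm number of relocation permutations (default 10000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param flank_bp gene flank in bp (default 1000).
#' @return data.frame with one row per term: `term_id`,
#'   `observed_count`, `expected_count`, `pval`, `n_perm`.
#' @export
enrich_terms <- function(intervals, genes, genome_length_map, n_perm = 10000,
                         seed, flank_bp = 1000) {
  stopifnot(length(intervals) >= 1)
  if (n_perm < 100) warning("n_perm < 100: empirical p-values are unstable")
  chroms_used <- unique(c(vapply(intervals, `[[`, "", "chrom"), genes$chrom))
  if (!all(chroms_used %in% names(genome_length_map))) {
    stop("genome_length_map does not cover all chromosomes in use")
  }
  terms <- sort(unique(unlist(genes$term_ids)))
  if (length(terms) == 0) {
    return(data.frame(term_id = character(0), observed_count = integer(0),
                      expected_count = numeric(0), pval = numeric(0),
                      n_perm = integer(0)))
  }
  term_genes <- lapply(terms, function(t) {
    which(vapply(genes$term_ids, function(x) t %in% x, TRUE))
  })
  names(term_genes) <- terms
  ichrom <- vapply(intervals, `[[`, "", "chrom")
  istart <- vapply(intervals, function(x) x$start, 1)
  iend <- vapply(intervals, function(x) x$end, 1)
  ilen <- iend - istart
  count_terms <- function(ov) {
    vapply(term_genes, function(idx) {
      sum(rowSums(ov[, idx, drop = FALSE]) > 0)
    }, 1L)
  }
  observed <- count_terms(interval_gene_overlap(ichrom, istart, iend, genes, flank_bp))
  chr_names <- names(genome_length_map)
  chr_prob <- genome_length_map / sum(genome_length_map)
  n_int <- length(intervals)
  null_counts <- matrix(0L, nrow = n_perm, ncol = length(terms))
  withr_seed(seed, {
    for (r in seq_len(n_perm)) {
      new_chr <- sample(chr_names, n_int, replace = TRUE, prob = chr_prob)
      max_start <- pmax(1, genome_length_map[new_chr] - ilen)
      new_start <- floor(runif(n_int, min = 1, max = max_start + 1))
      ov <- interval_gene_overlap(new_chr, new_start, new_start + ilen,
                                  genes, flank_bp)
      null_counts[r, ] <- count_terms(ov)
    }
  })
  exceed <- colSums(null_counts >= rep(observed, each = n_perm))
  data.frame(term_id = terms,
             observed_count = observed,
             expected_count = colMeans(null_counts),
             pval = (1 + exceed) / (n_perm + 1),
             n_perm = n_perm,
             row.names = NULL)
}

# evaluate `expr` under a local, seeded RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Assign instruments to pathway categories
#'
#' A variant joins category C when (1) its LD interval overlaps at least
#' one flanked gene carrying at least one of C's terms, and (2) at least
#' one of C's terms is enriched at `enrich_p_max` in the interval set.
#' Variants may join several categories; the `specific` flag marks
#' membership in exactly one.
#'
#' @param intervals list of [build_ld_interval()] results (one per
#'   instrument; names or `lead` fields give the variant ids).
#' @param genes a `gene_table`.
#' @param config a [category_config()].
#' @param enrichment result of [enrich_terms()] on the same intervals.
#' @param enrich_p_max enrichment gate (default 0.05).
#' @param flank_bp gene flank in bp (default 1000).
#' @return data.frame of class `category_assignment`: one row per
#'   (variant, category) membership with columns `variant_id`,
#'   `category`, `specific`. Attribute `categories` lists all configured
#'   categories (so empty ones remain visible).
#' @export
assign_categories <- function(intervals, genes, config, enrichment,
                              enrich_p_max = 0.05, flank_bp = 1000) {
  config <- category_config(unclass(config))
  leads <- vapply(intervals, `[[`, "", "lead")
  rows <- list()
  for (cat_name in names(config)) {
    terms_c <- config[[cat_name]]
    gate <- enrichment$term_id %in% terms_c & enrichment$pval <= enrich_p_max
    if (!any(gate)) {
      warning("category '", cat_name, "' has no enriched term; emitted empty")
      next
    }
    carrier <- vapply(genes$term_ids, function(x) any(terms_c %in% x), TRUE)
    cg <- genes[carrier, , drop = FALSE]
    if (nrow(cg) == 0) next
    member <- vapply(intervals, function(iv) {
      length(overlap_genes(iv, cg, flank_bp)) > 0
    }, TRUE)
    if (any(member)) {
      rows[[cat_name]] <- data.frame(variant_id = leads[member],
                                     category = cat_name,
                                     stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(variant_id = character(0), category = character(0))
  n_cats <- table(out$variant_id)
  out$specific <- n_cats[out$variant_id] == 1L
  out$specific <- as.logical(out$specific)
  rownames(out) <- NULL
  class(out) <- c("category_assignment", "data.frame")
  attr(out, "categories") <- names(config)
  out
}
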