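#' Wakefield log approximate Bayes factor
#'
#' Log ABF for a single association statistic under a normal prior on the
#' true effect with standard deviation `prior_sd`:
#' `0.5 * log(se^2 / (se^2 + prior_sd^2)) + z^2/2 * prior_sd^2 / (se^2 +
#' prior_sd^2)` with `z = beta/se`. Positive values favour association.
#'
#' @param beta,se estimate and standard error (`se > 0`).
#' @param prior_sd prior standard deviation of the true effect (> 0).
#' @return numeric vector of log ABFs.
#' @export
wakefield_labf <- function(beta, se, prior_sd) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || !is.finite(prior_sd)) {
    stop("non-finite input to wakefield_labf")
  }
  if (any(se <= 0) || prior_sd < 0) stop("se and prior_sd must be positive")
  z2 <- (beta / se)^2
  shrink <- prior_sd^2 / (se^2 + prior_sd^2)
  0.5 * log(1 - shrink) + z2 / 2 * shrink
}

logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, tolerant of tiny negative differences
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Approximate-Bayes-factor colocalization of two association regions
#'
#' Enumeration-based colocalization over the variants shared by two
#' summary-statistic regions under the five-hypothesis framework:
#' H0 no association; H1/H2 association with one trait only; H3 two
#' distinct causal variants; H4 one shared causal variant. All hypothesis
#' sums are computed in log space.
#'
#' @param region1,region2 `variant_table`s (or data.frames with
#'   `variant_id`, `beta`, `se`) for the two traits over one region.
#' @param p1,p2 prior probability a variant is causal for trait 1 / 2.
#' @param p12 prior probability a variant is causal for both.
#' @param prior_sd1,prior_sd2 Wakefield prior sd per trait (default 0.15,
#'   the standard quantitative-trait choice).
#' @return list of class `coloc_result` with fields `pp` (named numeric
#'   `PP_H0`..`PP_H4`, summing to 1), `n_snps`, `snp_ids`, `labf1`,
#'   `labf2`.
#' @export
coloc_abf <- function(region1, region2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = 0.15, prior_sd2 = 0.15) {
  shared <- intersect(region1$variant_id, region2$variant_id)
  if (length(shared) == 0) stop("region mismatch: no shared variants")
  r1 <- region1[match(shared, region1$variant_id), , drop = FALSE]
  r2 <- region2[match(shared, region2$variant_id), , drop = FALSE]
  labf1 <- wakefield_labf(r1$beta, r1$se, prior_sd1)
  labf2 <- wakefield_labf(r2$beta, r2$se, prior_sd2)
  ls1 <- logsumexp(labf1)
  ls2 <- logsumexp(labf2)
  ls12 <- logsumexp(labf1 + labf2)
  # H3 sums BF1_i * BF2_j over i != j = (sum BF1)(sum BF2) - sum BF1_i BF2_i
  lh <- c(H0 = 0,
          H1 = log(p1) + ls1,
          H2 = log(p2) + ls2,
          H3 = log(p1) + log(p2) + logdiffexp(ls1 + ls2, ls12),
          H4 = log(p12) + ls12)
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP_", names(lh))
  stopifnot(abs(sum(pp) - 1) < 1e-9)
  structure(list(pp = pp, n_snps = length(shared), snp_ids = shared,
                 labf1 = labf1, labf2 = labf2),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("coloc over", x$n_snps, "shared variants:\n")
  print(round(x$pp, 4))
  invisible(x)
}

#' Assign instruments to tissue groups by eQTL colocalization
#'
#' For each instrument, every gene whose eQTL region overlaps the
#' `+/- window_bp` window centred on the instrument is colocalized with
#' the exposure statistics over that window; the instrument joins a
#' tissue group when the maximum PP_H4 across the group's sub-tissues and
#' genes strictly exceeds `pp4_thresh`. Tissue groups may be unions of
#' sub-tissues (e.g. artery = aorta + coronary).
#'
#' @param instruments an instrument set (`variant_table`).
#' @param exposure_region `variant_table` of exposure summary statistics
#'   covering the instrument neighbourhoods (typically the full GWAS).
#' @param eqtl_panels nested list: `tissue -> gene -> variant_table` of
#'   cis-eQTL summary statistics (each with `chrom`/`pos`).
#' @param tissue_groups named list: group name -> character vector of
#'   sub-tissue names; defaults to one group per panel tissue.
#' @param window_bp half-width of the colocalization window (default
#'   100 kbp).
#' @param pp4_thresh PP_H4 membership threshold (default 0.9, strict).
#' @param priors named list overriding `p1`, `p2`, `p12`.
#' @return data.frame of class `tissue_assignment`: one row per
#'   (variant, group) with `variant_id`, `tissue`, `best_gene`,
#'   `PP_H0`..`PP_H4` (of the best gene), `member`.
#' @export
assign_tissues <- function(instruments, exposure_region, eqtl_panels,
                           tissue_groups = NULL, window_bp = 1e5,
                           pp4_thresh = 0.9, priors = list()) {
  if (length(eqtl_panels) == 0 || any(vapply(eqtl_panels, length, 1L) == 0)) {
    stop("configuration error: empty eQTL panel")
  }
  if (is.null(tissue_groups)) {
    tissue_groups <- as.list(setNames(names(eqtl_panels), names(eqtl_panels)))
  }
  pr <- modifyList(list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5), priors)
  rows <- list()
  for (gi in seq_along(tissue_groups)) {
    group <- names(tissue_groups)[gi]
    subs <- tissue_groups[[gi]]
    if (!all(subs %in% names(eqtl_panels))) {
      stop("configuration error: tissue group '", group,
           "' references missing panel(s)")
    }
    for (vi in seq_len(nrow(instruments))) {
      v <- instruments[vi, ]
      lo <- v$pos - window_bp; hi <- v$pos + window_bp
      win <- exposure_region[exposure_region$chrom == v$chrom &
                               exposure_region$pos >= lo &
                               exposure_region$pos <= hi, , drop = FALSE]
      best <- NULL
      for (sub in subs) {
        for (gene in names(eqtl_panels[[sub]])) {
          reg <- eqtl_panels[[sub]][[gene]]
          if (!any(reg$chrom == v$chrom & reg$pos >= lo & reg$pos <= hi)) next
          if (length(intersect(reg$variant_id, win$variant_id)) == 0) next
          cr <- coloc_abf(win, reg, p1 = pr$p1, p2 = pr$p2, p12 = pr$p12)
          if (is.null(best) || cr$pp["PP_H4"] > best$pp["PP_H4"]) {
            best <- cr
            best_gene <- gene
          }
        }
      }
      if (!is.null(best)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = v$variant_id, tissue = group, best_gene = best_gene,
          as.list(best$pp),
          member = unname(best$pp["PP_H4"] > pp4_thresh),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(variant_id = character(0), tissue = character(0),
               best_gene = character(0), PP_H0 = numeric(0),
               PP_H1 = numeric(0), PP_H2 = numeric(0), PP_H3 = numeric(0),
               PP_H4 = numeric(0), member = logical(0))
  rownames(out) <- NULL
  class(out) <- c("tissue_assignment", "data.frame")
  attr(out, "pp4_thresh") <- pp4_thresh
  out
}

#' Per-variant PP_H4 table for a two-tissue assignment
#'
#' Pivots a [assign_tissues()] result into the wide per-variant table
#' consumed by [mvmr_pp4_weighted()] and [permute_pp4_null()]: the
#' maximum PP_H4 per variant in each of the two tissue groups (0 when a
#' variant has no colocalization candidate there).
#'
#' @param assignment a `tissue_assignment`.
#' @param variant_ids ids to cover (defaults to those present).
#' @param tissues length-2 character vector naming the groups mapped to
#'   `pp4_a` / `pp4_b`; defaults to the two groups present.
#' @return data.frame with columns `variant_id`, `pp4_a`, `pp4_b`.
#' @export
pp4_table <- function(assignment, variant_ids = NULL, tissues = NULL) {
  if (is.null(tissues)) tissues <- sort(unique(assignment$tissue))
  if (length(tissues) != 2) stop("exactly two tissue groups required")
  if (is.null(variant_ids)) variant_ids <- unique(assignment$variant_id)
  out <- data.frame(variant_id = variant_ids, pp4_a = 0, pp4_b = 0)
  for (k in 1:2) {
    col <- c("pp4_a", "pp4_b")[k]
    sub <- assignment[assignment$tissue == tissues[k], , drop = FALSE]
    if (nrow(sub) == 0) next
    best <- tapply(sub$PP_H4, sub$variant_id, max)
    idx <- match(names(best), out$variant_id)
    out[[col]][idx[!is.na(idx)]] <- as.numeric(best)[!is.na(idx)]
  }
  out
}
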