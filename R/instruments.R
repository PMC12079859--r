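#' Select independent genome-wide-significant instruments by LD clumping
#'
#' Greedy p-ordered clumping as in plink's `--clump`: variants below the
#' significance threshold are sorted by ascending p (ties broken by
#' chromosome, position, then id), the best remaining variant is retained,
#' and every other variant with r2 >= `r2_thresh` within `window_bp` of it
#' is removed; repeated until exhausted. The result is row-order
#' invariant and audited against its own invariant (all retained pairwise
#' r2 below threshold within the window).
#'
#' @param records a `variant_table` of exposure summary statistics.
#' @param ld an [ld_reference()] covering the significant variants.
#' @param p_thresh genome-wide significance threshold (default 5e-8).
#' @param r2_thresh clumping r2 threshold (default 0.001).
#' @param window_bp clumping window in base pairs (default 10 Mbp).
#' @return An `instrument_set`: a `variant_table` sorted by chrom/pos with
#'   attribute `selection` recording the parameters.
#' @export
clump <- function(records, ld, p_thresh = 5e-8, r2_thresh = 0.001,
                  window_bp = 1e7) {
  if (nrow(records) == 0) stop("no input records")
  sig <- records[records$pval < p_thresh, , drop = FALSE]
  if (nrow(sig) == 0) {
    warning("no variant below the significance threshold; empty instrument set")
  }
  ord <- order(sig$pval, sig$chrom, sig$pos, sig$variant_id)
  sig <- sig[ord, , drop = FALSE]
  active <- rep(TRUE, nrow(sig))
  keep <- logical(nrow(sig))
  for (i in seq_len(nrow(sig))) {
    if (!active[i]) next
    keep[i] <- TRUE
    active[i] <- FALSE
    if (!any(active)) break
    cand <- which(active)
    same_chr <- sig$chrom[cand] == sig$chrom[i] &
      abs(sig$pos[cand] - sig$pos[i]) <= window_bp
    cand <- cand[same_chr]
    if (length(cand) > 0) {
      r2 <- ld_r2(ld, sig$variant_id[i], sig$variant_id[cand])
      active[cand[r2 >= r2_thresh]] <- FALSE
    }
  }
  out <- sig[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("instrument_set", "variant_table", "data.frame")
  attr(out, "selection") <- list(p_thresh = p_thresh, r2_thresh = r2_thresh,
                                 window_bp = window_bp)
  audit_instrument_set(out, ld)
  out
}

# post-build assertion: every retained pair within the window has
# r2 < r2_thresh
audit_instrument_set <- function(set, ld) {
  sel <- attr(set, "selection")
  k <- nrow(set)
  if (k < 2) return(invisible(TRUE))
  for (i in seq_len(k - 1)) {
    j <- (i + 1):k
    in_win <- set$chrom[j] == set$chrom[i] &
      abs(set$pos[j] - set$pos[i]) <= sel$window_bp
    if (any(in_win)) {
      r2 <- ld_r2(ld, set$variant_id[i], set$variant_id[j[in_win]])
      if (any(r2 >= sel$r2_thresh)) {
        stop("instrument-set audit failed: correlated pair retained")
      }
    }
  }
  invisible(TRUE)
}

#' Find an LD proxy for a variant missing from the outcome dataset
#'
#' Returns the outcome-present variant with the greatest r2 to `target`
#' provided that r2 exceeds `min_r2`, else `NULL`. Ties are broken by
#' smaller chromosomal distance to the target, then lexicographic id.
#'
#' @param target variant id absent from `outcome_ids`.
#' @param outcome_ids character vector of ids available in the outcome.
#' @param ld an [ld_reference()] containing `target`.
#' @param min_r2 minimum acceptable r2 (default 0.8, strict inequality).
#' @return A variant id, or `NULL` when no adequate proxy exists.
#' @export
find_proxy <- function(target, outcome_ids, ld, min_r2 = 0.8) {
  if (target %in% outcome_ids) {
    stop("precondition violation: target is present in the outcome dataset")
  }
  p <- ld_partners(ld, target)
  p <- p[p$variant_id %in% outcome_ids & p$r2 > min_r2, , drop = FALSE]
  if (nrow(p) == 0) return(NULL)
  tpos <- ld_pos(ld, target)$pos
  ord <- order(-p$r2, abs(p$pos - tpos), p$variant_id)
  p$variant_id[ord[1]]
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

flip_allele <- function(a) {
  out <- COMPLEMENT[a]
  out[is.na(out)] <- a[is.na(out)]  # indels pass through
  unname(out)
}

is_palindromic <- function(ea, oa) {
  !is.na(COMPLEMENT[ea]) & flip_allele(ea) == oa
}

#' Harmonize outcome effects onto exposure effect alleles
#'
#' For each instrument present in both datasets the outcome row is aligned
#' so that both betas refer to the exposure's effect allele: swapped
#' alleles negate the outcome beta and complement its EAF; strand flips
#' are detected via allele complements; palindromic (A/T, C/G) variants
#' are resolved by EAF only when both frequencies are outside
#' `0.5 +/- palindrome_eaf_window` and dropped otherwise. Unresolvable
#' allele mismatches are dropped with a message. Harmonization is
#' idempotent: applying it to already-aligned data changes nothing.
#'
#' @param exposure instrument set (a `variant_table`).
#' @param outcome `variant_table` of outcome summary statistics.
#' @param palindrome_eaf_window half-width of the ambiguous EAF zone
#'   around 0.5 (default 0.08).
#' @return data.frame of harmonized pairs with columns `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `beta_exp`,
#'   `se_exp`, `eaf_exp`, `pval_exp`, `n_exp`, `beta_out`, `se_out`,
#'   `eaf_out`, `pval_out`, `n_out`, `flipped`, `proxy_of`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  if (anyDuplicated(exposure$variant_id) > 0) stop("duplicate variant ids in exposure")
  if (anyDuplicated(outcome$variant_id) > 0) stop("duplicate variant ids in outcome")
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]
  k <- length(shared)
  keep <- rep(TRUE, k)
  flipped <- rep(FALSE, k)
  beta_out <- ou$beta; eaf_out <- ou$eaf
  for (i in seq_len(k)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    pal <- is_palindromic(ea_x, oa_x)
    if (pal) {
      # alleles cannot distinguish strand; orientation must come from EAF
      if (!(identical(c(ea_y, oa_y), c(ea_x, oa_x)) ||
            identical(c(ea_y, oa_y), c(oa_x, ea_x)))) {
        keep[i] <- FALSE
        next
      }
      if (is.na(ex$eaf[i]) || is.na(ou$eaf[i])) {
        stop("precondition error: EAF required to resolve palindromic variant ",
             shared[i])
      }
      if (abs(ex$eaf[i] - 0.5) <= palindrome_eaf_window ||
          abs(ou$eaf[i] - 0.5) <= palindrome_eaf_window) {
        keep[i] <- FALSE
        next
      }
      ou_eaf_for_ea_y <- ou$eaf[i]
      # same-label orientation: minor/major agreement decides the strand
      same_side <- identical(c(ea_y, oa_y), c(ea_x, oa_x))
      eaf_aligned <- if (same_side) ou_eaf_for_ea_y else 1 - ou_eaf_for_ea_y
      if ((ex$eaf[i] > 0.5) == (eaf_aligned > 0.5)) {
        if (!same_side) { beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i]; flipped[i] <- TRUE }
      } else {
        # frequencies disagree: outcome row is on the other strand
        if (same_side) { beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i]; flipped[i] <- TRUE }
      }
    } else {
      if (ea_y == ea_x && oa_y == oa_x) {
        # already aligned
      } else if (ea_y == oa_x && oa_y == ea_x) {
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
        flipped[i] <- TRUE
      } else if (flip_allele(ea_y) == ea_x && flip_allele(oa_y) == oa_x) {
        # strand flip, same orientation
      } else if (flip_allele(ea_y) == oa_x && flip_allele(oa_y) == ea_x) {
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
        flipped[i] <- TRUE
      } else {
        keep[i] <- FALSE
      }
    }
  }
  if (any(!keep)) {
    message(sum(!keep), " variant(s) dropped during harmonization ",
            "(ambiguous palindrome or allele mismatch)")
  }
  out <- data.frame(
    variant_id = shared, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_exp = ex$beta, se_exp = ex$se, eaf_exp = ex$eaf,
    pval_exp = ex$pval, n_exp = ex$n,
    beta_out = beta_out, se_out = ou$se, eaf_out = eaf_out,
    pval_out = ou$pval, n_out = ou$n,
    flipped = flipped, proxy_of = NA_character_,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("harmonized_pairs", "data.frame")
  out
}
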