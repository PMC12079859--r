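#' Draw two random SNP subsets for the pathway resampling null
#'
#' Two independent uniform draws without replacement (within each subset)
#' from the full instrument set; the subsets may overlap each other, as
#' the observed pathway partitions may.
#'
#' @param all_ids character vector of instrument ids.
#' @param n1,n2 subset sizes (each `<= length(all_ids)`).
#' @return list with character vectors `subset1`, `subset2`.
#' @export
draw_pathway_null <- function(all_ids, n1, n2) {
  m <- length(all_ids)
  if (n1 > m || n2 > m) stop("subset size exceeds instrument count")
  list(subset1 = sample(all_ids, n1), subset2 = sample(all_ids, n2))
}

#' Permute PP_H4 values for the tissue resampling null
#'
#' Pools all `2m` PP_H4 values across both tissues and variants, shuffles
#' them uniformly, reassigns them to the (variant, tissue) slots, and
#' extracts the variants whose permuted value exceeds the threshold per
#' tissue. Subset sizes therefore vary across replicates while the
#' multiset of values is conserved.
#'
#' @param pp4 data.frame with columns `variant_id`, `pp4_a`, `pp4_b`.
#' @param threshold membership gate (default 0.9, strict).
#' @return list with `subsetA`, `subsetB` (character vectors) and
#'   `permuted` (the permuted pp4 table).
#' @export
permute_pp4_null <- function(pp4, threshold = 0.9) {
  if (nrow(pp4) == 0) stop("empty PP_H4 table")
  vals <- sample(c(pp4$pp4_a, pp4$pp4_b))
  m <- nrow(pp4)
  perm <- data.frame(variant_id = pp4$variant_id,
                     pp4_a = vals[seq_len(m)], pp4_b = vals[m + seq_len(m)])
  list(subsetA = perm$variant_id[perm$pp4_a > threshold],
       subsetB = perm$variant_id[perm$pp4_b > threshold],
       permuted = perm)
}

#' Empirical test of a between-partition effect difference
#'
#' Runs `analysis` on the observed subsets to get the observed absolute
#' difference of the two partition estimates, then `R` times on subsets
#' drawn from `null_generator`, recording the absolute difference each
#' time. The two-tailed empirical p-value is the exceedance frequency
#' `#{|diff_r| >= observed} / R` floored at `1/R` (so `R = 1000` gives
#' the floor 1e-3), and the 95% interval of the difference is the 2.5%
#' and 97.5% quantiles of the replicate distribution. Replicates on
#' which the analysis fails (empty subset, collinearity, ...) are
#' redrawn up to `5R` total attempts.
#'
#' @param analysis function(subset1, subset2) returning a numeric vector
#'   of two estimates (or a list with `est1`, `est2`).
#' @param null_generator function() returning a list with two subsets
#'   (first two elements used).
#' @param observed_subsets list of the two observed subsets.
#' @param R number of replicates (default 1000).
#' @param seed RNG seed covering all draws.
#' @param label free-text analysis label carried into the result.
#' @return list of class `resampling_result` with `observed_diff`,
#'   `replicate_diffs`, `empirical_p`, `ci95`, `R`, `seed`, `label`,
#'   `n_failed`.
#' @export
empirical_diff_test <- function(analysis, null_generator, observed_subsets,
                                R = 1000, seed = 1, label = "") {
  ests <- analysis(observed_subsets[[1]], observed_subsets[[2]])
  if (is.list(ests)) ests <- c(ests$est1, ests$est2)
  observed <- abs(ests[1] - ests[2])
  diffs <- numeric(R)
  n_failed <- 0
  withr_seed(seed, {
    r <- 1
    attempts <- 0
    while (r <= R) {
      attempts <- attempts + 1
      if (attempts > 5 * R) {
        stop("unstable null: too many failed replicates (",
             n_failed, " failures in ", attempts, " attempts)")
      }
      subs <- null_generator()
      e <- tryCatch(suppressWarnings(analysis(subs[[1]], subs[[2]])),
                    error = function(e) NULL)
      if (is.list(e)) e <- c(e$est1, e$est2)
      if (is.null(e) || anyNA(e[1:2])) {
        n_failed <- n_failed + 1
        next
      }
      diffs[r] <- abs(e[1] - e[2])
      r <- r + 1
    }
  })
  if (n_failed > 0.2 * R) {
    stop("unstable null: more than 20% of replicates failed (", n_failed, ")")
  }
  structure(list(observed_diff = observed, replicate_diffs = diffs,
                 empirical_p = max(sum(diffs >= observed) / R, 1 / R),
                 ci95 = unname(quantile(diffs, c(0.025, 0.975))),
                 R = R, seed = seed, label = label, n_failed = n_failed),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("resampling null [%s]: observed |diff| = %.4f, empirical p = %.4g (R = %d)\n",
              x$label, x$observed_diff, x$empirical_p, x$R))
  cat(sprintf("  95%% interval of null |diff|: [%.4f, %.4f]; failed replicates: %d\n",
              x$ci95[1], x$ci95[2], x$n_failed))
  invisible(x)
}
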