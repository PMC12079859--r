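#' Simulation parameters for a synthetic partitioned-MR study
#'
#' Returns the default parameter list, with any named overrides applied.
#' The defaults describe the world the package's tests and acceptance
#' checks operate in: a unit-variance continuous exposure driven by two
#' disjoint pathway components plus an unpartitioned remainder, block-LD
#' genotypes, GWAS cohorts of 10,000, eQTL panels of 300, and a headline
#' pathway contrast of direct effects 0.15 vs 0.
#'
#' @param ... named overrides of any default.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(...) {
  p <- list(
    n_individuals = 10000,   # one-sample cohort
    n_gwas = 10000,          # each summary-stat cohort (exposure, outcome)
    n_eqtl = 300,            # per-tissue eQTL sample
    n_blocks = 30,
    snps_per_block = 10,
    ld_rho = 0.8,            # AR-1 latent correlation within block
    maf_range = c(0.1, 0.5),
    pi1 = 0.4, pi2 = 0.4,    # proportion of instruments in P1 / P2 (rest P0)
    tau = 0.25,              # sd of per-SNP exposure effects (shape only)
    h2_exposure = 0.6,       # total exposure variance explained by SNPs
    effects = "normal",      # "normal" or "fixed" (equal |beta|, random sign)
    theta1 = 0.15, theta2 = 0, theta0 = 0,  # pathway direct effects on outcome
    outcome_noise_sd = 1,
    prevalence = 0.1,        # binary outcome
    eqtl_effect = 0.6,       # |effect| of the causal eQTL variant
    decoy_rate = 0.3,        # non-colocalizing gene in the other tissue
    noise_region_rate = 0.5, # pure-noise region for P0 instruments
    specificity = 1,         # P(category gene inside a P_k interval)
    background_rate = 0,     # P(category gene inside a non-P_k interval)
    n_background_genes = 20, # term-less genes placed uniformly
    gene_width = 10000,
    block_spacing = 2e6, snp_spacing = 5000,
    seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown) > 0) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(overrides)] <- overrides
  stopifnot(p$pi1 + p$pi2 <= 1, p$prevalence > 0, p$prevalence < 1,
            p$ld_rho >= 0, p$ld_rho < 1)
  class(p) <- "sim_params"
  p
}

# fixed layout of variants, blocks, pathways and causal effects; consumes RNG
simulate_genome <- function(params) {
  m <- params$n_blocks * params$snps_per_block
  block <- rep(seq_len(params$n_blocks), each = params$snps_per_block)
  within <- rep(seq_len(params$snps_per_block), params$n_blocks)
  pos <- (block - 1) * params$block_spacing + within * params$snp_spacing
  ids <- sprintf("rs%d_%d", block, within)
  maf <- runif(m, params$maf_range[1], params$maf_range[2])
  causal_within <- ceiling(params$snps_per_block / 2)
  n1 <- round(params$pi1 * params$n_blocks)
  n2 <- round(params$pi2 * params$n_blocks)
  pathway_of_block <- rep("P0", params$n_blocks)
  pathway_of_block[seq_len(n1)] <- "P1"
  pathway_of_block[n1 + seq_len(n2)] <- "P2"
  pathway_of_block <- sample(pathway_of_block)  # shuffle block order
  causal <- within == causal_within
  beta <- numeric(m)
  beta[causal] <- if (params$effects == "fixed")
    sample(c(-1, 1), sum(causal), replace = TRUE) * params$tau
  else rnorm(sum(causal), 0, params$tau)
  # rescale so the SNPs explain exactly h2_exposure of the unit-variance
  # exposure; effects stay normal-shaped, the per-SD scale becomes exact
  vg <- 2 * maf * (1 - maf)
  beta[causal] <- beta[causal] *
    sqrt(params$h2_exposure / sum(beta[causal]^2 * vg[causal]))
  list(variant_id = ids, chrom = rep("1", m), pos = pos, block = block,
       within = within, maf = maf, causal = causal,
       pathway = pathway_of_block[block], beta = beta,
       genome_length = c("1" = params$n_blocks * params$block_spacing))
}

#' Simulate block-LD genotype dosages
#'
#' Per block, each of the two haplotypes is a latent AR-1 Gaussian
#' (correlation `ld_rho^|i-j|`) thresholded at the MAF quantile; dosages
#' are the two haplotype alleles summed, so LD decays geometrically
#' within a block and is exactly zero across blocks.
#'
#' @param genome internal genome layout (from [simulate_study()]).
#' @param n number of individuals.
#' @param params a [sim_params()].
#' @return numeric matrix n x m with variant-id column names.
#' @export
simulate_genotypes <- function(genome, n, params) {
  m <- length(genome$variant_id)
  spb <- params$snps_per_block
  rho <- params$ld_rho
  dos <- matrix(0, n, m, dimnames = list(NULL, genome$variant_id))
  thr <- qnorm(genome$maf)
  for (h in 1:2) {
    z <- matrix(0, n, m)
    for (b in seq_len(params$n_blocks)) {
      cols <- (b - 1) * spb + seq_len(spb)
      z[, cols[1]] <- rnorm(n)
      for (j in cols[-1]) {
        z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * rnorm(n)
      }
    }
    dos <- dos + (z < rep(thr, each = n))
  }
  dos
}

# analytic within-block LD: r2 = rho^(2|i-j|); zero across blocks
ld_from_genome <- function(genome, params, min_r2 = 1e-6) {
  spb <- params$snps_per_block
  pairs <- list()
  for (b in seq_len(params$n_blocks)) {
    idx <- which(genome$block == b)
    cmb <- utils::combn(idx, 2)
    r2 <- params$ld_rho^(2 * abs(genome$within[cmb[1, ]] - genome$within[cmb[2, ]]))
    keep <- r2 >= min_r2
    pairs[[b]] <- data.frame(id1 = genome$variant_id[cmb[1, keep]],
                             id2 = genome$variant_id[cmb[2, keep]],
                             r2 = r2[keep])
  }
  variants <- data.frame(variant_id = genome$variant_id,
                         chrom = genome$chrom, pos = genome$pos)
  ld_reference(variants, do.call(rbind, pairs))
}

#' Simulate exposure and outcome phenotypes with pathway structure
#'
#' The exposure is the sum of the three pathway genetic components plus
#' small age/sex effects and Gaussian noise calibrated so the exposure
#' variance is ~1 (per-SD and raw scales coincide). The continuous
#' outcome is `theta1*C1 + theta2*C2 + theta0*C0` plus the same covariate
#' effects and noise -- exposure noise is not transmitted, so pathway
#' effects are the only exposure-mediated signal. The binary outcome
#' applies a logistic link to the same linear predictor with the
#' intercept solved to hit the target prevalence.
#'
#' @param dosages matrix from [simulate_genotypes()].
#' @param genome internal genome layout.
#' @param params a [sim_params()].
#' @return list with `exposure`, `outcome_cont`, `outcome_bin`,
#'   `covariates` (age, sex, pc1..pc10, chip), and the pathway
#'   components `C1`, `C2`, `C0`.
#' @export
simulate_phenotypes <- function(dosages, genome, params) {
  n <- nrow(dosages)
  comp <- function(pw) {
    j <- genome$causal & genome$pathway == pw
    if (!any(j)) return(numeric(n))
    as.numeric(dosages[, j, drop = FALSE] %*% genome$beta[j])
  }
  c1 <- comp("P1"); c2 <- comp("P2"); c0 <- comp("P0")
  covs <- data.frame(age = rnorm(n, 57, 8), sex = rbinom(n, 1, 0.5),
                     chip = rbinom(n, 1, 0.5))
  for (k in 1:10) covs[[paste0("pc", k)]] <- rnorm(n)
  cov_part <- 0.05 * (covs$age - 57) / 8 + 0.05 * covs$sex
  gpart <- c1 + c2 + c0 + cov_part
  noise_sd <- sqrt(max(0.1, 1 - var(gpart)))
  x <- gpart + rnorm(n, 0, noise_sd)
  eta <- params$theta1 * c1 + params$theta2 * c2 + params$theta0 * c0 + cov_part
  y_cont <- eta + rnorm(n, 0, params$outcome_noise_sd)
  alpha <- stats::uniroot(function(a) mean(stats::plogis(a + eta)) - params$prevalence,
                          c(-30, 30))$root
  y_bin <- rbinom(n, 1, stats::plogis(alpha + eta))
  list(exposure = x, outcome_cont = y_cont, outcome_bin = y_bin,
       covariates = covs, C1 = c1, C2 = c2, C0 = c0)
}

# vectorized per-SNP OLS summary statistics; p from the normal approximation
summary_stats_from_cohort <- function(dosages, y, genome) {
  n <- nrow(dosages)
  gc_ <- scale(dosages, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(gc_^2)
  sxy <- as.numeric(crossprod(gc_, yc))
  beta <- sxy / sxx
  rss <- sum(yc^2) - beta * sxy
  se <- sqrt(pmax(rss / (n - 2), 1e-300) / sxx)
  z <- beta / se
  variant_table(data.frame(
    variant_id = genome$variant_id, chrom = genome$chrom, pos = genome$pos,
    effect_allele = "A", other_allele = "G",
    eaf = colMeans(dosages) / 2, beta = beta, se = se,
    pval = pmax(2 * pnorm(-abs(z)), 1e-300), n = n))
}

#' Simulate per-tissue cis-eQTL panels with planted colocalization
#'
#' Two tissues are simulated. Every P1 causal variant is a planted
#' colocalizing eQTL in `tissue_a` and every P2 causal variant in
#' `tissue_b`: the gene's expression in an independent sample of
#' `n_eqtl` individuals is driven by the instrument itself with effect
#' magnitude `eqtl_effect` (random sign). With probability `decoy_rate`
#' the instrument additionally gets a non-colocalizing gene in the other
#' tissue whose causal variant is the most distant (lowest-LD) variant
#' of the block; P0 instruments get pure-noise regions at rate
#' `noise_region_rate`. True colocalization flags are returned.
#'
#' @param genome internal genome layout.
#' @param params a [sim_params()].
#' @return list with `panels` (tissue -> gene -> `variant_table`) and
#'   `truth` (data.frame variant_id, tissue, gene, colocalizes).
#' @export
simulate_eqtl_panels <- function(genome, params) {
  tissues <- c("tissue_a", "tissue_b")
  coloc_tissue <- c(P1 = "tissue_a", P2 = "tissue_b", P0 = NA)
  geno <- lapply(tissues, function(t) simulate_genotypes(genome, params$n_eqtl, params))
  names(geno) <- tissues
  panels <- list(tissue_a = list(), tissue_b = list())
  truth <- list()
  add_region <- function(tissue, gene, causal_idx, lead_id) {
    g <- geno[[tissue]]
    block_idx <- which(genome$block == genome$block[match(lead_id, genome$variant_id)])
    # effect expressed per genotype SD so planted signal strength does not
    # depend on MAF (z ~ eqtl_effect * sqrt(n_eqtl) / sqrt(1 + eqtl_effect^2))
    expr <- if (is.na(causal_idx)) rnorm(params$n_eqtl) else
      sample(c(-1, 1), 1) * params$eqtl_effect *
        as.numeric(scale(g[, causal_idx])) + rnorm(params$n_eqtl)
    sub <- list(variant_id = genome$variant_id[block_idx],
                chrom = genome$chrom[block_idx], pos = genome$pos[block_idx],
                maf = genome$maf[block_idx])
    panels[[tissue]][[gene]] <<- summary_stats_from_cohort(
      g[, block_idx, drop = FALSE], expr, sub)
  }
  for (j in which(genome$causal)) {
    id <- genome$variant_id[j]
    pw <- genome$pathway[j]
    if (pw %in% c("P1", "P2")) {
      t_co <- coloc_tissue[[pw]]
      gene_co <- paste0("gene_", id, "_co")
      add_region(t_co, gene_co, j, id)
      truth[[length(truth) + 1]] <- data.frame(variant_id = id, tissue = t_co,
                                               gene = gene_co, colocalizes = TRUE)
      if (runif(1) < params$decoy_rate) {
        t_ot <- setdiff(tissues, t_co)
        blk <- which(genome$block == genome$block[j])
        far <- blk[which.max(abs(genome$within[blk] - genome$within[j]))]
        gene_de <- paste0("gene_", id, "_decoy")
        add_region(t_ot, gene_de, far, id)
        truth[[length(truth) + 1]] <- data.frame(variant_id = id, tissue = t_ot,
                                                 gene = gene_de, colocalizes = FALSE)
      }
    } else {
      for (t in tissues) {
        if (runif(1) < params$noise_region_rate) {
          gene_no <- paste0("gene_", id, "_", t, "_noise")
          add_region(t, gene_no, NA, id)
          truth[[length(truth) + 1]] <- data.frame(variant_id = id, tissue = t,
                                                   gene = gene_no, colocalizes = FALSE)
        }
      }
    }
  }
  list(panels = panels,
       truth = if (length(truth) > 0) do.call(rbind, truth) else NULL)
}

#' Simulate category-labelled gene annotations
#'
#' Places a gene carrying the category-1 term inside each P1 instrument's
#' LD interval with probability `specificity` (likewise category 2 / P2);
#' non-matching intervals receive a category gene at `background_rate`.
#' `n_background_genes` term-less genes are placed uniformly. Returns the
#' annotations together with the two-category configuration
#' (`path1` = TERM_P1, `path2` = TERM_P2).
#'
#' @param genome internal genome layout.
#' @param intervals named list of [build_ld_interval()] results keyed by
#'   instrument id.
#' @param params a [sim_params()].
#' @return list with `genes` (a `gene_table`) and `config`
#'   (a [category_config()]).
#' @export
simulate_gene_annotations <- function(genome, intervals, params) {
  terms <- c(P1 = "TERM_P1", P2 = "TERM_P2")
  gid <- character(0); gchrom <- character(0)
  gstart <- integer(0); gend <- integer(0); gterms <- list()
  place_in <- function(iv, term, tag) {
    center <- floor((iv$start + iv$end) / 2)
    half <- floor(params$gene_width / 2)
    gid <<- c(gid, paste0("gene_", tag))
    gchrom <<- c(gchrom, iv$chrom)
    gstart <<- c(gstart, max(1, center - half))
    gend <<- c(gend, center + half)
    gterms[[length(gterms) + 1]] <<- term
  }
  for (id in names(intervals)) {
    j <- match(id, genome$variant_id)
    for (pw in c("P1", "P2")) {
      pr <- if (genome$pathway[j] == pw) params$specificity else params$background_rate
      if (runif(1) < pr) {
        place_in(intervals[[id]], terms[[pw]], paste0(id, "_", pw))
      }
    }
  }
  glen <- genome$genome_length
  for (k in seq_len(params$n_background_genes)) {
    chrom <- sample(names(glen), 1, prob = glen / sum(glen))
    start <- floor(runif(1, 1, glen[[chrom]] - params$gene_width))
    gid <- c(gid, paste0("gene_bg", k))
    gchrom <- c(gchrom, chrom)
    gstart <- c(gstart, start)
    gend <- c(gend, start + params$gene_width)
    gterms[[length(gterms) + 1]] <- character(0)
  }
  list(genes = gene_table(gid, gchrom, gstart, gend, gterms),
       config = category_config(list(path1 = "TERM_P1", path2 = "TERM_P2")))
}

#' Generate a complete synthetic partitioned-MR study
#'
#' Orchestrates the full stated world from one seed: genome layout and
#' analytic LD reference; three independent cohorts (one-sample
#' individual-level, exposure GWAS, outcome GWAS) with pathway-structured
#' phenotypes; per-SNP summary statistics from exact OLS fits;
#' LD intervals per instrument; category-labelled gene annotations;
#' per-tissue eQTL panels with planted colocalization; and a ground-truth
#' table covering every instrument. Bit-reproducible given
#' `params$seed`.
#'
#' @param params a [sim_params()].
#' @return list of class `simulated_study`.
#' @export
simulate_study <- function(params = sim_params()) {
  withr_seed(params$seed, {
    genome <- simulate_genome(params)
    ld <- ld_from_genome(genome, params)
    dos1 <- simulate_genotypes(genome, params$n_individuals, params)
    ph1 <- simulate_phenotypes(dos1, genome, params)
    dosx <- simulate_genotypes(genome, params$n_gwas, params)
    phx <- simulate_phenotypes(dosx, genome, params)
    dosy <- simulate_genotypes(genome, params$n_gwas, params)
    phy <- simulate_phenotypes(dosy, genome, params)
    exposure_stats <- summary_stats_from_cohort(dosx, phx$exposure, genome)
    outcome_stats <- summary_stats_from_cohort(dosy, phy$outcome_cont, genome)
    cohort <- cohort_data(dos1, ph1$covariates,
                          data.frame(exposure = ph1$exposure,
                                     outcome_cont = ph1$outcome_cont,
                                     outcome_bin = ph1$outcome_bin))
    inst_ids <- genome$variant_id[genome$causal]
    intervals <- lapply(inst_ids, build_ld_interval, ld = ld)
    names(intervals) <- inst_ids
    ann <- simulate_gene_annotations(genome, intervals, params)
    eq <- simulate_eqtl_panels(genome, params)
    j <- match(inst_ids, genome$variant_id)
    truth <- data.frame(
      variant_id = inst_ids, pathway = genome$pathway[j],
      beta_exp_true = genome$beta[j],
      theta = c(P1 = params$theta1, P2 = params$theta2,
                P0 = params$theta0)[genome$pathway[j]],
      coloc_tissue_a = genome$pathway[j] == "P1",
      coloc_tissue_b = genome$pathway[j] == "P2",
      row.names = NULL)
    structure(list(params = params, genome = genome, ld = ld,
                   cohort = cohort,
                   exposure_stats = exposure_stats,
                   outcome_stats = outcome_stats,
                   intervals = intervals,
                   genes = ann$genes, config = ann$config,
                   eqtl_panels = eq$panels, eqtl_truth = eq$truth,
                   truth = truth),
              class = "simulated_study")
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("simulated_study:", nrow(x$truth), "instruments (",
      sum(x$truth$pathway == "P1"), "P1 /", sum(x$truth$pathway == "P2"),
      "P2 /", sum(x$truth$pathway == "P0"), "P0 ),",
      length(x$genome$variant_id), "variants, seed", x$params$seed, "\n")
  invisible(x)
}
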