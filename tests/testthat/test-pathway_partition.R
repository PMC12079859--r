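test_that("build_ld_interval spans the most distant qualifying partners", {
  ids <- c("lead", "p1", "p2", "p3", "far")
  pos <- c(10000, 5000, 12000, 8000, 10000 + 2e6)
  ld <- make_ld(ids, pos,
                data.frame(id1 = "lead", id2 = c("p1", "p2", "p3", "far"),
                           r2 = c(0.9, 0.85, 0.5, 0.95)))
  iv <- build_ld_interval("lead", ld)
  # p3 fails r2, far is beyond the 1 Mbp window
  expect_equal(c(iv$start, iv$end), c(5000, 12000))
  expect_setequal(iv$members, c("lead", "p1", "p2"))

  # degenerate: no qualifying partner
  iv0 <- build_ld_interval("p3", make_ld(ids, pos))
  expect_equal(c(iv0$start, iv0$end), c(8000, 8000))

  expect_error(build_ld_interval("nope", ld), "unknown")
})

test_that("build_ld_interval equals a brute-force scan on a simulated block", {
  p <- small_params(seed = 5)
  st <- simulate_study(p)
  g <- st$genome
  for (lead in sample(g$variant_id, 10)) {
    iv <- build_ld_interval(lead, st$ld)
    i <- match(lead, g$variant_id)
    qual <- abs(g$pos - g$pos[i]) <= 1e6 & g$chrom == g$chrom[i] &
      vapply(g$variant_id, function(j) ld_r2(st$ld, lead, j), 1) >= 0.8
    expect_equal(iv$start, min(g$pos[qual]))
    expect_equal(iv$end, max(g$pos[qual]))
  }
})

test_that("overlap_genes uses closed flanked intervals on one chromosome", {
  iv <- structure(list(lead = "v", chrom = "1", start = 10000, end = 20000,
                       members = "v"), class = "ld_interval")
  genes <- gene_table(c("gA", "gB", "gC"), c("1", "1", "2"),
                      c(5000, 8999, 12000), c(9000, 9000, 15000))
  # gA ends exactly flank_bp before the interval start: still included
  expect_setequal(overlap_genes(iv, genes), c("gA", "gB"))
  # with a 999 bp flank both genes now end short of the interval
  expect_length(overlap_genes(iv, genes, flank_bp = 999), 0)

  # brute force on random instances
  set.seed(2)
  for (rep in 1:5) {
    gs <- sort(sample.int(1e6, 30))
    genes_r <- gene_table(paste0("g", 1:30), sample(c("1", "2"), 30, TRUE),
                          gs, gs + sample.int(5e4, 30))
    ivs <- lapply(1:10, function(k) {
      s <- sample.int(1e6, 1)
      structure(list(lead = paste0("L", k), chrom = sample(c("1", "2"), 1),
                     start = s, end = s + 2e4, members = character(0)),
                class = "ld_interval")
    })
    for (iv_r in ivs) {
      brute <- genes_r$gene_id[
        genes_r$chrom == iv_r$chrom &
          pmax(genes_r$start - 1000, 0) <= iv_r$end &
          genes_r$end + 1000 >= iv_r$start]
      expect_setequal(overlap_genes(iv_r, genes_r), brute)
    }
  }
})

test_that("enrich_terms gives p = 1 for absent overlap and the floor when forced", {
  glen <- c("1" = 1e6)
  iv <- function(s, e) structure(list(lead = "x", chrom = "1", start = s,
                                      end = e, members = character(0)),
                                 class = "ld_interval")
  # term gene far away from every interval: observed 0, p = 1
  genes <- gene_table(c("g1", "g2"), "1", c(9e5, 100), c(9e5 + 100, 200),
                      list("T_far", "T_near"))
  res <- enrich_terms(list(iv(50, 300)), genes, glen, n_perm = 200, seed = 1)
  expect_equal(res$observed_count[res$term_id == "T_far"], 0)
  expect_equal(res$pval[res$term_id == "T_far"], 1)

  # saturated: single interval covering the whole genome -> p = 1
  res2 <- enrich_terms(list(iv(1, 1e6)), genes, glen, n_perm = 200, seed = 1)
  expect_true(all(res2$pval == 1))

  # all intervals on tiny term-T genes: floor (1/(R+1)) reached
  genes3 <- gene_table(paste0("t", 1:5), "1", (1:5) * 1e5, (1:5) * 1e5 + 50,
                       as.list(rep("T", 5)))
  ivs3 <- lapply(1:5, function(k) iv(k * 1e5, k * 1e5 + 50))
  res3 <- enrich_terms(ivs3, genes3, glen, n_perm = 1000, seed = 1)
  expect_equal(res3$pval, 1 / 1001)

  expect_warning(enrich_terms(ivs3, genes3, glen, n_perm = 50, seed = 1),
                 "unstable")
})

test_that("enrichment empirical p is roughly uniform under random placement", {
  glen <- c("1" = 1e6)
  set.seed(9)
  pvals <- replicate(60, {
    gs <- sample.int(9e5, 8)
    genes <- gene_table(paste0("g", 1:8), "1", gs, gs + 2000,
                        as.list(rep("T", 8)))
    ivs <- lapply(1:6, function(k) {
      s <- sample.int(9e5, 1)
      structure(list(lead = "x", chrom = "1", start = s, end = s + 5e4,
                     members = character(0)), class = "ld_interval")
    })
    suppressWarnings(enrich_terms(ivs, genes, glen, n_perm = 99,
                                  seed = sample.int(1e6, 1))$pval)
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("assign_categories honours the enrichment gate and dual membership", {
  iv <- function(id, s, e) structure(list(lead = id, chrom = "1", start = s,
                                          end = e, members = character(0)),
                                     class = "ld_interval")
  intervals <- list(v1 = iv("v1", 1e5, 2e5), v2 = iv("v2", 5e5, 6e5))
  # one gene carries both renal and vessel terms under v1
  genes <- gene_table(c("dual", "ves"), "1", c(1.5e5, 5.5e5), c(1.6e5, 5.6e5),
                      list(c("HP_RENAL", "HP_VESSEL"), "HP_VESSEL"))
  config <- category_config(list(renal = "HP_RENAL", vessel = "HP_VESSEL"))
  enr <- data.frame(term_id = c("HP_RENAL", "HP_VESSEL"),
                    observed_count = c(1, 2), expected_count = c(.1, .1),
                    pval = c(0.01, 0.01), n_perm = 1000)
  asg <- assign_categories(intervals, genes, config, enr)
  expect_setequal(asg$category[asg$variant_id == "v1"], c("renal", "vessel"))
  expect_false(any(asg$specific[asg$variant_id == "v1"]))
  expect_equal(asg$category[asg$variant_id == "v2"], "vessel")
  expect_true(asg$specific[asg$variant_id == "v2"])

  # gate at 0: everything empty, with warnings per category
  w <- capture_warnings(asg0 <- assign_categories(intervals, genes, config, enr,
                                                  enrich_p_max = 0))
  expect_length(w, 2)
  expect_match(w, "no enriched", all = TRUE)
  expect_equal(nrow(asg0), 0)

  # monotone in enrich_p_max
  enr2 <- enr; enr2$pval <- c(0.03, 0.2)
  asg_small <- suppressWarnings(assign_categories(intervals, genes, config, enr2,
                                                  enrich_p_max = 0.05))
  asg_large <- assign_categories(intervals, genes, config, enr2,
                                 enrich_p_max = 0.5)
  key <- function(a) paste(a$variant_id, a$category)
  expect_true(all(key(asg_small) %in% key(asg_large)))
})

test_that("planted pathway partition is recovered exactly on clean simulation", {
  st <- simulate_study(small_params(seed = 11, effects = "fixed"))
  enr <- enrich_terms(st$intervals, st$genes, st$genome$genome_length,
                      n_perm = 500, seed = 2)
  asg <- assign_categories(st$intervals, st$genes, st$config, enr)
  tr <- st$truth
  expect_setequal(asg$variant_id[asg$category == "path1"],
                  tr$variant_id[tr$pathway == "P1"])
  expect_setequal(asg$variant_id[asg$category == "path2"],
                  tr$variant_id[tr$pathway == "P2"])
  expect_true(all(asg$specific))
})
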