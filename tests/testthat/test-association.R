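test_that("VCF genotypes round-trip to the planted dosage matrix", {
  g <- synth_genotype_aridity(n_ecotypes = 30, n_snps = 8, causal_ve = 0,
                              seed = 13)
  dir <- withr::local_tempdir()
  write_panel(g$panel, dir, truth = g$truth)
  panel <- read_genotypes(file.path(dir, "snps.vcf"),
                          groups = file.path(dir, "groups.csv"),
                          aridity = file.path(dir, "aridity.csv"))
  expect_equal(panel$dosages, g$panel$dosages)
  expect_equal(panel$groups, g$panel$groups)
  expect_true(file.exists(file.path(dir, "truth.json")))
})

test_that("GT parsing maps genotype strings to dosages", {
  f <- onsenfate:::gt_to_dosage
  expect_equal(f("0/0"), 0L)
  expect_equal(f("0/1"), 1L)
  expect_equal(f("1/1"), 2L)
  expect_equal(f("0|1"), 1L)
  expect_true(is.na(f("./.")))
  expect_true(is.na(f(NA_character_)))
})

test_that("multiallelic sites are skipped with a warning", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\te1\te2",
    "1\t100\ts1\tA\tT\t.\tPASS\t.\tGT\t0/0\t1/1",
    "1\t200\ts2\tA\tT,C\t.\tPASS\t.\tGT\t0/1\t1/2"),
    file.path(dir, "multi.vcf"))
  expect_warning(panel <- read_genotypes(file.path(dir, "multi.vcf")),
                 "multiallelic")
  expect_equal(colnames(panel$dosages), "s1")
})

test_that("maf filter retains strictly above-threshold SNPs and matches brute force", {
  dos <- cbind(mono = rep(0L, 6), half = c(0L, 0L, 0L, 2L, 2L, 2L),
               low = c(0L, 0L, 0L, 0L, 0L, 1L))
  rownames(dos) <- paste0("e", 1:6)
  panel <- tiny_panel(dos)
  kept <- maf_filter(panel, threshold = 0.3)
  expect_equal(kept, "half") # maf 0.5 retained; maf 0 and 1/12 dropped
  # brute-force allele-count oracle on a synthetic spectrum
  g <- synth_genotype_aridity(n_ecotypes = 100, n_snps = 30, causal_ve = 0,
                              seed = 3, maf_range = c(0.05, 0.5))
  kept2 <- maf_filter(g$panel, 0.3)
  brute <- colnames(g$panel$dosages)[apply(g$panel$dosages, 2, function(v) {
    cnt <- sum(v); tot <- 2 * length(v)
    min(cnt, tot - cnt) / tot > 0.3
  })]
  expect_equal(kept2, brute)
  # maf range [0.3, 0.5] in expectation keeps most SNPs
  g2 <- synth_genotype_aridity(n_ecotypes = 2000, n_snps = 20, causal_ve = 0,
                               seed = 4, maf_range = c(0.35, 0.5))
  expect_equal(length(maf_filter(g2$panel, 0.3)), 20)
  all_na <- tiny_panel(cbind(x = rep(NA_integer_, 4), y = c(0L, 1L, 1L, 2L)) |>
                         `rownames<-`(paste0("e", 1:4)))
  expect_warning(kept3 <- maf_filter(all_na, 0.3), "all-missing")
  expect_equal(kept3, "y")
})

test_that("KING kinship is symmetric, 0.5 for duplicates, NA when undefined", {
  set.seed(5)
  dos <- matrix(sample(0:2, 40 * 6, replace = TRUE), 6, 40,
                dimnames = list(paste0("e", 1:6), paste0("s", 1:40)))
  dos[2, ] <- dos[1, ] # duplicate pair
  panel <- tiny_panel(dos)
  k <- king_kinship(panel)
  expect_equal(k, t(k))
  expect_equal(k["e1", "e2"], 0.5)
  expect_equal(unname(diag(k)), rep(0.5, 6))
  # opposing homozygotes with no heterozygous site: undefined
  opp <- tiny_panel(matrix(c(rep(0L, 5), rep(2L, 5)), 2, 5, byrow = TRUE,
                           dimnames = list(c("a", "b"), paste0("s", 1:5))))
  k2 <- king_kinship(opp)
  expect_true(is.na(k2["a", "b"]))
  expect_error(king_kinship(tiny_panel(dos[1, , drop = FALSE])), ">= 2")
})

test_that("parent-offspring pairs have kinship near 0.25", {
  set.seed(11)
  m <- 10000; n_pairs <- 15
  p <- runif(m, 0.2, 0.8)
  ks <- vapply(seq_len(n_pairs), function(i) {
    parent <- rbinom(m, 2, p)
    transmitted <- rbinom(m, 1, parent / 2)       # one allele from the parent
    offspring <- transmitted + rbinom(m, 1, p)    # one random allele
    dos <- rbind(parent = parent, offspring = offspring)
    rownames(dos) <- c("p", "o"); colnames(dos) <- paste0("s", seq_len(m))
    king_kinship(tiny_panel(dos))["p", "o"]
  }, 0)
  expect_equal(mean(ks), 0.25, tolerance = 0.02)
})

test_that("greedy pruning keeps one representative per duplicate cluster", {
  g <- synth_genotype_aridity(n_ecotypes = 40, n_snps = 50, causal_ve = 0,
                              seed = 7, duplicate_clusters = 3,
                              cluster_size = 3)
  k <- king_kinship(g$panel)
  kept <- prune_related(k, cutoff = 0.5)
  for (members in g$truth$cluster_members) {
    expect_equal(sum(members %in% kept), 1)
  }
  # everything unrelated stays
  others <- setdiff(rownames(k), unlist(g$truth$cluster_members))
  high <- k[others, others]; diag(high) <- 0
  if (all(high < 0.5, na.rm = TRUE)) expect_true(all(others %in% kept))
  # no pair at or above the cutoff: identity
  sub <- k[others, others]
  expect_equal(sort(prune_related(sub, cutoff = 1.1)), sort(others))
})

test_that("LD r2 is 1 on the diagonal/duplicated SNPs and respects relabeling", {
  set.seed(9)
  dos <- matrix(sample(0:2, 50 * 4, replace = TRUE, prob = c(1, 2, 1)), 50, 4,
                dimnames = list(paste0("e", 1:50), paste0("s", 1:4)))
  dos[, 2] <- dos[, 1]        # duplicated SNP
  panel <- tiny_panel(dos)
  r2 <- ld_r2(panel)
  expect_equal(unname(diag(r2)), rep(1, 4))
  expect_equal(r2["s1", "s2"], 1)
  flipped <- dos; flipped[, 3] <- 2L - flipped[, 3] # allele relabeling
  expect_equal(ld_r2(tiny_panel(flipped)), r2)
  const <- dos; const[, 4] <- 1L
  r2c <- ld_r2(tiny_panel(const))
  expect_true(all(is.na(r2c["s4", ])))
  expect_error(ld_r2(panel, snp_ids = "s1"), ">= 2")
})

test_that("independent SNPs show near-zero mean off-diagonal r2", {
  g <- synth_genotype_aridity(n_ecotypes = 1000, n_snps = 12, causal_ve = 0,
                              seed = 15)
  r2 <- ld_r2(g$panel)
  off <- r2[lower.tri(r2)]
  expect_lt(mean(off), 0.01)
})

test_that("the mixed model collapses to OLS when group variance is absent", {
  g <- synth_genotype_aridity(n_ecotypes = 300, n_groups = 5, n_snps = 2,
                              causal_ve = 10, group_sd = 0, seed = 19)
  fit <- fit_lmm_snp(g$panel, g$truth$causal_snp)
  d <- fit$data
  ols <- lm(aridity ~ dosage, data = d)
  expect_equal(fit$beta, unname(coef(ols)[["dosage"]]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(coef(ols)[[1]]), tolerance = 1e-6)
  ve_ols <- 100 * coef(ols)[["dosage"]]^2 * var(d$dosage) /
    (coef(ols)[["dosage"]]^2 * var(d$dosage) + sum(ols$residuals^2) / nrow(d))
  expect_equal(fit$variance_explained, unname(ve_ols), tolerance = 1e-4)
})

test_that("the profile-ML fit agrees with lme4 maximum likelihood", {
  skip_if_not_installed("lme4")
  g <- synth_genotype_aridity(n_ecotypes = 400, n_groups = 8, n_snps = 2,
                              causal_ve = 4.3, seed = 23)
  fit <- fit_lmm_snp(g$panel, g$truth$causal_snp)
  d <- fit$data
  m <- lme4::lmer(aridity ~ dosage + (1 | group), data = d, REML = FALSE)
  expect_equal(fit$beta, unname(lme4::fixef(m)[["dosage"]]), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$sigma2_g, vc$vcov[1], tolerance = 1e-3)
  expect_equal(fit$sigma2_e, vc$vcov[2], tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-5)
})

test_that("degenerate mixed-model inputs are rejected", {
  g <- synth_genotype_aridity(n_ecotypes = 50, n_groups = 1, n_snps = 2,
                              causal_ve = 0, seed = 29)
  expect_error(fit_lmm_snp(g$panel, colnames(g$panel$dosages)[1]),
               ">= 2 admixture groups")
  g2 <- synth_genotype_aridity(n_ecotypes = 50, n_groups = 4, n_snps = 2,
                               causal_ve = 0, seed = 31)
  g2$panel$dosages[, 1] <- 1L
  expect_error(fit_lmm_snp(g2$panel, colnames(g2$panel$dosages)[1]),
               "constant dosage")
  expect_error(fit_lmm_snp(g2$panel, "nope"), "not in panel")
  bare <- tiny_panel(g2$panel$dosages)
  expect_error(fit_lmm_snp(bare, colnames(g2$panel$dosages)[2]),
               "groups.*aridity")
})
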