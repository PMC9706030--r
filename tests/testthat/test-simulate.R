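test_that("the generator is deterministic given its seed", {
  cfg <- sim_config(seed = 99, n_genes = 500, total_reads = 3e4,
                    genus_profile = c(A = 0.5, B = 0.3, C = 0.1))
  s1 <- simulate_catalog(cfg)
  s2 <- simulate_catalog(cfg)
  expect_identical(s1$catalog$genes, s2$catalog$genes)
  expect_identical(s1$truth$expected_cc, s2$truth$expected_cc)
  # a different seed moves the draw
  s3 <- simulate_catalog(sim_config(seed = 100, n_genes = 500,
                                    total_reads = 3e4,
                                    genus_profile = c(A = 0.5, B = 0.3,
                                                      C = 0.1)))
  expect_false(identical(s1$catalog$genes, s3$catalog$genes))
})

test_that("generated catalogs satisfy the catalog contract for many seeds", {
  for (seed in 1:5) {
    sim <- simulate_catalog(sim_config(seed = seed, n_genes = 400,
                                       total_reads = 2e4,
                                       genus_profile = c(A = 0.45, B = 0.25,
                                                         C = 0.05)))
    cat <- sim$catalog
    expect_s3_class(cat, "gene_catalog")   # construction validates
    expect_lte(sum(cat$genes$read_count), cat$total_reads)
    expect_true(all(cat$genes$genus[cat$genes$lineage ==
                                      "domain:Bacteria;phylum:Firmicutes"]
                    == "unassigned"))
  }
})

test_that("sim_config rejects infeasible designs", {
  expect_error(sim_config(genus_profile = c(A = 0.8, B = 0.4)), "infeasible")
  expect_error(sim_config(genus_profile = c(A = -0.1)), "non-negative")
  expect_error(sim_config(genus_profile = c(A = 0.5), dispersion = 0),
               "dispersion")
  expect_error(sim_config(genus_profile = c(A = 0.5),
                          noncazyme_fraction = 1), "noncazyme")
})

test_that("proportional allocation yields CC near 1 everywhere", {
  cfg <- sim_config(seed = 12, n_genes = 10000, total_reads = 1e6,
                    genus_profile = c(A = 0.5, B = 0.3, C = 0.15),
                    noncazyme_fraction = 0.2)
  expect_equal(unname(expected_cc(cfg)), matrix(1, 4, 15),
               tolerance = 1e-12)
  sim <- simulate_catalog(cfg)
  fit <- cazy_cc(sim$catalog)
  cc <- coef(fit)[c("A", "B", "C"), ]
  defined <- !is.na(cc)
  expect_true(all(abs(cc[defined] - 1) < 0.5))
  expect_lt(abs(mean(cc[defined]) - 1), 0.05)
})

test_that("the consortium preset recovers its genus profile within 0.02", {
  cfg <- tmc7_preset(seed = 3)
  sim <- simulate_catalog(cfg)
  r <- genus_abundances(sim$catalog)
  target <- cfg$genus_profile
  expect_true(all(abs(r[names(target)] - target) < 0.02))
  roles <- attr(cfg, "planted_roles")
  expect_setequal(names(roles)[roles == "cheater"],
                  c("Symbiobacterium", "Desulfotomaculum"))
})

test_that("estimated CC converges to the design's expected CC with depth", {
  # two depths, modest replication: bias shrinks and estimates track the
  # closed-form ground truth
  profile <- c(A = 0.45, B = 0.3, C = 0.2)
  alloc <- matrix(1, 3, 15,
                  dimnames = list(names(profile),
                                  cazycontrib:::CAZY_FUNCTIONS))
  alloc["A", cazycontrib:::HYDROLASE_FUNCTIONS] <- 1.5
  alloc["C", cazycontrib:::HYDROLASE_FUNCTIONS] <- 0.4
  err <- sapply(c(1e5, 1e6), function(depth) {
    e <- sapply(1:6, function(s) {
      cfg <- sim_config(seed = s, n_genes = 20000, total_reads = depth,
                        genus_profile = profile, allocation = alloc,
                        noncazyme_fraction = 0.3)
      sim <- simulate_catalog(cfg)
      fit <- cazy_cc(sim$catalog)
      cc <- coef(fit)[rownames(sim$truth$expected_cc),
                      colnames(sim$truth$expected_cc)[1:14]]
      mean(abs(cc - sim$truth$expected_cc[, 1:14]), na.rm = TRUE)
    })
    mean(e)
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("doubling read depth shrinks the abundance standard error", {
  profile <- c(A = 0.4, B = 0.3, C = 0.2)
  se_at <- function(depth) {
    est <- sapply(1:20, function(s) {
      sim <- simulate_catalog(sim_config(seed = s, n_genes = 1500,
                                         total_reads = depth,
                                         genus_profile = profile))
      genus_abundances(sim$catalog)[["A"]]
    })
    stats::sd(est)
  }
  ratio <- se_at(5e4) / se_at(1e5)
  # halving the variance means the SE falls by sqrt(2); accept the
  # factor-of-2 band around a halved SE
  expect_gte(ratio, 1)
  expect_lte(ratio, 4)
})

test_that("packaged profile tables carry the published totals", {
  ft <- fixture_tables()
  gh <- ft$table1[ft$table1$cazy_class == "GH", ]
  expect_equal(gh$family_count, 102)
  expect_equal(gh$gene_count, 643)
  expect_equal(gh$read_count, 2556056)
  expect_equal(nrow(ft$table2[ft$table2$section == "LMEs", ]), 4)
  # section sums of the family table reproduce its printed SUM rows
  lme <- ft$table2[ft$table2$section == "LMEs", ]
  expect_equal(sum(lme$gene_count), 57)
  expect_equal(sum(lme$read_count), 125248)
})
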