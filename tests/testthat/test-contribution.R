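make_two_gene_catalog <- function() {
  gene_catalog(data.frame(
    gene_id = c("a", "b"),
    genus = c("A", "B"),
    lineage = c("domain:Bacteria;genus:A", "domain:Bacteria;genus:B"),
    families = c("GH10", "GH10"),
    read_count = c(80, 20)), total_reads = 200)
}

test_that("function read shares follow the two-gene arithmetic", {
  dist <- function_distribution(make_two_gene_catalog(),
                                functions = "endo_xylanase")
  expect_equal(unname(dist$function_reads["endo_xylanase"]), 100)
  expect_equal(dist$values["A", "endo_xylanase"], 0.8)
  expect_equal(dist$values["B", "endo_xylanase"], 0.2)
})

test_that("a gene with two families of one function counts once", {
  cat <- gene_catalog(data.frame(
    gene_id = "a", genus = "A", lineage = "domain:Bacteria;genus:A",
    families = "GH10;GH11",   # both endo-xylanase
    read_count = 60), total_reads = 100)
  dist <- function_distribution(cat, functions = "endo_xylanase")
  expect_equal(unname(dist$function_reads["endo_xylanase"]), 60)
})

test_that("functions with no reads are flagged, not dropped", {
  dist <- function_distribution(make_two_gene_catalog(),
                                functions = c("endo_xylanase", "lignin_AA"))
  expect_true("lignin_AA" %in% colnames(dist$values))
  expect_equal(dist$flagged, "lignin_AA")
  expect_true(all(is.na(dist$values[, "lignin_AA"])))
  expect_error(function_distribution(make_two_gene_catalog(),
                                     functions = "no_such_function"),
               "unknown")
})

test_that("contribution coefficients reproduce the printed worked example", {
  # shares as published: R_g-f = 19.98%, R_g = 42.85% -> CC = 0.466
  cc <- 0.1998 / 0.4285
  expect_equal(signif(cc, 3), 0.466)

  # and through the estimator on a catalog engineered to those shares
  cat <- gene_catalog(data.frame(
    gene_id = c("r_lig", "o_lig", "r_other"),
    genus = c("Ruminiclostridium", "Other", "Ruminiclostridium"),
    lineage = c("domain:Bacteria;genus:Ruminiclostridium",
                "domain:Bacteria;genus:Other",
                "domain:Bacteria;genus:Ruminiclostridium"),
    families = c("AA4", "AA6", ""),
    read_count = c(19980, 80020, 65720)), total_reads = 200000)
  fit_cc <- contribution_coefficients(
    function_distribution(cat, functions = "lignin"),
    genus_abundances(cat))
  expect_equal(signif(fit_cc$values["Ruminiclostridium", "lignin"], 3), 0.466)
})

test_that("proportional representation gives CC = 1 and errors are caught", {
  dist <- function_distribution(make_two_gene_catalog(),
                                functions = "endo_xylanase")
  # abundances equal to the function shares -> CC exactly 1
  cc <- contribution_coefficients(dist, c(A = 0.8, B = 0.2))
  expect_equal(unname(cc$values[, "endo_xylanase"]), c(1, 1))
  expect_error(contribution_coefficients(dist, c(A = 0.5)), "B")
  # zero-abundance rows are undefined, never zero
  cc0 <- contribution_coefficients(dist, c(A = 0.8, B = 0))
  expect_true(is.na(cc0$values["B", "endo_xylanase"]))
})

test_that("share columns sum to one and the weighted CC identity holds", {
  funs <- c("cellulose", "hemicellulose", "endo_xylanase", "esterase")
  for (seed in c(5, 29)) {
    cat <- random_catalog(seed)
    dist <- function_distribution(cat, functions = funs)
    ok <- dist$function_reads > 0
    expect_equal(unname(colSums(dist$values[, ok, drop = FALSE])),
                 rep(1, sum(ok)))
    # all reads carry a genus bin here, so sum_g R_g * CC_g,f = 1
    cc <- contribution_coefficients(dist, genus_abundances(cat))
    v <- cc$values
    v[is.na(v)] <- 0
    expect_equal(unname(colSums(cc$abundances * v)[ok]), rep(1, sum(ok)))
  }
})

test_that("CC is invariant under uniform read rescaling", {
  cat <- random_catalog(31)
  k <- 13
  genes <- cat$genes
  genes$read_count <- genes$read_count * k
  cat_k <- gene_catalog(genes, total_reads = cat$total_reads * k)
  funs <- c("endoglucanase", "beta_xylosidase", "galactosidase")
  cc1 <- contribution_coefficients(function_distribution(cat, functions = funs),
                                   genus_abundances(cat))
  cc2 <- contribution_coefficients(function_distribution(cat_k, functions = funs),
                                   genus_abundances(cat_k))
  expect_equal(cc1$values, cc2$values)
})

test_that("matrix pipeline equals the brute-force per-record oracle", {
  map <- load_default_map()
  funs <- c(setdiff(cazycontrib:::CAZY_FUNCTIONS, "binding_module"),
            "cellulose", "hemicellulose", "lignin")
  for (seed in c(2, 8)) {
    cat <- random_catalog(seed, n = 500)
    dist <- function_distribution(cat, map, functions = funs)
    expect_equal(dist$counts, oracle_counts(cat, map, funs))
  }
  # and on a simulated consortium catalog under 1000 genes
  sim <- simulate_catalog(sim_config(seed = 4, n_genes = 800,
                                     total_reads = 5e4,
                                     genus_profile = c(A = 0.5, B = 0.3,
                                                       C = 0.1)))
  dist <- function_distribution(sim$catalog, map, functions = funs)
  expect_equal(dist$counts, oracle_counts(sim$catalog, map, funs))
})

test_that("role calls follow the quantile rule", {
  dist <- structure(list(values = matrix(0.5, 2, 3,
                                         dimnames = list(c("A", "B"),
                                                         c("endoglucanase",
                                                           "beta_xylosidase",
                                                           "galactosidase"))),
                         counts = NULL, function_reads = c(1, 1, 1)),
                    class = "distribution_matrix")
  # engineered CC: A all 2, B all 0.2
  cc <- contribution_coefficients(dist, c(A = 0.25, B = 2.5))
  roles <- classify_roles(cc)
  expect_equal(unname(roles["A"]), "contributor")
  expect_equal(unname(roles["B"]), "cheater")

  # no defined cells -> undetermined
  cc$values["A", ] <- NA
  expect_equal(unname(classify_roles(cc)["A"]), "undetermined")
  expect_error(classify_roles(cc, hydrolase_functions = character(0)),
               "non-empty")
  expect_error(classify_roles(cc, hydrolase_functions = "lignin_AA"),
               "absent")
})

test_that("circos export is bit-exact on integer counts and conserves N_f", {
  cat <- random_catalog(41)
  dist <- function_distribution(cat,
                                functions = c("cellulose", "hemicellulose"))
  path <- withr::local_tempfile(fileext = ".txt")
  export_circos_table(dist, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(dist$counts) + 1)
  back <- read_circos_table(path)
  expect_equal(back, dist$counts, ignore_attr = "storage.mode")
  expect_equal(colSums(back), dist$function_reads)
})

test_that("gene-count mode shares genes instead of reads", {
  cat <- make_two_gene_catalog()
  dist <- function_distribution(cat, functions = "endo_xylanase",
                                mode = "genes")
  expect_equal(unname(dist$values[, "endo_xylanase"]), c(0.5, 0.5))
})
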