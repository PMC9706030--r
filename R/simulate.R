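# Synthetic annotation-layer generator.  Simulation begins at the gene
# catalog the analysis consumes (no reads, no contigs): genes receive a
# genus, optionally a CAZy family drawn through the function ontology, and
# an overdispersed mapped-read count.

#' Configure a synthetic gene catalog
#'
#' The generator emulates the statistical structure of a consortium
#' metagenome gene catalog: a fixed genus abundance profile (read shares), a
#' per-genus allocation of genes to lignocellulolytic function categories,
#' and overdispersed per-gene read counts.  Reads are allocated
#' hierarchically: genus read totals are multinomial at the profile, then
#' spread over the genus's genes with gamma weights (a Dirichlet-multinomial),
#' so recovered abundances converge to the profile at rate `1/sqrt(N)`.
#'
#' The allocation multiplier `m[g, f]` scales the absolute probability that
#' a gene of genus `g` is a CAZyme of category `f`: `m = 1` means enzyme
#' investment proportional to abundance, `m < 1` cheater-like under-investment
#' (the genus has *more* non-CAZyme genes, nothing is renormalized), `m > 1`
#' contributor-like over-investment.
#'
#' @param seed Integer seed controlling all randomness of one run.
#' @param n_genes Number of genes in the catalog.
#' @param total_reads Total clean reads `N`; all of them fall on genes.
#' @param genus_profile Named vector of target genus read shares, summing to
#'   at most 1; the remainder becomes the `"unassigned"` bin.
#' @param allocation Genus x category multiplier matrix; rownames must cover
#'   the profile genera (an `"unassigned"` row is optional, default 1), and
#'   colnames must be base categories of the vocabulary.  Default: all 1
#'   over every category.
#' @param dispersion Gamma overdispersion of per-gene read weights (variance
#'   of the unit-mean weights); > 0.
#' @param noncazyme_fraction Fraction of genes with no CAZy family for a
#'   multiplier-1 genus, in `[0, 1)`.
#' @param base_weights Optional named relative weights over the allocation
#'   categories (default uniform).
#' @return A `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 50000,
                       total_reads = 1e6,
                       genus_profile,
                       allocation = NULL,
                       dispersion = 0.3,
                       noncazyme_fraction = 0.5,
                       base_weights = NULL) {
  stopifnot(is.numeric(genus_profile), !is.null(names(genus_profile)))
  if (any(genus_profile < 0)) stop("genus abundances must be non-negative",
                                   call. = FALSE)
  if (sum(genus_profile) > 1 + 1e-9) {
    stop("infeasible genus profile: abundances sum to more than 1",
         call. = FALSE)
  }
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (noncazyme_fraction < 0 || noncazyme_fraction >= 1) {
    stop("noncazyme_fraction must be in [0, 1)", call. = FALSE)
  }
  if (is.null(allocation)) {
    cats <- CAZY_FUNCTIONS
    allocation <- matrix(1, nrow = length(genus_profile), ncol = length(cats),
                         dimnames = list(names(genus_profile), cats))
  }
  stopifnot(is.matrix(allocation), !is.null(rownames(allocation)),
            !is.null(colnames(allocation)))
  if (any(allocation < 0)) stop("allocation multipliers must be non-negative",
                                call. = FALSE)
  missing_rows <- setdiff(names(genus_profile), rownames(allocation))
  if (length(missing_rows) > 0) {
    stop("allocation lacks rows for: ", paste(missing_rows, collapse = ", "),
         call. = FALSE)
  }
  bad_cats <- setdiff(colnames(allocation), CAZY_FUNCTIONS)
  if (length(bad_cats) > 0) {
    stop("allocation columns outside the vocabulary: ",
         paste(bad_cats, collapse = ", "), call. = FALSE)
  }
  if (is.null(base_weights)) {
    base_weights <- stats::setNames(rep(1, ncol(allocation)),
                                    colnames(allocation))
  }
  stopifnot(all(colnames(allocation) %in% names(base_weights)))
  base_weights <- base_weights[colnames(allocation)]
  base_weights <- base_weights / sum(base_weights)

  structure(list(seed = as.integer(seed),
                 n_genes = as.integer(n_genes),
                 total_reads = total_reads,
                 genus_profile = genus_profile,
                 allocation = allocation,
                 dispersion = dispersion,
                 noncazyme_fraction = noncazyme_fraction,
                 base_weights = base_weights),
            class = "sim_config")
}

# Full genus set and probabilities, appending the unassigned remainder.
sim_genera <- function(cfg) {
  p <- cfg$genus_profile
  rem <- 1 - sum(p)
  if (rem > 1e-12) p <- c(p, unassigned = rem)
  p / sum(p)
}

# Allocation row for a genus; absent rows (unassigned) default to 1.
alloc_row <- function(cfg, genus) {
  if (genus %in% rownames(cfg$allocation)) {
    cfg$allocation[genus, ]
  } else {
    stats::setNames(rep(1, ncol(cfg$allocation)), colnames(cfg$allocation))
  }
}

#' Closed-form expected contribution coefficients of a simulation design
#'
#' Under the generator the asymptotic CC of genus `g` for function `f` is
#' determined by the design alone: a gene of genus `g` draws category `f`
#' with probability proportional to `base[f] * m[g, f]` and then a family
#' uniformly within the category, and because families are shared between
#' categories a function column collects reads from every category whose
#' families overlap it.  This function evaluates that expectation exactly;
#' it equals the planted multiplier `m[g, f]` whenever families are
#' category-exclusive and the profile-weighted multipliers average 1, and is
#' the generator's ground truth otherwise (the weighted identity
#' `sum_g R_g * CC[g, f] = 1` always holds).
#'
#' @param cfg A [sim_config].
#' @param map A [function_map][load_default_map].
#' @param functions Function names (roll-ups allowed); default the
#'   allocation's categories.
#' @return Genus x function matrix of expected CC (includes `"unassigned"`).
#' @export
expected_cc <- function(cfg, map = load_default_map(), functions = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  functions <- expand_functions(map, functions %||% colnames(cfg$allocation))
  p <- sim_genera(cfg)
  genera <- names(p)
  cats <- colnames(cfg$allocation)
  fam_sets <- lapply(cats, families_for, map = map)
  names(fam_sets) <- cats
  fams <- sort(unique(unlist(fam_sets)))

  # famP[g, fam]: per-gene probability (up to a constant) that a gene of
  # genus g carries family fam
  amat <- do.call(rbind, lapply(genera, alloc_row, cfg = cfg))
  rownames(amat) <- genera
  famP <- matrix(0, nrow = length(genera), ncol = length(fams),
                 dimnames = list(genera, fams))
  for (f in cats) {
    fs <- fam_sets[[f]]
    if (length(fs) == 0) next
    contrib <- cfg$base_weights[[f]] * amat[, f] / length(fs)
    famP[, fs] <- famP[, fs] + contrib
  }

  out <- matrix(NA_real_, nrow = length(genera), ncol = length(functions),
                dimnames = list(genera, functions))
  for (fun in functions) {
    members <- base_categories(map, fun)
    fam_fun <- sort(unique(unlist(fam_sets[intersect(members, cats)])))
    if (length(fam_fun) == 0) next
    s <- rowSums(famP[, fam_fun, drop = FALSE])
    denom <- sum(p * s)
    if (denom > 0) out[, fun] <- s / denom
  }
  out
}

#' Simulate a gene catalog with known structure
#'
#' Draws a synthetic annotation-layer catalog from a [sim_config]:
#' reproducible given the seed, passing [gene_catalog] validation, and
#' accompanied by its ground truth (true genus shares, the allocation
#' multipliers, and the design's [expected_cc] matrix).
#'
#' @param cfg A [sim_config].
#' @param map A [function_map][load_default_map] supplying the family sets
#'   per category (subfamily blocks emit a concrete subfamily label).
#' @param verbose Log progress to stderr.
#' @return A list of class `sim_result` with elements `catalog`
#'   (a [gene_catalog]) and `truth` (list: `genus_profile`, `allocation`,
#'   `expected_cc`, `seed`, `generator`).
#' @export
simulate_catalog <- function(cfg, map = load_default_map(), verbose = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p <- sim_genera(cfg)
  genera <- names(p)
  n <- cfg$n_genes
  cats <- colnames(cfg$allocation)

  # category sampling probabilities per genus (absolute, "none" absorbs)
  caz_rate <- 1 - cfg$noncazyme_fraction
  probs <- lapply(genera, function(g) {
    pr <- caz_rate * cfg$base_weights * alloc_row(cfg, g)
    if (sum(pr) > 1) {
      stop("allocation multipliers too large for genus ", g,
           ": category probabilities exceed 1", call. = FALSE)
    }
    pr
  })
  names(probs) <- genera

  # family pools per category (subfamily blocks expand to member labels)
  sub_members <- list()
  for (i in seq_len(nrow(map$entries))) {
    e <- map$entries[i, ]
    if (e$subfamilies && nzchar(e$subfamily_members)) {
      sub_members[[e$family_label]] <-
        strsplit(e$subfamily_members, " ", fixed = TRUE)[[1]]
    }
  }
  fam_pool <- lapply(cats, function(f) {
    fs <- families_for(map, f)
    if (length(fs) == 0) character(0) else fs
  })
  names(fam_pool) <- cats

  genus <- sample(genera, n, replace = TRUE, prob = p)
  family <- character(n)
  for (g in genera) {
    idx <- which(genus == g)
    if (length(idx) == 0) next
    pr <- probs[[g]]
    draw <- sample(c(cats, ".none"), length(idx), replace = TRUE,
                   prob = c(pr, 1 - sum(pr)))
    for (f in cats) {
      sel <- idx[draw == f]
      pool <- fam_pool[[f]]
      if (length(sel) == 0 || length(pool) == 0) next
      fam <- pool[sample.int(length(pool), length(sel), replace = TRUE)]
      # subfamily blocks emit a concrete subfamily label
      for (b in intersect(unique(fam), names(sub_members))) {
        hit <- which(fam == b)
        mem <- sub_members[[b]]
        fam[hit] <- mem[sample.int(length(mem), length(hit), replace = TRUE)]
      }
      family[sel] <- fam
    }
  }

  # hierarchical read allocation: multinomial genus totals, then
  # gamma-weighted (Dirichlet-multinomial) split within each genus
  reads <- numeric(n)
  genus_tot <- as.vector(rmultinom(1, cfg$total_reads, p))
  names(genus_tot) <- genera
  shape <- 1 / cfg$dispersion
  for (g in genera) {
    idx <- which(genus == g)
    if (length(idx) == 0) next
    w <- rgamma(length(idx), shape = shape, rate = shape)
    if (all(w == 0)) w <- rep(1, length(idx))
    reads[idx] <- as.vector(rmultinom(1, genus_tot[[g]], w))
  }
  msg_verbose(verbose, sprintf(
    "simulated %d genes (%d CAZyme) over %d genera, %.0f reads",
    n, sum(nzchar(family)), length(genera), sum(reads)))

  lineage <- ifelse(
    genus == "unassigned",
    "domain:Bacteria;phylum:Firmicutes",
    paste0("domain:Bacteria;phylum:Firmicutes;class:Bacilli;",
           "order:Bacillales;family:synthetic;genus:", genus))

  catalog <- gene_catalog(
    data.frame(gene_id = sprintf("gene_%06d", seq_len(n)),
               genus = genus,
               lineage = lineage,
               families = family,
               read_count = reads,
               stringsAsFactors = FALSE),
    total_reads = cfg$total_reads)

  structure(list(
    catalog = catalog,
    truth = list(genus_profile = p,
                 allocation = cfg$allocation,
                 expected_cc = expected_cc(cfg, map),
                 seed = cfg$seed,
                 generator = "cazycontrib synthetic annotation generator v1")),
    class = "sim_result")
}

#' Consortium-emulation simulation preset
#'
#' A [sim_config] emulating a nine-genus thermophilic lignocellulolytic
#' consortium: the dominant-genus abundance profile (42.85%, 18.41%, 10.44%,
#' 7.48%, 2.65%, 2.47%, 2.33%, 1.56%, 1.26%, remainder unassigned), two
#' dominant contributors over-investing in hydrolase genes (`m = 1.25`), two
#' low-abundance sugar cheaters under-investing (`m = 0.2` on hydrolases but
#' over-representing AA/esterase genes, `m = 1.5`), and five genuinely
#' intermediate genera that specialize: high investment (`m = 1.7`) in one
#' block of hydrolase functions and low (`m = 0.4`) in the other, with the
#' blocks chosen along the main-chain/debranching split so the planted
#' pattern survives family sharing between categories (see [expected_cc]).
#' Planted roles are attached as attribute `planted_roles`.
#'
#' @param seed Integer seed.
#' @param n_genes,total_reads,dispersion,noncazyme_fraction See
#'   [sim_config()].
#' @return A `sim_config` with attribute `planted_roles` (named character:
#'   contributor/cheater/intermediate per genus).
#' @export
tmc7_preset <- function(seed = 1L, n_genes = 50000, total_reads = 1e6,
                        dispersion = 0.3, noncazyme_fraction = 0.5) {
  profile <- c(Ruminiclostridium = 0.4285,
               Thermoanaerobacterium = 0.1841,
               Geobacillus = 0.1044,
               unclassified_f__Bacillaceae = 0.0748,
               Aeribacillus = 0.0265,
               Symbiobacterium = 0.0247,
               Desulfotomaculum = 0.0233,
               Caldibacillus = 0.0156,
               Clostridium = 0.0126)
  contributors <- c("Ruminiclostridium", "Thermoanaerobacterium")
  cheaters <- c("Symbiobacterium", "Desulfotomaculum")
  intermediates <- setdiff(names(profile), c(contributors, cheaters))

  cats <- CAZY_FUNCTIONS
  hydro <- HYDROLASE_FUNCTIONS
  mainchain <- c("endoglucanase", "exoglucanase", "beta_glucosidase",
                 "endo_xylanase", "beta_xylosidase", "beta_mannanase")
  debranch <- setdiff(hydro, mainchain)
  mc_high <- c("Aeribacillus", "Caldibacillus", "Clostridium")
  db_high <- c("Geobacillus", "unclassified_f__Bacillaceae")

  alloc <- matrix(1, nrow = length(profile), ncol = length(cats),
                  dimnames = list(names(profile), cats))
  alloc[contributors, hydro] <- 1.25
  alloc[contributors, "lignin_AA"] <- 0.5
  alloc[cheaters, hydro] <- 0.2
  alloc[cheaters, c("lignin_AA", "esterase")] <- 1.5
  alloc[mc_high, mainchain] <- 1.7
  alloc[mc_high, debranch] <- 0.4
  alloc[db_high, mainchain] <- 0.4
  alloc[db_high, debranch] <- 1.7

  cfg <- sim_config(seed = seed, n_genes = n_genes,
                    total_reads = total_reads,
                    genus_profile = profile,
                    allocation = alloc,
                    dispersion = dispersion,
                    noncazyme_fraction = noncazyme_fraction)
  roles <- c(stats::setNames(rep("contributor", length(contributors)),
                             contributors),
             stats::setNames(rep("cheater", length(cheaters)), cheaters),
             stats::setNames(rep("intermediate", length(intermediates)),
                             intermediates))
  attr(cfg, "planted_roles") <- roles[names(profile)]
  cfg
}

#' Packaged published-style profile tables
#'
#' Returns the packaged class-level and family-level CAZyme summary fixtures
#' of the reference consortium metagenome: six class rows (families, genes,
#' reads per CAZy class) and the per-family table of lignocellulose
#' degradation CAZymes with its curated sections.
#'
#' @return List with `table1` (class level: `cazy_class`, `family_count`,
#'   `gene_count`, `read_count`) and `table2` (family level: `section`,
#'   `family_label`, `description`, `gene_count`, `read_count`).
#' @export
fixture_tables <- function() {
  t1 <- read.delim(system.file("extdata", "table1_classes.tsv",
                               package = "cazycontrib", mustWork = TRUE),
                   check.names = FALSE)
  t2 <- read.delim(system.file("extdata", "table2_families.tsv",
                               package = "cazycontrib", mustWork = TRUE),
                   check.names = FALSE)
  list(table1 = t1, table2 = t2)
}
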