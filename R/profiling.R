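# Profiling: class/family aggregates and genus abundances.

# Long-format gene x family table: one row per (gene, family label) pair,
# with the label resolved against the map (subfamily -> parent block) when a
# map is given.  gene index refers to rows of catalog$genes.
gene_family_long <- function(catalog, map = NULL) {
  g <- catalog$genes
  fam_list <- lapply(g$families, split_families)
  n_fam <- lengths(fam_list)
  idx <- rep.int(seq_len(nrow(g)), n_fam)
  label <- unlist(fam_list, use.names = FALSE)
  out <- data.frame(gene = idx,
                    label = label %||% character(0),
                    stringsAsFactors = FALSE)
  out$class <- class_of_label(out$label)
  out$resolved <- if (!is.null(map)) {
    r <- resolve_families(out$label, map)
    ifelse(is.na(r), out$label, r)
  } else out$label
  out
}

#' Genus relative abundances
#'
#' Computes the relative abundance of each genus in the catalog as
#' `R_g = N_g / N`, where `N_g` is the sum of mapped-read counts of the genes
#' assigned to the genus and `N` the total clean read number of the
#' metagenome.  Every genus present in the catalog appears, including the
#' `"unassigned"` bin; abundances are fractions of `N` and sum to at most 1
#' (unmapped or unannotated reads make up the remainder).
#'
#' @param catalog A [gene_catalog].
#' @return Named numeric vector of `R_g`, sorted decreasing.
#' @export
genus_abundances <- function(catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (catalog$total_reads <= 0) stop("total clean reads N must be positive",
                                     call. = FALSE)
  g <- catalog$genes
  n_g <- tapply(g$read_count, g$genus, sum)
  r <- as.numeric(n_g) / catalog$total_reads
  names(r) <- names(n_g)
  sort(r, decreasing = TRUE)
}

#' Report-style genus abundance table
#'
#' Formats genus abundances the way consortium composition figures are drawn:
#' genera below a threshold are combined into an `"others"` bucket at report
#' time (the underlying abundances are never merged).  The `"unassigned"` bin
#' also folds into `"others"`.
#'
#' @param abundances Named vector from [genus_abundances()].
#' @param combine_below Fraction under which genera are pooled (default 1%).
#' @return A `data.frame` with columns `genus` and `abundance`, major genera
#'   sorted decreasing with `others` last.
#' @export
genus_abundance_table <- function(abundances, combine_below = 0.01) {
  minor <- abundances < combine_below | names(abundances) == "unassigned"
  major <- abundances[!minor]
  out <- data.frame(genus = names(major), abundance = as.numeric(major),
                    stringsAsFactors = FALSE)
  if (any(minor)) {
    out <- rbind(out, data.frame(genus = "others",
                                 abundance = sum(abundances[minor])))
  }
  attr(out, "ordered") <- TRUE
  out
}

#' CAZyme class- and family-level profile
#'
#' Aggregates the catalog into the standard CAZyme repertoire summaries: per
#' CAZy class (GH/GT/PL/CE/AA/CBM) the number of distinct families, genes and
#' mapped reads; per family the gene and read counts; and per curated map
#' section the gene/read sums.  A gene counts once in every class and every
#' family it is annotated with, carrying its full read count into each
#' (multifunctional genes are composed of several catalytic modules and the
#' tallies are per-family), but is never counted twice within one class or
#' family.  Subfamily labels are pooled into their parent block when the map
#' curates the parent that way.
#'
#' Genes whose families map to no function category still count here (the
#' class-level repertoire covers all CAZymes, including GT and PL classes
#' with no direct degradation role); they are excluded only from the
#' function-level distribution and contribution matrices.
#'
#' @param catalog A [gene_catalog].
#' @param map A [function_map][load_default_map] used for subfamily pooling
#'   and section sums.
#' @return An object of class `cazyme_profile`: list with `class_summary`,
#'   `family_summary`, `section_sums`, `genus_abundance`, `n_cazyme_genes`,
#'   `cazyme_reads`, `total_reads`.
#' @export
cazyme_profile <- function(catalog, map = load_default_map()) {
  stopifnot(inherits(catalog, "gene_catalog"), inherits(map, "function_map"))
  g <- catalog$genes
  long <- gene_family_long(catalog, map)

  if (nrow(long) == 0) {
    empty <- data.frame(cazy_class = character(0), family_count = integer(0),
                        gene_count = integer(0), read_count = numeric(0))
    return(structure(list(
      class_summary = empty,
      family_summary = data.frame(family_label = character(0),
                                  gene_count = integer(0),
                                  read_count = numeric(0)),
      section_sums = data.frame(section = character(0),
                                gene_count = integer(0),
                                read_count = numeric(0)),
      genus_abundance = genus_abundances(catalog),
      n_cazyme_genes = 0L, cazyme_reads = 0,
      total_reads = catalog$total_reads), class = "cazyme_profile"))
  }

  reads <- g$read_count

  # one row per (gene, class)
  gc <- unique(long[, c("gene", "class")])
  class_gene <- tapply(gc$gene, gc$class, length)
  class_read <- tapply(reads[gc$gene], gc$class, sum)
  fam_per_class <- tapply(long$resolved, long$class,
                          function(x) length(unique(x)))
  classes <- sort(names(class_gene))
  class_summary <- data.frame(
    cazy_class = classes,
    family_count = as.integer(fam_per_class[classes]),
    gene_count = as.integer(class_gene[classes]),
    read_count = as.numeric(class_read[classes]))

  # one row per (gene, resolved family)
  gf <- unique(long[, c("gene", "resolved")])
  fam_gene <- tapply(gf$gene, gf$resolved, length)
  fam_read <- tapply(reads[gf$gene], gf$resolved, sum)
  fams <- sort(names(fam_gene))
  family_summary <- data.frame(
    family_label = fams,
    gene_count = as.integer(fam_gene[fams]),
    read_count = as.numeric(fam_read[fams]))

  # section sums over the map's curated sections
  sec_of <- unique(map$entries[, c("family_label", "section")])
  gs <- merge(gf, sec_of, by.x = "resolved", by.y = "family_label")
  gs <- unique(gs[, c("gene", "section")])
  section_sums <- if (nrow(gs) > 0) {
    sec_gene <- tapply(gs$gene, gs$section, length)
    sec_read <- tapply(reads[gs$gene], gs$section, sum)
    secs <- sort(names(sec_gene))
    data.frame(section = secs,
               gene_count = as.integer(sec_gene[secs]),
               read_count = as.numeric(sec_read[secs]))
  } else {
    data.frame(section = character(0), gene_count = integer(0),
               read_count = numeric(0))
  }

  caz_genes <- unique(long$gene)
  structure(list(
    class_summary = class_summary,
    family_summary = family_summary,
    section_sums = section_sums,
    genus_abundance = genus_abundances(catalog),
    n_cazyme_genes = length(caz_genes),
    cazyme_reads = sum(reads[caz_genes]),
    total_reads = catalog$total_reads), class = "cazyme_profile")
}

#' Fraction of metagenome reads on CAZyme genes
#'
#' The total mapped-read count of CAZyme-annotated genes as a percentage of
#' the total clean reads `N`, rounded half-up to two decimals (internal
#' arithmetic is at full precision).
#'
#' @param profile A [cazyme_profile] object, or a `data.frame` with a
#'   `read_count` column (e.g. a class-level summary table) whose rows are
#'   summed.
#' @param catalog Optional [gene_catalog] providing `N`; alternatively give
#'   `total_reads` directly.
#' @param total_reads Total clean reads `N` (used when no catalog is given).
#' @return A single number: the percentage (e.g. `5.81`).
#' @export
cazyme_read_fraction <- function(profile, catalog = NULL, total_reads = NULL) {
  caz_reads <- if (inherits(profile, "cazyme_profile")) {
    profile$cazyme_reads
  } else if (is.data.frame(profile) && "read_count" %in% names(profile)) {
    sum(as.numeric(profile$read_count))
  } else {
    stop("profile must be a cazyme_profile or a data.frame with read_count",
         call. = FALSE)
  }
  n <- if (!is.null(catalog)) {
    stopifnot(inherits(catalog, "gene_catalog"))
    catalog$total_reads
  } else if (!is.null(total_reads)) {
    total_reads
  } else if (inherits(profile, "cazyme_profile")) {
    profile$total_reads
  } else {
    stop("supply a catalog or total_reads", call. = FALSE)
  }
  if (is.na(n) || n <= 0) stop("total clean reads N must be positive",
                               call. = FALSE)
  round_half_up(100 * caz_reads / n, 2)
}

#' @export
print.cazyme_profile <- function(x, ...) {
  cat(sprintf("CAZyme profile: %d genes, %.0f reads (%.2f%% of N = %.0f)\n",
              x$n_cazyme_genes, x$cazyme_reads,
              100 * x$cazyme_reads / x$total_reads, x$total_reads))
  print(x$class_summary, row.names = FALSE)
  invisible(x)
}
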