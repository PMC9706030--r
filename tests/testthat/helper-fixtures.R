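# Shared fixtures and independent oracles, built in code at test time.

toy_genes <- function() {
  data.frame(
    gene_id = c("g1", "g2", "g3"),
    genus = c("A", "A", "unassigned"),
    lineage = c("domain:Bacteria;phylum:Firmicutes;genus:A",
                "domain:Bacteria;phylum:Firmicutes;genus:A",
                "domain:Bacteria;phylum:Firmicutes"),
    families = c("GH10", "", "GH5_4;CBM3"),
    read_count = c(100, 50, 25),
    stringsAsFactors = FALSE)
}

toy_catalog <- function(total_reads = 1000) {
  gene_catalog(toy_genes(), total_reads = total_reads)
}

# Write the three annotation TSVs for a gene table (the upstream layout
# read_catalog() consumes); returns the directory.
write_toy_tables <- function(genes, dir = tempfile("tables"),
                             drop_taxonomy_for = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(genes[, c("gene_id", "read_count")],
              file.path(dir, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tax <- genes[nzchar(genes$lineage) &
                 !genes$gene_id %in% drop_taxonomy_for,
               c("gene_id", "lineage")]
  write.table(tax, file.path(dir, "taxonomy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  caz <- genes[nzchar(genes$families), c("gene_id", "families")]
  write.table(caz, file.path(dir, "cazy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dir
}

# Small random catalog over real map families plus non-CAZyme genes.
random_catalog <- function(seed, n = 200, genera = c("A", "B", "C",
                                                     "unassigned")) {
  set.seed(seed)
  map <- load_default_map()
  fams <- unique(map$entries$family_label)
  genus <- sample(genera, n, replace = TRUE)
  families <- vapply(seq_len(n), function(i) {
    k <- sample(0:2, 1, prob = c(0.4, 0.45, 0.15))
    if (k == 0) "" else paste(sample(fams, k), collapse = ";")
  }, character(1))
  reads <- stats::rnbinom(n, mu = 50, size = 2)
  lineage <- ifelse(genus == "unassigned", "domain:Bacteria",
                    paste0("domain:Bacteria;genus:", genus))
  gene_catalog(
    data.frame(gene_id = sprintf("g%04d", seq_len(n)), genus = genus,
               lineage = lineage, families = families, read_count = reads,
               stringsAsFactors = FALSE),
    total_reads = sum(reads) + sample(0:1000, 1))
}

# Independent brute-force re-aggregation of N_g-f by plain per-record loops
# (uses categories_of per family; no shared code path with
# function_distribution's merge/tapply pipeline).
oracle_counts <- function(catalog, map, functions) {
  g <- catalog$genes
  genera <- sort(unique(g$genus))
  counts <- matrix(0, length(genera), length(functions),
                   dimnames = list(genera, functions))
  for (i in seq_len(nrow(g))) {
    fams <- strsplit(g$families[i], ";", fixed = TRUE)[[1]]
    fams <- fams[nzchar(fams)]
    if (length(fams) == 0) next
    cats <- unique(unlist(lapply(fams, function(f) categories_of(map, f))))
    for (fun in functions) {
      base <- if (fun %in% names(map$rollups)) map$rollups[[fun]] else fun
      if (any(base %in% cats)) {
        counts[g$genus[i], fun] <- counts[g$genus[i], fun] + g$read_count[i]
      }
    }
  }
  counts
}

# Brute-force total CAZyme reads: per-record loop.
oracle_cazyme_reads <- function(catalog) {
  g <- catalog$genes
  total <- 0
  for (i in seq_len(nrow(g))) {
    if (nzchar(g$families[i])) total <- total + g$read_count[i]
  }
  total
}
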