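#' Construct a gene catalog
#'
#' A gene catalog holds one record per predicted gene of a metagenome
#' assembly: an identifier, the genus the gene was assigned to (or
#' `"unassigned"`), the taxonomic lineage, the set of CAZy family labels the
#' gene carries (possibly none), and the number of clean reads mapped to the
#' gene.  The total clean read number `N` of the metagenome is stored
#' alongside the records because unmapped and unannotated reads are allowed:
#' `N` may exceed the sum of per-gene counts, and all relative abundances are
#' computed against `N`.
#'
#' @param genes A `data.frame` with columns `gene_id` (unique character),
#'   `genus` (character; `"unassigned"` when the lineage lacks a genus rank),
#'   `lineage` (character; `;`-separated `rank:name` pairs, possibly empty),
#'   `families` (character; `;`-separated CAZy family labels such as
#'   `"GH5_4;CBM3"`, empty for non-CAZyme genes) and `read_count`
#'   (non-negative integer).
#' @param total_reads Positive number: total clean reads `N` in the
#'   metagenome.  Must be at least the sum of per-gene read counts.
#'
#' @return An object of class `gene_catalog`: a list with elements `genes`
#'   (the validated data frame) and `total_reads`.
#' @seealso [read_catalog()] to build a catalog from annotation tables,
#'   [simulate_catalog()] to generate one synthetically.
#' @export
gene_catalog <- function(genes, total_reads) {
  stopifnot(is.data.frame(genes))
  required <- c("gene_id", "genus", "lineage", "families", "read_count")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop("gene table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  genes <- genes[, required]
  genes$gene_id <- as.character(genes$gene_id)
  genes$genus <- as.character(genes$genus)
  genes$lineage <- as.character(genes$lineage)
  genes$families <- as.character(genes$families)
  genes$lineage[is.na(genes$lineage)] <- ""
  genes$families[is.na(genes$families)] <- ""

  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(genes$read_count) || any(genes$read_count < 0)) {
    bad <- genes$gene_id[is.na(genes$read_count) | genes$read_count < 0]
    stop("negative or missing read_count for gene(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  genes$read_count <- as.numeric(genes$read_count)

  fams <- unlist(lapply(genes$families, split_families), use.names = FALSE)
  if (length(fams) > 0) assert_family_labels(fams, where = "cazy annotations")

  if (!is.numeric(total_reads) || length(total_reads) != 1 ||
      is.na(total_reads) || total_reads <= 0) {
    stop("total_reads must be a single positive number", call. = FALSE)
  }
  mapped <- sum(genes$read_count)
  if (mapped > total_reads) {
    stop(sprintf(
      "sum of per-gene read counts (%.0f) exceeds total_reads (%.0f)",
      mapped, total_reads), call. = FALSE)
  }

  rownames(genes) <- NULL
  structure(list(genes = genes, total_reads = as.numeric(total_reads)),
            class = "gene_catalog")
}

#' Read a gene catalog from annotation tables
#'
#' Joins the three gene-level tables produced upstream of this package (gene
#' catalog construction, read mapping, taxonomic annotation and dbCAN CAZyme
#' annotation) into a validated [gene_catalog]: a gene table with per-gene
#' mapped-read counts, a taxonomy table with per-gene lineages, and a
#' dbCAN-overview-style CAZy table with `;`-separated family hits.  Genes
#' absent from the taxonomy table are binned as genus `"unassigned"`; genes
#' absent from the CAZy table carry no families (non-CAZyme genes).
#'
#' All files are tab-separated with a header row.  Expected columns:
#' `genes.tsv` `gene_id`, `read_count`; `taxonomy.tsv` `gene_id`, `lineage`
#' (`;`-separated `rank:name` pairs down to genus); `cazy.tsv` `gene_id`,
#' `families` (`;`-separated family labels).  Any extra columns (domain
#' coordinates, e-values) are ignored: e-value thresholding is assumed to
#' have happened upstream.
#'
#' @param genes_path,taxonomy_path,cazy_path Paths to the three TSV files.
#' @param total_reads Total clean read number `N` of the metagenome (supplied
#'   independently because unmapped reads are not in the gene table).
#' @param verbose Log progress to stderr.
#'
#' @return A [gene_catalog].
#' @export
read_catalog <- function(genes_path, taxonomy_path, cazy_path, total_reads,
                         verbose = FALSE) {
  for (p in c(genes_path, taxonomy_path, cazy_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  genes <- read.delim(genes_path, colClasses = "character",
                      check.names = FALSE)
  taxonomy <- read.delim(taxonomy_path, colClasses = "character",
                         check.names = FALSE)
  cazy <- read.delim(cazy_path, colClasses = "character", check.names = FALSE)
  for (tab in list(c("genes", "gene_id", "read_count"),
                   c("taxonomy", "gene_id", "lineage"),
                   c("cazy", "gene_id", "families"))) {
    df <- get(tab[1])
    if (!all(tab[-1] %in% names(df))) {
      stop(sprintf("%s table must have columns %s", tab[1],
                   paste(tab[-1], collapse = ", ")), call. = FALSE)
    }
  }
  msg_verbose(verbose, sprintf("read %d genes, %d taxonomy rows, %d cazy rows",
                               nrow(genes), nrow(taxonomy), nrow(cazy)))

  extra_tax <- setdiff(taxonomy$gene_id, genes$gene_id)
  extra_caz <- setdiff(cazy$gene_id, genes$gene_id)
  if (length(extra_tax) > 0 || length(extra_caz) > 0) {
    stop("taxonomy/cazy tables mention gene_id(s) absent from the gene table: ",
         paste(utils::head(unique(c(extra_tax, extra_caz)), 10),
               collapse = ", "), call. = FALSE)
  }

  rc <- suppressWarnings(as.numeric(genes$read_count))
  if (anyNA(rc)) {
    stop("non-numeric read_count for gene(s): ",
         paste(genes$gene_id[is.na(rc)], collapse = ", "), call. = FALSE)
  }

  lineage <- taxonomy$lineage[match(genes$gene_id, taxonomy$gene_id)]
  lineage[is.na(lineage)] <- ""
  families <- cazy$families[match(genes$gene_id, cazy$gene_id)]
  families[is.na(families)] <- ""

  gene_catalog(
    data.frame(gene_id = genes$gene_id,
               genus = genus_from_lineage(lineage),
               lineage = lineage,
               families = families,
               read_count = rc,
               stringsAsFactors = FALSE),
    total_reads = total_reads
  )
}

#' Write a gene catalog back to its three annotation tables
#'
#' Emits `genes.tsv`, `taxonomy.tsv` and `cazy.tsv` under `dir` in the layout
#' accepted by [read_catalog()].  Taxonomy rows are written only for genes
#' with a non-empty lineage and CAZy rows only for genes carrying families,
#' so a written-and-reread catalog is identical to the original (given the
#' same `total_reads`).
#'
#' @param catalog A [gene_catalog].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_catalog <- function(catalog, dir) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- catalog$genes
  paths <- file.path(dir, c("genes.tsv", "taxonomy.tsv", "cazy.tsv"))
  write_table(data.frame(gene_id = g$gene_id, read_count = g$read_count),
              paths[1])
  tax <- g[nzchar(g$lineage), c("gene_id", "lineage")]
  if (nrow(tax) > 0) write_table(tax, paths[2]) else
    writeLines("gene_id\tlineage", paths[2])
  caz <- g[nzchar(g$families), c("gene_id", "families")]
  if (nrow(caz) > 0) write_table(caz, paths[3]) else
    writeLines("gene_id\tfamilies", paths[3])
  invisible(paths)
}

#' Write a result table as TSV
#'
#' All result tables of the package are written tab-separated with a header
#' row, UTF-8 encoded, and in a deterministic row order: lexicographic
#' (C-locale radix order) by the first column, unless the table carries an
#' explicit order (attribute `ordered = TRUE`), in which case rows are
#' written as-is.
#'
#' @param table A non-empty `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(table, path) {
  if (!is.data.frame(table)) stop("table must be a data.frame", call. = FALSE)
  if (nrow(table) == 0) stop("refusing to write an empty table", call. = FALSE)
  if (!isTRUE(attr(table, "ordered"))) {
    table <- table[lex_order(as.character(table[[1]])), , drop = FALSE]
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.gene_catalog <- function(x, ...) {
  g <- x$genes
  n_caz <- sum(nzchar(g$families))
  cat(sprintf("gene catalog: %d genes (%d CAZyme-annotated), %d genera\n",
              nrow(g), n_caz, length(unique(g$genus))))
  cat(sprintf("  mapped reads: %.0f of N = %.0f total clean reads (%.2f%%)\n",
              sum(g$read_count), x$total_reads,
              100 * sum(g$read_count) / x$total_reads))
  invisible(x)
}
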