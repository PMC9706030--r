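# Genus x function read-share distributions and contribution coefficients.

#' Genus-by-function read-share distribution
#'
#' For each target function `f`, the genes carrying at least one CAZy family
#' curated under `f` are selected; their mapped-read counts sum to the
#' function's total read number `N_f` (each qualifying gene counts once per
#' function, even when several of its families map to `f`).  The genus share
#' `R_g-f = N_g-f / N_f` is the fraction of those reads carried by genes of
#' genus `g`.  For every function with `N_f > 0` the shares over all genera
#' (including `"unassigned"`) sum to 1; functions with no reads are kept and
#' flagged, their shares set to `NA`.
#'
#' The published shares are read-based; `mode = "genes"` instead computes
#' gene-count shares (each qualifying gene contributing 1), since per-gene
#' "distribution of degradation genes" can be read either way.
#'
#' @param catalog A [gene_catalog].
#' @param map A [function_map][load_default_map].
#' @param functions Character vector of function names (roll-ups such as
#'   `cellulose` allowed).  Defaults to all catalytic categories plus the
#'   lignin and esterase columns.
#' @param mode `"reads"` (default) or `"genes"`.
#' @return An object of class `distribution_matrix`: list with `values`
#'   (genus x function matrix of `R_g-f`), `counts` (genus x function
#'   `N_g-f`), `function_reads` (`N_f` per function), `flagged` (functions
#'   with `N_f = 0`) and `mode`.
#' @export
function_distribution <- function(catalog, map = load_default_map(),
                                  functions = setdiff(CAZY_FUNCTIONS,
                                                      "binding_module"),
                                  mode = c("reads", "genes")) {
  stopifnot(inherits(catalog, "gene_catalog"), inherits(map, "function_map"))
  mode <- match.arg(mode)
  functions <- expand_functions(map, functions)

  g <- catalog$genes
  genera <- sort(unique(g$genus))
  long <- gene_family_long(catalog, map)
  pairs <- map_pairs(map)

  # gene x base-category pairs (unique: one count per gene per category)
  gcat <- merge(long[, c("gene", "resolved")], pairs,
                by.x = "resolved", by.y = "family_label")
  gcat <- unique(gcat[, c("gene", "category")])

  weight <- if (mode == "reads") g$read_count else rep(1, nrow(g))

  counts <- matrix(0, nrow = length(genera), ncol = length(functions),
                   dimnames = list(genera, functions))
  for (fun in functions) {
    base <- base_categories(map, fun)
    genes_f <- unique(gcat$gene[gcat$category %in% base])
    if (length(genes_f) == 0) next
    s <- tapply(weight[genes_f], g$genus[genes_f], sum)
    counts[names(s), fun] <- as.numeric(s)
  }

  n_f <- colSums(counts)
  values <- sweep(counts, 2, n_f, "/")
  values[, n_f == 0] <- NA_real_

  structure(list(values = values,
                 counts = counts,
                 function_reads = n_f,
                 flagged = names(n_f)[n_f == 0],
                 mode = mode),
            class = "distribution_matrix")
}

#' Contribution coefficients
#'
#' The contribution coefficient of genus `g` for function `f` is
#' `CC = R_g-f / R_g`: the genus's share of the function's reads divided by
#' its overall relative abundance.  `CC > 1` means the genus contributes more
#' function-`f` enzyme genes than its resource occupancy; `CC < 1` fewer — the
#' signature of a "sugar cheater" when persistent across hydrolase functions.
#' Cells are defined only where `R_g > 0` and `N_f > 0`; undefined cells are
#' `NA` (never 0).
#'
#' @param dist A [distribution_matrix][function_distribution].
#' @param abundances Named vector of `R_g` from [genus_abundances()]; every
#'   genus row of `dist` must be present.
#' @return An object of class `cc_matrix`: list with `values` (genus x
#'   function CC matrix), `abundances`, `function_reads`.
#' @export
contribution_coefficients <- function(dist, abundances) {
  stopifnot(inherits(dist, "distribution_matrix"))
  genera <- rownames(dist$values)
  missing <- setdiff(genera, names(abundances))
  if (length(missing) > 0) {
    stop("no abundance supplied for genus/genera: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  r_g <- abundances[genera]
  cc <- sweep(dist$values, 1, r_g, "/")
  cc[r_g == 0, ] <- NA_real_
  structure(list(values = cc,
                 abundances = r_g,
                 function_reads = dist$function_reads),
            class = "cc_matrix")
}

#' Call contributors and sugar cheaters
#'
#' Operationalizes the qualitative rule that a genus contributing more
#' lignocellulolytic enzymes than its resource occupancy across most
#' hydrolase functions is a contributor, and one persistently below parity a
#' cheater: a genus is called `contributor` when at least a
#' `cheater_quantile` fraction of its defined hydrolase-function CCs exceed
#' `contributor_cutoff`, `cheater` when at least that fraction fall below
#' `cheater_cutoff`, otherwise `intermediate`.  Genera with no defined cell
#' among the listed functions are `undetermined`.  Lignin (AA) and esterase
#' columns are excluded by default: cheaters typically retain those
#' activities, and the call is about the catalytic hydrolases.
#'
#' @param cc A [cc_matrix][contribution_coefficients].
#' @param hydrolase_functions Functions used for the call; defaults to the
#'   twelve catalytic hydrolase categories present in `cc`.
#' @param cheater_quantile Fraction of defined CCs that must fall on one side
#'   of the cutoff (default 0.75).
#' @param cheater_cutoff,contributor_cutoff CC thresholds (default 1.0).
#' @return Named character vector of roles per genus.
#' @export
classify_roles <- function(cc,
                           hydrolase_functions = NULL,
                           cheater_quantile = 0.75,
                           cheater_cutoff = 1.0,
                           contributor_cutoff = 1.0) {
  stopifnot(inherits(cc, "cc_matrix"))
  hydrolase_functions <- hydrolase_functions %||%
    intersect(colnames(cc$values), HYDROLASE_FUNCTIONS)
  if (length(hydrolase_functions) == 0) {
    stop("hydrolase_functions must be non-empty", call. = FALSE)
  }
  missing <- setdiff(hydrolase_functions, colnames(cc$values))
  if (length(missing) > 0) {
    stop("function(s) absent from the CC matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- cc$values[, hydrolase_functions, drop = FALSE]
  apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return("undetermined")
    if (mean(x > contributor_cutoff) >= cheater_quantile) return("contributor")
    if (mean(x < cheater_cutoff) >= cheater_quantile) return("cheater")
    "intermediate"
  })
}

#' Export a distribution matrix in Circos tableviewer format
#'
#' Writes the integer read counts `N_g-f` as a tab-delimited table in the
#' Circos tableviewer dialect: first row the function labels, first column
#' the genus labels, cells the read counts.  Re-importing the file with
#' [read_circos_table()] reproduces the counts exactly.
#'
#' @param dist A [distribution_matrix][function_distribution].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_circos_table <- function(dist, path) {
  stopifnot(inherits(dist, "distribution_matrix"))
  counts <- dist$counts
  if (length(counts) == 0) stop("empty distribution matrix", call. = FALSE)
  if (max(counts) < .Machine$integer.max) storage.mode(counts) <- "integer"
  df <- data.frame(genus = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a Circos tableviewer matrix
#'
#' @param path Path written by [export_circos_table()].
#' @return Integer matrix of `N_g-f` with genus rownames and function
#'   colnames.
#' @export
read_circos_table <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Distribution and CC matrices as writable tables
#'
#' @param x A `distribution_matrix` or `cc_matrix`.
#' @return A `data.frame` with a leading `genus` column, undefined cells
#'   left as `NA` (rendered blank by [write_table()]).
#' @export
as_table <- function(x) {
  values <- x$values
  df <- data.frame(genus = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' @export
print.distribution_matrix <- function(x, ...) {
  cat(sprintf("genus x function %s-share distribution: %d genera, %d functions\n",
              x$mode, nrow(x$values), ncol(x$values)))
  if (length(x$flagged) > 0) {
    cat("  functions with no reads:", paste(x$flagged, collapse = ", "), "\n")
  }
  print(round(x$values, 4))
  invisible(x)
}

#' @export
print.cc_matrix <- function(x, ...) {
  cat(sprintf("contribution coefficients: %d genera, %d functions\n",
              nrow(x$values), ncol(x$values)))
  print(round(x$values, 3))
  invisible(x)
}
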