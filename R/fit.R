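#' Fit the genus contribution model to a gene catalog
#'
#' The one-stop estimator of the package: from a [gene_catalog] it computes
#' genus relative abundances `R_g = N_g / N`, the genus-by-function
#' read-share distribution `R_g-f = N_g-f / N_f`, the contribution
#' coefficient matrix `CC = R_g-f / R_g`, and contributor/cheater role calls.
#' `CC` measures how a genus's enzyme-gene investment in a function compares
#' with its overall resource occupancy: `CC = 1` is proportional
#' representation, `CC > 1` over-investment (a contributor when persistent
#' across the hydrolase functions) and `CC < 1` under-investment (a "sugar
#' cheater" when persistent).
#'
#' @param catalog A [gene_catalog].
#' @param map A [function_map][load_default_map].
#' @param functions Function columns to estimate (roll-ups allowed); default
#'   all catalytic categories plus lignin and esterase.
#' @param mode `"reads"` (published convention) or `"genes"`; see
#'   [function_distribution()].
#' @param abundance_denominator `"total"` uses the metagenome's total clean
#'   reads `N` as the `R_g` denominator (the published definition);
#'   `"annotated"` uses the catalog's mapped-read sum instead.  CC is a ratio
#'   of shares, so the choice matters only through consistency; it is
#'   enforced on both numerator inputs.
#' @param ... Passed to [classify_roles()] (`cheater_quantile`,
#'   `cheater_cutoff`, `contributor_cutoff`, `hydrolase_functions`).
#'
#' @return An object of class `cazy_cc` with components `abundances`,
#'   `distribution`, `cc`, `roles`, `profile`, `functions`, `map`, `call`.
#'   Methods: [print][print.cazy_cc], [summary][summary.cazy_cc],
#'   [coef][coef.cazy_cc] (the CC matrix), [residuals][residuals.cazy_cc]
#'   (log2 CC), [plot][plot.cazy_cc] (heatmap) and
#'   [simulate][simulate.cazy_cc] (parametric catalogs from the fit).
#' @examples
#' sim <- simulate_catalog(tmc7_preset(seed = 42, n_genes = 2000,
#'                                     total_reads = 5e4))
#' fit <- cazy_cc(sim$catalog)
#' fit
#' round(coef(fit)["Ruminiclostridium", ], 2)
#' @export
cazy_cc <- function(catalog,
                    map = load_default_map(),
                    functions = setdiff(CAZY_FUNCTIONS, "binding_module"),
                    mode = c("reads", "genes"),
                    abundance_denominator = c("total", "annotated"),
                    ...) {
  stopifnot(inherits(catalog, "gene_catalog"))
  mode <- match.arg(mode)
  abundance_denominator <- match.arg(abundance_denominator)

  if (abundance_denominator == "annotated") {
    catalog <- gene_catalog(catalog$genes,
                            total_reads = sum(catalog$genes$read_count))
  }
  abund <- genus_abundances(catalog)
  dist <- function_distribution(catalog, map, functions, mode = mode)
  cc <- contribution_coefficients(dist, abund)
  roles <- classify_roles(cc, ...)

  structure(list(abundances = abund,
                 distribution = dist,
                 cc = cc,
                 roles = roles,
                 profile = cazyme_profile(catalog, map),
                 functions = colnames(dist$values),
                 map = map,
                 n_genes = nrow(catalog$genes),
                 total_reads = catalog$total_reads,
                 abundance_denominator = abundance_denominator,
                 call = match.call()),
            class = "cazy_cc")
}

#' @export
print.cazy_cc <- function(x, ...) {
  cat("Genus contribution model (CC = R_g-f / R_g)\n")
  cat(sprintf("  catalog: %d genes, N = %.0f clean reads (%s denominator)\n",
              x$n_genes, x$total_reads, x$abundance_denominator))
  cat(sprintf("  %d genera x %d functions; CAZyme reads: %.2f%% of N\n",
              nrow(x$cc$values), length(x$functions),
              100 * x$profile$cazyme_reads / x$profile$total_reads))
  tab <- table(factor(x$roles, levels = c("contributor", "intermediate",
                                          "cheater", "undetermined")))
  cat(sprintf("  roles: %d contributor, %d intermediate, %d cheater, %d undetermined\n",
              tab[["contributor"]], tab[["intermediate"]], tab[["cheater"]],
              tab[["undetermined"]]))
  invisible(x)
}

#' Summarize a fitted contribution model
#'
#' @param object A [cazy_cc] fit.
#' @param ... Unused.
#' @return A `data.frame` (one row per genus, abundance-sorted): abundance,
#'   number of defined CC cells, median and range of CC over the fitted
#'   functions, and the role call.
#' @export
summary.cazy_cc <- function(object, ...) {
  cc <- object$cc$values
  genera <- names(sort(object$abundances, decreasing = TRUE))
  rows <- lapply(genera, function(g) {
    x <- cc[g, ]
    x <- x[!is.na(x)]
    data.frame(genus = g,
               abundance = unname(object$abundances[g]),
               n_functions = length(x),
               median_cc = if (length(x)) median(x) else NA_real_,
               min_cc = if (length(x)) min(x) else NA_real_,
               max_cc = if (length(x)) max(x) else NA_real_,
               role = unname(object$roles[g]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "ordered") <- TRUE
  class(out) <- c("summary.cazy_cc", class(out))
  out
}

#' @export
print.summary.cazy_cc <- function(x, digits = 3, ...) {
  y <- x
  class(y) <- "data.frame"
  y$abundance <- round(y$abundance, 4)
  for (col in c("median_cc", "min_cc", "max_cc")) y[[col]] <- round(y[[col]], digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cazy_cc <- function(object, ...) object$cc$values

#' Deviations from proportional representation
#'
#' @param object A [cazy_cc] fit.
#' @param ... Unused.
#' @return Genus x function matrix of `log2(CC)`: 0 is proportional
#'   representation, positive over-investment, negative under-investment.
#' @export
residuals.cazy_cc <- function(object, ...) log2(object$cc$values)

#' Heatmap of contribution coefficients
#'
#' Draws the genus-by-function CC matrix as a heatmap (undefined cells stay
#' blank).  Uses \pkg{pheatmap} when installed, otherwise a base-graphics
#' image.
#'
#' @param x A [cazy_cc] fit.
#' @param ... Passed to the underlying heatmap function.
#' @export
plot.cazy_cc <- function(x, ...) {
  m <- x$cc$values
  genera <- names(sort(x$abundances, decreasing = TRUE))
  m <- m[genera, , drop = FALSE]
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       na_col = "white", ...)
  } else {
    graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                    axes = FALSE, ...)
    graphics::axis(1, at = seq(0, 1, length.out = ncol(m)),
                   labels = colnames(m), las = 2, cex.axis = 0.7)
    graphics::axis(2, at = seq(0, 1, length.out = nrow(m)),
                   labels = rev(rownames(m)), las = 2, cex.axis = 0.7)
  }
  invisible(x)
}

#' Simulate catalogs from a fitted contribution model
#'
#' Parametric resampling: generates synthetic gene catalogs whose genus
#' profile equals the fitted abundances and whose allocation multipliers are
#' the fitted CC values (undefined cells fall back to 1), using the
#' synthetic annotation generator.
#'
#' @param object A [cazy_cc] fit.
#' @param nsim Number of catalogs.
#' @param seed Integer seed for the first catalog; catalog `i` uses
#'   `seed + i - 1`.
#' @param n_genes,total_reads,dispersion,noncazyme_fraction Generator knobs,
#'   see [sim_config()]; defaults mirror the fitted catalog's size and depth.
#' @param ... Unused.
#' @return A list of `sim_result` objects of length `nsim`.
#' @export
simulate.cazy_cc <- function(object, nsim = 1, seed = 1L,
                             n_genes = object$n_genes,
                             total_reads = object$total_reads,
                             dispersion = 0.3,
                             noncazyme_fraction = 0.5, ...) {
  abund <- object$abundances
  abund <- abund[names(abund) != "unassigned"]
  base_funs <- intersect(object$functions, CAZY_FUNCTIONS)
  alloc <- object$cc$values[names(abund), base_funs, drop = FALSE]
  alloc[is.na(alloc)] <- 1
  lapply(seq_len(nsim), function(i) {
    cfg <- sim_config(seed = as.integer(seed) + i - 1L,
                      n_genes = n_genes, total_reads = total_reads,
                      genus_profile = abund, allocation = alloc,
                      dispersion = dispersion,
                      noncazyme_fraction = noncazyme_fraction)
    simulate_catalog(cfg, object$map)
  })
}
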