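#' Load the curated CAZy family-to-function map
#'
#' The package ships a frozen, curated many-to-many mapping between CAZy
#' families (and subfamily blocks) and lignocellulolytic function categories
#' for a thermophilic lignocellulose-degrading consortium: the three
#' cooperating cellulase activities, the hemicellulose main-chain and
#' debranching hydrolases, carbohydrate esterases, lignin-modifying auxiliary
#' activities, and carbohydrate-binding modules.  A family may carry several
#' categories (many CAZymes are multifunctional), and subfamily labels such
#' as `GH5_4` roll up to their parent entry when the parent is mapped as a
#' subfamily block.
#'
#' The controlled vocabulary is `r paste(CAZY_FUNCTIONS, collapse = ", ")`,
#' plus the substrate roll-ups `cellulose`, `hemicellulose` and `lignin`.
#'
#' @param path Optional path to an alternative map TSV with columns
#'   `family_label`, `cazy_class`, `category` (may be empty for families with
#'   no lignocellulolytic role), `section`, `subfamilies` (0/1),
#'   `subfamily_members`, `source_note`.  Defaults to the packaged fixture.
#'
#' @return An object of class `function_map`: list with `entries` (the pair
#'   table), `categories` (vocabulary), `rollups` (named list of category
#'   groups).
#' @export
load_default_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "function_map.tsv",
                                package = "cazycontrib", mustWork = TRUE)
  entries <- read.delim(path, colClasses = "character", check.names = FALSE)
  required <- c("family_label", "cazy_class", "category", "section")
  if (!all(required %in% names(entries))) {
    stop("function map must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (is.null(entries$subfamilies)) entries$subfamilies <- "0"
  if (is.null(entries$subfamily_members)) entries$subfamily_members <- ""
  entries$subfamilies <- entries$subfamilies == "1"
  entries$category[is.na(entries$category)] <- ""

  assert_family_labels(entries$family_label, where = "function map")
  bad_class <- setdiff(unique(entries$cazy_class), CAZY_CLASSES)
  if (length(bad_class) > 0) {
    stop("unknown CAZy class in function map: ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  }
  bad_cat <- setdiff(unique(entries$category),
                     c(CAZY_FUNCTIONS, ""))
  if (length(bad_cat) > 0) {
    stop("category outside the controlled vocabulary: ",
         paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  mism <- entries$cazy_class != class_of_label(entries$family_label)
  if (any(mism)) {
    stop("cazy_class does not match family label prefix for: ",
         paste(unique(entries$family_label[mism]), collapse = ", "),
         call. = FALSE)
  }

  structure(list(entries = entries,
                 categories = CAZY_FUNCTIONS,
                 rollups = CAZY_ROLLUPS),
            class = "function_map")
}

#' Families mapped to a function category
#'
#' Returns the set of CAZy family labels curated under a function category.
#' Subfamily blocks (e.g. the GH5 subfamilies) count as one family.  Roll-up
#' names (`cellulose`, `hemicellulose`, `lignin`) return the union over their
#' member categories.
#'
#' @param map A [function_map][load_default_map].
#' @param category A function name from the controlled vocabulary, or a
#'   roll-up name.
#' @return Character vector of family labels (sorted).
#' @export
families_for <- function(map, category) {
  stopifnot(inherits(map, "function_map"))
  if (length(category) != 1 || !is.character(category)) {
    stop("category must be a single string", call. = FALSE)
  }
  if (category %in% names(map$rollups)) {
    members <- map$rollups[[category]]
    return(sort(unique(unlist(lapply(members, families_for, map = map)))))
  }
  if (!category %in% map$categories) {
    stop("unknown function category: ", category, call. = FALSE)
  }
  sort(unique(map$entries$family_label[map$entries$category == category]))
}

#' Function categories of a CAZy family
#'
#' Looks up the categories curated for a family label.  A subfamily label
#' (e.g. `GH5_4`) that has no exact entry resolves through its parent when
#' the parent is mapped as a subfamily block; exact entries (e.g. `GH30_8`)
#' take precedence.  Families absent from the map return an empty set.
#'
#' @param map A [function_map][load_default_map].
#' @param family A CAZy family label such as `"GH10"` or `"GH5_4"`.
#' @return Character vector of category names (possibly empty).
#' @export
categories_of <- function(map, family) {
  stopifnot(inherits(map, "function_map"))
  if (length(family) != 1 || !is.character(family)) {
    stop("family must be a single string", call. = FALSE)
  }
  assert_family_labels(family, where = "categories_of()")
  resolved <- resolve_families(family, map)
  if (is.na(resolved)) return(character(0))
  cats <- map$entries$category[map$entries$family_label == resolved]
  sort(unique(cats[nzchar(cats)]))
}

# Resolve raw family labels to map entry labels: exact match first, then
# parent rollup for subfamily labels when the parent is a subfamily block.
# Unmapped labels resolve to NA.  Vectorized.
resolve_families <- function(labels, map) {
  known <- unique(map$entries$family_label)
  subfam_parents <- unique(map$entries$family_label[map$entries$subfamilies])
  parent <- sub("_[0-9]+$", "", labels)
  out <- ifelse(labels %in% known, labels,
                ifelse(grepl("_", labels) & parent %in% subfam_parents,
                       parent, NA_character_))
  out
}

# The map's (family, category) pairs as a data frame, categories only.
map_pairs <- function(map) {
  e <- map$entries[nzchar(map$entries$category),
                   c("family_label", "category")]
  unique(e)
}

# Expand roll-up names in a function list to base categories; keeps order,
# errors on unknown names.
expand_functions <- function(map, functions) {
  unknown <- setdiff(functions, c(map$categories, names(map$rollups)))
  if (length(unknown) > 0) {
    stop("unknown function name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  functions
}

# Base categories covered by one (possibly roll-up) function name.
base_categories <- function(map, fun) {
  if (fun %in% names(map$rollups)) map$rollups[[fun]] else fun
}

#' @export
print.function_map <- function(x, ...) {
  pairs <- map_pairs(x)
  cat(sprintf(
    "CAZy function map: %d families, %d (family, category) pairs, %d categories\n",
    length(unique(x$entries$family_label)), nrow(pairs),
    length(unique(pairs$category))))
  counts <- table(pairs$category)
  for (cat_name in intersect(CAZY_FUNCTIONS, names(counts))) {
    cat(sprintf("  %-20s %2d families\n", cat_name, counts[[cat_name]]))
  }
  invisible(x)
}
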