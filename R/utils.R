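# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Round half away from zero (the convention used for reported percentages);
# base round() rounds half to even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Split a ';'-separated family string into a character vector (empty -> none).
split_families <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  out <- strsplit(x, ";", fixed = TRUE)[[1]]
  trimws(out[nzchar(trimws(out))])
}

assert_family_labels <- function(labels, where = "input") {
  bad <- unique(labels[!grepl(FAMILY_LABEL_PATTERN, labels)])
  if (length(bad) > 0) {
    stop(sprintf("invalid CAZy family label(s) in %s: %s", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(labels)
}

# CAZy class of a (valid) family label: its alphabetic prefix.
class_of_label <- function(labels) {
  sub("^([A-Z]+).*$", "\\1", labels)
}

# Extract the genus from a ';'-separated "rank:name" lineage string; genes
# whose lineage lacks a genus rank are binned as "unassigned".
genus_from_lineage <- function(lineage) {
  vapply(lineage, function(x) {
    if (is.na(x) || !nzchar(x)) return("unassigned")
    parts <- strsplit(x, ";", fixed = TRUE)[[1]]
    g <- grep("^\\s*genus:", parts, value = TRUE)
    if (length(g) == 0) return("unassigned")
    name <- trimws(sub("^\\s*genus:", "", g[[1]]))
    if (nzchar(name)) name else "unassigned"
  }, character(1), USE.NAMES = FALSE)
}

# Deterministic lexicographic order independent of the session locale.
lex_order <- function(x) order(x, method = "radix")

msg_verbose <- function(verbose, ...) {
  if (isTRUE(verbose)) message(...)
}
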