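#' Read a differential-expression contrast table
#'
#' Reads one comparison's per-feature effect sizes and FDRs from a delimited
#' text file (tab-separated by default, comma accepted) into a validated
#' contrast table. A contrast table is the consumed product of an upstream
#' differential-expression fit (e.g. a negative-binomial Wald test) or of a
#' gene-set enrichment run: one row per feature with a signed effect (log2
#' fold change, or a normalized enrichment score in pathway mode) and a
#' BH-adjusted p-value.
#'
#' Rows whose effect or FDR is missing or non-finite are dropped with a
#' warning listing the offending row numbers. Duplicated feature ids and FDRs
#' outside \[0, 1\] are errors.
#'
#' @param path Path to a delimited text file with a header.
#' @param cell_type Optional cell-type label attached to the table.
#' @param contrast_label Optional label for the comparison
#'   (e.g. `"O-A_vs_Control"`).
#' @param col_map Named character vector remapping the required columns.
#'   Names must be `feature`, `effect`, `fdr`; values are the column names in
#'   the file. The default accepts `feature` / `log2fc` (or `nes`) / `fdr`.
#' @param delim Field delimiter. `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#'
#' @return A tibble of class `contrast_table` with columns `feature`,
#'   `effect`, `fdr` and attributes `cell_type` and `contrast_label`.
#' @seealso [align_contrasts()], [write_contrast_table()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("feature\tlog2fc\tfdr", "BMP6\t1.2\t0.01", "FN1\t-0.4\t0.3"), tf)
#' read_contrast_table(tf, cell_type = "VEC")
read_contrast_table <- function(path, cell_type = NA_character_,
                                contrast_label = NA_character_,
                                col_map = NULL, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("contrast file not found: ", path), class = "cscore_config_error")
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE)
  if (is.null(col_map)) {
    effect_col <- intersect(c("log2fc", "nes", "effect"), names(raw))[1]
    if (is.na(effect_col)) effect_col <- "log2fc"
    col_map <- c(feature = "feature", effect = effect_col, fdr = "fdr")
  }
  required <- c("feature", "effect", "fdr")
  if (!all(required %in% names(col_map))) {
    abort("col_map must map 'feature', 'effect' and 'fdr'",
          class = "cscore_config_error")
  }
  missing_cols <- setdiff(unname(col_map[required]), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", ")),
          class = "cscore_config_error")
  }
  tbl <- tibble(
    feature = as.character(raw[[col_map[["feature"]]]]),
    effect  = as.numeric(raw[[col_map[["effect"]]]]),
    fdr     = as.numeric(raw[[col_map[["fdr"]]]])
  )
  bad <- which(!is.finite(tbl$effect) | !is.finite(tbl$fdr) |
                 is.na(tbl$feature) | tbl$feature == "")
  if (length(bad) > 0) {
    warn(paste0("dropping ", length(bad),
                " row(s) with missing/non-finite values (rows: ",
                paste(bad, collapse = ", "), ")"))
    tbl <- tbl[-bad, , drop = FALSE]
  }
  new_contrast_table(tbl, cell_type = cell_type, contrast_label = contrast_label)
}

#' Construct a contrast table from in-memory data
#'
#' @param x A data frame with columns `feature`, `effect`, `fdr`.
#' @inheritParams read_contrast_table
#' @return A `contrast_table` tibble.
#' @export
contrast_table <- function(x, cell_type = NA_character_,
                           contrast_label = NA_character_) {
  stopifnot(is.data.frame(x))
  required <- c("feature", "effect", "fdr")
  if (!all(required %in% names(x))) {
    abort("x must have columns feature, effect, fdr",
          class = "cscore_config_error")
  }
  tbl <- tibble(feature = as.character(x$feature),
                effect = as.numeric(x$effect),
                fdr = as.numeric(x$fdr))
  new_contrast_table(tbl, cell_type = cell_type, contrast_label = contrast_label)
}

new_contrast_table <- function(tbl, cell_type, contrast_label) {
  if (nrow(tbl) == 0) {
    abort("contrast table has no valid rows", class = "cscore_validation_error")
  }
  dup <- unique(tbl$feature[duplicated(tbl$feature)])
  if (length(dup) > 0) {
    abort(paste0("duplicated feature id(s): ",
                 paste(head(dup, 5), collapse = ", ")),
          class = "cscore_validation_error")
  }
  out_of_range <- tbl$fdr < 0 | tbl$fdr > 1
  if (any(out_of_range)) {
    abort(paste0("fdr outside [0, 1] for feature(s): ",
                 paste(head(tbl$feature[out_of_range], 5), collapse = ", ")),
          class = "cscore_validation_error")
  }
  if (!all(is.finite(tbl$effect))) {
    abort("non-finite effect values", class = "cscore_validation_error")
  }
  structure(tbl,
            class = c("contrast_table", class(tibble())),
            cell_type = cell_type, contrast_label = contrast_label)
}

#' Write a contrast table to TSV
#'
#' Full double precision is preserved so that a write/read round trip
#' reproduces the table exactly.
#'
#' @param x A `contrast_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contrast_table <- function(x, path) {
  stopifnot(inherits(x, "contrast_table"))
  out <- tibble(feature = x$feature,
                log2fc = format(x$effect, digits = 17, trim = TRUE,
                                scientific = FALSE),
                fdr = format(x$fdr, digits = 17, trim = TRUE,
                             scientific = FALSE))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Align two contrast tables into a dual contrast
#'
#' Inner-joins two contrast tables on feature id so that every retained
#' feature carries both comparisons' effect (`e1`, `e2`) and FDR (`fdr1`,
#' `fdr2`). Features present in only one table are excluded by default (the
#' concordance score is defined only where both comparisons report the gene);
#' `missing_as_zero = TRUE` instead keeps the union, imputing effect 0 and
#' FDR 1 on the missing side, which the zero rule later scores as 0.
#'
#' Features are ordered lexicographically after intersection so downstream
#' results are independent of input row order.
#'
#' @param a,b `contrast_table` objects for contrast 1 and contrast 2.
#' @param missing_as_zero Keep union of features, imputing `effect = 0`,
#'   `fdr = 1` where a side is missing. Default `FALSE` (intersection).
#' @param quiet Suppress the message reporting dropped feature counts.
#'
#' @return A tibble of class `dual_contrast` with columns `feature`, `e1`,
#'   `fdr1`, `e2`, `fdr2`; attributes `cell_type`, `contrast1`, `contrast2`
#'   and `dropped` (named counts of ids dropped from each side).
#' @export
#' @examples
#' a <- contrast_table(data.frame(feature = c("g1", "g2", "g3"),
#'                                effect = c(1, 2, -1), fdr = c(0.01, 0.2, 0.6)))
#' b <- contrast_table(data.frame(feature = c("g2", "g3", "g4"),
#'                                effect = c(2, 1, 0.5), fdr = c(0.03, 0.5, 0.9)))
#' align_contrasts(a, b, quiet = TRUE)
align_contrasts <- function(a, b, missing_as_zero = FALSE, quiet = FALSE) {
  stopifnot(inherits(a, "contrast_table"), inherits(b, "contrast_table"))
  ct_a <- attr(a, "cell_type") %||% NA_character_
  ct_b <- attr(b, "cell_type") %||% NA_character_
  if (!is.na(ct_a) && !is.na(ct_b) && !identical(ct_a, ct_b)) {
    warn(paste0("cell types differ: '", ct_a, "' vs '", ct_b, "'"))
  }
  if (missing_as_zero) {
    features <- sort(union(a$feature, b$feature), method = "radix")
  } else {
    features <- sort(intersect(a$feature, b$feature), method = "radix")
    if (length(features) == 0) {
      abort("no features shared between the two contrast tables",
            class = "cscore_validation_error")
    }
  }
  ia <- match(features, a$feature)
  ib <- match(features, b$feature)
  dc <- tibble(
    feature = features,
    e1   = ifelse(is.na(ia), 0, a$effect[ia]),
    fdr1 = ifelse(is.na(ia), 1, a$fdr[ia]),
    e2   = ifelse(is.na(ib), 0, b$effect[ib]),
    fdr2 = ifelse(is.na(ib), 1, b$fdr[ib])
  )
  dropped <- c(from_a = sum(!a$feature %in% features),
               from_b = sum(!b$feature %in% features))
  if (!quiet && any(dropped > 0)) {
    inform(paste0("align_contrasts: dropped ", dropped[["from_a"]],
                  " feature(s) unique to contrast 1 and ", dropped[["from_b"]],
                  " unique to contrast 2"))
  }
  structure(dc,
            class = c("dual_contrast", class(tibble())),
            cell_type = ct_a %||% ct_b,
            contrast1 = attr(a, "contrast_label"),
            contrast2 = attr(b, "contrast_label"),
            dropped = dropped)
}

#' Construct a dual contrast from in-memory vectors
#'
#' Low-level constructor used by the simulator and tests; [align_contrasts()]
#' is the user path from two contrast tables.
#'
#' @param feature Character feature ids (unique).
#' @param e1,e2 Effects (log2 fold change or NES) in the two contrasts.
#' @param fdr1,fdr2 BH-adjusted p-values in the two contrasts.
#' @param cell_type Optional cell-type label.
#' @return A `dual_contrast` tibble, features sorted lexicographically.
#' @export
dual_contrast <- function(feature, e1, fdr1, e2, fdr2,
                          cell_type = NA_character_) {
  n <- length(feature)
  stopifnot(length(e1) == n, length(fdr1) == n, length(e2) == n,
            length(fdr2) == n)
  if (anyDuplicated(feature)) {
    abort("duplicated feature ids", class = "cscore_validation_error")
  }
  if (any(fdr1 < 0 | fdr1 > 1 | fdr2 < 0 | fdr2 > 1)) {
    abort("fdr outside [0, 1]", class = "cscore_validation_error")
  }
  ord <- order(feature, method = "radix")
  structure(
    tibble(feature = as.character(feature)[ord],
           e1 = as.numeric(e1)[ord], fdr1 = as.numeric(fdr1)[ord],
           e2 = as.numeric(e2)[ord], fdr2 = as.numeric(fdr2)[ord]),
    class = c("dual_contrast", class(tibble())),
    cell_type = cell_type, contrast1 = NA_character_, contrast2 = NA_character_,
    dropped = c(from_a = 0L, from_b = 0L)
  )
}
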