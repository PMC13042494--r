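#' Read a ligand-receptor resource table
#'
#' Reads a LIANA-style consensus resource: one row per ligand-receptor pair,
#' with multi-subunit complexes (e.g. integrin heterodimers such as
#' ITGA3_ITGB1) encoded by joining subunit gene ids with `"_"`.
#'
#' @param path CSV or TSV file with columns `pair_name`, `ligand`, `receptor`.
#' @param delim `NULL` auto-detects tab vs comma.
#' @return A tibble of class `lr_resource` with list-columns
#'   `ligand_subunits` and `receptor_subunits`.
#' @export
read_lr_resource <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("resource file not found: ", path),
          class = "cscore_config_error")
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE)
  required <- c("pair_name", "ligand", "receptor")
  if (!all(required %in% names(raw))) {
    abort(paste0("resource must have columns: ",
                 paste(required, collapse = ", ")),
          class = "cscore_config_error")
  }
  lr_resource(raw)
}

#' Construct a ligand-receptor resource from a data frame
#'
#' @param x Data frame with character columns `pair_name`, `ligand`,
#'   `receptor`; subunits of complexes joined by `"_"`.
#' @return An `lr_resource` tibble.
#' @export
lr_resource <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("pair_name", "ligand", "receptor") %in% names(x)))
  if (anyDuplicated(x$pair_name)) {
    abort("pair_name must be unique in a resource",
          class = "cscore_validation_error")
  }
  res <- tibble(
    pair_name = as.character(x$pair_name),
    ligand = as.character(x$ligand),
    receptor = as.character(x$receptor),
    ligand_subunits = strsplit(as.character(x$ligand), "_", fixed = TRUE),
    receptor_subunits = strsplit(as.character(x$receptor), "_", fixed = TRUE)
  )
  if (any(lengths(res$ligand_subunits) == 0) ||
      any(lengths(res$receptor_subunits) == 0)) {
    abort("empty subunit list in resource", class = "cscore_validation_error")
  }
  structure(res, class = c("lr_resource", class(tibble())))
}

#' Build the C-score-weighted cell-cell communication network
#'
#' For every ordered (sender, receiver) pair of cell types and every
#' ligand-receptor pair in the resource, collects the C-scores of the ligand
#' subunit genes from the sender's score table and of the receptor subunit
#' genes from the receiver's, and emits a directed edge (a
#' sender-receiver-ligand-receptor tetramer) weighted by the sum of those
#' C-scores, with the arithmetic mean of the genes' permutation p-values
#' attached as the edge's significance. A positive edge weight means the
#' interaction's genes respond concordantly in the two contrasts; negative
#' means discordantly.
#'
#' An edge is emitted only if at least one ligand subunit is found in the
#' sender's table and at least one receptor subunit in the receiver's
#' (`require_all_subunits = TRUE` demands every subunit); missing subunits
#' contribute nothing and are counted in `n_genes_missing`.
#'
#' @param scores_by_celltype Named list of `cscore_result` tables (with
#'   `perm_p`), one per cell type; names are the cell-type labels.
#' @param resource An `lr_resource` (see [read_lr_resource()]).
#' @param include_self_edges Emit sender == receiver edges. Default `FALSE`:
#'   the network maps ligands from one cell type to receptors of another.
#' @param subunit_agg How subunit C-scores combine within each side of a
#'   pair before the two sides are summed: `"sum"` (default), `"mean"` or
#'   `"min"`.
#' @param require_all_subunits Emit an edge only when every subunit of both
#'   sides is present in the corresponding score table.
#' @param max_mean_p Optional significance filter: drop edges whose mean
#'   permutation p exceeds this value. Default `NULL` (no filter).
#' @return A tibble of class `ccc_network` with columns `sender`, `receiver`,
#'   `pair`, `ligand`, `receptor`, `weight`, `mean_p`, `n_genes_contributing`,
#'   `n_genes_missing` and list-columns `ligand_genes`, `receptor_genes`
#'   (the subunits actually found); attribute `cell_types`.
#' @export
build_ccc_network <- function(scores_by_celltype, resource,
                              include_self_edges = FALSE,
                              subunit_agg = c("sum", "mean", "min"),
                              require_all_subunits = FALSE,
                              max_mean_p = NULL) {
  subunit_agg <- match.arg(subunit_agg)
  stopifnot(inherits(resource, "lr_resource"), nrow(resource) > 0)
  cell_types <- names(scores_by_celltype)
  if (is.null(cell_types) || any(cell_types == "")) {
    abort("scores_by_celltype must be a named list",
          class = "cscore_config_error")
  }
  n_ct <- length(cell_types)
  if (n_ct < 2 && !include_self_edges) {
    abort("need at least 2 cell types (or include_self_edges = TRUE)",
          class = "cscore_config_error")
  }
  lookup <- lapply(scores_by_celltype, function(tab) {
    if (is.null(tab) || nrow(tab) == 0) {
      abort("empty score table for a listed cell type",
            class = "cscore_validation_error")
    }
    if (anyDuplicated(tab$feature)) {
      abort("duplicated feature in a score table",
            class = "cscore_validation_error")
    }
    if (is.null(tab$perm_p)) {
      abort("score tables must carry perm_p (run permutation_test first)",
            class = "cscore_config_error")
    }
    tab
  })
  agg_fun <- switch(subunit_agg, sum = sum, mean = mean, min = min)

  edges <- vector("list", n_ct * n_ct)
  k <- 0L
  for (s in cell_types) {
    stab <- lookup[[s]]
    for (r in cell_types) {
      if (s == r && !include_self_edges) next
      rtab <- lookup[[r]]
      li <- match_subunits(resource$ligand_subunits, stab$feature)
      ri <- match_subunits(resource$receptor_subunits, rtab$feature)
      n_li_found <- vapply(li, length, integer(1))
      n_ri_found <- vapply(ri, length, integer(1))
      keep <- if (require_all_subunits) {
        n_li_found == lengths(resource$ligand_subunits) &
          n_ri_found == lengths(resource$receptor_subunits)
      } else {
        n_li_found >= 1 & n_ri_found >= 1
      }
      if (!any(keep)) next
      rows <- which(keep)
      w <- vapply(rows, function(q) {
        agg_fun(stab$c_score[li[[q]]]) + agg_fun(rtab$c_score[ri[[q]]])
      }, numeric(1))
      mp <- vapply(rows, function(q) {
        mean(c(stab$perm_p[li[[q]]], rtab$perm_p[ri[[q]]]))
      }, numeric(1))
      k <- k + 1L
      edges[[k]] <- tibble(
        sender = s, receiver = r,
        pair = resource$pair_name[rows],
        ligand = resource$ligand[rows],
        receptor = resource$receptor[rows],
        weight = w, mean_p = mp,
        n_genes_contributing = n_li_found[rows] + n_ri_found[rows],
        n_genes_missing = lengths(resource$ligand_subunits)[rows] +
          lengths(resource$receptor_subunits)[rows] -
          n_li_found[rows] - n_ri_found[rows],
        ligand_genes = lapply(rows, function(q) stab$feature[li[[q]]]),
        receptor_genes = lapply(rows, function(q) rtab$feature[ri[[q]]])
      )
    }
  }
  out <- if (k == 0L) empty_ccc_edges() else bind_rows(edges[seq_len(k)])
  if (!is.null(max_mean_p)) out <- out[out$mean_p <= max_mean_p, , drop = FALSE]
  out <- arrange(out, .data$sender, .data$receiver, .data$pair)
  new_ccc_network(out, cell_types)
}

match_subunits <- function(subunit_lists, features) {
  lapply(subunit_lists, function(g) {
    idx <- match(g, features)
    idx[!is.na(idx)]
  })
}

empty_ccc_edges <- function() {
  tibble(sender = character(), receiver = character(), pair = character(),
         ligand = character(), receptor = character(), weight = numeric(),
         mean_p = numeric(), n_genes_contributing = integer(),
         n_genes_missing = integer(), ligand_genes = list(),
         receptor_genes = list())
}

new_ccc_network <- function(edges, cell_types) {
  structure(edges, class = c("ccc_network", class(tibble())),
            cell_types = cell_types)
}

#' Split a communication network by edge sign
#'
#' Positive-weight edges form the "shared" network (interactions whose genes
#' respond in the same direction in both contrasts); negative-weight edges
#' form the "different" network. Zero-weight edges belong to neither and are
#' dropped (their count is returned).
#'
#' @param net A `ccc_network`.
#' @return A list with elements `shared` and `different` (both
#'   `ccc_network`s over the same cell types) and `n_zero_dropped`.
#' @export
split_by_sign <- function(net) {
  stopifnot(inherits(net, "ccc_network"))
  ct <- attr(net, "cell_types")
  list(
    shared = new_ccc_network(net[net$weight > 0, , drop = FALSE], ct),
    different = new_ccc_network(net[net$weight < 0, , drop = FALSE], ct),
    n_zero_dropped = sum(net$weight == 0)
  )
}

#' Weighted in- and out-degrees per cell type
#'
#' The out-degree of a cell type is the sum of absolute edge weights it
#' sends; the in-degree, the sum of absolute weights it receives. Absolute
#' values make degrees comparable between the positive-weight "shared" and
#' negative-weight "different" subnetworks. Cell types with no edges get 0.
#'
#' @param net A `ccc_network`.
#' @return A tibble with columns `cell_type`, `out_degree`, `in_degree`,
#'   one row per cell type of the network (including edge-less ones).
#' @export
ccc_degrees <- function(net) {
  stopifnot(inherits(net, "ccc_network"))
  ct <- attr(net, "cell_types")
  out_deg <- tapply(abs(net$weight), factor(net$sender, levels = ct), sum)
  in_deg <- tapply(abs(net$weight), factor(net$receiver, levels = ct), sum)
  tibble(cell_type = ct,
         out_degree = as.numeric(ifelse(is.na(out_deg), 0, out_deg)),
         in_degree = as.numeric(ifelse(is.na(in_deg), 0, in_deg)))
}

#' Rank sender ligands or receiver receptors by network weight
#'
#' Aggregates absolute edge weight per (cell type, gene) over the edges in
#' which the gene participates as a found ligand subunit (cell type = the
#' sender) or receptor subunit (cell type = the receiver). High-ranking
#' ligand genes are a cell type's dominant outgoing signals.
#'
#' @param net A `ccc_network`.
#' @param role `"ligand"` or `"receptor"`.
#' @return A tibble `cell_type`, `gene`, `score` (summed absolute weight),
#'   sorted by descending score with ties broken by gene id.
#' @export
rank_ccc_genes <- function(net, role = c("ligand", "receptor")) {
  stopifnot(inherits(net, "ccc_network"))
  role <- match.arg(role)
  if (nrow(net) == 0) {
    return(tibble(cell_type = character(), gene = character(),
                  score = numeric()))
  }
  gene_col <- if (role == "ligand") "ligand_genes" else "receptor_genes"
  ct_col <- if (role == "ligand") "sender" else "receiver"
  tibble(
    cell_type = rep(net[[ct_col]], lengths(net[[gene_col]])),
    gene = unlist(net[[gene_col]], use.names = FALSE),
    w = rep(abs(net$weight), lengths(net[[gene_col]]))
  ) |>
    group_by(.data$cell_type, .data$gene) |>
    summarise(score = sum(.data$w), .groups = "drop") |>
    arrange(desc(.data$score), .data$gene)
}

#' Write a communication network edge list to TSV
#'
#' List-columns of found subunits are collapsed with `"_"`.
#'
#' @param net A `ccc_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ccc_network <- function(net, path) {
  stopifnot(inherits(net, "ccc_network"))
  flat <- as_tibble(net)
  flat$ligand_genes <- vapply(net$ligand_genes, paste, character(1),
                              collapse = "_")
  flat$receptor_genes <- vapply(net$receptor_genes, paste, character(1),
                                collapse = "_")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
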