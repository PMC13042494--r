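#' Run the full concordance analysis from a config
#'
#' Orchestrates the pipeline end-to-end for one or more cell types: align
#' the two contrast tables, score, permutation-test, classify, build the
#' ligand-receptor communication network, split it by sign and compute
#' degree tables — writing every artifact under the output directory and
#' returning a machine-readable run summary. Deterministic given the config
#' (including its seed).
#'
#' Files written: `scores_<cell_type>.tsv` per cell type;
#' `network_full.tsv`, `network_shared.tsv`, `network_different.tsv`;
#' `degrees_full.tsv`, `degrees_shared.tsv`, `degrees_different.tsv`;
#' `dropped_records.tsv` (an audit of every excluded gene or edge with its
#' reason); `summary.json`; and `config_used.yaml` (the effective merged
#' config).
#'
#' @param config A YAML/JSON file path or an equivalent named list with
#'   elements:
#'   \describe{
#'     \item{cell_types}{List of entries `name`, `contrast1`, `contrast2`
#'       (paths to contrast TSVs).}
#'     \item{resource}{Path to the ligand-receptor resource table.}
#'     \item{permutation}{Optional: `n_perm`, `gene_count_threshold`,
#'       `n_perm_large`, `exact`, `seed`, `p_correction`, `null`.}
#'     \item{alpha}{Significance level, in (0, 1). Default 0.05.}
#'     \item{zero_rule}{`"either"` or `"both"`. Default `"either"`.}
#'     \item{network}{Optional: `include_self_edges`, `subunit_agg`,
#'       `require_all_subunits`, `max_mean_p`.}
#'     \item{output_dir}{Directory for outputs (created if needed).}
#'   }
#' @param output_dir Overrides `config$output_dir` when given.
#' @return A list of class `cscore_run`: `pattern_counts` (per-cell-type
#'   tibble), `network_counts`, `degrees` (list of tibbles), `seed`,
#'   `alpha`, `output_dir`, `version`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- load_run_config(config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  if (is.null(cfg$output_dir)) {
    pipeline_abort("config", "output_dir is required")
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  dropped <- list()
  note_drop <- function(stage, record, reason) {
    dropped[[length(dropped) + 1]] <<- tibble(stage = stage, record = record,
                                              reason = reason)
  }

  # --- stage: resource -------------------------------------------------
  resource <- with_stage("resource", read_lr_resource(cfg$resource))

  # --- stage: score ----------------------------------------------------
  perm <- cfg$permutation
  scores_by_ct <- list()
  for (ct in cfg$cell_types) {
    scores_by_ct[[ct$name]] <- with_stage(paste0("score:", ct$name), {
      a <- read_contrast_table(ct$contrast1, cell_type = ct$name,
                               contrast_label = "contrast1")
      b <- read_contrast_table(ct$contrast2, cell_type = ct$name,
                               contrast_label = "contrast2")
      dc <- align_contrasts(a, b, quiet = TRUE)
      dr <- attr(dc, "dropped")
      if (dr[["from_a"]] > 0) {
        note_drop("align", ct$name,
                  paste0(dr[["from_a"]], " feature(s) unique to contrast 1"))
      }
      if (dr[["from_b"]] > 0) {
        note_drop("align", ct$name,
                  paste0(dr[["from_b"]], " feature(s) unique to contrast 2"))
      }
      sc <- cscore_test(
        dc, zero_rule = cfg$zero_rule %||% "either",
        n_perm = perm$n_perm,
        gene_count_threshold = perm$gene_count_threshold %||% 200,
        n_perm_large = perm$n_perm_large %||% 40000,
        exact = isTRUE(perm$exact), seed = perm$seed %||% 1L,
        p_correction = perm$p_correction %||% "add_one",
        null = perm$null %||% "pooled", alpha = cfg$alpha %||% 0.05
      )
      for (f in sc$feature[sc$c_score == 0]) {
        note_drop("score", paste0(ct$name, ":", f), "zero C-score")
      }
      write_cscore_table(sc, file.path(cfg$output_dir,
                                       paste0("scores_", ct$name, ".tsv")))
      sc
    })
  }

  # --- stage: network --------------------------------------------------
  netcfg <- cfg$network %||% list()
  net <- with_stage("network", build_ccc_network(
    scores_by_ct, resource,
    include_self_edges = isTRUE(netcfg$include_self_edges),
    subunit_agg = netcfg$subunit_agg %||% "sum",
    require_all_subunits = isTRUE(netcfg$require_all_subunits),
    max_mean_p = netcfg$max_mean_p
  ))
  parts <- split_by_sign(net)
  if (parts$n_zero_dropped > 0) {
    note_drop("network", "zero-weight edges",
              paste0(parts$n_zero_dropped, " edge(s) with weight 0"))
  }
  nets <- list(full = net, shared = parts$shared, different = parts$different)
  degs <- lapply(nets, ccc_degrees)
  for (nm in names(nets)) {
    write_ccc_network(nets[[nm]],
                      file.path(cfg$output_dir, paste0("network_", nm, ".tsv")))
    readr::write_tsv(degs[[nm]],
                     file.path(cfg$output_dir, paste0("degrees_", nm, ".tsv")),
                     progress = FALSE)
  }

  # --- stage: report ---------------------------------------------------
  pattern_counts <- purrr::imap_dfr(scores_by_ct, function(sc, nm) {
    tibble(cell_type = nm,
           pattern = factor(levels(sc$pattern), levels = levels(sc$pattern))) |>
      left_join(count(as_tibble(sc), .data$pattern), by = "pattern") |>
      mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  })
  network_counts <- tibble(
    network = c("full", "shared", "different"),
    n_edges = vapply(nets, nrow, integer(1))
  )
  drop_tbl <- if (length(dropped) > 0) bind_rows(dropped) else
    tibble(stage = character(), record = character(), reason = character())
  readr::write_tsv(drop_tbl, file.path(cfg$output_dir, "dropped_records.tsv"),
                   progress = FALSE)
  summary <- structure(list(
    pattern_counts = pattern_counts,
    network_counts = network_counts,
    degrees = degs,
    n_zero_edges_dropped = parts$n_zero_dropped,
    seed = perm$seed %||% 1L,
    alpha = cfg$alpha %||% 0.05,
    output_dir = cfg$output_dir,
    version = as.character(utils::packageVersion("cscore"))
  ), class = "cscore_run")
  jsonlite::write_json(
    list(pattern_counts = pattern_counts, network_counts = network_counts,
         degrees = degs, n_zero_edges_dropped = parts$n_zero_dropped,
         seed = summary$seed, alpha = summary$alpha,
         version = summary$version),
    file.path(cfg$output_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  cfg_echo <- cfg
  yaml::write_yaml(cfg_echo, file.path(cfg$output_dir, "config_used.yaml"))
  summary
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      pipeline_abort("config", paste0("config file not found: ", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) pipeline_abort("config", "config must be a list or path")
  if (is.null(config$cell_types) || length(config$cell_types) == 0) {
    pipeline_abort("config", "cell_types is required")
  }
  for (ct in config$cell_types) {
    for (fld in c("name", "contrast1", "contrast2")) {
      if (is.null(ct[[fld]])) {
        pipeline_abort("config", paste0("each cell_types entry needs '", fld, "'"))
      }
    }
    for (fld in c("contrast1", "contrast2")) {
      if (!file.exists(ct[[fld]])) {
        pipeline_abort("config", paste0("missing file: ", ct[[fld]]))
      }
    }
  }
  if (is.null(config$resource)) pipeline_abort("config", "resource is required")
  if (!file.exists(config$resource)) {
    pipeline_abort("config", paste0("missing resource file: ", config$resource))
  }
  alpha <- config$alpha %||% 0.05
  if (alpha <= 0 || alpha >= 1) pipeline_abort("config", "alpha must be in (0, 1)")
  config$permutation <- config$permutation %||% list()
  config
}

pipeline_abort <- function(stage, msg) {
  abort(paste0("[", stage, "] ", msg), class = "cscore_pipeline_error")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "cscore_pipeline_error")) stop(e)
    pipeline_abort(stage, conditionMessage(e))
  })
}

#' Hypergeometric comparison of two gene sets
#'
#' Intersects two gene-id sets and tests the overlap for enrichment against
#' a declared universe size with the one-sided ("greater") hypergeometric
#' test (see [hypergeom_overlap()]).
#'
#' @param set_a,set_b Character vectors of feature ids (de-duplicated).
#' @param universe Background universe size; both sets must fit inside it.
#' @return A one-row tibble: `k` (overlap), `n1`, `n2`, `universe`, `p`.
#' @export
#' @examples
#' compare_gene_sets(c("g1", "g2", "g3"), c("g2", "g3", "g4"), universe = 100)
compare_gene_sets <- function(set_a, set_b, universe) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (length(set_a) > universe || length(set_b) > universe) {
    abort("a set is larger than the declared universe",
          class = "cscore_domain_error")
  }
  k <- length(intersect(set_a, set_b))
  tibble(k = k, n1 = length(set_a), n2 = length(set_b), universe = universe,
         p = hypergeom_overlap(k, length(set_a), length(set_b), universe))
}
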