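#' @export
print.cscore_result <- function(x, ...) {
  ct <- attr(x, "cell_type")
  cat("<cscore_result> ", nrow(x), " features",
      if (!is.null(ct) && !is.na(ct)) paste0(" [", ct, "]"), "\n", sep = "")
  if (!is.null(x$perm_p)) {
    cat("  permutations: ", attr(x, "n_perm"),
        if (isTRUE(attr(x, "exact"))) " (exact cross-pair enumeration)",
        ", pooled null size: ", format(attr(x, "n_null"), big.mark = ","),
        "\n", sep = "")
  }
  if (!is.null(x$pattern)) {
    tab <- table(x$pattern)
    cat("  patterns: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  NextMethod()
}

#' @export
print.ccc_network <- function(x, ...) {
  cat("<ccc_network> ", nrow(x), " edges over ",
      length(attr(x, "cell_types")), " cell types\n", sep = "")
  NextMethod()
}

#' Tidy a C-score result
#'
#' @param x A `cscore_result`.
#' @param ... Unused.
#' @return A plain tibble of the per-feature score table.
#' @method tidy cscore_result
#' @export
tidy.cscore_result <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a C-score result
#'
#' @param x A `cscore_result`.
#' @param ... Unused.
#' @return A one-row tibble: feature count, per-pattern counts (if
#'   classified), permutation settings.
#' @method glance cscore_result
#' @export
glance.cscore_result <- function(x, ...) {
  out <- tibble(n_features = nrow(x))
  if (!is.null(x$pattern)) {
    tab <- table(x$pattern)
    out <- dplyr::bind_cols(out, as_tibble(t(as.matrix(tab))))
  }
  out$n_perm <- attr(x, "n_perm") %||% NA_integer_
  out$n_null <- attr(x, "n_null") %||% NA_real_
  out$alpha <- attr(x, "alpha") %||% NA_real_
  out
}

#' Tidy a communication network into a flat edge table
#'
#' @param x A `ccc_network`.
#' @param ... Unused.
#' @return A tibble with subunit list-columns collapsed by `"_"`.
#' @method tidy ccc_network
#' @export
tidy.ccc_network <- function(x, ...) {
  flat <- as_tibble(x)
  flat$ligand_genes <- vapply(x$ligand_genes, paste, character(1),
                              collapse = "_")
  flat$receptor_genes <- vapply(x$receptor_genes, paste, character(1),
                                collapse = "_")
  flat
}

#' One-row summary of a communication network
#'
#' @param x A `ccc_network`.
#' @param ... Unused.
#' @return A one-row tibble: edge counts by sign, cell-type count, total
#'   absolute weight.
#' @method glance ccc_network
#' @export
glance.ccc_network <- function(x, ...) {
  tibble(
    n_edges = nrow(x),
    n_positive = sum(x$weight > 0),
    n_negative = sum(x$weight < 0),
    n_zero = sum(x$weight == 0),
    n_cell_types = length(attr(x, "cell_types")),
    total_abs_weight = sum(abs(x$weight))
  )
}

#' Concordance scatter plot of a scored dual contrast
#'
#' Plots each feature's contrast-1 effect against its contrast-2 effect,
#' colored by classified pattern (or by C-score if unclassified). The
#' diagonal quadrants where both effects share a sign hold shared responses;
#' the off-diagonal quadrants hold different responses.
#'
#' @param object A `cscore_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cscore_result
#' @export
autoplot.cscore_result <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$e1, y = .data$e2)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::labs(x = "effect, contrast 1 (log2FC or NES)",
                  y = "effect, contrast 2 (log2FC or NES)") +
    ggplot2::theme_minimal()
  if (!is.null(df$pattern)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$pattern),
                            alpha = 0.7, size = 1)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$c_score),
                            alpha = 0.7, size = 1) +
      ggplot2::scale_colour_gradient2(low = "#b2182b", mid = "grey80",
                                      high = "#2166ac", midpoint = 0)
  }
}

#' Sender-receiver heatmap of a communication network
#'
#' Tiles summed absolute edge weight for each ordered (sender, receiver)
#' cell-type pair.
#'
#' @param object A `ccc_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ccc_network
#' @export
autoplot.ccc_network <- function(object, ...) {
  ct <- attr(object, "cell_types")
  df <- as_tibble(object) |>
    group_by(.data$sender, .data$receiver) |>
    summarise(weight = sum(abs(.data$weight)), .groups = "drop") |>
    mutate(sender = factor(.data$sender, levels = ct),
           receiver = factor(.data$receiver, levels = ct))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$receiver, y = .data$sender,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "sum |weight|") +
    ggplot2::labs(x = "receiver", y = "sender") +
    ggplot2::theme_minimal()
}

#' Bar plot of per-cell-type network degrees
#'
#' @param degrees A degree table from [ccc_degrees()].
#' @return A ggplot object.
#' @export
plot_degrees <- function(degrees) {
  stopifnot(all(c("cell_type", "out_degree", "in_degree") %in% names(degrees)))
  df <- tidyr::pivot_longer(degrees, c("out_degree", "in_degree"),
                            names_to = "direction", values_to = "degree")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type, y = .data$degree,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "summed |edge weight|") +
    ggplot2::theme_minimal()
}

#' @export
print.cscore_run <- function(x, ...) {
  cat("<cscore_run> seed ", x$seed, ", alpha ", x$alpha, "\n", sep = "")
  cat("pattern counts:\n")
  print(tidyr::pivot_wider(x$pattern_counts, names_from = "pattern",
                           values_from = "n"))
  cat("network edges: ",
      paste(x$network_counts$network, x$network_counts$n_edges,
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
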