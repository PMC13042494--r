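#' Simulate a dual differential-expression contrast with planted truth
#'
#' Generates two aligned case-vs-control DE contrasts over the same genes
#' with a known per-gene regulation class, emulating the statistical
#' structure the concordance score consumes: per-gene log2 fold changes with
#' BH FDRs in two comparisons. Classes and their generative models:
#'
#' * `shared_up`: both true effects positive; magnitudes drawn independently
#'   per contrast from Normal(`effect_mean`, `effect_sd`) truncated at 0.
#' * `shared_down`: as above with both signs negative.
#' * `different`: opposite nonzero signs (which contrast is up is random per
#'   gene), same magnitude law.
#' * `null`: both true effects exactly 0.
#'
#' Observed effects add Normal(0, `noise_se`) noise to the truth; each
#' contrast's p-values come from the two-sided z-test
#' `2 * (1 - pnorm(|E| / noise_se))` and are BH-adjusted within the contrast.
#' Everything is deterministic given `seed`.
#'
#' Effects are generated directly on the log2 scale rather than via count
#' simulation: the score consumes only (effect, FDR) pairs, so count-level
#' realism would add nothing the downstream method can see.
#'
#' @param n_genes Number of genes (>= 10). Default 2000.
#' @param proportions Named numeric vector over classes `shared_up`,
#'   `shared_down`, `different`, `null`, summing to 1. Default
#'   `c(0.05, 0.05, 0.05, 0.85)`: 15% planted signal.
#' @param effect_mean,effect_sd Mean and sd of the true |log2 fold change|
#'   of planted genes. Defaults 1.5 and 0.3.
#' @param noise_se Standard error of the observed effect around the truth.
#'   Default 0.25.
#' @param seed Integer seed.
#' @param cell_type Label attached to the dual contrast.
#' @return A list with `contrasts` (a `dual_contrast`) and `truth` (a tibble
#'   `feature`, `true_class`, `theta1`, `theta2`).
#' @export
#' @examples
#' sim <- simulate_dual_contrast(n_genes = 100, seed = 1)
#' table(sim$truth$true_class)
simulate_dual_contrast <- function(n_genes = 2000,
                                   proportions = c(shared_up = 0.05,
                                                   shared_down = 0.05,
                                                   different = 0.05,
                                                   null = 0.85),
                                   effect_mean = 1.5, effect_sd = 0.3,
                                   noise_se = 0.25, seed = 1L,
                                   cell_type = "synthetic") {
  check_sim_config(n_genes, proportions, effect_sd, noise_se)
  classes <- c("shared_up", "shared_down", "different", "null")
  withr::with_seed(seed, {
    cls <- sample(classes, n_genes, replace = TRUE,
                  prob = proportions[classes])
    theta1 <- numeric(n_genes)
    theta2 <- numeric(n_genes)
    planted <- cls != "null"
    m1 <- rtruncnorm_pos(sum(planted), effect_mean, effect_sd)
    m2 <- rtruncnorm_pos(sum(planted), effect_mean, effect_sd)
    s1 <- numeric(sum(planted))
    pcls <- cls[planted]
    s1[pcls == "shared_up"] <- 1
    s1[pcls == "shared_down"] <- -1
    flip <- runif(sum(pcls == "different")) < 0.5
    s1[pcls == "different"] <- ifelse(flip, 1, -1)
    s2 <- ifelse(pcls == "different", -s1, s1)
    theta1[planted] <- s1 * m1
    theta2[planted] <- s2 * m2
    e1 <- theta1 + rnorm(n_genes, 0, noise_se)
    e2 <- theta2 + rnorm(n_genes, 0, noise_se)
  })
  p1 <- 2 * pnorm(-abs(e1) / noise_se)
  p2 <- 2 * pnorm(-abs(e2) / noise_se)
  feature <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
  dc <- dual_contrast(feature = feature, e1 = e1, fdr1 = bh_adjust(p1),
                      e2 = e2, fdr2 = bh_adjust(p2), cell_type = cell_type)
  truth <- tibble(feature = feature, true_class = cls,
                  theta1 = theta1, theta2 = theta2) |>
    arrange(.data$feature)
  list(contrasts = dc, truth = truth)
}

# positive half-line truncation by rejection; negligible rejection rate at
# the default mean/sd but exact for any configuration
rtruncnorm_pos <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

check_sim_config <- function(n_genes, proportions, effect_sd, noise_se) {
  classes <- c("shared_up", "shared_down", "different", "null")
  if (!all(classes %in% names(proportions))) {
    abort(paste0("proportions must be named over: ",
                 paste(classes, collapse = ", ")),
          class = "cscore_config_error")
  }
  if (abs(sum(proportions[classes]) - 1) > 1e-9 || any(proportions < 0)) {
    abort("proportions must be non-negative and sum to 1",
          class = "cscore_config_error")
  }
  if (n_genes < 10) {
    abort("n_genes must be at least 10", class = "cscore_config_error")
  }
  if (effect_sd <= 0 || noise_se <= 0) {
    abort("effect_sd and noise_se must be positive",
          class = "cscore_config_error")
  }
}

#' Simulate a toy ligand-receptor resource
#'
#' Samples ligand and receptor genes from a gene pool (without replacement
#' while the pool lasts) and marks a configurable fraction of pairs as
#' 2-subunit receptor complexes, mimicking the shape of LIANA-style
#' consensus resources.
#'
#' @param gene_pool Character vector of candidate gene ids (>= 4).
#' @param n_pairs Number of ligand-receptor pairs. Default 10.
#' @param complex_fraction Fraction of pairs whose receptor gets a second
#'   subunit. Default 0.3.
#' @param seed Integer seed.
#' @return An `lr_resource` tibble.
#' @export
simulate_lr_resource <- function(gene_pool, n_pairs = 10,
                                 complex_fraction = 0.3, seed = 1L) {
  if (length(gene_pool) < 4) {
    abort("gene_pool must contain at least 4 genes",
          class = "cscore_config_error")
  }
  if (complex_fraction < 0 || complex_fraction > 1) {
    abort("complex_fraction must be in [0, 1]", class = "cscore_config_error")
  }
  n_complex <- round(n_pairs * complex_fraction)
  n_needed <- 2 * n_pairs + n_complex
  withr::with_seed(seed, {
    genes <- if (n_needed <= length(gene_pool)) {
      sample(gene_pool, n_needed)
    } else {
      c(sample(gene_pool), sample(gene_pool, n_needed - length(gene_pool),
                                  replace = TRUE))
    }
    is_complex <- rep(FALSE, n_pairs)
    if (n_complex > 0) is_complex[sample.int(n_pairs, n_complex)] <- TRUE
  })
  ligand <- genes[seq_len(n_pairs)]
  receptor1 <- genes[n_pairs + seq_len(n_pairs)]
  extra <- genes[2 * n_pairs + seq_len(n_complex)]
  receptor <- receptor1
  receptor[is_complex] <- paste(receptor1[is_complex], extra, sep = "_")
  lr_resource(tibble(
    pair_name = paste(ligand, receptor, sep = "->"),
    ligand = ligand, receptor = receptor
  ))
}

#' Simulate scored dual contrasts for several cell types
#'
#' Runs [simulate_dual_contrast()] independently per cell type (the master
#' seed is offset by the cell-type index), then the full scoring pipeline
#' (score, permutation test, classification), yielding ready inputs for
#' [build_ccc_network()]. Permutation seeds use a fixed offset of 500 from
#' the generation seed so generation and testing draws never overlap.
#'
#' @param n_cell_types Number of cell types. Default 3.
#' @param cell_type_names Optional labels; default `CT1`, `CT2`, ...
#' @inheritParams simulate_dual_contrast
#' @inheritParams permutation_test
#' @param alpha Significance level for pattern classification.
#' @param ... Further arguments passed to [simulate_dual_contrast()].
#' @return A named list per cell type, each element a list with `scores`
#'   (a classified `cscore_result`) and `truth`.
#' @export
simulate_celltype_scores <- function(n_cell_types = 3, cell_type_names = NULL,
                                     n_genes = 200, seed = 1L, n_perm = NULL,
                                     exact = FALSE, alpha = 0.05, ...) {
  if (n_cell_types < 1) {
    abort("n_cell_types must be >= 1", class = "cscore_config_error")
  }
  if (is.null(cell_type_names)) {
    cell_type_names <- paste0("CT", seq_len(n_cell_types))
  }
  stopifnot(length(cell_type_names) == n_cell_types)
  out <- lapply(seq_len(n_cell_types), function(k) {
    sim <- simulate_dual_contrast(n_genes = n_genes, seed = seed + k,
                                  cell_type = cell_type_names[k], ...)
    scores <- cscore_test(sim$contrasts, n_perm = n_perm, exact = exact,
                          seed = seed + 500L + k, alpha = alpha)
    list(scores = scores, truth = sim$truth)
  })
  setNames(out, cell_type_names)
}
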