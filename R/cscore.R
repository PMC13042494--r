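#' FDR significance weight
#'
#' Piecewise weight that down-weights non-significant effects: 1 for
#' FDR < 0.05, and `log10(FDR) / log10(0.05)` otherwise. The two branches
#' agree at FDR = 0.05 (both give 1) and the weight decays to 0 at FDR = 1.
#'
#' @param fdr Numeric vector of BH-adjusted p-values in \[0, 1\].
#' @return Numeric vector of weights in \[0, 1\].
#' @export
#' @examples
#' wfdr(c(0.01, 0.05, 0.5, 1))
wfdr <- function(fdr) {
  if (!is.numeric(fdr) || any(!is.finite(fdr)) || any(fdr < 0 | fdr > 1)) {
    abort("fdr must be finite and in [0, 1]", class = "cscore_domain_error")
  }
  ifelse(fdr < 0.05, 1, log10(fdr) / log10(0.05))
}

#' Direction-agreement ratio of two effects
#'
#' Positive when the two effects agree in sign, non-positive otherwise:
#' \deqn{Ratio = \frac{\max(|E_1|, |E_2|)}{|E_1 - E_2| + 1}} when
#' \eqn{E_1 E_2 > 0}, and
#' \deqn{Ratio = -\frac{|E_1 - E_2|}{\max(|E_1|, |E_2|) + 1}} when
#' \eqn{E_1 E_2 \le 0}. `cscore_ratio(0, 0)` is 0.
#'
#' @param e1,e2 Numeric vectors of effects (log2 fold change or NES).
#' @return Numeric vector; sign encodes concordance.
#' @export
#' @examples
#' cscore_ratio(c(1, 1, 2), c(1, -1, 1))
cscore_ratio <- function(e1, e2) {
  if (any(!is.finite(e1)) || any(!is.finite(e2))) {
    abort("effects must be finite", class = "cscore_domain_error")
  }
  big <- pmax(abs(e1), abs(e2))
  gap <- abs(e1 - e2)
  ifelse(e1 * e2 > 0, big / (gap + 1), -gap / (big + 1))
}

#' FDR-weighted magnitude of a dual effect
#'
#' `|E1| * wfdr(FDR1) + |E2| * wfdr(FDR2)`: the combined size of the two
#' responses, each discounted by how non-significant it is.
#'
#' @inheritParams cscore_ratio
#' @param fdr1,fdr2 BH-adjusted p-values for each contrast.
#' @return Non-negative numeric vector.
#' @export
cscore_magnitude <- function(e1, fdr1, e2, fdr2) {
  if (any(!is.finite(e1)) || any(!is.finite(e2))) {
    abort("effects must be finite", class = "cscore_domain_error")
  }
  abs(e1) * wfdr(fdr1) + abs(e2) * wfdr(fdr2)
}

#' The C-score: concordance of a feature across two contrasts
#'
#' `c_score = cscore_magnitude(...) * cscore_ratio(...)`. Positive scores mean
#' the feature moved in the same direction in both comparisons (shared
#' response, up or down); negative scores mean opposite directions (different
#' response); larger magnitude means larger, more significant fold changes.
#' Features with a zero effect are scored exactly 0 (direction undefined):
#' with `zero_rule = "either"` (default) a single zero effect suffices, with
#' `"both"` both must be zero.
#'
#' @inheritParams cscore_magnitude
#' @param zero_rule `"either"` or `"both"`; which zero-effect features are
#'   forced to score 0.
#' @return Numeric vector of C-scores.
#' @export
#' @examples
#' c_score(e1 = c(1, 1, 0), fdr1 = c(0.01, 0.01, 0.001),
#'         e2 = c(1, -1, 5), fdr2 = c(0.01, 0.01, 0.001))
c_score <- function(e1, fdr1, e2, fdr2, zero_rule = c("either", "both")) {
  zero_rule <- match.arg(zero_rule)
  s <- cscore_magnitude(e1, fdr1, e2, fdr2) * cscore_ratio(e1, e2)
  zero <- if (zero_rule == "either") e1 == 0 | e2 == 0 else e1 == 0 & e2 == 0
  s[zero] <- 0
  s
}

#' Score every feature of a dual contrast
#'
#' Computes the C-score and its components for each feature of an aligned
#' dual contrast. Rows keep the dual contrast's (lexicographic) feature
#' order. The permutation p-value column is added by [permutation_test()].
#'
#' @param dc A `dual_contrast` (see [align_contrasts()]).
#' @inheritParams c_score
#' @return A tibble of class `cscore_result` with columns `feature`, `e1`,
#'   `fdr1`, `e2`, `fdr2`, `wfdr1`, `wfdr2`, `magnitude`, `ratio`, `c_score`.
#' @seealso [permutation_test()], [classify_patterns()], [cscore_test()]
#' @export
score_contrasts <- function(dc, zero_rule = c("either", "both")) {
  stopifnot(inherits(dc, "dual_contrast") ||
              all(c("feature", "e1", "fdr1", "e2", "fdr2") %in% names(dc)))
  zero_rule <- match.arg(zero_rule)
  res <- tibble(
    feature = dc$feature,
    e1 = dc$e1, fdr1 = dc$fdr1, e2 = dc$e2, fdr2 = dc$fdr2,
    wfdr1 = wfdr(dc$fdr1), wfdr2 = wfdr(dc$fdr2),
    magnitude = cscore_magnitude(dc$e1, dc$fdr1, dc$e2, dc$fdr2),
    ratio = cscore_ratio(dc$e1, dc$e2),
    c_score = c_score(dc$e1, dc$fdr1, dc$e2, dc$fdr2, zero_rule = zero_rule)
  )
  structure(res,
            class = c("cscore_result", class(tibble())),
            cell_type = attr(dc, "cell_type"),
            zero_rule = zero_rule)
}

#' Permutation significance test for C-scores
#'
#' Builds a null distribution of C-scores by repeatedly shuffling each
#' contrast's (effect, FDR) row-pairs across features independently (an
#' effect always travels with its own FDR) and rescoring. By default the
#' permuted scores from all features and all permutations are pooled into one
#' shared null — equivalently, the null is the distribution of
#' `C(e1[i], fdr1[i], e2[j], fdr2[j])` over ordered cross-pairs `(i, j)` —
#' and each observed score is compared against that pool: for a positive
#' observed score, p is the null frequency of scores strictly greater; for a
#' negative score, strictly smaller; zero scores get p = 1.
#'
#' The number of permutations defaults to 40 000 when the table has more
#' than `gene_count_threshold` features and to (number of features)^2
#' otherwise. `exact = TRUE` enumerates all n^2 ordered cross-pairs instead of
#' sampling, which is the exhaustive version of the same pooled null.
#'
#' @param scores A `cscore_result` from [score_contrasts()].
#' @param n_perm Number of permutations; `NULL` applies the size rule above.
#' @param gene_count_threshold Feature count above which `n_perm` defaults to
#'   `n_perm_large` instead of n^2. Default 200.
#' @param n_perm_large Permutation count used above the threshold
#'   (default 40 000).
#' @param exact Enumerate all n^2 cross-pairs exactly instead of sampling.
#' @param seed Integer seed; all shuffles for both contrasts are drawn from
#'   one generator in a fixed interleaved order, so results are reproducible.
#' @param p_correction `"add_one"` (default): p = (count + 1) / (N + 1),
#'   avoiding p = 0 under finite sampling; `"raw_frequency"`: p = count / N,
#'   the literal frequency rule.
#' @param null `"pooled"` (default) compares each feature against the shared
#'   null pool; `"per_gene"` compares each feature only against its own
#'   permuted scores.
#' @return `scores` with a `perm_p` column added and attributes `n_perm`,
#'   `n_null`, `perm_seed`, `p_correction`, `null`.
#' @export
permutation_test <- function(scores, n_perm = NULL, gene_count_threshold = 200,
                             n_perm_large = 40000, exact = FALSE, seed = 1L,
                             p_correction = c("add_one", "raw_frequency"),
                             null = c("pooled", "per_gene")) {
  stopifnot(inherits(scores, "cscore_result"))
  p_correction <- match.arg(p_correction)
  null <- match.arg(null)
  n <- nrow(scores)
  if (n < 2) abort("need at least 2 features", class = "cscore_domain_error")
  if (!is.null(n_perm) && (!is.numeric(n_perm) || n_perm < 1)) {
    abort("n_perm must be a positive integer", class = "cscore_config_error")
  }
  if (gene_count_threshold < 1) {
    abort("gene_count_threshold must be >= 1", class = "cscore_config_error")
  }
  zero_rule <- attr(scores, "zero_rule") %||% "either"
  e1 <- scores$e1; e2 <- scores$e2
  obs <- scores$c_score
  # wFDR weights are invariant under shuffling (an effect travels with its
  # own FDR), so the weighted |effect| terms can be precomputed once.
  a1 <- abs(e1) * scores$wfdr1
  a2 <- abs(e2) * scores$wfdr2
  either <- zero_rule == "either"
  kernel <- function(i1, i2) {
    x <- e1[i1]; y <- e2[i2]
    big <- pmax(abs(x), abs(y))
    gap <- abs(x - y)
    s <- (a1[i1] + a2[i2]) * ifelse(x * y > 0, big / (gap + 1), -gap / (big + 1))
    s[if (either) x == 0 | y == 0 else x == 0 & y == 0] <- 0
    s
  }

  if (exact) {
    pool <- kernel(rep(seq_len(n), each = n), rep(seq_len(n), times = n))
    n_null <- length(pool)
    pool_sorted <- sort(pool)
    cnt_gt <- n_null - findInterval(obs, pool_sorted)
    cnt_lt <- findInterval(obs, pool_sorted, left.open = TRUE)
    n_perm_used <- n_null
  } else {
    if (is.null(n_perm)) {
      n_perm <- if (n > gene_count_threshold) n_perm_large else n * n
    }
    n_perm <- as.integer(n_perm)
    cnt_gt <- numeric(n)
    cnt_lt <- numeric(n)
    withr::with_seed(seed, {
      for (b in seq_len(n_perm)) {
        s <- kernel(sample.int(n), sample.int(n))
        if (null == "pooled") {
          s <- sort(s)
          cnt_gt <- cnt_gt + (n - findInterval(obs, s))
          cnt_lt <- cnt_lt + findInterval(obs, s, left.open = TRUE)
        } else {
          cnt_gt <- cnt_gt + (s > obs)
          cnt_lt <- cnt_lt + (s < obs)
        }
      }
    })
    n_null <- if (null == "pooled") as.numeric(n_perm) * n else as.numeric(n_perm)
    n_perm_used <- n_perm
  }

  tail_count <- ifelse(obs > 0, cnt_gt, cnt_lt)
  p <- if (p_correction == "add_one") {
    (tail_count + 1) / (n_null + 1)
  } else {
    tail_count / n_null
  }
  p[obs == 0] <- 1

  scores$perm_p <- p
  attr(scores, "n_perm") <- n_perm_used
  attr(scores, "n_null") <- n_null
  attr(scores, "perm_seed") <- if (exact) NA_integer_ else seed
  attr(scores, "p_correction") <- p_correction
  attr(scores, "null") <- null
  attr(scores, "exact") <- exact
  scores
}

#' Classify features into shared / different patterns
#'
#' Applies the one-sided significance cut to permutation p-values and labels
#' each feature: `zero` (C-score exactly 0), `not_significant`
#' (p >= `alpha`), `shared_up` (significant positive score, both effects up),
#' `shared_down` (significant positive score, both effects down), or
#' `different` (significant negative score: opposite directions).
#'
#' @param scores A `cscore_result` with `perm_p` (see [permutation_test()]).
#' @param alpha One-sided significance level; default 0.05.
#' @return `scores` with a `pattern` factor column added.
#' @export
classify_patterns <- function(scores, alpha = 0.05) {
  stopifnot(inherits(scores, "cscore_result"))
  if (is.null(scores$perm_p)) {
    abort("run permutation_test() before classify_patterns()",
          class = "cscore_config_error")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must be in (0, 1)", class = "cscore_config_error")
  }
  lv <- c("shared_up", "shared_down", "different", "zero", "not_significant")
  pattern <- dplyr::case_when(
    scores$c_score == 0 ~ "zero",
    scores$perm_p >= alpha ~ "not_significant",
    scores$c_score > 0 & scores$e1 > 0 ~ "shared_up",
    scores$c_score > 0 & scores$e1 < 0 ~ "shared_down",
    scores$c_score < 0 ~ "different"
  )
  scores$pattern <- factor(pattern, levels = lv)
  attr(scores, "alpha") <- alpha
  scores
}

#' Score, permute and classify in one call
#'
#' Convenience wrapper chaining [score_contrasts()], [permutation_test()] and
#' [classify_patterns()].
#'
#' @inheritParams score_contrasts
#' @inheritParams permutation_test
#' @inheritParams classify_patterns
#' @return A classified `cscore_result`.
#' @export
#' @examples
#' dc <- dual_contrast(feature = c("g1", "g2", "g3", "g4"),
#'                     e1 = c(2, -1.5, 1, 0.1), fdr1 = c(0.001, 0.01, 0.6, 0.9),
#'                     e2 = c(1.8, -1.2, -1, 0.05), fdr2 = c(0.002, 0.04, 0.5, 0.8))
#' cscore_test(dc, exact = TRUE)
cscore_test <- function(dc, zero_rule = c("either", "both"), n_perm = NULL,
                        gene_count_threshold = 200, n_perm_large = 40000,
                        exact = FALSE, seed = 1L,
                        p_correction = c("add_one", "raw_frequency"),
                        null = c("pooled", "per_gene"), alpha = 0.05) {
  score_contrasts(dc, zero_rule = zero_rule) |>
    permutation_test(n_perm = n_perm,
                     gene_count_threshold = gene_count_threshold,
                     n_perm_large = n_perm_large, exact = exact, seed = seed,
                     p_correction = p_correction, null = null) |>
    classify_patterns(alpha = alpha)
}

#' Write a C-score result table to TSV
#'
#' @param scores A `cscore_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cscore_table <- function(scores, path) {
  stopifnot(inherits(scores, "cscore_result"))
  readr::write_tsv(as_tibble(scores), path, progress = FALSE)
  invisible(path)
}
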