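# shared fixture builders; everything generated in code, nothing on disk

toy_contrast <- function(features, effects, fdrs, cell_type = "CTB",
                         label = NA_character_) {
  contrast_table(data.frame(feature = features, effect = effects, fdr = fdrs),
                 cell_type = cell_type, contrast_label = label)
}

write_toy_tsv <- function(features, effects, fdrs,
                          path = tempfile(fileext = ".tsv"),
                          effect_col = "log2fc") {
  df <- data.frame(feature = features, e = effects, fdr = fdrs)
  names(df)[2] <- effect_col
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# independent double-loop brute-force oracle for the exact pooled
# permutation p; deliberately naive and separate from the implementation
brute_force_perm_p <- function(e1, f1, e2, f2, p_correction = "add_one",
                               zero_rule = "either") {
  n <- length(e1)
  obs <- c_score(e1, f1, e2, f2, zero_rule = zero_rule)
  pool <- numeric(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      pool <- c(pool, c_score(e1[i], f1[i], e2[j], f2[j],
                              zero_rule = zero_rule))
    }
  }
  vapply(seq_len(n), function(g) {
    if (obs[g] == 0) return(1)
    cnt <- if (obs[g] > 0) sum(pool > obs[g]) else sum(pool < obs[g])
    if (p_correction == "add_one") (cnt + 1) / (length(pool) + 1)
    else cnt / length(pool)
  }, numeric(1))
}

# tiny two-cell-type scored fixture with hand-set values (perm_p set directly
# so network arithmetic can be checked by hand)
hand_scored_tables <- function() {
  mk <- function(features, cs, ps) {
    structure(
      tibble::tibble(feature = features, e1 = cs, fdr1 = 0.01, e2 = cs,
                     fdr2 = 0.01, wfdr1 = 1, wfdr2 = 1, magnitude = abs(cs),
                     ratio = sign(cs), c_score = cs, perm_p = ps),
      class = c("cscore_result", class(tibble::tibble())))
  }
  list(
    A = mk(c("L1", "L2", "R1", "R2"), c(2, -0.5, 1, 1), c(0.01, 0.2, 0.05, 0.1)),
    B = mk(c("L1", "R1", "R2", "R3"), c(-0.5, -0.5, 1, 0.2), c(0.2, 0.2, 0.01, 0.5))
  )
}
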