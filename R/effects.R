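# Per-CpG effect-size estimation from young/old reference groups, plus the
# CpG filters used to build reduced and "top effect size" clock variants.

.as_effect_table <- function(df) {
  need <- c("cpg_id", "ground_state", "old_state", "effect_size")
  if (!all(need %in% names(df)))
    stopf("effect table must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$cpg_id)) stopf("duplicate CpG ids in effect table")
  if (any(df$ground_state < 0 | df$ground_state > 1) ||
      any(df$old_state < 0 | df$old_state > 1))
    stopf("ground/old states must lie in [0, 1]")
  df$cpg_id <- as.character(df$cpg_id)
  class(df) <- c("effect_table", "data.frame")
  df
}

#' Estimate per-CpG ground states and effect sizes
#'
#' The mean beta over the young group defines each CpG's ground state (the
#' simulator's starting value); the signed difference old minus young is the
#' effect size, whose sign fixes the direction of simulated change and whose
#' magnitude drives the per-step alteration probability. Zero-effect CpGs are
#' retained (they simply never change in the simulator).
#'
#' @param young,old beta-value matrices (CpGs x samples) with CpG rownames;
#'   at least two samples each, no missing values.
#' @param cpg_subset optional character vector restricting to these CpGs
#'   (e.g. a published clock's CpG set); all must be present in both groups.
#' @return an `effect_table` data.frame: `cpg_id`, `ground_state`,
#'   `old_state`, `effect_size`.
#' @export
estimate_effects <- function(young, old, cpg_subset = NULL) {
  for (nm in c("young", "old")) {
    m <- get(nm)
    if (!is.matrix(m) || is.null(rownames(m)))
      stopf("`%s` must be a matrix with CpG rownames", nm)
    if (ncol(m) < 2) stopf("`%s` needs >= 2 samples", nm)
    if (anyNA(m))
      stopf("missing values in `%s`; imputation is out of scope", nm)
  }
  cpgs <- if (is.null(cpg_subset)) intersect(rownames(young), rownames(old))
          else as.character(cpg_subset)
  miss_y <- setdiff(cpgs, rownames(young))
  miss_o <- setdiff(cpgs, rownames(old))
  if (length(miss_y) || length(miss_o))
    stopf("CpGs missing: %s",
          paste(head(unique(c(miss_y, miss_o)), 5), collapse = ", "))
  if (!length(cpgs)) stopf("no shared CpGs between groups")
  g <- rowMeans(young[cpgs, , drop = FALSE])
  o <- rowMeans(old[cpgs, , drop = FALSE])
  .as_effect_table(data.frame(cpg_id = cpgs, ground_state = unname(g),
                              old_state = unname(o),
                              effect_size = unname(o - g),
                              stringsAsFactors = FALSE))
}

#' Filter CpGs for a ground-state-insensitive (reduced) clock
#'
#' Keeps CpGs whose ground states agree across two cell types (absolute
#' difference strictly below `max_ground_diff`) and whose age-effect
#' directions are concordant and nonzero. Used to show that a stochastic
#' clock does not hinge on the ground state of the training cell type.
#'
#' @param effects_a,effects_b `effect_table`s from two cell types.
#' @param max_ground_diff maximum allowed ground-state difference (strict),
#'   default 0.1 beta-units.
#' @return character vector of passing CpG ids.
#' @export
reduced_clock_filter <- function(effects_a, effects_b, max_ground_diff = 0.1) {
  effects_a <- .as_effect_table(effects_a)
  effects_b <- .as_effect_table(effects_b)
  shared <- intersect(effects_a$cpg_id, effects_b$cpg_id)
  if (!length(shared)) stopf("effect tables share no CpGs")
  a <- effects_a[match(shared, effects_a$cpg_id), ]
  b <- effects_b[match(shared, effects_b$cpg_id), ]
  pass <- abs(a$ground_state - b$ground_state) < max_ground_diff &
    sign(a$effect_size) == sign(b$effect_size) &
    sign(a$effect_size) != 0
  shared[pass]
}

#' Select the k CpGs with largest absolute effect size
#'
#' Basis for stochastic clocks built from a single study's top age-related
#' CpGs rather than a published clock's CpG set. Ties are broken by CpG id
#' (lexicographic) so selection is deterministic.
#'
#' @param effects an `effect_table`.
#' @param k number of CpGs to select, `1 <= k <= nrow(effects)`.
#' @return character vector of k CpG ids.
#' @export
select_top_cpgs <- function(effects, k) {
  effects <- .as_effect_table(effects)
  k <- .check_count(k, "k", min = 1)
  if (k > nrow(effects)) stopf("`k` exceeds the number of CpGs (%d)", nrow(effects))
  ord <- order(-abs(effects$effect_size), effects$cpg_id)
  effects$cpg_id[ord][seq_len(k)]
}

#' Write an effect table as CSV
#' @param effects an `effect_table`.
#' @param path output file.
#' @export
write_effect_table <- function(effects, path) {
  effects <- .as_effect_table(effects)
  write.csv(as.data.frame(effects), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an effect table from CSV
#' @param path CSV with columns cpg_id, ground_state, old_state, effect_size.
#' @return an `effect_table`.
#' @export
read_effect_table <- function(path) {
  .as_effect_table(read.csv(path, stringsAsFactors = FALSE, comment.char = "#"))
}
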