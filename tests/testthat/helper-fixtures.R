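# Shared in-code fixtures. Everything is generated programmatically at test
# time; small sizes keep the default run fast.

# A tiny deterministic effect table for arithmetic-level tests.
tiny_effects <- function() {
  data.frame(
    cpg_id = c("cgA", "cgB", "cgC", "cgD"),
    ground_state = c(0.10, 0.50, 0.90, 0.30),
    old_state = c(0.14, 0.46, 0.90, 0.35),
    effect_size = c(0.04, -0.04, 0.00, 0.05),
    stringsAsFactors = FALSE
  )
}

# Cached mid-size panel shared by slower tests (built once per run).
.panel_cache <- new.env(parent = emptyenv())
shared_panel <- function(n_cpgs = 120, seed = 2024) {
  key <- sprintf("p_%d_%d", n_cpgs, seed)
  if (is.null(.panel_cache[[key]]))
    .panel_cache[[key]] <- make_reference_panel(n_cpgs, n_young = 20,
                                                n_old = 10, seed = seed)
  .panel_cache[[key]]
}

# A beta matrix with rownames/colnames from a vector of means.
beta_matrix_from <- function(means, n, ids = NULL, seed = 1, noise = 0.05) {
  if (is.null(ids)) ids <- sprintf("cg%03d", seq_along(means))
  withr::with_seed(seed, {
    m <- pnorm(qnorm(pmin(pmax(means, 1e-6), 1 - 1e-6)) +
                 matrix(rnorm(length(means) * n, 0, noise), ncol = n))
  })
  dimnames(m) <- list(ids, sprintf("s%02d", seq_len(n)))
  m
}
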