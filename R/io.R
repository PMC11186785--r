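# Delimited-text readers/writers for the pipeline's artifact formats.
# All writers emit a provenance comment header (# stage / seed / config
# hash); all readers skip comment lines.

.provenance_header <- function(stage, seed = NA, config = NULL) {
  sprintf("# stocclock stage=%s seed=%s hash=%s", stage, format(seed),
          .tiny_hash(config))
}

#' Write a beta matrix as TSV
#'
#' First column `cpg_id`, header row of sample ids, one provenance comment
#' line on top.
#'
#' @param betas CpGs x samples matrix with dimnames.
#' @param path output file.
#' @param stage,seed,config provenance fields for the header.
#' @export
write_beta_matrix <- function(betas, path, stage = "betas", seed = NA,
                              config = NULL) {
  if (!is.matrix(betas) || is.null(rownames(betas)) || is.null(colnames(betas)))
    stopf("`betas` must be a matrix with CpG rownames and sample colnames")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(stage, seed, config), con)
  df <- data.frame(cpg_id = rownames(betas), betas, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a beta matrix
#'
#' Expects the format written by [write_beta_matrix()] (TSV, `cpg_id` first
#' column). Values outside the unit interval are rejected with their
#' coordinates,
#' duplicate CpG ids and missing values are rejected.
#'
#' @param path input file (TSV; CSV accepted via `sep`).
#' @param sep field separator, default tab.
#' @return CpGs x samples numeric matrix.
#' @export
read_beta_matrix <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] != "cpg_id") stopf("first column must be `cpg_id`")
  if (anyDuplicated(df$cpg_id))
    stopf("duplicate CpG id(s): %s",
          paste(head(unique(df$cpg_id[duplicated(df$cpg_id)]), 3),
                collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric beta values")
  rownames(m) <- df$cpg_id
  bad <- which(is.na(m) | m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("invalid beta value at (%s, %s)%s",
          rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
          if (nrow(bad) > 1) sprintf(" and %d more", nrow(bad) - 1) else "")
  }
  m
}

#' Write a sample sheet as CSV
#' @param samples data.frame with at least `sample_id` and `age`.
#' @param path output file.
#' @inheritParams write_beta_matrix
#' @export
write_sample_sheet <- function(samples, path, stage = "samples", seed = NA,
                               config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(stage, seed, config), con)
  write.csv(samples, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' Requires unique `sample_id` and finite nonnegative `age`; if `frac_*`
#' columns are present their rows must sum to 1 within 1e-6.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "age") %in% names(df)))
    stopf("sample sheet needs `sample_id` and `age` columns")
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample ids")
  if (anyNA(df$age) || any(!is.finite(df$age)) || any(df$age < 0))
    stopf("ages must be finite and >= 0")
  fcols <- grep("^frac_", names(df), value = TRUE)
  if (length(fcols)) {
    rs <- rowSums(df[, fcols, drop = FALSE])
    if (any(abs(rs - 1) > 1e-6))
      stopf("fraction rows must sum to 1 (worst deviation %.2g)",
            max(abs(rs - 1)))
  }
  df
}
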