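#' Profile matrices
#'
#' A profile matrix holds the measurements of `p` module features (nodes) on
#' `n` subjects: subjects are rows, features are columns, and the column order
#' must match the node order of any companion network. Internally it is a
#' plain numeric matrix with subject IDs as rownames and feature IDs as
#' colnames.
#'
#' @param x A numeric matrix, or a data frame whose first column is the
#'   subject ID and whose remaining columns are numeric features.
#' @param subject_ids,feature_ids Optional label overrides.
#' @return A labelled numeric matrix.
#' @export
as_profile_matrix <- function(x, subject_ids = NULL, feature_ids = NULL) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1L]])
    x <- as.matrix(x[, -1L, drop = FALSE])
    rownames(x) <- ids
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("Profiles must be a numeric matrix or a data frame with an ID column.",
      class = "netshy_invalid_profiles"
    )
  }
  if (anyNA(x)) {
    abort("Profiles must not contain missing values; impute or filter upstream.",
      class = "netshy_invalid_profiles"
    )
  }
  rownames(x) <- subject_ids %||% rownames(x) %||% paste0("S", seq_len(nrow(x)))
  colnames(x) <- feature_ids %||% colnames(x) %||% paste0("V", seq_len(ncol(x)))
  x
}

# Features of X must match the network nodes in content and order.
check_alignment <- function(X, net) {
  if (ncol(X) != n_nodes(net)) {
    abort(
      sprintf(
        "Profiles have %d features but the network has %d nodes.",
        ncol(X), n_nodes(net)
      ),
      class = "netshy_alignment_error"
    )
  }
  if (!identical(colnames(X), net$node_ids)) {
    abort("Profile feature IDs do not match the network node IDs (content and order).",
      class = "netshy_alignment_error"
    )
  }
  invisible(X)
}

#' @rdname as_profile_matrix
#' @param path File path; comma-separated with subjects as rows, the first
#'   column holding subject IDs and the header row holding feature IDs.
#' @export
read_profiles <- function(path) {
  # base-R parser (strtod) so that full-precision decimals round-trip exactly
  df <- utils::read.csv(path, check.names = FALSE)
  as_profile_matrix(df)
}

#' @rdname as_profile_matrix
#' @export
write_profiles <- function(x, path) {
  x <- as_profile_matrix(x)
  df <- full_precision(tibble::as_tibble(x, rownames = "subject_id"))
  readr::write_csv(df, path)
  invisible(path)
}
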