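#' @importFrom rlang %||% abort warn .data
#' @importFrom generics tidy glance augment
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` means "use the current
# stream" (no isolation).
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.", class = "netshy_invalid_seed")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

#' Derive a component-specific sub-seed from a master seed
#'
#' Pipelines that consume several independent random streams (network
#' generation, profile draws, phenotype noise, measurement noise) derive one
#' sub-seed per component from the master seed, so that all randomness flows
#' from a single integer while the streams stay distinct. The derivation is a
#' small polynomial string hash of the component name folded with the seed,
#' reduced modulo 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param component Character tag naming the consuming component.
#' @return A positive integer seed below 2^31.
#' @examples
#' sub_seed(1, "network")
#' sub_seed(1, "profiles")
#' @export
sub_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  stopifnot(is.character(component), length(component) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps everything exact in doubles
  h <- 0
  for (ch in utf8ToInt(component)) {
    h <- (h * 31 + ch) %% m
  }
  out <- (h * 1000003 + (abs(seed) %% m)) %% m
  as.integer(out + 1L)
}

# Format numeric columns with 17 significant digits so that text files
# round-trip doubles exactly.
full_precision <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  })
  df
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name),
      class = "netshy_invalid_argument"
    )
  }
  if (x < lower || x > upper) {
    abort(
      sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x),
      class = "netshy_invalid_argument"
    )
  }
  invisible(x)
}
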