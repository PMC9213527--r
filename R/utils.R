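# Internal helpers: seed streams, argument checks, lightweight logging.

#' Derive a reproducible sub-seed from a top-level seed and an operation tag
#'
#' Every random operation in the package draws its seed from the single
#' top-level seed through this function, so inserting a new pipeline step
#' never shifts the random stream of an existing one.
#'
#' @param seed integer top-level seed.
#' @param tag character scalar naming the operation (stable across versions).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' seed_stream(42, "clump") != seed_stream(42, "score")
seed_stream <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps results in 32-bit range
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  as.integer((as.numeric(seed) %% m * 48271 + h) %% m)
}

# Run expr with a local RNG state seeded by `seed`; restores the caller's
# RNG so library code never perturbs user-level reproducibility.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

hlog <- function(...) {
  kv <- list(...)
  parts <- vapply(seq_along(kv), function(i) {
    paste0(names(kv)[i], "=", paste(format(kv[[i]]), collapse = ","))
  }, FUN.VALUE = "")
  message("[htnprs] ", paste(parts, collapse = " "))
}

stop_config <- function(...) stop(paste0(...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# canonical variant key string used for joins/uniqueness; positions are
# formatted as plain integers so numeric input never turns scientific
variant_key <- function(chrom, pos, ea, oa) {
  paste(chrom, format(pos, scientific = FALSE, trim = TRUE), ea, oa,
        sep = ":")
}

# position-level key (allele-agnostic), used by allele harmonization
locus_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(a) {
  out <- DNA_COMP[a]
  unname(out)
}

is_palindromic <- function(ea, oa) {
  unname(DNA_COMP[ea] == oa)
}
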