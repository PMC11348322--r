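#' @keywords internal
#' @useDynLib codroplet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Deterministic, dependency-free seed derivation.  Combines an integer seed
# with further integer/character components into a value in [0, 2^31 - 2] so
# every internal RNG stream is reproducible from a single user-facing seed.
derive_seed <- function(seed, ...) {
  h <- as.double(seed %% 2147483647L)
  for (comp in list(...)) {
    if (is.character(comp)) comp <- utf8ToInt(paste(comp, collapse = "\r"))
    for (x in as.double(comp)) {
      h <- (h * 69069 + x + 1) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Canonically order a protein pair
#'
#' Returns the two identifiers sorted lexicographically (C locale), the
#' canonical order used for pair deduplication and score lookup throughout
#' the package.
#'
#' @param id_a,id_b Protein identifiers.
#' @return Character vector of length two, ordered.
#' @export
canonical_pair <- function(id_a, id_b) {
  stopifnot(length(id_a) == 1L, length(id_b) == 1L)
  a <- as.character(id_a)
  b <- as.character(id_b)
  if (a <= b) c(a, b) else c(b, a)
}

# Vectorised canonical ordering; returns a two-column character matrix.
canonical_pairs <- function(id_a, id_b) {
  a <- as.character(id_a)
  b <- as.character(id_b)
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  cbind(id_a = a, id_b = b)
}

pair_key <- function(id_a, id_b) {
  m <- canonical_pairs(id_a, id_b)
  paste(m[, 1L], m[, 2L], sep = "\r")
}

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% AA_ALPHABET20))
  if (length(bad)) {
    stop(sprintf(
      "invalid amino-acid character '%s' at position %d (alphabet: %s)",
      chars[bad[1L]], bad[1L], paste(AA_ALPHABET20, collapse = "")
    ), call. = FALSE)
  }
  chars
}

`%||%` <- function(a, b) if (is.null(a)) b else a
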