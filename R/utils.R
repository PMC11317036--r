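#' @keywords internal
"_PACKAGE"

DNA_ALPHABET <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state,
#' so seeded package functions do not perturb the global random stream.
#' A `NULL` seed evaluates the expression with the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-stream seed from a root seed
#'
#' Replicates and emission streams use `root + 7919 * k` reduced modulo
#' 2^31 - 1 so derived seeds stay valid 32-bit integers for any root.
#'
#' @param root Integer root seed.
#' @param k Non-negative stream counter.
#' @return An integer seed.
#' @export
derive_seed <- function(root, k) {
  s <- (as.numeric(root) + 7919 * as.numeric(k)) %% 2147483647
  as.integer(s) + 1L
}

#' Hamming distance between equal-length strings
#'
#' @param a Single string.
#' @param b Character vector of strings with the same width as `a`.
#' @return Integer vector of per-position disagreement counts.
#' @export
hamming_dist <- function(a, b) {
  stopifnot(length(a) == 1L, all(nchar(b) == nchar(a)))
  ra <- charToRaw(a)
  vapply(b, function(x) sum(charToRaw(x) != ra), integer(1), USE.NAMES = FALSE)
}

#' Complement and reverse-complement of nucleotide strings
#'
#' @param x Character vector over A/C/G/T.
#' @return Character vector of the same length.
#' @export
complement_seq <- function(x) chartr("ACGT", "TGCA", x)

paste0_strict <- function(...) {
  args <- list(...)
  if (any(lengths(args) == 0L)) return(character(0))
  paste0(...)
}

#' @rdname complement_seq
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("non-ACGT characters in ", what, ": ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

random_dna <- function(n_bases) {
  paste(sample(DNA_ALPHABET, n_bases, replace = TRUE), collapse = "")
}
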