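# Quantitative metrics: Ideal Scores (template/primer), mismatch ratio,
# positional error-rate windows, Bray-Curtis dissimilarity, classical MDS
# ordination and alpha diversity.

unify_labels <- function(x, y) {
  labs <- union(names(x), names(y))
  if (is.null(labs)) {
    if (length(x) != length(y)) {
      stop("unnamed vectors must have equal length", call. = FALSE)
    }
    labs <- as.character(seq_along(x))
    names(x) <- labs
    names(y) <- labs
  }
  xx <- stats::setNames(rep(0, length(labs)), labs)
  yy <- xx
  xx[names(x)] <- x
  yy[names(y)] <- y
  list(x = xx, y = yy)
}

as_proportions <- function(x) {
  if (any(x < 0)) stop("negative abundances", call. = FALSE)
  s <- sum(x)
  if (s == 0) stop("cannot normalize an all-zero abundance vector",
                   call. = FALSE)
  x / s
}

#' Ideal Score between observed and expected abundance distributions
#'
#' The summed absolute difference between the observed and expected relative
#' abundances of each feature, in percent units: `IS = sum(|100 o_i - 100
#' e_i|)`. Ranges from 0 (observed equals expected) to 200 (disjoint
#' supports). Equivalent to 200 times the Bray-Curtis dissimilarity of the
#' two proportion vectors.
#'
#' @param observed,expected Named count or proportion vectors; labels are
#'   unified and missing features treated as zero; each vector is normalized
#'   on entry.
#' @return The Ideal Score in `[0, 200]`.
#' @export
ideal_score <- function(observed, expected) {
  u <- unify_labels(observed, expected)
  o <- as_proportions(u$x)
  e <- as_proportions(u$y)
  sum(abs(100 * o - 100 * e))
}

pool_expectation <- function(pool, uniform = FALSE) {
  if (uniform) {
    stats::setNames(rep(1 / length(pool$members), length(pool$members)),
                    pool$members)
  } else {
    pool$proportions
  }
}

#' Ideal Template Score
#'
#' Dissimilarity of the observed template distribution from the input
#' template ratios of the pool (the expectation follows the pool's relative
#' concentrations, so uneven input pools score 0 when recovered exactly).
#' Higher values mean higher distortion of the input template distribution.
#'
#' @param observed Named counts over templates (a template-margin row).
#' @param template_pool The [make_pool()] used as input.
#' @param uniform_expectation Use a uniform expectation over pool members
#'   instead of the input concentrations.
#' @return ITS in `[0, 200]`.
#' @export
ideal_template_score <- function(observed, template_pool,
                                 uniform_expectation = FALSE) {
  extra <- setdiff(names(observed)[observed > 0], template_pool$members)
  if (length(extra)) {
    stop("observed templates not in the pool: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  ideal_score(observed, pool_expectation(template_pool, uniform_expectation))
}

#' Ideal Primer Score
#'
#' Dissimilarity of primer utilization from the input primer ratios. Higher
#' values mean more selective use of primers.
#'
#' @param observed Named counts over primers (a primer-margin row).
#' @param primer_pool The [make_pool()] used as input.
#' @param uniform_expectation Use a uniform expectation over pool members.
#' @return IPS in `[0, 200]`.
#' @export
ideal_primer_score <- function(observed, primer_pool,
                               uniform_expectation = FALSE) {
  extra <- setdiff(names(observed)[observed > 0], primer_pool$members)
  if (length(extra)) {
    stop("observed primers not in the pool: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  ideal_score(observed, pool_expectation(primer_pool, uniform_expectation))
}

#' Mismatch ratio of an interaction-count row
#'
#' Counts on pairs with at least one primer-template mismatch divided by
#' counts on perfectly matching pairs. 0 when only perfect matches were
#' used; `Inf` when mismatched pairs were counted but no perfect-match pair
#' exists or was used.
#'
#' @param counts Named counts (names = `pair_id`), e.g. one matrix row.
#' @param space The [interaction_space()] giving each pair's mismatch count.
#' @return A non-negative number, possibly `Inf`.
#' @export
mismatch_ratio <- function(counts, space) {
  if (length(counts) == 0L || sum(counts) == 0) {
    stop("empty count row", call. = FALSE)
  }
  idx <- match(names(counts), space$pair_id)
  if (anyNA(idx)) {
    stop("counts contain pairs absent from the space: ",
         paste(utils::head(names(counts)[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  }
  mm <- space$n_mismatches[idx]
  num <- sum(counts[mm > 0])
  den <- sum(counts[mm == 0])
  if (num == 0) return(0)
  if (den == 0) return(Inf)
  num / den
}

#' Per-replicate metrics for an interaction matrix
#'
#' @param mat An `interaction_matrix`.
#' @param space The [interaction_space()].
#' @param template_pool,primer_pool Input pools defining the expectations.
#' @return A data.frame with one row per replicate: `its`, `ips`,
#'   `mismatch_ratio`.
#' @export
matrix_metrics <- function(mat, space, template_pool, primer_pool) {
  margins <- split_matrix(mat)
  data.frame(
    replicate = rownames(mat),
    its = apply(margins$template, 1L, ideal_template_score, template_pool),
    ips = apply(margins$primer, 1L, ideal_primer_score, primer_pool),
    mismatch_ratio = apply(unclass(mat), 1L, mismatch_ratio, space),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity
#'
#' `BC = sum(|x_i - y_i|) / sum(x_i + y_i)` on counts or proportions. With
#' one matrix argument, the full pairwise dissimilarity matrix is returned.
#'
#' @param x Abundance vector, or a samples-by-features matrix when `y` is
#'   `NULL`.
#' @param y Optional second abundance vector.
#' @return A single dissimilarity in `[0, 1]`, or a symmetric matrix.
#' @export
bray_curtis <- function(x, y = NULL) {
  if (is.null(y)) {
    return(as.matrix(vegan::vegdist(unclass(x), method = "bray")))
  }
  u <- unify_labels(x, y)
  if (sum(u$x) == 0 && sum(u$y) == 0) {
    stop("both vectors are all-zero", call. = FALSE)
  }
  as.numeric(vegan::vegdist(rbind(u$x, u$y), method = "bray"))
}

#' Classical (principal-coordinate) MDS ordination
#'
#' Wraps [stats::cmdscale()] with a fixed sign convention: within each axis
#' the first coordinate of magnitude above `1e-8` is made positive.
#'
#' @param d Symmetric zero-diagonal dissimilarity matrix (or `dist`).
#' @param k Number of dimensions (default 2).
#' @return A points matrix (rows = samples) with eigenvalues in attribute
#'   `eig`.
#' @export
mds_ordination <- function(d, k = 2L) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m)) || any(abs(diag(m)) > 1e-12)) {
    stop("dissimilarity matrix must be symmetric with a zero diagonal",
         call. = FALSE)
  }
  k <- min(k, nrow(m) - 1L)
  if (all(m == 0)) {
    # all points coincide: the embedding is the origin in every dimension
    pts <- matrix(0, nrow(m), k, dimnames = list(rownames(m), NULL))
    attr(pts, "eig") <- rep(0, nrow(m))
    return(pts)
  }
  fit <- stats::cmdscale(m, k = k, eig = TRUE)
  pts <- fit$points
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-8)
    if (length(nz) && pts[nz[1], j] < 0) pts[, j] <- -pts[, j]
  }
  attr(pts, "eig") <- fit$eig
  pts
}

#' Shannon diversity
#'
#' `H = -sum(p_i log p_i)` over nonzero proportions (natural log).
#'
#' @param counts Non-negative abundance vector.
#' @return H >= 0.
#' @export
shannon_diversity <- function(counts) {
  p <- as_proportions(counts)
  as.numeric(vegan::diversity(p, index = "shannon"))
}

#' Feature richness
#'
#' @param counts Non-negative abundance vector.
#' @return Number of features with nonzero counts.
#' @export
richness <- function(counts) sum(counts > 0)

#' Truth references for emitted reads
#'
#' The reference for a read from pair (primer, template) is the template
#' sequence with the primer core substituted at the forward priming site --
#' what the read would be with zero copy and sequencing error.
#'
#' @param pair_ids Character vector of `primer:template` pair ids.
#' @param design A design list (from [default_design()]).
#' @return Character vector of reference sequences.
#' @export
truth_references <- function(pair_ids, design) {
  templates <- design$templates
  primers <- design$primers
  fw <- attr(templates, "forward_width")
  p <- sub(":.*$", "", pair_ids)
  t <- sub("^.*:", "", pair_ids)
  cores <- stats::setNames(primers$core, primers$primer_id)
  bodies <- stats::setNames(substr(templates$sequence, fw + 1L,
                                   nchar(templates$sequence)),
                            templates$template_id)
  unname(paste0(cores[p], bodies[t]))
}

#' Positional error profile of reads against truth references
#'
#' Per position, the fraction of reads disagreeing with their reference;
#' per window, the mean over the window's positions. Reads shorter than a
#' window contribute only to the positions they cover. Alignment is
#' gap-free (the error model is substitution-only).
#'
#' @param sequences Character vector of read sequences.
#' @param references Character vector of same-length reference sequences.
#' @param windows Named list of `c(start, end)` windows, 1-based inclusive.
#'   The defaults follow the primer region (1-20), the next 20 bases and
#'   the next 60.
#' @return A list with `per_position` (mismatch fraction per position) and
#'   `per_window` (named mean rates).
#' @export
error_profile <- function(sequences, references,
                          windows = list(primer = c(1L, 20L),
                                         post_primer = c(21L, 40L),
                                         body = c(41L, 100L))) {
  stopifnot(length(sequences) == length(references))
  if (length(sequences) == 0L) stop("no reads", call. = FALSE)
  width <- max(vapply(windows, max, numeric(1)))
  widths <- pmin(nchar(sequences), nchar(references))
  per_pos <- numeric(width)
  for (pos in seq_len(width)) {
    covered <- widths >= pos
    if (!any(covered)) {
      per_pos[pos] <- NA_real_
      next
    }
    a <- substr(sequences[covered], pos, pos)
    b <- substr(references[covered], pos, pos)
    per_pos[pos] <- mean(a != b)
  }
  per_window <- vapply(windows, function(w)
    mean(per_pos[w[1]:w[2]], na.rm = TRUE), numeric(1))
  list(per_position = per_pos, per_window = per_window)
}
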