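# From merged reads to the biological observation matrix: quality filter,
# exact-match assignment of each read to a (primer, template) pair via the
# mapping of primer variants and recognition sequences, matrix construction,
# rarefaction and margin splits.

CS1_LINKER <- "ACACTGACGACATGGTTCTACA"
CS2_LINKER <- "TACGGTAGCAGAGACTTGGTCT"

#' Read a FASTQ file into a read data.frame
#'
#' @param path FASTQ path.
#' @param replicate_id Replicate tag attached to every read; defaults to the
#'   file name without extension.
#' @return A data.frame with `read_id`, `sequence`, `quality`,
#'   `replicate_id`.
#' @export
read_fastq <- function(path, replicate_id = NULL) {
  if (is.null(replicate_id)) {
    replicate_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = names(x), sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             replicate_id = replicate_id, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Mean Phred quality per read
#'
#' @param quality Character vector of Phred+33 quality strings.
#' @return Numeric vector of mean qualities.
#' @export
mean_quality <- function(quality) {
  vapply(quality, function(q) mean(utf8ToInt(q) - 33L), numeric(1),
         USE.NAMES = FALSE)
}

#' Filter reads on mean quality
#'
#' Retains reads whose mean Phred quality is greater than or equal to the
#' threshold (inclusive boundary).
#'
#' @param reads Read data.frame.
#' @param min_mean_quality Threshold (default 20).
#' @return The retained reads, with attributes `n_retained` and `n_dropped`.
#' @export
quality_filter <- function(reads, min_mean_quality = 20) {
  keep <- mean_quality(reads$quality) >= min_mean_quality
  out <- reads[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Merge a read pair by best gap-free overlap
#'
#' Aligns the 3' end of R1 against the 5' end of the reverse-complemented R2
#' without gaps, choosing the overlap that maximizes matches minus
#' mismatches among overlaps of at least `min_overlap` bases with a mismatch
#' fraction at most `max_overlap_mismatch_fraction`. Disagreements in the
#' overlap are resolved toward the higher-quality base and the consensus
#' quality is the higher of the two. Unmergeable pairs are dropped and
#' counted in the `n_unmerged` attribute.
#'
#' @param r1,r2 Read data.frames aligned by `read_id`.
#' @param min_overlap Minimum overlap in bases.
#' @param max_overlap_mismatch_fraction Maximum disagreement fraction within
#'   the overlap.
#' @return A merged read data.frame.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10L,
                        max_overlap_mismatch_fraction = 0.25) {
  if (!identical(r1$read_id, r2$read_id)) {
    stop("R1/R2 read ids do not match", call. = FALSE)
  }
  merged <- vector("list", nrow(r1))
  dropped <- 0L
  for (i in seq_len(nrow(r1))) {
    s1 <- r1$sequence[i]; q1 <- r1$quality[i]
    s2 <- reverse_complement(r2$sequence[i])
    q2 <- paste(rev(strsplit(r2$quality[i], "")[[1]]), collapse = "")
    n1 <- nchar(s1); n2 <- nchar(s2)
    best <- NULL; best_score <- -Inf
    for (o in seq.int(min(n1, n2), min_overlap)) {
      a <- substr(s1, n1 - o + 1L, n1)
      b <- substr(s2, 1L, o)
      mism <- sum(charToRaw(a) != charToRaw(b))
      if (mism / o > max_overlap_mismatch_fraction) next
      score <- (o - mism) - mism
      if (score > best_score) {
        best_score <- score
        best <- list(o = o, mism = mism)
      }
    }
    if (is.null(best)) {
      dropped <- dropped + 1L
      next
    }
    o <- best$o
    ca <- strsplit(substr(s1, n1 - o + 1L, n1), "")[[1]]
    cb <- strsplit(substr(s2, 1L, o), "")[[1]]
    qa <- utf8ToInt(substr(q1, n1 - o + 1L, n1)) - 33L
    qb <- utf8ToInt(substr(q2, 1L, o)) - 33L
    cons <- ifelse(qb > qa, cb, ca)
    qcons <- pmax(qa, qb)
    merged[[i]] <- data.frame(
      read_id = r1$read_id[i],
      sequence = paste0(substr(s1, 1L, n1 - o),
                        paste(cons, collapse = ""),
                        substr(s2, o + 1L, n2)),
      quality = paste0(substr(q1, 1L, n1 - o),
                       intToUtf8(qcons + 33L),
                       substr(q2, o + 1L, n2)),
      replicate_id = r1$replicate_id[i], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, merged[!vapply(merged, is.null, logical(1))])
  if (is.null(out)) {
    out <- r1[0, c("read_id", "sequence", "quality", "replicate_id")]
  }
  attr(out, "n_unmerged") <- dropped
  out
}

#' Trim a literal 5' linker when present
#'
#' @param reads Read data.frame.
#' @param linker Literal prefix to remove (default CS1).
#' @return Reads with the prefix removed where it occurred.
#' @export
trim_linker <- function(reads, linker = CS1_LINKER) {
  has <- startsWith(reads$sequence, linker)
  n <- nchar(linker)
  reads$sequence[has] <- substring(reads$sequence[has], n + 1L)
  reads$quality[has] <- substring(reads$quality[has], n + 1L)
  reads
}

ASSIGNMENT_STATUSES <- c("assigned", "unassigned_primer",
                         "unassigned_recognition", "filtered_quality",
                         "excluded_not_in_design")

#' Classify reads into primer-template pairs by exact matching
#'
#' Reads must begin at the forward priming site. In `full_primer` mode the
#' first bases of the read must equal some primer core exactly; in
#' `variant_positions` mode only the bases at the variant offsets must match
#' a primer triple. The template is identified by exact equality of the
#' recognition window with some recognition sequence. There is no error
#' tolerance. Pairs whose primer or template is not part of the experiment's
#' design are excluded.
#'
#' @param reads Read data.frame.
#' @param space An [interaction_space()] (the mapping of all combinations).
#' @param mode "full_primer" (default) or "variant_positions".
#' @param design_pairs Optional subset of `space` restricting the pairs in
#'   this experiment (see [design_pairs_of()] semantics via pools); defaults
#'   to the whole space.
#' @param min_mean_quality Optional mean-quality threshold applied first;
#'   failing reads get status `filtered_quality`.
#' @return An assignment data.frame with `read_id`, `replicate_id`,
#'   `status`, `primer_id`, `template_id`.
#' @export
classify_reads <- function(reads, space,
                           mode = c("full_primer", "variant_positions"),
                           design_pairs = NULL, min_mean_quality = NULL) {
  mode <- match.arg(mode)
  if (is.null(design_pairs)) design_pairs <- space
  primers <- attr(space, "primers")
  templates <- attr(space, "templates")
  fw <- attr(space, "forward_width")
  rec_off <- attr(space, "recognition_offset")
  rec_len <- attr(space, "recognition_length")
  rec_end <- rec_off + rec_len - 1L
  spec <- attr(space, "spec")
  pos <- variant_positions(spec, fw)

  n <- nrow(reads)
  status <- rep("assigned", n)
  primer_id <- rep(NA_character_, n)
  template_id <- rep(NA_character_, n)

  live <- rep(TRUE, n)
  if (!is.null(min_mean_quality)) {
    bad <- mean_quality(reads$quality) < min_mean_quality
    status[bad] <- "filtered_quality"
    live <- live & !bad
  }
  short <- nchar(reads$sequence) < rec_end
  status[live & short] <- "unassigned_recognition"
  live <- live & !short

  if (mode == "full_primer") {
    key <- substr(reads$sequence, 1L, fw)
    pidx <- match(key, primers$core)
  } else {
    key <- vapply(reads$sequence, function(s)
      paste(substring(s, pos, pos), collapse = ""), character(1),
      USE.NAMES = FALSE)
    pidx <- match(key, primers$triple)
  }
  no_primer <- live & is.na(pidx)
  status[no_primer] <- "unassigned_primer"
  live <- live & !no_primer
  primer_id[live] <- primers$primer_id[pidx[live]]

  rec <- substr(reads$sequence, rec_off, rec_end)
  tidx <- match(rec, templates$recognition_seq)
  no_rec <- live & is.na(tidx)
  status[no_rec] <- "unassigned_recognition"
  live <- live & !no_rec
  template_id[live] <- templates$template_id[tidx[live]]

  pair <- paste0(primer_id, ":", template_id)
  out_design <- live & !(pair %in% design_pairs$pair_id)
  status[out_design] <- "excluded_not_in_design"
  primer_id[status != "assigned"] <- NA_character_
  template_id[status != "assigned"] <- NA_character_

  data.frame(read_id = reads$read_id, replicate_id = reads$replicate_id,
             status = status, primer_id = primer_id,
             template_id = template_id, stringsAsFactors = FALSE)
}

#' Collate assignments into an interaction count matrix
#'
#' @param assignments Output of [classify_reads()].
#' @param space An [interaction_space()].
#' @param design_pairs Optional subset of `space` defining the columns;
#'   defaults to the whole space.
#' @param metadata Optional metadata list (method, temperature, pools)
#'   merged into the matrix metadata.
#' @return An `interaction_matrix` whose metadata carries per-status read
#'   accounting in `status_counts`.
#' @export
build_interaction_matrix <- function(assignments, space, design_pairs = NULL,
                                     metadata = list()) {
  if (is.null(design_pairs)) design_pairs <- space
  reps <- sort(unique(assignments$replicate_id))
  counts <- matrix(0L, length(reps), nrow(design_pairs),
                   dimnames = list(reps, design_pairs$pair_id))
  ok <- assignments$status == "assigned"
  if (any(ok)) {
    tab <- table(assignments$replicate_id[ok],
                 paste0(assignments$primer_id[ok], ":",
                        assignments$template_id[ok]))
    counts[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  status_counts <- table(factor(assignments$status,
                                levels = ASSIGNMENT_STATUSES))
  md <- utils::modifyList(list(status_counts = status_counts), metadata)
  new_interaction_matrix(counts, md)
}

#' Rarefy an interaction matrix
#'
#' Subsamples each replicate's counts without replacement to exactly
#' `depth`. Replicates with fewer total counts than `depth` are dropped with
#' a warning.
#'
#' @param mat An `interaction_matrix` (or plain count matrix).
#' @param depth Rarefaction depth (default 7000).
#' @param seed Optional seed.
#' @return The rarefied matrix; every row sums to `depth`. Metadata gains
#'   `rarefaction_depth` and `dropped_replicates`.
#' @export
rarefy <- function(mat, depth = 7000L, seed = NULL) {
  stopifnot(depth >= 1L)
  totals <- rowSums(mat)
  low <- totals < depth
  if (all(low)) {
    stop("all replicates are below the rarefaction depth ", depth,
         call. = FALSE)
  }
  if (any(low)) {
    warning("dropping ", sum(low), " replicate(s) below depth ", depth, ": ",
            paste(rownames(mat)[low], collapse = ", "), call. = FALSE)
  }
  kept <- mat[!low, , drop = FALSE]
  if (ncol(kept) == 1L) {
    # a single feature: subsampling a row with total >= depth keeps depth
    res <- matrix(depth, nrow(kept), 1L)
  } else {
    # rrarefy warns on counts whose minimum exceeds 1; inputs are validated
    # integer counts here, so the warning is spurious
    res <- with_seed(seed, suppressWarnings(vegan::rrarefy(kept, depth)))
  }
  out <- matrix(as.integer(res), nrow(kept), ncol(kept),
                dimnames = dimnames(kept))
  md <- attr(mat, "metadata")
  if (is.null(md)) md <- list()
  md$rarefaction_depth <- depth
  md$dropped_replicates <- rownames(mat)[low]
  new_interaction_matrix(out, md)
}

#' Split an interaction matrix into template and primer margins
#'
#' @param mat An `interaction_matrix` with `primer:template` pair columns.
#' @return A list with `template` (replicates x templates) and `primer`
#'   (replicates x primers) matrices; each margin row sum equals the source
#'   row sum.
#' @export
split_matrix <- function(mat) {
  primer <- sub(":.*$", "", colnames(mat))
  template <- sub("^.*:", "", colnames(mat))
  margin <- function(group) {
    m <- t(rowsum(t(unclass(mat)), group))
    m[, order(colnames(m)), drop = FALSE]
  }
  list(template = margin(template), primer = margin(primer))
}

#' Write an interaction matrix as TSV and as BIOM JSON
#'
#' @param mat An `interaction_matrix`.
#' @param path Output TSV path; when `biom_path` is given the matrix is also
#'   written in BIOM 1.0 JSON via the biomformat package.
#' @param biom_path Optional BIOM output path.
#' @return `path`, invisibly.
#' @export
write_interaction_matrix <- function(mat, path, biom_path = NULL) {
  df <- data.frame(replicate = rownames(mat),
                   as.data.frame(unclass(mat), check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(biom_path)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("the biomformat package is required for BIOM output",
           call. = FALSE)
    }
    b <- biomformat::make_biom(t(unclass(mat)))
    biomformat::write_biom(b, biom_path)
  }
  invisible(path)
}
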