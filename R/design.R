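# Synthetic design space: templates differing only at three priming-site
# positions and a short internal recognition sequence, and the full
# combinatorial set of primer variants at those positions.

#' Variant-position specification for the priming site
#'
#' Describes which priming-site positions are varied between templates and
#' primers. Offsets are counted from the primer 3' end, with the terminal
#' base at offset -1, so the defaults -14, -8, -2 correspond to string
#' positions 7, 13 and 19 of a 20-base primer. The conventional field labels
#' are 5' (distal), M (middle) and 3' (proximal), encoded "5p", "M", "3p".
#'
#' @param offsets Strictly increasing negative integers, offsets from the
#'   3' end.
#' @param labels One tag per offset.
#' @param alphabet Nucleotide alphabet used for enumeration.
#' @return An object of class `variant_spec`.
#' @export
variant_spec <- function(offsets = c(-14L, -8L, -2L),
                         labels = c("5p", "M", "3p"),
                         alphabet = DNA_ALPHABET) {
  offsets <- as.integer(offsets)
  if (length(offsets) != length(labels)) {
    stop("labels must be the same length as offsets", call. = FALSE)
  }
  if (length(offsets) > 1 && any(diff(offsets) <= 0)) {
    stop("offsets must be strictly increasing toward the 3' end",
         call. = FALSE)
  }
  if (any(offsets >= 0)) stop("offsets must be negative", call. = FALSE)
  structure(list(offsets = offsets, labels = labels, alphabet = alphabet),
            class = "variant_spec")
}

#' Map 3'-anchored offsets to 1-based string positions
#'
#' @param spec A [variant_spec()].
#' @param width Primer (or priming-site) width in bases.
#' @return Integer positions within the primer string.
#' @export
variant_positions <- function(spec, width) {
  pos <- width + 1L + spec$offsets
  if (any(pos < 1L) || any(pos > width)) {
    stop("variant offsets fall outside a primer of width ", width,
         call. = FALSE)
  }
  pos
}

triple_of <- function(seqs, positions) {
  if (length(positions) == 0L) return(rep("", length(seqs)))
  vapply(seqs, function(s) {
    paste(substring(s, positions, positions), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

stamp_triple <- function(base, triple, positions) {
  ch <- strsplit(base, "", fixed = TRUE)[[1]]
  ch[positions] <- strsplit(triple, "", fixed = TRUE)[[1]]
  paste(ch, collapse = "")
}

#' Enumerate all primer variants of a base core
#'
#' Produces one primer per combination of alphabet bases at the variant
#' positions (4^k primers for k positions). Ids are assigned
#' deterministically: the base core itself first, then variants grouped by
#' number of substituted positions, within a group by position combination
#' (5'-most first), then bases in A<C<G<T order. Specific id-to-variant
#' assignments (such as a published V1..V9 ordering) can be imposed with
#' `id_overrides`.
#'
#' @param base_core Primer core sequence (default design: 20 bases).
#' @param spec A [variant_spec()].
#' @param id_prefix Prefix for primer ids (default "V").
#' @param id_overrides Optional named character vector mapping primer ids to
#'   variant triples, e.g. `c(V1 = "GTA")`.
#' @param linker Optional 5' linker sequence carried as an attribute.
#' @return A `primer_set` data.frame with columns `primer_id`, `core`,
#'   `triple`, `n_mismatch` (substitutions relative to `base_core`).
#' @export
enumerate_primer_variants <- function(base_core, spec = variant_spec(),
                                      id_prefix = "V", id_overrides = NULL,
                                      linker = NULL) {
  check_dna(base_core, "base core")
  width <- nchar(base_core)
  pos <- variant_positions(spec, width)
  k <- length(pos)
  base_triple <- triple_of(base_core, pos)

  if (k == 0L) {
    triples <- ""
  } else {
    grid <- expand.grid(rev(replicate(k, spec$alphabet, simplify = FALSE)),
                        stringsAsFactors = FALSE)
    triples <- do.call(paste0, rev(grid))
  }
  ref <- strsplit(base_triple, "", fixed = TRUE)[[1]]
  mm <- vapply(strsplit(triples, "", fixed = TRUE),
               function(x) sum(x != ref), integer(1))
  # position pattern: 5'-most mismatch weighted highest so 5' variants sort
  # first within a mismatch-count group
  pat <- vapply(strsplit(triples, "", fixed = TRUE), function(x) {
    sum(2^(rev(seq_len(k)) - 1L) * (x != ref))
  }, numeric(1))
  ord <- order(mm, -pat, triples)
  triples <- triples[ord]

  ids <- paste0(id_prefix, seq_along(triples) - 1L)
  if (!is.null(id_overrides)) {
    miss <- setdiff(id_overrides, triples)
    if (length(miss)) {
      stop("id_overrides name unknown triples: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    fixed_idx <- match(id_overrides, triples)
    names(fixed_idx) <- names(id_overrides)
    remaining <- setdiff(seq_along(triples), fixed_idx)
    free_ids <- setdiff(ids, names(fixed_idx))
    perm <- integer(length(triples))
    perm[match(names(fixed_idx), ids)] <- fixed_idx
    perm[match(free_ids, ids)] <- remaining
    triples <- triples[perm]
  }

  cores <- vapply(triples, function(t) {
    if (k == 0L) base_core else stamp_triple(base_core, t, pos)
  }, character(1), USE.NAMES = FALSE)
  out <- data.frame(primer_id = ids, core = cores, triple = triples,
                    n_mismatch = hamming_dist(base_triple, triples),
                    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  attr(out, "linker") <- linker
  attr(out, "base_core") <- base_core
  class(out) <- c("primer_set", "data.frame")
  out
}

#' Generate recognition sequences with a minimum pairwise Hamming distance
#'
#' Rejection-samples random sequences, keeping a candidate only if it is at
#' least `min_hamming` substitutions away from every accepted sequence.
#'
#' @param n Number of sequences.
#' @param length Sequence length in bases.
#' @param min_hamming Minimum pairwise Hamming distance.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param max_attempts Rejection budget per sequence before failing.
#' @return Character vector of `n` sequences.
#' @export
generate_recognition_set <- function(n, length = 12L, min_hamming = 4L,
                                     seed = NULL, max_attempts = 10000L) {
  stopifnot(n >= 1L, length >= 1L, min_hamming >= 0L)
  if (min_hamming > length) {
    stop("infeasible constraint: min_hamming (", min_hamming,
         ") exceeds sequence length (", length, ")", call. = FALSE)
  }
  with_seed(seed, {
    accepted <- character(0)
    while (base::length(accepted) < n) {
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        cand <- random_dna(length)
        if (base::length(accepted) == 0L ||
            all(hamming_dist(cand, accepted) >= min_hamming)) {
          accepted <- c(accepted, cand)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("infeasible constraint: could not place sequence ",
             base::length(accepted) + 1L, " of ", n,
             " with min_hamming = ", min_hamming, " within ", max_attempts,
             " attempts", call. = FALSE)
      }
    }
    accepted
  })
}

#' Build a set of synthetic templates
#'
#' Templates share `base_sequence` (which starts at the first base of the
#' forward priming site and ends at the last base of the constant reverse
#' site) and differ only at the variant positions of the forward site and in
#' a recognition window linked one-to-one with each variant triple.
#'
#' @param base_sequence Amplicon-sense template sequence.
#' @param variant_triples Character vector of triples (one per template).
#' @param recognition_seqs Character vector, same length as
#'   `variant_triples`.
#' @param recognition_offset 1-based start of the recognition window,
#'   counted from the first base of the forward priming site.
#' @param spec A [variant_spec()].
#' @param template_ids Optional ids; default `ST0`, `ST1`, ...
#' @param forward_width,reverse_width Widths of the priming sites.
#' @return A `template_set` data.frame with columns `template_id`,
#'   `sequence`, `forward_site`, `triple`, `recognition_seq`.
#' @export
build_template_set <- function(base_sequence, variant_triples,
                               recognition_seqs, recognition_offset = 99L,
                               spec = variant_spec(), template_ids = NULL,
                               forward_width = 20L, reverse_width = 20L) {
  check_dna(base_sequence, "base sequence")
  check_dna(recognition_seqs, "recognition sequence")
  n <- length(variant_triples)
  if (length(recognition_seqs) != n) {
    stop("need one recognition sequence per variant triple", call. = FALSE)
  }
  if (anyDuplicated(variant_triples)) {
    stop("duplicate variant triples", call. = FALSE)
  }
  if (anyDuplicated(recognition_seqs)) {
    stop("duplicate recognition sequences", call. = FALSE)
  }
  rec_len <- nchar(recognition_seqs[1])
  stopifnot(all(nchar(recognition_seqs) == rec_len))
  total <- nchar(base_sequence)
  rec_end <- recognition_offset + rec_len - 1L
  if (recognition_offset <= forward_width ||
      rec_end > total - reverse_width) {
    stop("recognition window [", recognition_offset, ", ", rec_end,
         "] does not fit between the priming sites", call. = FALSE)
  }
  pos <- variant_positions(spec, forward_width)
  if (is.null(template_ids)) template_ids <- paste0("ST", seq_len(n) - 1L)

  seqs <- character(n)
  fwd <- character(n)
  for (i in seq_len(n)) {
    s <- stamp_triple(base_sequence, variant_triples[i], pos)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[recognition_offset:rec_end] <-
      strsplit(recognition_seqs[i], "", fixed = TRUE)[[1]]
    seqs[i] <- paste(ch, collapse = "")
    fwd[i] <- substr(seqs[i], 1L, forward_width)
  }
  out <- data.frame(template_id = template_ids, sequence = seqs,
                    forward_site = fwd, triple = variant_triples,
                    recognition_seq = recognition_seqs,
                    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  attr(out, "forward_width") <- forward_width
  attr(out, "reverse_width") <- reverse_width
  attr(out, "recognition_offset") <- recognition_offset
  attr(out, "recognition_length") <- rec_len
  attr(out, "reverse_site") <- substr(base_sequence, total - reverse_width + 1L,
                                      total)
  class(out) <- c("template_set", "data.frame")
  out
}

pairing_key <- function(primer_base, template_base) {
  # the annealed duplex pairs the primer base against the complement of the
  # template coding-strand base
  paste0_strict(primer_base, "-", complement_seq(template_base))
}

#' Mismatch profile of a primer against a template priming site
#'
#' @param primer A `primer_set` row, a list with `$core`, or a core string.
#' @param template A `template_set` row, a list with `$forward_site`, or a
#'   priming-site string.
#' @param spec A [variant_spec()].
#' @return A data.frame with one row per mismatched variant position:
#'   `label`, `offset`, `position`, `primer_base`, `template_base`,
#'   `pairing`. Zero rows for a perfect match.
#' @export
mismatch_profile <- function(primer, template, spec = variant_spec()) {
  core <- if (is.character(primer)) primer else primer$core
  site <- if (is.character(template)) template else template$forward_site
  stopifnot(length(core) == 1L, length(site) == 1L)
  if (nchar(core) != nchar(site)) {
    stop("primer core and template forward site differ in length",
         call. = FALSE)
  }
  pos <- variant_positions(spec, nchar(core))
  pb <- substring(core, pos, pos)
  tb <- substring(site, pos, pos)
  hit <- pb != tb
  data.frame(label = spec$labels[hit], offset = spec$offsets[hit],
             position = pos[hit], primer_base = pb[hit],
             template_base = tb[hit],
             pairing = pairing_key(pb[hit], tb[hit]),
             stringsAsFactors = FALSE)
}

#' Enumerate the full primer-by-template interaction space
#'
#' One row per (primer, template) pair with its mismatch profile, serving as
#' the mapping file for exact-match read classification. Lookup keys
#' (primer core, recognition sequence) and (variant triple, recognition
#' sequence) must be unique.
#'
#' @param templates A `template_set`.
#' @param primers A `primer_set`.
#' @param spec A [variant_spec()].
#' @return An `interaction_space` data.frame keyed by
#'   `pair_id = "<primer_id>:<template_id>"`.
#' @export
interaction_space <- function(templates, primers, spec = attr(templates, "spec")) {
  stopifnot(nrow(templates) >= 1L, nrow(primers) >= 1L)
  if (anyDuplicated(primers$primer_id) || anyDuplicated(templates$template_id)) {
    stop("primer and template ids must be unique", call. = FALSE)
  }
  if (anyDuplicated(templates$recognition_seq)) {
    stop("key collision: recognition sequences are not unique",
         call. = FALSE)
  }
  idx <- expand.grid(p = seq_len(nrow(primers)), t = seq_len(nrow(templates)))
  profiles <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    profiles[[i]] <- mismatch_profile(primers$core[idx$p[i]],
                                      templates$forward_site[idx$t[i]], spec)
  }
  out <- data.frame(
    pair_id = paste0(primers$primer_id[idx$p], ":",
                     templates$template_id[idx$t]),
    primer_id = primers$primer_id[idx$p],
    template_id = templates$template_id[idx$t],
    primer_core = primers$core[idx$p],
    primer_triple = primers$triple[idx$p],
    recognition_seq = templates$recognition_seq[idx$t],
    n_mismatches = vapply(profiles, nrow, integer(1)),
    mismatch_labels = vapply(profiles, function(p)
      paste(p$label, collapse = "+"), character(1)),
    mismatch_offsets = vapply(profiles, function(p)
      paste(p$offset, collapse = "+"), character(1)),
    mismatch_pairings = vapply(profiles, function(p)
      paste(p$pairing, collapse = "+"), character(1)),
    stringsAsFactors = FALSE)
  out$profile <- profiles
  if (anyDuplicated(paste(out$primer_core, out$recognition_seq)) ||
      anyDuplicated(paste(out$primer_triple, out$recognition_seq))) {
    stop("key collision: (primer, recognition sequence) keys are not unique",
         call. = FALSE)
  }
  attr(out, "spec") <- spec
  attr(out, "templates") <- templates
  attr(out, "primers") <- primers
  attr(out, "forward_width") <- attr(templates, "forward_width")
  attr(out, "recognition_offset") <- attr(templates, "recognition_offset")
  attr(out, "recognition_length") <- attr(templates, "recognition_length")
  class(out) <- c("interaction_space", "data.frame")
  out
}

#' Write / read the interaction space as a mapping TSV
#'
#' @param space An [interaction_space()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping_tsv <- function(space, path) {
  cols <- c("pair_id", "primer_id", "template_id", "primer_core",
            "primer_triple", "recognition_seq", "n_mismatches",
            "mismatch_labels", "mismatch_offsets", "mismatch_pairings")
  utils::write.table(as.data.frame(space)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mapping_tsv
#' @export
read_mapping_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write templates or primers as FASTA
#'
#' Ids are the record ids; descriptions carry the variant triple.
#'
#' @param x A `template_set` or `primer_set`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_design_fasta <- function(x, path) {
  if (inherits(x, "template_set")) {
    seqs <- x$sequence
    ids <- paste0(x$template_id, " triple=", x$triple,
                  " recognition=", x$recognition_seq)
  } else {
    seqs <- x$core
    ids <- paste0(x$primer_id, " triple=", x$triple)
  }
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Registry of the experimental template and primer pools
#'
#' Template pools A-E and primer pools 1/9/10/27/64 with their relative
#' concentrations: A is the single original template; B is all ten templates
#' equimolar; C down-weights ST0 to 10%; D and E are two-fold dilution
#' series over the 3' and M single-mismatch template sets.
#'
#' @return A named list with elements `templates` and `primers`, each a list
#'   of named relative-concentration vectors.
#' @export
pool_registry <- function() {
  st <- function(i) paste0("ST", i)
  v <- function(i) paste0("V", i)
  list(
    templates = list(
      A = c(ST0 = 1),
      B = stats::setNames(rep(1, 10), st(0:9)),
      C = stats::setNames(c(0.1, rep(1, 9)), st(0:9)),
      D = c(ST0 = 1, ST7 = 2, ST9 = 4, ST8 = 8),
      E = c(ST0 = 1, ST5 = 2, ST4 = 4, ST6 = 8)
    ),
    primers = list(
      `1` = c(V0 = 1),
      `9` = stats::setNames(rep(1, 9), v(1:9)),
      `10` = stats::setNames(rep(1, 10), v(0:9)),
      `27` = stats::setNames(rep(1, 27), v(10:36)),
      `64` = stats::setNames(rep(1, 64), v(0:63))
    )
  )
}

#' Construct a pool specification
#'
#' @param pool_id Pool tag. Looked up in the bundled registry when `members`
#'   is not given (template pools by letter, primer pools by size).
#' @param members Optional member ids.
#' @param concentrations Optional positive relative concentrations, recycled
#'   to `length(members)`; equimolar by default.
#' @param kind "templates" or "primers"; used only for registry lookup.
#' @return A `pool_spec` list with `pool_id`, `members`, `concentrations`
#'   and normalized `proportions`.
#' @export
make_pool <- function(pool_id, members = NULL, concentrations = NULL,
                      kind = c("templates", "primers")) {
  kind <- match.arg(kind)
  if (is.null(members)) {
    reg <- pool_registry()[[kind]]
    if (!pool_id %in% names(reg)) {
      stop("unknown ", kind, " pool id: ", pool_id, call. = FALSE)
    }
    conc <- reg[[pool_id]]
    members <- names(conc)
    concentrations <- unname(conc)
  } else {
    if (is.null(concentrations)) concentrations <- rep(1, length(members))
    concentrations <- rep_len(concentrations, length(members))
  }
  if (length(members) == 0L) stop("empty pool", call. = FALSE)
  if (anyDuplicated(members)) stop("duplicate pool members", call. = FALSE)
  if (any(concentrations <= 0)) {
    stop("pool concentrations must be strictly positive", call. = FALSE)
  }
  structure(list(pool_id = pool_id, members = members,
                 concentrations = concentrations,
                 proportions = stats::setNames(
                   concentrations / sum(concentrations), members)),
            class = "pool_spec")
}

#' The default design space
#'
#' Ten templates and 64 primers built around the reference forward priming
#' site `GGACTACCAGGGTATCTAAT` (variant bases C/T/A at the -14/-8/-2
#' positions). Templates ST1-ST9 carry the variant triples of primers
#' V1-V9, so each is a single mismatch away from V0; V1-V6 follow the
#' published base assignments (5': G,T,A; M: A,C,G) and V7-V9 take the 3'
#' alternatives alphabetically. The template interior outside the priming
#' sites and recognition window is seeded random sequence shared by all
#' templates; the amplicon spans 250 nt so that merged 2 x 153 reads cover
#' it.
#'
#' @param n_templates Number of templates (<= 64).
#' @param amplicon_length Total template length from forward to reverse
#'   site.
#' @param recognition_offset,recognition_length Recognition window
#'   placement (1-based offset from the forward-site start).
#' @param min_hamming Minimum pairwise Hamming distance between recognition
#'   sequences.
#' @param seed Seed for the recognition set and neutral interior. The
#'   default fixes the design as a package constant.
#' @return A list with `spec`, `templates`, `primers`, `space`.
#' @export
default_design <- function(n_templates = 10L, amplicon_length = 250L,
                           recognition_offset = 99L,
                           recognition_length = 12L, min_hamming = 4L,
                           seed = 806L) {
  spec <- variant_spec()
  base_core <- "GGACTACCAGGGTATCTAAT"
  overrides <- c(V1 = "GTA", V2 = "TTA", V3 = "ATA",
                 V4 = "CAA", V5 = "CCA", V6 = "CGA",
                 V7 = "CTC", V8 = "CTG", V9 = "CTT")
  primers <- enumerate_primer_variants(base_core, spec,
                                       id_overrides = overrides)
  if (n_templates > nrow(primers)) {
    stop("cannot build more templates than primer variants", call. = FALSE)
  }
  interior <- with_seed(seed, random_dna(amplicon_length - nchar(base_core)))
  base_sequence <- paste0(base_core, interior)
  recog <- generate_recognition_set(n_templates, recognition_length,
                                    min_hamming, seed = derive_seed(seed, 1))
  templates <- build_template_set(base_sequence,
                                  primers$triple[seq_len(n_templates)],
                                  recog, recognition_offset, spec)
  list(spec = spec, templates = templates, primers = primers,
       space = interaction_space(templates, primers, spec))
}
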