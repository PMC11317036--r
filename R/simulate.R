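# Two amplification regimes over the design space. DePCR: two cycles of
# linear copying in which the primer annealing to the source template is
# recorded in the product. Standard PCR: exponential amplification in which
# primers anneal to copies whose priming site carries the triple of the
# primer that created the copy's lineage ("scrambling").

#' Annealing-efficiency model
#'
#' Per-mismatch penalties in (0, 1], keyed by variant-position label and
#' annealing temperature, optionally refined by base pairing. A profile's
#' efficiency is the product of its entries' penalties (perfect match = 1);
#' the multiplicative composition is a model assumption, overridable by
#' supplying a custom penalty table.
#'
#' @param fallback data.frame with columns `label`, `temperature`,
#'   `penalty`: the positional penalty used when no pairing-specific entry
#'   exists.
#' @param pairing Optional data.frame with columns `label`, `temperature`,
#'   `pairing`, `penalty` for pairing-specific overrides.
#' @return An `efficiency_model` object.
#' @export
efficiency_model <- function(fallback, pairing = NULL) {
  stopifnot(all(c("label", "temperature", "penalty") %in% names(fallback)))
  if (any(fallback$penalty <= 0) || any(fallback$penalty > 1) ||
      (!is.null(pairing) && (any(pairing$penalty <= 0) || any(pairing$penalty > 1)))) {
    stop("penalties must lie in (0, 1]", call. = FALSE)
  }
  structure(list(fallback = fallback, pairing = pairing),
            class = "efficiency_model")
}

#' Default penalty calibration
#'
#' Head-to-head competition between a perfect-match primer and a single
#' mismatch primer at equimolar input estimates the penalty directly as the
#' mismatch-to-match ratio. The defaults take the midpoints of the measured
#' ranges: 5' 0.65 at 45 C / 0.21 at 55 C; middle 0.54 / 0.155 with the
#' poorly tolerated C-A pairing overridden to 0.36 / 0.10; 3' 0.13 / 0.01.
#'
#' @return An [efficiency_model()].
#' @export
default_efficiency_model <- function() {
  fallback <- data.frame(
    label = rep(c("5p", "M", "3p"), each = 2L),
    temperature = rep(c(45, 55), 3L),
    penalty = c(0.65, 0.21, 0.54, 0.155, 0.13, 0.01))
  pairing <- data.frame(label = "M", temperature = c(45, 55),
                        pairing = "C-A", penalty = c(0.36, 0.10))
  efficiency_model(fallback, pairing)
}

#' Annealing efficiency of a mismatch profile
#'
#' @param profile A [mismatch_profile()] data.frame.
#' @param temperature Annealing temperature in degrees C.
#' @param model An [efficiency_model()].
#' @return Efficiency in (0, 1]; 1 for an empty profile.
#' @export
annealing_efficiency <- function(profile, temperature,
                                 model = default_efficiency_model()) {
  if (!temperature %in% model$fallback$temperature) {
    stop("temperature ", temperature,
         " C is not calibrated in the efficiency model", call. = FALSE)
  }
  if (nrow(profile) == 0L) return(1)
  pen <- numeric(nrow(profile))
  for (i in seq_len(nrow(profile))) {
    p <- NA_real_
    if (!is.null(model$pairing)) {
      hit <- model$pairing$label == profile$label[i] &
        model$pairing$temperature == temperature &
        model$pairing$pairing == profile$pairing[i]
      if (any(hit)) p <- model$pairing$penalty[which(hit)[1]]
    }
    if (is.na(p)) {
      hit <- model$fallback$label == profile$label[i] &
        model$fallback$temperature == temperature
      if (!any(hit)) {
        stop("no penalty for position label '", profile$label[i],
             "' at ", temperature, " C", call. = FALSE)
      }
      p <- model$fallback$penalty[which(hit)[1]]
    }
    pen[i] <- p
  }
  prod(pen)
}

#' Efficiencies for every pair of an interaction space
#'
#' @param space An [interaction_space()] (or subset).
#' @param temperature Annealing temperature.
#' @param model An [efficiency_model()].
#' @return Named numeric vector (names = `pair_id`).
#' @export
pair_efficiencies <- function(space, temperature,
                              model = default_efficiency_model()) {
  stats::setNames(
    vapply(space$profile, annealing_efficiency, numeric(1),
           temperature = temperature, model = model),
    space$pair_id)
}

# mismatch profile between a primer triple and a molecule's site triple
triple_profile <- function(primer_triple, site_triple, spec) {
  pb <- strsplit(primer_triple, "", fixed = TRUE)[[1]]
  tb <- strsplit(site_triple, "", fixed = TRUE)[[1]]
  hit <- pb != tb
  data.frame(label = spec$labels[hit], offset = spec$offsets[hit],
             position = rep(NA_integer_, sum(hit)), primer_base = pb[hit],
             template_base = tb[hit], pairing = pairing_key(pb[hit], tb[hit]),
             stringsAsFactors = FALSE)
}

#' Simulation run configuration
#'
#' @param method "depcr" or "standard".
#' @param temperature Annealing temperature in degrees C (default design:
#'   45 or 55).
#' @param cycles Amplification cycles; defaults to 2 locus-specific linear
#'   cycles for DePCR and 28 for standard PCR.
#' @param scrambling_mode How primers anneal to copies in standard PCR:
#'   "neutral" (mismatch-independent, probability proportional to primer
#'   proportion) or "penalized" (efficiency model applied to the primer vs
#'   site-triple profile).
#' @param per_base_error_rate Substitution probability per emitted base,
#'   modelling polymerase plus sequencing error.
#' @param reads_per_replicate Reads emitted per technical replicate.
#' @param n_replicates Technical replicates (default 8).
#' @param seed Root seed; per-replicate streams are derived with
#'   [derive_seed()].
#' @param q_high,q_low,low_quality_fraction Two-tier read-quality model:
#'   a `low_quality_fraction` of reads get constant Phred `q_low`, the rest
#'   `q_high`.
#' @param debug_ids Append the true (primer, template) pair to read ids for
#'   round-trip testing.
#' @return A `run_config` list.
#' @export
run_config <- function(method = c("depcr", "standard"), temperature = 55,
                       cycles = NULL,
                       scrambling_mode = c("neutral", "penalized"),
                       per_base_error_rate = 0, reads_per_replicate = 20000L,
                       n_replicates = 8L, seed = 1L, q_high = 37L,
                       q_low = 12L, low_quality_fraction = 0,
                       debug_ids = FALSE) {
  method <- match.arg(method)
  scrambling_mode <- match.arg(scrambling_mode)
  if (is.null(cycles)) cycles <- if (method == "depcr") 2L else 28L
  stopifnot(cycles >= 1L, per_base_error_rate >= 0,
            per_base_error_rate <= 1, reads_per_replicate >= 1L,
            n_replicates >= 1L, low_quality_fraction >= 0,
            low_quality_fraction <= 1)
  structure(list(method = method, temperature = temperature,
                 cycles = as.integer(cycles),
                 scrambling_mode = scrambling_mode,
                 per_base_error_rate = per_base_error_rate,
                 reads_per_replicate = as.integer(reads_per_replicate),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), q_high = as.integer(q_high),
                 q_low = as.integer(q_low),
                 low_quality_fraction = low_quality_fraction,
                 debug_ids = isTRUE(debug_ids)),
            class = "run_config")
}

new_interaction_matrix <- function(counts, metadata) {
  structure(counts, metadata = metadata,
            class = c("interaction_matrix", class(counts)))
}

#' @export
print.interaction_matrix <- function(x, ...) {
  md <- attr(x, "metadata")
  cat("interaction_matrix:", nrow(x), "replicates x", ncol(x), "pairs\n")
  if (!is.null(md$method)) {
    cat("  method:", md$method, " temperature:", md$temperature, "C\n")
  }
  cat("  total counts:", sum(x), "\n")
  invisible(x)
}

#' Metadata of an interaction matrix
#'
#' @param x An `interaction_matrix`.
#' @return The metadata list (method, temperature, pools, rarefaction depth,
#'   read-status accounting) carried with the matrix.
#' @export
matrix_metadata <- function(x) attr(x, "metadata")

design_pairs_of <- function(space, template_pool, primer_pool) {
  sel <- space$primer_id %in% primer_pool$members &
    space$template_id %in% template_pool$members
  space[sel, , drop = FALSE]
}

#' Simulate DePCR linear copying
#'
#' Each copy event pairs one source-template molecule with one primer,
#' sampled with probability proportional to template proportion x primer
#' proportion x annealing efficiency. The recorded (primer, template) pair
#' is fixed at the copy event; the later exponential stage only amplifies
#' barcoded products and cannot alter it, so the event counts are the final
#' read-class counts (only error injection at emission can corrupt them).
#'
#' @param template_pool,primer_pool [make_pool()] specifications.
#' @param temperature Annealing temperature in degrees C.
#' @param config A [run_config()].
#' @param space An [interaction_space()].
#' @param model An [efficiency_model()].
#' @return An `interaction_matrix` of per-replicate counts over
#'   (primer, template) pairs.
#' @export
simulate_depcr <- function(template_pool, primer_pool, temperature, config,
                           space, model = default_efficiency_model()) {
  sub <- design_pairs_of(space, template_pool, primer_pool)
  if (nrow(sub) == 0L) stop("pools select no pairs from the space",
                            call. = FALSE)
  eff <- pair_efficiencies(sub, temperature, model)
  prob <- template_pool$proportions[sub$template_id] *
    primer_pool$proportions[sub$primer_id] * eff
  if (all(prob == 0)) stop("all annealing efficiencies are zero",
                           call. = FALSE)
  counts <- matrix(0L, config$n_replicates, nrow(sub),
                   dimnames = list(paste0("rep", seq_len(config$n_replicates)),
                                   sub$pair_id))
  for (r in seq_len(config$n_replicates)) {
    counts[r, ] <- with_seed(derive_seed(config$seed, r),
                             stats::rmultinom(1L, config$reads_per_replicate,
                                              prob)[, 1L])
  }
  new_interaction_matrix(counts, list(
    method = "depcr", temperature = temperature,
    template_pool = template_pool$pool_id, primer_pool = primer_pool$pool_id,
    cycles = config$cycles, seed = config$seed,
    expected_prob = prob / sum(prob)))
}

#' Simulate standard exponential PCR
#'
#' Deterministic expected-value propagation of molecule classes
#' (origin template x current site triple), with multinomial read sampling
#' at the end. In every cycle the original templates are linearly copied
#' with the same efficiency rule as DePCR; from cycle 3 onward primers also
#' anneal to copies, whose forward-site state equals the variant triple of
#' the primer that created the lineage's most recent forward strand. Copy
#' priming is mismatch-independent in `scrambling_mode = "neutral"` and
#' efficiency-weighted against the copy's site triple in "penalized" mode.
#' Primer concentrations are treated as non-limiting. Emitted reads report
#' (primer implied by the current site triple, origin template).
#'
#' @inheritParams simulate_depcr
#' @param return_trajectory Also return the per-cycle primer-usage
#'   distribution (as attribute `trajectory`).
#' @return An `interaction_matrix` of per-replicate counts.
#' @export
simulate_standard_pcr <- function(template_pool, primer_pool, temperature,
                                  config, space,
                                  model = default_efficiency_model(),
                                  return_trajectory = FALSE) {
  sub <- design_pairs_of(space, template_pool, primer_pool)
  if (nrow(sub) == 0L) stop("pools select no pairs from the space",
                            call. = FALSE)
  spec <- attr(space, "spec")
  primers <- attr(space, "primers")
  primers <- primers[primers$primer_id %in% primer_pool$members, ,
                     drop = FALSE]
  tmpl_ids <- template_pool$members
  prim_ids <- primers$primer_id
  p <- unname(primer_pool$proportions[prim_ids])
  tprop <- unname(template_pool$proportions[tmpl_ids])
  J <- length(tmpl_ids); P <- length(prim_ids)

  # efficiency of primer i against original template j
  eff <- pair_efficiencies(sub, temperature, model)
  E_orig <- matrix(0, J, P, dimnames = list(tmpl_ids, prim_ids))
  E_orig[cbind(match(sub$template_id, tmpl_ids),
               match(sub$primer_id, prim_ids))] <- eff
  w_orig <- (tprop %o% p) * E_orig
  if (all(w_orig == 0)) stop("all annealing efficiencies are zero",
                             call. = FALSE)

  # primer-to-copy transition: column = priming primer, row = site triple of
  # the copy being primed (identified with the primer that stamped it)
  if (config$scrambling_mode == "neutral") {
    W <- matrix(rep(p, each = P), P, P)
  } else {
    W <- matrix(0, P, P)
    for (s in seq_len(P)) {
      for (i in seq_len(P)) {
        prof <- triple_profile(primers$triple[i], primers$triple[s], spec)
        W[s, i] <- p[i] * annealing_efficiency(prof, temperature, model)
      }
    }
  }

  C <- matrix(0, J, P, dimnames = list(tmpl_ids, prim_ids))
  traj <- matrix(NA_real_, config$cycles, P,
                 dimnames = list(NULL, prim_ids))
  for (cyc in seq_len(config$cycles)) {
    additions <- w_orig
    if (cyc >= 3L) additions <- additions + C %*% W
    C <- C + additions
    traj[cyc, ] <- colSums(C) / sum(C)
  }

  prob <- as.vector(t(C))  # pair order: primer varies within template
  ids <- as.vector(t(outer(tmpl_ids, prim_ids,
                           function(t, i) paste0(i, ":", t))))
  keep <- ids %in% sub$pair_id
  prob <- prob[keep]; ids <- ids[keep]
  counts <- matrix(0L, config$n_replicates, length(ids),
                   dimnames = list(paste0("rep", seq_len(config$n_replicates)),
                                   ids))
  for (r in seq_len(config$n_replicates)) {
    counts[r, ] <- with_seed(derive_seed(config$seed, r),
                             stats::rmultinom(1L, config$reads_per_replicate,
                                              prob)[, 1L])
  }
  out <- new_interaction_matrix(counts, list(
    method = "standard", temperature = temperature,
    template_pool = template_pool$pool_id, primer_pool = primer_pool$pool_id,
    cycles = config$cycles, scrambling_mode = config$scrambling_mode,
    seed = config$seed, expected_prob = prob / sum(prob)))
  if (return_trajectory) attr(out, "trajectory") <- traj
  out
}

#' Inject substitution errors into sequences
#'
#' Independent per-base substitution to a uniformly chosen different base.
#'
#' @param sequences Character vector of reads.
#' @param per_base_rate Substitution probability in `[0, 1]`.
#' @param seed Optional seed (deterministic output for a fixed seed).
#' @param positions Optional integer vector restricting which positions are
#'   error-eligible (used for standard-PCR reads whose primer region is the
#'   oligo itself and carries no copy errors).
#' @return Character vector of mutated sequences.
#' @export
apply_errors <- function(sequences, per_base_rate, seed = NULL,
                         positions = NULL) {
  stopifnot(per_base_rate >= 0, per_base_rate <= 1)
  if (per_base_rate == 0 || length(sequences) == 0L) return(sequences)
  with_seed(seed, {
    out <- sequences
    widths <- nchar(sequences)
    for (i in seq_along(out)) {
      elig <- if (is.null(positions)) seq_len(widths[i]) else
        positions[positions <= widths[i]]
      m <- length(elig)
      if (m == 0L) next
      k <- stats::rbinom(1L, m, per_base_rate)
      if (k == 0L) next
      at <- if (k == m) elig else sample(elig, k)
      ch <- strsplit(out[i], "", fixed = TRUE)[[1]]
      ch[at] <- vapply(ch[at], function(b)
        sample(setdiff(DNA_ALPHABET, b), 1L), character(1))
      out[i] <- paste(ch, collapse = "")
    }
    out
  })
}

phred_string <- function(q, width) {
  strrep(rawToChar(as.raw(q + 33L)), width)
}

#' Emit merged reads for simulated interaction counts
#'
#' Builds one merged read per counted event: the primer core followed by the
#' template body downstream of the forward priming site, so reads start at
#' the priming site and span the amplicon. Error injection depends on the
#' method: DePCR primer regions are copies and receive errors like the rest
#' of the read; standard-PCR primer regions are the input oligos and are
#' emitted error-free.
#'
#' @param mat An `interaction_matrix` from a simulator.
#' @param design A design list from [default_design()] (needs `templates`
#'   and `primers`).
#' @param config The [run_config()] used for the simulation.
#' @param out_dir Optional directory; when given, one FASTQ per replicate is
#'   written and paths are returned in the result's `files` attribute.
#' @return A named list of per-replicate read data.frames with columns
#'   `read_id`, `sequence`, `quality`, `replicate_id`.
#' @export
emit_reads <- function(mat, design, config, out_dir = NULL) {
  templates <- design$templates
  primers <- design$primers
  fw <- attr(templates, "forward_width")
  bodies <- stats::setNames(substr(templates$sequence, fw + 1L,
                                   nchar(templates$sequence)),
                            templates$template_id)
  cores <- stats::setNames(primers$core, primers$primer_id)
  pair_primer <- sub(":.*$", "", colnames(mat))
  pair_template <- sub("^.*:", "", colnames(mat))
  method <- matrix_metadata(mat)$method
  files <- character(0)
  out <- vector("list", nrow(mat))
  names(out) <- rownames(mat)
  for (r in seq_len(nrow(mat))) {
    cnt <- mat[r, ]
    idx <- rep(seq_along(cnt), cnt)
    seqs <- paste0(cores[pair_primer[idx]], bodies[pair_template[idx]])
    n <- length(seqs)
    rid <- sprintf("%s_read%06d", rownames(mat)[r], seq_len(n))
    if (config$debug_ids) rid <- paste0(rid, "|", colnames(mat)[idx])
    emit_seed <- derive_seed(config$seed, 10000L + r)
    if (config$per_base_error_rate > 0 && n > 0L) {
      pos <- if (method == "standard" && n > 0L)
        seq.int(fw + 1L, nchar(seqs[1])) else NULL
      seqs <- apply_errors(seqs, config$per_base_error_rate,
                           seed = emit_seed, positions = pos)
    }
    q <- rep(config$q_high, n)
    if (config$low_quality_fraction > 0 && n > 0L) {
      low <- with_seed(derive_seed(config$seed, 20000L + r),
                       stats::runif(n) < config$low_quality_fraction)
      q[low] <- config$q_low
    }
    quals <- vapply(seq_len(n), function(i) phred_string(q[i], nchar(seqs[i])),
                    character(1))
    reads <- data.frame(read_id = rid, sequence = seqs, quality = quals,
                        replicate_id = rownames(mat)[r],
                        stringsAsFactors = FALSE)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(out_dir, paste0(rownames(mat)[r], ".fastq"))
      write_fastq(reads, f)
      files <- c(files, f)
    }
    out[[r]] <- reads
  }
  if (length(files)) attr(out, "files") <- files
  out
}

#' Split merged reads into a simulated read pair
#'
#' Convenience for exercising the overlap merger: R1 is the first
#' `read_length` bases, R2 the reverse complement of the last
#' `read_length` bases.
#'
#' @param reads A read data.frame (from [emit_reads()]).
#' @param read_length Per-mate read length (default 153).
#' @return A list with elements `r1` and `r2`.
#' @export
split_read_pairs <- function(reads, read_length = 153L) {
  len <- nchar(reads$sequence)
  if (any(2L * read_length < len)) {
    stop("mates of length ", read_length,
         " cannot cover the amplicon with an overlap", call. = FALSE)
  }
  r1 <- reads
  r1$sequence <- substr(reads$sequence, 1L, read_length)
  r1$quality <- substr(reads$quality, 1L, read_length)
  r2 <- reads
  r2$sequence <- reverse_complement(substr(reads$sequence,
                                           len - read_length + 1L, len))
  r2$quality <- vapply(substr(reads$quality, len - read_length + 1L, len),
                       function(q) paste(rev(strsplit(q, "")[[1]]),
                                         collapse = ""),
                       character(1), USE.NAMES = FALSE)
  list(r1 = r1, r2 = r2)
}

#' Write reads as FASTQ
#'
#' @param reads Read data.frame with `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- reads$read_id
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}
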