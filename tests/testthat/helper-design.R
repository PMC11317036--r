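# Shared fixtures built in code. The default design is deterministic, so it
# is built once per test run.

.fixtures <- new.env(parent = emptyenv())

test_design <- function() {
  if (is.null(.fixtures$design)) .fixtures$design <- default_design()
  .fixtures$design
}

# independent classifier oracle: scan every mapping-file combination
brute_force_classify <- function(sequences, space) {
  fw <- attr(space, "forward_width")
  ro <- attr(space, "recognition_offset")
  re <- ro + attr(space, "recognition_length") - 1L
  out <- rep(NA_character_, length(sequences))
  for (k in seq_len(nrow(space))) {
    hit <- substr(sequences, 1L, fw) == space$primer_core[k] &
      substr(sequences, ro, re) == space$recognition_seq[k]
    out[hit] <- space$pair_id[k]
  }
  out
}

# Welch statistics from the textbook formulas, independent of stats::t.test
welch_by_hand <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# one-way ANOVA F from the sum-of-squares identities
anova_f_by_hand <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

# read data.frame from raw sequences, constant quality
make_reads <- function(sequences, q = 37L, replicate_id = "rep1") {
  data.frame(
    read_id = sprintf("r%04d", seq_along(sequences)),
    sequence = sequences,
    quality = vapply(nchar(sequences), function(w)
      strrep(rawToChar(as.raw(q + 33L)), w), character(1)),
    replicate_id = replicate_id, stringsAsFactors = FALSE)
}

substitute_base <- function(sequence, at, base) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ch[at] <- base
  paste(ch, collapse = "")
}
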