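test_that("quality filter keeps reads at or above the mean threshold", {
  reads <- make_reads(rep(strrep("A", 10L), 3L))
  reads$quality <- c(strrep(rawToChar(as.raw(40L + 33L)), 10L),
                     strrep(rawToChar(as.raw(10L + 33L)), 10L),
                     paste0(strrep(rawToChar(as.raw(15L + 33L)), 5L),
                            strrep(rawToChar(as.raw(25L + 33L)), 5L)))
  expect_equal(mean_quality(reads$quality), c(40, 10, 20))
  kept <- quality_filter(reads, 20)
  expect_equal(kept$read_id, reads$read_id[c(1, 3)])  # mean == 20 retained
  expect_equal(attr(kept, "n_dropped"), 1L)
})

test_that("read pairs merge by best gap-free overlap", {
  d <- test_design()
  tp <- make_pool("A", kind = "templates")
  pp <- make_pool("1", kind = "primers")
  rc <- run_config("depcr", 55, n_replicates = 1L,
                   reads_per_replicate = 30L, seed = 12L)
  sim <- simulate_depcr(tp, pp, 55, rc, d$space)
  reads <- emit_reads(sim, d, rc)[[1]]
  pair <- split_read_pairs(reads, 153L)
  merged <- merge_pairs(pair$r1, pair$r2)
  expect_equal(nrow(merged), 30L)
  expect_equal(merged$sequence, reads$sequence)
  expect_equal(attr(merged, "n_unmerged"), 0L)

  # non-overlapping pair is dropped and counted
  r1 <- make_reads(strrep("A", 40L))
  r2 <- make_reads(strrep("C", 40L))  # rc = G..., no overlap with A...
  dropped <- merge_pairs(r1, r2, min_overlap = 10L,
                         max_overlap_mismatch_fraction = 0)
  expect_equal(nrow(dropped), 0L)
  expect_equal(attr(dropped, "n_unmerged"), 1L)

  # disagreement resolved toward the higher-quality base
  amplicon <- "GATTACCGTAGCGCATTGCAACGGTCATCTAGGCTAGTCA"
  r1 <- make_reads(substr(amplicon, 1L, 30L), q = 40L)
  mate2 <- reverse_complement(substr(amplicon, 11L, 40L))
  # mate2 position 30 reads amplicon position 11; corrupt it at low quality
  r2 <- make_reads(substitute_base(mate2, 30L, "A"), q = 10L)
  # r2's corrupted base sits at amplicon position 11, inside the overlap
  m <- merge_pairs(r1, r2, min_overlap = 5L)
  expect_equal(substr(m$sequence, 11L, 11L), substr(amplicon, 11L, 11L))
  expect_equal(m$sequence, amplicon)

  expect_error(merge_pairs(make_reads("ACGT"),
                           make_reads(c("ACGT", "ACGT"))), "ids")
})

test_that("linker prefixes are trimmed when present", {
  linker <- "ACACTGACGACATGGTTCTACA"
  reads <- make_reads(c(paste0(linker, "ACGTACGT"), "ACGTACGT"))
  trimmed <- trim_linker(reads)
  expect_equal(trimmed$sequence, c("ACGTACGT", "ACGTACGT"))
  expect_equal(nchar(trimmed$quality), c(8L, 8L))
})

test_that("exact-match classification distinguishes the two modes", {
  d <- test_design()
  v0 <- d$primers$core[d$primers$primer_id == "V0"]
  st0 <- d$templates[d$templates$template_id == "ST0", ]
  body <- substr(st0$sequence, 21L, 250L)
  clean <- paste0(v0, body)

  asn <- classify_reads(make_reads(clean), d$space)
  expect_equal(asn$status, "assigned")
  expect_equal(asn$primer_id, "V0")
  expect_equal(asn$template_id, "ST0")

  # substitution at a non-variant primer base: full-primer mode rejects,
  # variant-positions mode accepts
  corrupted <- substitute_base(clean, 2L, "T")
  full <- classify_reads(make_reads(corrupted), d$space)
  expect_equal(full$status, "unassigned_primer")
  expect_true(is.na(full$primer_id))
  var <- classify_reads(make_reads(corrupted), d$space,
                        mode = "variant_positions")
  expect_equal(var$status, "assigned")
  expect_equal(var$primer_id, "V0")

  # unknown recognition window
  bad_rec <- substitute_base(clean, 100L,
                             setdiff(c("A", "C", "G", "T"),
                                     substr(clean, 100L, 100L))[1])
  expect_equal(classify_reads(make_reads(bad_rec), d$space)$status,
               "unassigned_recognition")

  # short read cannot reach the recognition window
  expect_equal(classify_reads(make_reads(substr(clean, 1L, 60L)),
                              d$space)$status,
               "unassigned_recognition")

  # a legal pair outside the experiment design is excluded
  design_pairs <- d$space[d$space$pair_id == "V1:ST0", ]
  out <- classify_reads(make_reads(clean), d$space,
                        design_pairs = design_pairs)
  expect_equal(out$status, "excluded_not_in_design")
  expect_true(is.na(out$primer_id))

  # quality filtering takes precedence
  lowq <- make_reads(clean, q = 10L)
  expect_equal(classify_reads(lowq, d$space, min_mean_quality = 20)$status,
               "filtered_quality")
})

test_that("indexed classification equals a brute-force mapping scan", {
  d <- test_design()
  set.seed(314)
  n <- 10000L
  pairs <- d$space[sample.int(640L, n, replace = TRUE), ]
  seqs <- truth_references(pairs$pair_id, d)
  seqs <- apply_errors(seqs, 0.02, seed = 314L)  # many near-miss reads
  reads <- make_reads(seqs)

  asn <- classify_reads(reads, d$space)
  oracle <- brute_force_classify(seqs, d$space)
  got <- ifelse(asn$status == "assigned",
                paste0(asn$primer_id, ":", asn$template_id), NA_character_)
  expect_identical(got, oracle)
})

test_that("matrix construction conserves reads across statuses", {
  d <- test_design()
  v0 <- d$primers$core[d$primers$primer_id == "V0"]
  st0 <- d$templates[d$templates$template_id == "ST0", ]
  clean <- paste0(v0, substr(st0$sequence, 21L, 250L))
  reads <- make_reads(rep(clean, 100L))
  asn <- classify_reads(reads, d$space)
  mat <- build_interaction_matrix(asn, d$space)
  expect_equal(unname(mat[1, "V0:ST0"]), 100L)
  expect_equal(sum(mat), 100L)

  # mixed statuses: matrix total plus per-status totals equal input count
  mixed <- rbind(reads[1:40, ],
                 make_reads(substitute_base(clean, 2L, "T"))[rep(1, 30), ],
                 make_reads(substr(clean, 1L, 50L))[rep(1, 30), ])
  asn2 <- classify_reads(mixed, d$space, min_mean_quality = 20)
  mat2 <- build_interaction_matrix(asn2, d$space)
  sc <- matrix_metadata(mat2)$status_counts
  expect_equal(sum(mat2) + sum(sc[names(sc) != "assigned"]), nrow(mixed))
  expect_equal(unname(sc["assigned"]), sum(mat2))
})

test_that("simulator-to-classifier round trip is exact at zero error", {
  d <- test_design()
  tp <- make_pool("B", kind = "templates")
  pp <- make_pool("10", kind = "primers")
  rc <- run_config("depcr", 45, n_replicates = 2L,
                   reads_per_replicate = 3000L, seed = 21L)
  sim <- simulate_depcr(tp, pp, 45, rc, d$space)
  reads <- do.call(rbind, emit_reads(sim, d, rc))
  design_pairs <- d$space[d$space$pair_id %in% colnames(sim), ]
  asn <- classify_reads(reads, d$space, design_pairs = design_pairs)
  mat <- build_interaction_matrix(asn, d$space, design_pairs)
  expect_equal(unclass(mat)[rownames(sim), colnames(sim)],
               unclass(sim)[, ], ignore_attr = TRUE)
})

test_that("rarefaction subsamples rows to depth without replacement", {
  d <- test_design()
  tp <- make_pool("B", kind = "templates")
  pp <- make_pool("10", kind = "primers")
  rc <- run_config("depcr", 45, n_replicates = 3L,
                   reads_per_replicate = 14000L, seed = 31L)
  sim <- simulate_depcr(tp, pp, 45, rc, d$space)
  rare <- rarefy(sim, 7000L, seed = 1L)
  expect_true(all(rowSums(rare) == 7000L))
  expect_true(all(rare <= unclass(sim)[, ]))
  expect_identical(unclass(rarefy(sim, 7000L, seed = 1L))[, ],
                   unclass(rare)[, ])

  # a row already at depth is returned unchanged
  at_depth <- matrix(c(3500L, 3500L), 1, 2,
                     dimnames = list("r1", c("a", "b")))
  expect_equal(unclass(rarefy(at_depth, 7000L))[, ], at_depth[, ])

  # short rows are dropped with a warning; all short is an error
  mixed <- rbind(unclass(sim)[, ], low = rep(1L, ncol(sim)))
  expect_warning(r2 <- rarefy(mixed, 7000L, seed = 2L), "below depth")
  expect_false("low" %in% rownames(r2))
  expect_error(suppressWarnings(rarefy(mixed["low", , drop = FALSE], 7000L)),
               "below the rarefaction depth")
})

test_that("rarefied cell values match the hypergeometric expectation", {
  row <- matrix(c(8000L, 4000L, 2000L), 1, 3,
                dimnames = list("r1", c("a", "b", "c")))
  depth <- 7000L
  total <- sum(row)
  n_seeds <- 100L
  draws <- vapply(seq_len(n_seeds), function(s)
    unclass(rarefy(row, depth, seed = s))[1, ], numeric(3))
  for (j in 1:3) {
    k <- row[1, j]
    expected <- depth * k / total
    v <- depth * (k / total) * (1 - k / total) * (total - depth) /
      (total - 1)
    se_mean <- sqrt(v / n_seeds)
    expect_lt(abs(mean(draws[j, ]) - expected), 4 * se_mean)
  }
})

test_that("margin splits conserve row totals", {
  d <- test_design()
  tp <- make_pool("B", kind = "templates")
  pp <- make_pool("64", kind = "primers")
  rc <- run_config("depcr", 45, n_replicates = 2L,
                   reads_per_replicate = 5000L, seed = 41L)
  sim <- simulate_depcr(tp, pp, 45, rc, d$space)
  m <- split_matrix(sim)
  expect_equal(ncol(m$template), 10L)
  expect_equal(ncol(m$primer), 64L)
  expect_equal(rowSums(m$template), rowSums(unclass(sim)[, ]))
  expect_equal(rowSums(m$primer), rowSums(unclass(sim)[, ]))

  single <- matrix(5L, 1, 1, dimnames = list("r", "V0:ST0"))
  ms <- split_matrix(single)
  expect_equal(unname(ms$template[1, 1]), 5L)
  expect_equal(unname(ms$primer[1, 1]), 5L)
})

test_that("interaction matrices serialize to TSV (and BIOM when available)", {
  d <- test_design()
  tp <- make_pool("A", kind = "templates")
  pp <- make_pool("10", kind = "primers")
  rc <- run_config("depcr", 45, n_replicates = 2L,
                   reads_per_replicate = 1000L, seed = 51L)
  sim <- simulate_depcr(tp, pp, 45, rc, d$space)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_interaction_matrix(sim, tsv)
  back <- utils::read.table(tsv, sep = "\t", header = TRUE,
                            check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), unclass(sim)[, ],
               ignore_attr = TRUE)
  if (requireNamespace("biomformat", quietly = TRUE)) {
    biom <- withr::local_tempfile(fileext = ".biom")
    write_interaction_matrix(sim, withr::local_tempfile(fileext = ".tsv"),
                             biom_path = biom)
    b <- biomformat::read_biom(biom)
    expect_equal(unname(as.matrix(biomformat::biom_data(b))),
                 unname(t(unclass(sim)[, ])))
  }
})
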