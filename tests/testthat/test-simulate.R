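test_that("annealing efficiency composes penalties multiplicatively", {
  model <- default_efficiency_model()
  d <- test_design()
  st0 <- d$templates[d$templates$template_id == "ST0", ]
  empty <- mismatch_profile("GGACTACCAGGGTATCTAAT", st0, d$spec)
  expect_equal(annealing_efficiency(empty, 55, model), 1)

  p3 <- mismatch_profile(d$primers[d$primers$primer_id == "V7", ], st0,
                         d$spec)
  expect_equal(annealing_efficiency(p3, 55, model), 0.01)
  p5 <- mismatch_profile(d$primers[d$primers$primer_id == "V1", ], st0,
                         d$spec)
  expect_equal(annealing_efficiency(p5, 45, model), 0.65)

  # C-A pairing override at the middle position
  pm <- mismatch_profile(d$primers[d$primers$primer_id == "V5", ], st0,
                         d$spec)
  expect_equal(annealing_efficiency(pm, 45, model), 0.36)

  both <- rbind(p5, p3)
  expect_equal(annealing_efficiency(both, 45, model), 0.65 * 0.13)
  expect_error(annealing_efficiency(p3, 60, model), "not calibrated")
})

test_that("DePCR sampling matches the closed-form event probabilities", {
  d <- test_design()
  tp <- make_pool("A", kind = "templates")
  pp <- make_pool("hh", members = c("V0", "V7"), kind = "primers")
  rc <- run_config("depcr", 55, n_replicates = 1L,
                   reads_per_replicate = 100000L, seed = 42L)
  sim <- simulate_depcr(tp, pp, 55, rc, d$space)

  # brute-force enumeration of event probabilities: t * p * e, normalized
  p <- 0.01
  expect_equal(sort(unname(matrix_metadata(sim)$expected_prob)),
               sort(c(1, p) / (1 + p)), tolerance = 1e-12)

  f <- sim[1, "V7:ST0"] / sum(sim[1, ])
  expected <- p / (1 + p)
  se <- sqrt(expected * (1 - expected) / sum(sim[1, ]))
  expect_lt(abs(f - expected), 3 * se)

  # single template + its perfect-match primer: all events are that pair
  only <- simulate_depcr(tp, make_pool("1", kind = "primers"), 55, rc,
                         d$space)
  expect_equal(unname(only[1, "V0:ST0"]), 100000L)
})

test_that("A10 DePCR mismatch ratio equals the sum of penalties", {
  d <- test_design()
  model <- default_efficiency_model()
  tp <- make_pool("A", kind = "templates")
  pp <- make_pool("10", kind = "primers")
  rc <- run_config("depcr", 45, n_replicates = 2L,
                   reads_per_replicate = 100000L, seed = 9L)
  sim <- simulate_depcr(tp, pp, 45, rc, d$space)
  sub <- d$space[d$space$template_id == "ST0" &
                   d$space$primer_id %in% pp$members, ]
  penalties <- pair_efficiencies(sub[sub$n_mismatches > 0, ], 45, model)
  expected_ratio <- sum(penalties)  # equimolar: ratio = sum of penalties
  f_exp <- expected_ratio / (1 + expected_ratio)
  for (r in 1:2) {
    ratio <- mismatch_ratio(sim[r, ], d$space)
    f <- ratio / (1 + ratio)
    se <- sqrt(f_exp * (1 - f_exp) / sum(sim[r, ]))
    expect_lt(abs(f - f_exp), 3 * se)
  }
})

test_that("head-to-head simulations recover known penalties", {
  d <- test_design()
  tp <- make_pool("A", kind = "templates")
  n <- 100000L
  cases <- list(list(primer = "V7", temp = 55, p = 0.01),
                list(primer = "V5", temp = 55, p = 0.10),
                list(primer = "V1", temp = 45, p = 0.65))
  for (cs in cases) {
    pp <- make_pool("hh", members = c("V0", cs$primer), kind = "primers")
    rc <- run_config("depcr", cs$temp, n_replicates = 1L,
                     reads_per_replicate = n, seed = 101L)
    sim <- simulate_depcr(tp, pp, cs$temp, rc, d$space)
    mm <- sum(sim[1, paste0(cs$primer, ":ST0")])
    pm <- sum(sim[1, "V0:ST0"])
    p_hat <- mm / pm
    f <- cs$p / (1 + cs$p)
    se_f <- sqrt(f * (1 - f) / n)
    se_p <- se_f / (1 - f)^2  # delta method on p = f / (1 - f)
    expect_lt(abs(p_hat - cs$p), 3 * se_p)
  }
})

test_that("standard PCR scrambles primer usage toward input proportions", {
  d <- test_design()
  tp <- make_pool("A", kind = "templates")

  # single primer: every read reports that primer
  rc1 <- run_config("standard", 55, n_replicates = 1L,
                    reads_per_replicate = 5000L, seed = 2L)
  one <- simulate_standard_pcr(tp, make_pool("1", kind = "primers"), 55,
                               rc1, d$space)
  expect_equal(unname(one[1, "V0:ST0"]), 5000L)

  # two equimolar primers, neutral mode: 50/50 within sampling error
  pp2 <- make_pool("two", members = c("V0", "V7"), kind = "primers")
  rc2 <- run_config("standard", 55, n_replicates = 1L,
                    reads_per_replicate = 100000L, seed = 3L)
  two <- simulate_standard_pcr(tp, pp2, 55, rc2, d$space)
  f <- two[1, "V0:ST0"] / sum(two[1, ])
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 1e5) + 1e-3)

  # total-variation distance to input proportions is non-increasing and
  # small after 28 cycles
  pp10 <- make_pool("10", kind = "primers")
  sim <- simulate_standard_pcr(tp, pp10, 55, rc2, d$space,
                               return_trajectory = TRUE)
  traj <- attr(sim, "trajectory")
  tv <- apply(traj, 1L, function(x) 0.5 * sum(abs(x - 0.1)))
  expect_true(all(diff(tv) <= 1e-12))
  expect_lt(tv[28], 0.02)

  # perfect-match usage approximately the input percentage (10%)
  f0 <- sim[1, "V0:ST0"] / sum(sim[1, ])
  expect_lt(abs(f0 - 0.10), 0.015)
})

test_that("substitution errors follow the binomial error model", {
  seqs <- rep(strrep("ACGT", 25L), 1000L)  # 1e5 bases
  expect_identical(apply_errors(seqs, 0), seqs)

  all_changed <- apply_errors(seqs[1:5], 1, seed = 1L)
  for (i in 1:5) {
    expect_equal(hamming_dist(seqs[i], all_changed[i]), 100L)
  }

  mutated <- apply_errors(seqs, 0.01, seed = 7L)
  n_sub <- sum(vapply(seq_along(seqs), function(i)
    hamming_dist(seqs[i], mutated[i]), integer(1)))
  n <- 1e5
  expect_lt(abs(n_sub - n * 0.01), 4 * sqrt(n * 0.01 * 0.99))

  expect_identical(apply_errors(seqs[1:50], 0.05, seed = 3L),
                   apply_errors(seqs[1:50], 0.05, seed = 3L))

  protected <- apply_errors(seqs[1:50], 0.5, seed = 5L, positions = 21:100)
  expect_true(all(substr(protected, 1L, 20L) == substr(seqs[1:50], 1L, 20L)))
})

test_that("emitted reads carry primer core and recognition window", {
  d <- test_design()
  tp <- make_pool("A", kind = "templates")
  pp <- make_pool("1", kind = "primers")
  rc <- run_config("depcr", 55, n_replicates = 2L,
                   reads_per_replicate = 50L, seed = 5L)
  sim <- simulate_depcr(tp, pp, 55, rc, d$space)
  reads <- emit_reads(sim, d, rc)
  expect_equal(names(reads), c("rep1", "rep2"))
  for (r in reads) {
    expect_equal(nrow(r), 50L)
    expect_true(all(substr(r$sequence, 1L, 20L) ==
                      d$primers$core[d$primers$primer_id == "V0"]))
    expect_true(all(substr(r$sequence, 99L, 110L) ==
                      d$templates$recognition_seq[
                        d$templates$template_id == "ST0"]))
    expect_true(all(nchar(r$sequence) == 250L))
  }

  # standard mode: primer region is the oligo itself, error-free even at
  # high error rates
  pp10 <- make_pool("10", kind = "primers")
  rc_err <- run_config("standard", 55, n_replicates = 1L,
                       reads_per_replicate = 400L,
                       per_base_error_rate = 0.2, seed = 6L)
  sim_s <- simulate_standard_pcr(tp, pp10, 55, rc_err, d$space)
  reads_s <- emit_reads(sim_s, d, rc_err)[[1]]
  expect_true(all(substr(reads_s$sequence, 1L, 20L) %in% d$primers$core))

  # DePCR mode: the primer region is a copy and does receive errors
  rc_err_d <- run_config("depcr", 55, n_replicates = 1L,
                         reads_per_replicate = 400L,
                         per_base_error_rate = 0.2, seed = 6L)
  sim_d <- simulate_depcr(tp, pp10, 55, rc_err_d, d$space)
  reads_d <- emit_reads(sim_d, d, rc_err_d)[[1]]
  expect_false(all(substr(reads_d$sequence, 1L, 20L) %in% d$primers$core))
})

test_that("FASTQ emission round-trips through Biostrings", {
  d <- test_design()
  tp <- make_pool("A", kind = "templates")
  pp <- make_pool("1", kind = "primers")
  rc <- run_config("depcr", 55, n_replicates = 1L,
                   reads_per_replicate = 20L, seed = 8L)
  sim <- simulate_depcr(tp, pp, 55, rc, d$space)
  dir <- withr::local_tempdir()
  reads <- emit_reads(sim, d, rc, out_dir = dir)
  back <- read_fastq(file.path(dir, "rep1.fastq"))
  expect_equal(back$sequence, reads$rep1$sequence)
  expect_equal(back$quality, reads$rep1$quality)
  expect_equal(back$read_id, reads$rep1$read_id)
})
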