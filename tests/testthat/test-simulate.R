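test_that("ph_response covers flat, dead and logistic shapes", {
  flat <- fitness_profile("flat", m_max = 0.6)
  expect_equal(ph_response(flat, c(4, 5.5, 9)), rep(0.6, 3))
  dead <- profile_preset("dead")
  expect_equal(ph_response(dead, 7), 0)
  # the logistic midpoint sits at half the maximal efficiency
  lg <- fitness_profile("alkaline", m_max = 0.5, ph_mid = 6.5, s = 0.4)
  expect_equal(ph_response(lg, 6.5), 0.25)
  acid <- fitness_profile("acid", m_max = 0.5, ph_mid = 6.5, s = 0.4)
  expect_equal(ph_response(acid, 6.5), 0.25)
  # mirrored pair: alkaline rises with pH, acid falls
  expect_gt(ph_response(lg, 8), ph_response(lg, 5))
  expect_lt(ph_response(acid, 8), ph_response(acid, 5))
  expect_error(ph_response(lg, 12), "out of bounds")
})

test_that("mating cycle update renormalizes survivors of selection", {
  expect_equal(mating_cycle_update(c(0.5, 0.5), c(0.25, 0.75)),
               c(0.25, 0.75))
  f <- c(0.2, 0.3, 0.5)
  expect_equal(mating_cycle_update(f, rep(0.4, 3)), f)
  out <- mating_cycle_update(c(0.5, 0.5), c(0, 0.6))
  expect_equal(out, c(0, 1))
  expect_error(mating_cycle_update(c(0.5, 0.5), c(0, 0)), "extinct")
  expect_error(mating_cycle_update(c(0.7, 0.7), c(1, 1)), "sum to 1")
})

test_that("vegetative passage compounds fitness per generation", {
  f <- c(0.5, 0.5)
  expect_equal(vegetative_passage_update(f, c(1, 1), 5), f)
  expect_equal(vegetative_passage_update(f, c(1, 2), 1), c(1/3, 2/3))
  expect_equal(vegetative_passage_update(f, c(1, 2), 0), f)
  expect_equal(vegetative_passage_update(f, c(1, 2), 2), c(0.2, 0.8))
  expect_error(vegetative_passage_update(f, c(0, 1), 1), "w > 0")
})

test_that("deterministic competition matches the closed-form trajectory", {
  lib <- subset_library(full_library, 6)
  m <- c(0.6, 0.3, 0.9, 0.05, 0.45, 0.6)
  cfg <- sim_config(cycles = 7, replicates = 2, reads_per_sample = 10,
                    drift_cells = NULL, seed = 5)
  run <- run_competition(lib, flat_profiles(lib, m), condition("SSA", 5.5),
                         cfg)
  f0 <- rep(1 / 6, 6)
  for (traj in run$trajectories) {
    expect_equal(unname(rowSums(traj)), rep(1, 8), tolerance = 1e-12)
    for (cyc in 0:7) {
      expect_equal(unname(traj[cyc + 1, ]),
                   f0 * m^cyc / sum(f0 * m^cyc), tolerance = 1e-12)
    }
  }
})

test_that("non-mating regime selects on vegetative fitness instead", {
  lib <- subset_library(full_library, 3)
  ids <- lib$variants$variant_id
  profiles <- stats::setNames(list(
    fitness_profile("flat", m_max = 0.6, w = 1),
    fitness_profile("flat", m_max = 0.6, w = 1.1),
    fitness_profile("flat", m_max = 0, w = 1)), ids)
  cfg <- sim_config(cycles = 3, replicates = 1, reads_per_sample = 10,
                    drift_cells = NULL, seed = 2, generations = 4)
  run <- run_competition(lib, profiles, condition("YEA", 5.5), cfg)
  traj <- run$trajectories[[1]]
  w <- c(1, 1.1, 1)^(4 * 3)
  expect_equal(unname(traj[4, ]), w / sum(w) , tolerance = 1e-12)
  # the mating-dead variant survives a non-mating passage
  expect_gt(traj[4, 3], 0)
})

test_that("two-variant selection increases the fitter frequency monotonically", {
  lib <- subset_library(full_library, 2)
  cfg <- sim_config(cycles = 6, replicates = 1, reads_per_sample = 10,
                    drift_cells = NULL, seed = 1)
  run <- run_competition(lib, flat_profiles(lib, c(0.7, 0.4)),
                         condition("SSA", 5.5), cfg)
  f1 <- run$trajectories[[1]][, 1]
  expect_true(all(diff(f1) > 0))
})

test_that("competition trajectories are seed-reproducible with drift", {
  lib <- subset_library(full_library, 5)
  cfg <- sim_config(cycles = 4, replicates = 2, reads_per_sample = 10,
                    drift_cells = 1e4, seed = 11)
  prof <- flat_profiles(lib, c(0.5, 0.6, 0.7, 0.4, 0.6))
  r1 <- run_competition(lib, prof, condition("SSA", 5.5), cfg)
  r2 <- run_competition(lib, prof, condition("SSA", 5.5), cfg)
  expect_identical(r1$trajectories, r2$trajectories)
  expect_equal(unname(rowSums(r1$trajectories[[1]])), rep(1, 5),
               tolerance = 1e-12)
  # replicates draw different bottlenecks
  expect_false(identical(r1$trajectories[[1]], r1$trajectories[[2]]))
})

test_that("simulated reads conserve count, layout and seed determinism", {
  freqs <- rep(1 / 20, 20)
  cfg <- sim_config(reads_per_sample = 1000, error_rate = 0, seed = 9)
  rs <- simulate_reads(freqs, small_library, cfg, "s1")
  expect_length(rs$sequences, 1000L)
  expect_equal(sum(rs$counts), 1000L)
  expect_true(all(nchar(rs$sequences) == 75L))
  # every error-free read carries its genotype barcode right after the
  # first anchor motif
  expect_equal(lookup_barcode(small_library,
                              extract_barcode(rs$sequences)),
               rs$genotype)

  rs2 <- simulate_reads(freqs, small_library, cfg, "s1")
  expect_identical(rs$sequences, rs2$sequences)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rs, f1)
  write_fastq(rs2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("read sampling recovers frequencies within the binomial bound", {
  freqs <- c(0.9, 0.1, rep(0, 18))
  n <- 1e5
  cfg <- sim_config(reads_per_sample = n, error_rate = 0, seed = 4)
  rs <- simulate_reads(freqs, small_library, cfg, "s1")
  cs <- count_sample(rs, small_library)
  f_hat <- cs$counts[[1]] / sum(cs$counts)
  expect_lt(abs(f_hat - 0.9), 3 * sqrt(0.9 * 0.1 / n))
  expect_equal(sum(cs$counts[-(1:2)]), 0L)
})
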