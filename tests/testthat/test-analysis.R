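test_that("developmental windows are normalized lifetime change", {
  g <- grid_spec()
  evo <- random_genome(g, "evo", seed = 1)
  expect_equal(window_morph(evo), 0)
  expect_equal(window_ctrl(evo), 0)

  maxdev <- make_fixture("devo-max")
  expect_equal(window_morph(maxdev), 1)

  # one mirrored pair (two voxels after expansion) changing by 1.5 cm
  one <- evo
  one$treatment <- "evodevo"
  one$ell_start[5] <- 0.25
  one$ell_final <- one$ell_start
  one$ell_final[5] <- 1.75
  expect_equal(window_morph(one), 2 * 1.5 / (48 * 1.5))

  # one voxel's phase moving by pi/2
  two <- evo
  two$treatment <- "evodevo"
  two$phi_start[30] <- 0
  two$phi_final <- two$phi_start
  two$phi_final[30] <- pi / 2
  expect_equal(window_ctrl(two), (pi / 2) / (48 * pi))

  # maximal control development
  full <- evo
  full$treatment <- "evodevo"
  full$phi_start <- rep(-pi / 2, g$n_vox)
  full$phi_final <- rep(pi / 2, g$n_vox)
  expect_equal(window_ctrl(full), 1)

  # scale-free over fuzzed genomes, any grid
  set.seed(11)
  for (i in 1:200) {
    grid <- grid_spec(sample(c(2, 3, 4), 1), sample(1:4, 1), sample(1:3, 1))
    gen <- random_genome(grid, sample(c("evo", "evodevo"), 1))
    expect_true(window_morph(gen) >= 0 && window_morph(gen) <= 1)
    expect_true(window_ctrl(gen) >= 0 && window_ctrl(gen) <= 1)
  }
})

test_that("lineage tracing recovers a known ancestor chain", {
  h <- tibble::tibble(
    generation = c(0L, 0L, 1L, 1L, 2L),
    uid = c(1L, 2L, 3L, 4L, 5L),
    parent_uid = c(NA_integer_, NA_integer_, 1L, 2L, 3L),
    age = c(0L, 0L, 1L, 1L, 2L),
    fitness = c(0.1, 0.2, 0.3, 0.25, 0.4),
    W_L = c(0, 0.1, 0.2, 0.1, 0.05),
    W_Phi = c(0, 0, 0.1, 0.2, 0.3),
    survived = TRUE)
  ln <- trace_lineage(h, champion_uid = 5L)
  expect_equal(ln$uid, c(1L, 3L, 5L))
  expect_equal(ln$fitness, c(0.1, 0.3, 0.4))
  expect_equal(ln$W_L, c(0, 0.2, 0.05))

  broken <- h[h$uid != 3L, ]
  expect_error(trace_lineage(broken, champion_uid = 5L), "broken")
})

test_that("robustness walks are seeded, cumulative, and subsystem-confined", {
  champ <- random_genome(tiny_grid(), "evodevo", seed = 17)

  w0 <- robustness_walk(champ, "control", n_steps = 0, n_walks = 3,
                        devo_cfg = tiny_devo(), phys_cfg = tiny_phys(),
                        record_interval = 0.05, seed = 1)
  expect_equal(dim(w0$fitness), c(3, 1))
  expect_equal(length(unique(w0$fitness[, 1])), 1)

  w1 <- robustness_walk(champ, "morphology", n_steps = 3, n_walks = 2,
                        devo_cfg = tiny_devo(), phys_cfg = tiny_phys(),
                        record_interval = 0.05, seed = 2)
  w2 <- robustness_walk(champ, "morphology", n_steps = 3, n_walks = 2,
                        devo_cfg = tiny_devo(), phys_cfg = tiny_phys(),
                        record_interval = 0.05, seed = 2)
  expect_identical(w1$fitness, w2$fitness)

  # mask check on the mutation operator itself: control walks leave
  # morphology untouched and vice versa, with rates frozen
  set.seed(4)
  g <- champ
  for (i in 1:25) {
    child <- mutate_genome(g, types = c("phi", "phi_final"),
                           adapt_rates = FALSE)
    expect_identical(child$ell_start, g$ell_start)
    expect_identical(child$ell_final, g$ell_final)
    expect_identical(child$rates, g$rates)
    g <- child
  }
  for (i in 1:25) {
    child <- mutate_genome(g, types = c("ell", "ell_final"),
                           adapt_rates = FALSE)
    expect_identical(child$phi_start, g$phi_start)
    expect_identical(child$phi_final, g$phi_final)
    g <- child
  }
  # under the Evo treatment only the undeveloped types are admissible
  evo <- random_genome(tiny_grid(), "evo", seed = 3)
  expect_error(mutate_genome(evo, types = c("phi", "phi_final")),
               "not applicable")
})

test_that("random morphology mutations do not improve an evolved champion", {
  cfg <- tiny_evo_config(treatment = "evodevo", pop_size = 6L,
                         generations = 12L, grid = toy_grid())
  trial <- run_trial(cfg, seed = 2)
  w <- robustness_walk(trial$champion$genome, "morphology", n_steps = 8,
                       n_walks = 3, devo_cfg = tiny_devo(),
                       phys_cfg = tiny_phys(), record_interval = 0.05,
                       seed = 5)
  expect_lte(median(w$fitness[, ncol(w$fitness)]),
             median(w$fitness[, 1]) + 0.05)
})

test_that("rollover onset is measured along a lineage", {
  cfg <- tiny_evo_config(pop_size = 3L, generations = 2L)
  trial <- run_trial(cfg, seed = 9)
  ln <- trace_lineage(trial)
  out <- rollover_onset_series(ln, trial$genomes,
                               devo_cfg = tiny_devo(),
                               phys_cfg = tiny_phys(),
                               record_interval = 0.05)
  expect_equal(nrow(out), nrow(ln))
  expect_true(all(is.na(out$rollover_time) |
                  (out$rollover_time >= 0 & out$rollover_time <= 1)))

  # a passive standing cube never brings its top layer to the ground
  static_ln <- tibble::tibble(uid = 999L, generation = 0L, fitness = 0,
                              W_L = 0, W_Phi = 0)
  env <- new.env(); env[["999"]] <- make_fixture("static", grid_spec(2, 2, 2))
  quiet <- rollover_onset_series(static_ln, env,
                                 devo_cfg = tiny_devo(amplitude = 0),
                                 phys_cfg = tiny_phys(),
                                 record_interval = 0.05)
  expect_true(is.na(quiet$rollover_time))
})

test_that("Mann-Whitney U agrees with enumeration and wilcox.test", {
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)

  inter <- mann_whitney_u(c(1, 3, 5), c(2, 4, 6))
  expect_equal(inter$U, 3)

  # exact p-values match wilcox.test on tie-free samples up to n = 6
  set.seed(8)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    vals <- sample(100, n1 + n2)
    a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
    ours <- mann_whitney_u(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE,
                                               correct = FALSE))
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }

  # large samples: normal approximation stays close to the exact answer
  set.seed(9)
  a <- rnorm(30); b <- rnorm(30, 0.8)
  ours <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_false(ours$exact)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)

  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("canalization summaries tabulate window trajectories", {
  flat <- tibble::tibble(uid = 1:3, generation = 0:2,
                         fitness = c(1, 1, 1), W_L = 0.2, W_Phi = 0.1)
  s <- canalization_summary(list(flat))
  expect_equal(s$W_L_start, s$W_L_max)
  expect_equal(s$W_L_max, s$W_L_final)

  risefall <- tibble::tibble(uid = 1:5, generation = 0:4,
                             fitness = seq(0.1, 0.9, length.out = 5),
                             W_L = c(0.1, 0.3, 0.6, 0.3, 0.05),
                             W_Phi = c(0.2, 0.25, 0.2, 0.3, 0.28))
  s2 <- canalization_summary(list(risefall))
  expect_gt(s2$W_L_max, s2$W_L_start)
  expect_lt(s2$W_L_final, s2$W_L_max)
  expect_equal(s2$fitness_final, 0.9)

  evo_ln <- tibble::tibble(uid = 1:2, generation = 0:1,
                           fitness = c(0.1, 0.2), W_L = 0, W_Phi = 0)
  s3 <- canalization_summary(list(evo_ln))
  expect_true(all(c(s3$W_L_start, s3$W_L_max, s3$W_L_final) == 0))
})

test_that("development removal keeps the birth phenotype bit-identical", {
  cfg <- tiny_evo_config(treatment = "evodevo", pop_size = 4L,
                         generations = 3L)
  trials <- lapply(1:2, function(s) run_trial(cfg, seed = s))
  tab <- remove_devo_experiment(trials)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$fitness_removed >= 0))
  for (tr in trials) {
    reduced <- remove_development(tr$champion$genome)
    expect_equal(window_morph(reduced), 0)
    expect_equal(window_ctrl(reduced), 0)
    l1 <- build_lattice(tr$champion$genome, tiny_devo(), tiny_phys())
    l2 <- build_lattice(reduced, tiny_devo(), tiny_phys())
    expect_identical(l1$pos, l2$pos)
  }
})
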