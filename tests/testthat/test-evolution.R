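ind <- function(f, a) structure(list(uid = 0L, fitness = f, age = a),
                                class = "voxdev_individual")

test_that("Pareto dominance on (fitness up, age down) is a strict order", {
  expect_true(dominates(ind(2, 3), ind(1, 5)))
  expect_false(dominates(ind(2, 3), ind(3, 1)))
  expect_true(dominates(ind(3, 1), ind(2, 3)))  # better in both directions
  expect_false(dominates(ind(2, 3), ind(2, 3)))  # irreflexive
  expect_error(dominates(ind(NA, 1), ind(1, 1)), "unevaluated")

  set.seed(10)
  for (i in 1:200) {
    a <- ind(runif(1), sample(5, 1)); b <- ind(runif(1), sample(5, 1))
    cc <- ind(runif(1), sample(5, 1))
    expect_false(dominates(a, b) && dominates(b, a))  # antisymmetric
    if (dominates(a, b) && dominates(b, cc))
      expect_true(dominates(a, cc))                   # transitive
  }
})

test_that("selection matches brute-force dominance enumeration on small pools", {
  set.seed(21)
  n_stallfree <- 0
  for (rep in 1:300) {
    pool <- random_pool(sample(5:8, 1))
    target <- sample(2:(length(pool) - 1), 1)
    res <- afpo_select(pool, target)
    expect_length(res$survivors, target)

    # the best-fitness individual always survives
    best <- max(vapply(pool, `[[`, numeric(1), "fitness"))
    expect_equal(max(vapply(res$survivors, `[[`, numeric(1), "fitness")),
                 best)

    if (res$stall_deletions == 0) {
      n_stallfree <- n_stallfree + 1
      # every deletion was a dominance deletion, so by transitivity each
      # non-survivor is dominated by some survivor
      surv_uid <- vapply(res$survivors, function(p) as.numeric(p$uid), numeric(1))
      for (x in pool) {
        if (x$uid %in% surv_uid) next
        expect_true(any(vapply(res$survivors, dominates, logical(1), j = x)))
      }
      # consequently the brute-force non-dominated set survives whole
      nd <- brute_force_nondominated(pool)
      if (length(nd) <= target)
        expect_true(all(nd %in% match(surv_uid,
                                      vapply(pool, function(p) as.numeric(p$uid), numeric(1)))))
    }
  }
  expect_gt(n_stallfree, 100)  # the dominance path does most of the work
})

test_that("one AFPO generation builds the 2N+1 pool and returns N survivors", {
  cfg <- tiny_evo_config(pop_size = 4L)
  trial <- run_trial(cfg, seed = 3)
  h <- trial$history
  expect_equal(as.integer(table(h$generation)[c("1", "2")]), c(9L, 9L))  # 2*4+1
  expect_equal(sum(h$survived & h$generation == 1), 4)
  # one injected age-0 newcomer per generation
  expect_equal(sum(h$age == 0 & h$generation == 1), 1)
  # ages bounded by generation + 1
  expect_true(all(h$age <= h$generation + 1))
  # elitism: the best of each evaluated pool survives
  for (g in 1:2) {
    pool <- h[h$generation == g, ]
    expect_true(pool$survived[which.max(pool$fitness)])
  }
})

test_that("trials are deterministic and log a connected ancestry", {
  cfg <- tiny_evo_config(pop_size = 3L, generations = 1L)
  t1 <- run_trial(cfg, seed = 7)
  t2 <- run_trial(cfg, seed = 7)
  expect_identical(t1$champion$uid, t2$champion$uid)
  expect_identical(t1$champion$fitness, t2$champion$fitness)
  expect_identical(as.data.frame(t1$history), as.data.frame(t2$history))

  h <- t1$history
  expect_setequal(unique(h$generation), c(0, 1))
  known <- h$uid
  parents <- h$parent_uid[!is.na(h$parent_uid)]
  expect_true(all(parents %in% known))

  ln <- trace_lineage(t1)
  expect_lte(nrow(ln), 2)
  expect_identical(ln$uid[nrow(ln)], t1$champion$uid)
})

test_that("Evo trials never log nonzero developmental windows", {
  cfg <- tiny_evo_config(treatment = "evo", pop_size = 3L, generations = 3L)
  trial <- run_trial(cfg, seed = 5)
  expect_true(all(trial$history$W_L == 0))
  expect_true(all(trial$history$W_Phi == 0))
})

test_that("expected mutation impact has the right limits and matches simulation", {
  g <- grid_spec()
  # all types always selected at rate 1: everything mutates
  expect_equal(expected_mutation_impact(1, g, "evodevo", type_prob = 1), 1)
  # vanishing rate, conditioned on at least one change: a single parameter
  total <- 2 * g$n_left + 2 * g$n_vox
  expect_equal(expected_mutation_impact(1e-9, g, "evodevo"), 1 / total,
               tolerance = 1e-6)

  # mask-level Monte Carlo of the two-stage scheme, rejection on empty draws
  mc_impact <- function(rate, n_sites, p, n_draws) {
    counts <- matrix(0, n_draws, length(n_sites))
    for (i in seq_along(n_sites)) {
      sel <- runif(n_draws) < p
      counts[, i] <- sel * rbinom(n_draws, n_sites[i], rate)
    }
    x <- rowSums(counts)
    x <- x[x > 0]
    list(mean = mean(x) / sum(n_sites),
         se = sd(x / sum(n_sites)) / sqrt(length(x)))
  }
  set.seed(2)
  for (rate in c(1 / 48, 0.2)) {
    mc <- mc_impact(rate, c(24, 24, 48, 48), 0.5, 20000)
    expect_lt(abs(expected_mutation_impact(rate, g, "evodevo") - mc$mean),
              3 * mc$se)
  }

  # and against the real mutation operator (mid-range parent, fixed rate)
  parent <- random_genome(g, "evodevo", seed = 1)
  parent$ell_start <- rep(1, g$n_left); parent$ell_final <- rep(1, g$n_left)
  parent$phi_start <- rep(0, g$n_vox); parent$phi_final <- rep(0, g$n_vox)
  params <- mutation_params(fixed_rate = 1 / 48)
  set.seed(3)
  fracs <- replicate(2000, {
    child <- mutate_genome(parent, params)
    (sum(child$ell_start != parent$ell_start) +
     sum(child$ell_final != parent$ell_final) +
     sum(child$phi_start != parent$phi_start) +
     sum(child$phi_final != parent$phi_final)) / total
  })
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - expected_mutation_impact(1 / 48, g, "evodevo")),
            3 * se)
})
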