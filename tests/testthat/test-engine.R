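test_that("conservation laws hold exactly in every seeded generation", {
  for (scen in 1:2) {
    p <- small_params(scenario = scen, seed = 40 + scen, generations = 8,
                      P0 = 30)
    s <- trap_sim(p)
    r <- s$records
    # killed + survived == spawned, per species
    expect_equal(r$killed_repro1 + r$killed_nonrepro1 + r$survived1,
                 r$spawned1)
    expect_equal(r$killed_repro2 + r$killed_nonrepro2 + r$survived2,
                 r$spawned2)
    # reproductive kills == parasitoids emerged (solitary, 1:1)
    expect_equal(r$killed_repro1 + r$killed_repro2, r$emerged)
    if (scen == 1) {
      # scenario 1: every kill is reproductive
      expect_true(all(r$killed_nonrepro1 == 0 & r$killed_nonrepro2 == 0))
    }
    # next generation's adults are exactly the emerged offspring
    expect_equal(r$P[-1], r$emerged[-nrow(r)])
    # parasitoids never outnumber the hosts killed that generation
    expect_true(all(r$emerged <= r$killed_repro1 + r$killed_repro2 +
                      r$killed_nonrepro1 + r$killed_nonrepro2))
  }
})

test_that("fixed S=1 population expresses the interaction table at population level", {
  # scenario 1: host-2 kills identically zero; scenario 2: host-2 kills all
  # non-reproductive and positive whenever host 2 is attacked
  for (scen in 1:2) {
    p <- small_params(scenario = scen, mu_q = 0, mu_S = 0, P0 = 40,
                      generations = 6, seed = 7)
    s <- trap_sim(p)
    r <- s$records
    expect_true(all(r$killed_repro2 == 0))
    if (scen == 1) {
      expect_true(all(r$killed_nonrepro2 == 0))
      expect_true(all(r$survived2 == r$spawned2))
    } else {
      expect_true(all(r$eggs2 == 0 | r$killed_nonrepro2 > 0))
      expect_gt(sum(r$killed_nonrepro2), 0)
    }
    # clonal, no mutation: only genotype (q = 0, S = 1) is ever present
    expect_true(all(r$freq_S1[r$P > 0] == 1))
    expect_true(all(r$mean_q[r$P > 0] == 0))
  }
})

test_that("a lone egg that completes in time yields one offspring and one kill", {
  # single parasitoid, single one-host patch, enormous maturation time:
  # the first laid egg always completes first
  p <- trap_params(n1 = 1, n2 = 1, K1 = 5, K2 = 5, P0 = 1, generations = 1,
                   mu_q = 0, mu_S = 0, scenario = 1)
  hosts <- data.frame(species = 1L, patch = 1L, maturation_time = 1e7)
  paras <- data.frame(q = 0, S = 1L)
  set.seed(12)
  gen <- run_generation(hosts, paras, p)
  expect_equal(gen$fate, "killed_reproductive")
  expect_equal(nrow(gen$offspring), 1)
  expect_equal(gen$offspring$S, 1L)
  expect_equal(gen$tally$survived, c(0, 0))
})

test_that("with no parasitoids every host survives and no offspring emerge", {
  p <- small_params(P0 = 0, generations = 1)
  set.seed(3)
  hosts <- fixed_hosts(120, 80, p)
  gen <- run_generation(hosts, fixed_parasitoids(0), p)
  expect_true(all(gen$fate == "survived"))
  expect_equal(gen$tally$survived, c(120, 80))
  expect_equal(nrow(gen$offspring), 0)
  expect_false(any(gen$attacked))
})

test_that("identical seeds give bit-identical time series", {
  p <- small_params(scenario = 2, generations = 6, P0 = 25)
  a <- trap_sim(p, replicate_seed = 123)
  b <- trap_sim(p, replicate_seed = 123)
  expect_identical(a$records, b$records)
  d <- trap_sim(p, replicate_seed = 124)
  expect_false(identical(d$records, a$records))
})

test_that("per-host attack probability is non-increasing in host density", {
  # emergent Holling type 2: fixed parasitoid count, one generation, host
  # densities spanning below and above the equilibrium
  p <- trap_params(mu_q = 0, mu_S = 0, generations = 1, scenario = 1)
  densities <- c(200, 800, 1386, 2500)
  set.seed(55)
  attack_prob <- vapply(densities, function(H) {
    probs <- replicate(4, {
      hosts <- fixed_hosts(H / 2, H / 2, p)
      gen <- run_generation(hosts, fixed_parasitoids(50), p)
      mean(gen$attacked)
    })
    mean(probs)
  }, numeric(1))
  expect_true(all(diff(attack_prob) <= 0))
  # saturation is real: highest density is attacked clearly less per head
  expect_lt(attack_prob[4], 0.9 * attack_prob[1])
})

test_that("extinct parasitoid populations leave host-only dynamics running", {
  s <- trap_sim(trap_params(n1 = 3, n2 = 1, K1 = 60, K2 = 1e-6, r2 = 2,
                            P0 = 0, generations = 4, seed = 31))
  expect_equal(s$extinction_generation, 1L)
  expect_equal(nrow(s$records), 4)
  expect_true(all(s$records$P == 0))
  expect_true(all(s$records$spawned1[-1] > 0))
  expect_true(all(is.na(s$records$freq_S1)))
})

test_that("grid runs derive reproducible per-replicate seeds and SE", {
  p <- small_params(generations = 3, P0 = 15)
  d <- experiment_design(list(a = p, b = small_params(generations = 3,
                                                      P0 = 15,
                                                      scenario = 2)),
                         replicates = 3)
  g <- trap_grid(d, master_seed = 5)
  expect_equal(nrow(g$finals), 6)
  expect_equal(nrow(g$summary), 2)
  # SE definition: sd / sqrt(n) over replicate finals
  f <- g$finals[g$finals$variant == "a", ]
  expect_equal(g$summary$se_freq_S1[1], sd(f$freq_S1) / sqrt(3))
  # a replicate rerun in isolation from its derived seed matches
  sim <- trap_sim(p, replicate_seed = replicate_seed(5, 1, 2))
  fin <- sim$records[nrow(sim$records), ]
  expect_equal(fin$P, f$P[f$replicate == 2])
  expect_equal(fin$freq_S1, f$freq_S1[f$replicate == 2])
  # single-replicate grids have no SE
  g1 <- trap_grid(experiment_design(p, replicates = 1), master_seed = 5)
  expect_true(is.na(g1$summary$se_freq_S1))
})
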