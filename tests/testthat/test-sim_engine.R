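# Short runs (a few thousand seconds) exercise the full event loop while
# keeping the suite fast; full-length runs are audited in the acceptance
# tests.

test_that("identical config and seed give bit-identical logs", {
  env <- toy_env(10)
  cfg <- bee_sim_config(duration = 8000)
  s1 <- run_simulation(env, cfg, seed = 123)
  s2 <- run_simulation(env, cfg, seed = 123)
  expect_identical(s1$visits, s2$visits)
  expect_identical(s1$transfers, s2$transfers)
  expect_identical(s1$bouts, s2$bouts)
  expect_identical(s1$q, s2$q)
  s3 <- run_simulation(env, cfg, seed = 124)
  expect_false(identical(s1$visits, s3$visits))
})

test_that("without learning the Q-table never moves from its prior", {
  env <- toy_env(12)
  sim <- run_simulation(env, bee_sim_config(alpha = 0, duration = 10000), seed = 5)
  for (b in seq_along(sim$q)) expect_identical(sim$q[[b]], sim$q0)
  # and with learning it does move
  sim2 <- run_simulation(env, bee_sim_config(alpha = 0.5, duration = 10000), seed = 5)
  expect_false(identical(sim2$q[[1]], sim2$q0))
})

test_that("with full plants and a slack distance cap every bout has 5 visits", {
  env <- generate_environment(20, seed = 8, renewal_duration = 5)  # refills every step
  cfg <- bee_sim_config(n_bees = 1, max_bout_distance = 1e9, duration = 20000)
  sim <- run_simulation(env, cfg, seed = 9)
  expect_gt(nrow(sim$bouts), 3)
  expect_true(all(sim$bouts$n_visits == 5))
  expect_true(all(abs(sim$bouts$nectar_uL - 5 * env$n_max) < 1e-9))
})

test_that("no bee revisits a plant within the working-memory span", {
  env <- toy_env(20)
  sim <- run_simulation(env, bee_sim_config(duration = 15000), seed = 10)
  for (b in unique(sim$visits$bee_id)) {
    v <- sim$visits[sim$visits$bee_id == b, ]
    gaps <- unlist(tapply(v$time_s, v$node_id, function(t) diff(sort(t))))
    if (length(gaps)) expect_gte(min(gaps), sim$config$wm_span)
  }
})

test_that("itineraries are continuous: inter-visit times match travel times", {
  env <- toy_env(15)
  cfg <- bee_sim_config(duration = 10000)
  sim <- run_simulation(env, cfg, seed = 11)
  dt <- cfg$timestep
  for (b in unique(sim$visits$bee_id)) {
    v <- sim$visits[sim$visits$bee_id == b, ]
    for (bout in unique(v$bout_index)) {
      vb <- v[v$bout_index == bout, ]
      vb <- vb[order(vb$time_s), ]
      # first leg leaves the nest at the recorded departure time
      dep <- sim$bouts$depart_s[sim$bouts$bee_id == b &
                                  sim$bouts$bout_index == bout]
      if (length(dep) == 1) {
        leg <- env$dist[1, vb$node_id[1] + 1]
        expect_equal(vb$time_s[1] - dep, ceiling(leg / (cfg$speed * dt)) * dt)
      }
      if (nrow(vb) > 1) {
        for (k in 2:nrow(vb)) {
          leg <- env$dist[vb$node_id[k - 1] + 1, vb$node_id[k] + 1]
          expect_equal(vb$time_s[k] - vb$time_s[k - 1],
                       ceiling(leg / (cfg$speed * dt)) * dt)
        }
      }
    }
  }
})

test_that("bout distance and crop limits are honoured", {
  env <- toy_env(20)
  cfg <- bee_sim_config(duration = 20000)
  sim <- run_simulation(env, cfg, seed = 12)
  # distance: never beyond the cap plus one homing leg
  max_home <- max(env$dist[1, ])
  expect_true(all(sim$bouts$distance_m <= cfg$max_bout_distance + max_home + 1e-9))
  # nectar: no bout collects more than the crop holds
  expect_true(all(sim$bouts$nectar_uL <= cfg$crop_capacity_units * env$n_max + 1e-9))
})

test_that("collected nectar never exceeds what the environment produced", {
  env <- toy_env(10)
  cfg <- bee_sim_config(n_bees = 3, duration = 15000)
  sim <- run_simulation(env, cfg, seed = 13)
  produced <- env$n_plants * env$n_max +
    env$n_plants * env$n_max * cfg$duration / env$renewal_duration
  expect_lte(sum(sim$visits$nectar_collected_uL), produced)
})

test_that("every recorded transfer coincides with a visit by the same bee", {
  env <- toy_env(12)
  sim <- run_simulation(env, bee_sim_config(duration = 10000), seed = 14)
  key <- paste(sim$visits$time_s, sim$visits$bee_id, sim$visits$node_id)
  tkey <- paste(sim$transfers$time_s, sim$transfers$bee_id,
                sim$transfers$recipient_plant)
  expect_true(all(tkey %in% key))
})

test_that("the simulated ledger equals the geometric re-walk of the visit log", {
  env <- toy_env(10)
  sim <- run_simulation(env, bee_sim_config(duration = 12000), seed = 15)
  oracle <- do.call(rbind, lapply(unique(sim$visits$bee_id), function(b) {
    v <- sim$visits[sim$visits$bee_id == b, ]
    bouts <- split(v$node_id[order(v$time_s)], v$bout_index[order(v$time_s)])
    oracle_pollen_totals(bouts, p = sim$config$p, cutoff = sim$config$cutoff)
  }))
  oracle <- aggregate(amount ~ donor + recipient, data = oracle, FUN = sum)
  oracle <- oracle[order(oracle$donor, oracle$recipient), ]
  got <- pair_totals(sim$transfers)
  expect_equal(got$donor_plant, oracle$donor)
  expect_equal(got$recipient_plant, oracle$recipient)
  expect_equal(got$amount, oracle$amount, tolerance = 1e-12)
})

test_that("metric computation handles degenerate records", {
  env <- toy_env(10)
  cfg <- bee_sim_config(n_bees = 1, duration = 10000, target_bout = 2)
  sim <- run_simulation(env, cfg, seed = 16)
  m <- compute_all_metrics(sim, modularity = FALSE)
  expect_equal(m$bees$i_loc, 0)                       # no competitor
  expect_false(is.na(m$summary$n_visits))
  # a bee that never reaches the target bout reports missing bout metrics
  cfg2 <- bee_sim_config(n_bees = 1, duration = 10000, target_bout = 500)
  m2 <- compute_all_metrics(run_simulation(env, cfg2, seed = 16),
                            modularity = FALSE)
  expect_true(is.na(m2$bees$n_visits))
  expect_true(is.na(m2$summary$intake_rate))
})

test_that("simulation records round-trip through the CSV writers", {
  env <- toy_env(6)
  sim <- run_simulation(env, bee_sim_config(duration = 6000), seed = 17)
  dir <- withr::local_tempdir()
  write_sim_record(sim, dir)
  v <- read.csv(file.path(dir, "visits.csv"))
  expect_equal(nrow(v), nrow(sim$visits))
  led <- read.csv(file.path(dir, "transfers.csv"))
  expect_equal(sum(led$amount), sum(sim$transfers$amount), tolerance = 1e-9)
  q <- read.csv(file.path(dir, "qtable_bee1.csv"))
  expect_equal(nrow(q), 7 * 6)
  m <- read_edge_list(withr::local_tempfile(fileext = ".csv", lines = c(
    "donor,recipient,weight", "1,2,0.5", "1,2,0.25", "3,3,1")))
  expect_equal(m["1", "2"], 0.75)
})
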