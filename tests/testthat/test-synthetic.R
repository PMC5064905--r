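test_that("generated registers match the configured counts deterministically", {
  cfg <- sim_config(n_councils = 1,
                    facilities_per_council = c(dispensary = 10,
                                               health_center = 2,
                                               hospital_opd = 1))
  reg <- generate_register(cfg, seed = 5)
  expect_equal(nrow(reg), 13L)
  expect_equal(sum(reg$type == "dispensary"), 10L)
  expect_equal(sum(reg$type == "health_center"), 2L)
  expect_equal(sum(reg$type == "hospital_opd"), 1L)
  expect_identical(reg, generate_register(cfg, seed = 5))
  expect_false(identical(reg$ownership,
                         generate_register(cfg, seed = 6)$ownership))
  expect_equal(nrow(validate_register(reg)), 13L)
})

test_that("ownership follows the largest-remainder allocation", {
  mix <- c(public = 0.5, faith_based = 0.5, private = 0, institutional = 0)
  expect_equal(allocate_ownership(20, mix),
               c(public = 10L, faith_based = 10L, private = 0L,
                 institutional = 0L))
  # quotas 1.5 / 0.9 / 0.6: floors 1/0/0, remainders to the two largest
  # fractional parts (faith_based 0.9, private 0.6)
  mix2 <- c(public = 0.5, faith_based = 0.3, private = 0.2,
            institutional = 0)
  expect_equal(allocate_ownership(3, mix2),
               c(public = 1L, faith_based = 1L, private = 1L,
                 institutional = 0L))
  # tie in fractional parts resolved by category order
  mix3 <- c(public = 0.25, faith_based = 0.25, private = 0.25,
            institutional = 0.25)
  expect_equal(allocate_ownership(2, mix3),
               c(public = 1L, faith_based = 1L, private = 0L,
                 institutional = 0L))
  cfg <- sim_config(n_councils = 1, ownership_mix = mix,
                    facilities_per_council = c(dispensary = 20))
  reg <- generate_register(cfg, seed = 1)
  expect_equal(sum(reg$ownership == "public"), 10L)
  expect_equal(sum(reg$ownership == "faith_based"), 10L)
})

test_that("degenerate quality settings hit the score bounds exactly", {
  inst <- demo_instrument()
  cfg1 <- sim_config(n_councils = 1,
                     facilities_per_council = c(dispensary = 3),
                     q = rep(1, 6), delta = 0, na_prob = 0,
                     scenario_prob = 1, rounds = "2011")
  sessions <- generate_round(inst, generate_register(cfg1, 1), cfg1, 1,
                             seed = 2)
  tab <- score_sessions(inst, sessions)
  expect_true(all(tab$percent == 100))

  cfg0 <- sim_config(n_councils = 1,
                     facilities_per_council = c(dispensary = 3),
                     q = rep(0, 6), delta = 0, na_prob = 0,
                     scenario_prob = 1, rounds = "2011")
  sessions <- generate_round(inst, generate_register(cfg0, 1), cfg0, 1,
                             seed = 2)
  expect_true(all(score_sessions(inst, sessions)$percent == 0))
})

test_that("identical seeds give byte-identical output files", {
  inst <- demo_instrument()
  cfg <- sim_config(n_councils = 1,
                    facilities_per_council = c(dispensary = 4,
                                               health_center = 1))
  out <- replicate(2, {
    d <- withr::local_tempdir()
    ds <- generate_dataset(inst, cfg, seed = 99)
    write_register(ds$register, file.path(d, "register.csv"))
    write_responses(ds$sessions, file.path(d, "responses.csv"),
                    scenarios_path = file.path(d, "scenarios.csv"))
    vapply(file.path(d, c("register.csv", "responses.csv",
                          "scenarios.csv")),
           function(f) paste(readLines(f), collapse = "\n"), "")
  })
  expect_identical(out[, 1], out[, 2])
})

test_that("scoring the generated data recovers the configured quality level", {
  inst <- demo_instrument()
  cfg <- sim_config(n_councils = 1,
                    facilities_per_council = c(dispensary = 50,
                                               health_center = 5,
                                               hospital_opd = 2),
                    q = rep(0.6, 6), delta = 0, na_prob = 0.05,
                    scenario_prob = 0.8, rounds = "2011")
  sessions <- generate_round(inst, generate_register(cfg, 3), cfg, 1,
                             seed = 3)
  tab <- score_sessions(inst, sessions)
  dim_mean <- mean(tab$percent[tab$level == "dimension"], na.rm = TRUE)
  expect_lt(abs(dim_mean - 60), 3)
})

test_that("an improvement increment is detected by the paired trend test", {
  inst <- demo_instrument()
  cfg <- sim_config(n_councils = 1,
                    facilities_per_council = c(dispensary = 35,
                                               health_center = 4,
                                               hospital_opd = 1),
                    q = rep(0.5, 6), delta = 0.1, na_prob = 0.05,
                    rounds = c("2011", "2012"))
  ds <- generate_dataset(inst, cfg, seed = 17)
  tab <- score_sessions(inst, ds$sessions)
  ov <- tab[tab$level == "overall", ]
  tr <- paired_trend_test(ov[ov$round == "2011", ],
                          ov[ov$round == "2012", ])
  expect_equal(tr$n_pairs, 40L)
  expect_gt(tr$mean_difference, 0)
  expect_lt(tr$p_value, 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(q = rep(0.9, 6), delta = 0.2,
                          rounds = c("a", "b")),
               class = "etiqh_error_config")
  expect_error(sim_config(q = rep(1.2, 6)), class = "etiqh_error_config")
  expect_error(sim_config(ownership_mix = c(public = 0.5,
                                            faith_based = 0.4,
                                            private = 0,
                                            institutional = 0)),
               class = "etiqh_error_config")
  expect_error(sim_config(q = rep(0.5, 3)), class = "etiqh_error_config")
})
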