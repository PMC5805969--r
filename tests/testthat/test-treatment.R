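test_that("death delays are exponential with the calibrated rate", {
  set.seed(21)
  dyn <- death_dynamics()                      # k_delay = 0.009 / h
  d <- sample_death_delay(1e5, dyn)
  expect_lt(abs(mean(d) - 1 / 0.009), 1.5)     # mean 111.1 h, CLT tolerance
  expect_true(all(d >= 0))
  set.seed(5); a <- sample_death_delay(10, dyn)
  set.seed(5); b <- sample_death_delay(10, dyn)
  expect_identical(a, b)                        # seeded reproducibility
})

test_that("mitotic fate frequencies follow the branch probabilities", {
  set.seed(31)
  expect_true(all(mitotic_fate(100, death_dynamics(p_mitoticCat = 0)) ==
                    "divide"))
  expect_true(all(mitotic_fate(100, death_dynamics(p_mitoticCat = 1,
                                                   p_senescence = 1)) ==
                    "senescent"))
  f <- table(mitotic_fate(1e5, death_dynamics()))  # (0.2, 0.05)
  expect_lt(abs(f[["divide"]] / 1e5 - 0.80), 3 * sqrt(0.8 * 0.2 / 1e5))
  expect_lt(abs(f[["giant"]] / 1e5 - 0.19), 3 * sqrt(0.19 * 0.81 / 1e5))
  expect_lt(abs(f[["senescent"]] / 1e5 - 0.01), 3 * sqrt(0.01 * 0.99 / 1e5))
})

test_that("heat fractions kill instantaneously and binomially", {
  set.seed(41)
  g <- ca_grid(diameter_voxels = 121)
  st <- seed_population(1e4, g)
  # S = 1: population untouched
  st1 <- apply_fraction(st, dose_Gy = 0, t43 = 0)
  expect_equal(count_compartments(st1)[["total"]], 1e4L)
  # S_HT = 0.5 via override: survivor count within 3 binomial SDs
  st2 <- apply_fraction(st, t43 = 5, s_ht = 0.5)
  n2 <- count_compartments(st2)[["total"]]
  expect_lt(abs(n2 - 5000), 3 * sqrt(1e4 * 0.25))
  expect_equal(count_compartments(st2)[["doomed"]], 0L)  # no delayed deaths
  # occupancy stays bijective after removal
  lin <- (st2$cells$pos_y - 1L) * g$n + st2$cells$pos_x
  expect_equal(sort(st2$grid$occ[lin]), seq_len(n2))
  expect_equal(sum(st2$grid$occ > 0L), n2)
})

test_that("radiation dooms cells; instantaneous mode removes them at once", {
  set.seed(51)
  g <- ca_grid(diameter_voxels = 121)
  st <- seed_population(5000, g)
  rt <- hct116_rt()
  std <- apply_fraction(st, dose_Gy = 5, rt_params = rt,
                        sensitivity = phase_sensitivity_uniform())
  ccd <- count_compartments(std)
  expect_equal(ccd[["total"]], 5000L)            # nothing removed yet
  s5 <- alphar_survival(5, rt)
  expect_lt(abs(ccd[["doomed"]] - 5000 * (1 - s5)),
            3 * sqrt(5000 * s5 * (1 - s5)) + 1)
  # doomed cells carry finite death times
  expect_true(all(is.finite(std$cells$death_time[std$cells$fate == 1L])))
  sti <- apply_fraction(st, dose_Gy = 5, rt_params = rt,
                        sensitivity = phase_sensitivity_uniform(),
                        mode = "instantaneous")
  cci <- count_compartments(sti)
  expect_equal(cci[["doomed"]], 0L)
  expect_lt(abs(cci[["total"]] - 5000 * s5), 3 * sqrt(5000 * s5) + 1)
})

test_that("delayed-kill curves dominate instantaneous-kill curves", {
  rt <- hct116_rt()
  sched <- treatment_schedule(24, dose_Gy = 5)
  run_mode <- function(mode) {
    cfg <- small_cfg(n0 = 800, d = 101, t_end = 160, schedule = sched,
                     rt_params = rt, mode = mode)
    run_experiment(cfg, seed = 404)
  }
  del <- run_mode("delayed")
  ins <- run_mode("instantaneous")
  expect_true(all(del$total >= ins$total - 1e-9))
  # early counts far exceed the clonogenic prediction under delayed kill
  s5 <- alphar_survival(5, rt)
  i48 <- which(del$time == 48)
  expect_gt(del$total[i48], 3 * ins$total[i48])
  # late dynamics are survivor-driven: the delayed viable population regrows
  # well beyond the initial survivor cohort while the doomed pool decays
  n_surv0 <- min(del$viable[del$time >= 24])
  expect_gt(tail(del$viable, 1), 10 * max(n_surv0, 1))
  # doomed lineages keep proliferating before their death times elapse
  i_tr <- which(del$time == 25)
  expect_gt(max(del$doomed), del$doomed[i_tr])
})

test_that("combined-fraction branch frequencies converge to the tree", {
  set.seed(61)
  g <- ca_grid(diameter_voxels = 121)
  st <- seed_population(1e4, g)
  s_ht <- 0.6; s_rtht <- 0.3
  st2 <- apply_fraction(st, dose_Gy = 2, t43 = 10,
                        s_ht = s_ht, s_rtht = s_rtht,
                        sensitivity = phase_sensitivity_uniform())
  cc <- count_compartments(st2)
  killed <- 1e4 - cc[["total"]]
  doomed <- cc[["doomed"]]
  surv <- cc[["total"]] - doomed
  tol <- function(p) 3 * sqrt(1e4 * p * (1 - p))
  expect_lt(abs(killed - 1e4 * (1 - s_ht)), tol(1 - s_ht))
  expect_lt(abs(doomed - 1e4 * (s_ht - s_rtht)), tol(s_ht - s_rtht))
  expect_lt(abs(surv - 1e4 * s_rtht), tol(s_rtht))
})

test_that("doomed lineages inherit death times; senescent cells persist", {
  set.seed(71)
  g <- small_grid(61)
  st <- seed_population(100, g)
  # doom every cell far in the future, then let them divide
  st$cells$fate[] <- 1L
  death_times <- 500 + seq_len(100)            # distinct, recognizable
  st$cells$death_time <- death_times
  dyn <- death_dynamics(p_mitoticCat = 0)      # pure division, no catastrophe
  st2 <- advance(st, 60, dynamics = dyn)
  cc2 <- count_compartments(st2)
  expect_gt(cc2[["total"]], 150)               # population grew
  expect_equal(cc2[["doomed"]], cc2[["total"]])
  expect_true(all(st2$cells$death_time %in% death_times))
  # with certain catastrophe and certain senescence, M exits all senesce
  st3 <- st
  st3$cells$death_time <- rep(1e4, 100)
  dyn_sen <- death_dynamics(p_mitoticCat = 1, p_senescence = 1)
  st3 <- advance(st3, 80, dynamics = dyn_sen)
  cc3 <- count_compartments(st3)
  expect_equal(cc3[["senescent"]], 100L)       # every founder senesced
  expect_equal(cc3[["total"]], 100L)           # and nothing ever divided
  st3b <- advance(st3, 300, dynamics = dyn_sen)
  expect_equal(count_compartments(st3b)[["senescent"]], 100L)
  # with certain catastrophe and no senescence, founders become giants
  st4 <- st
  st4$cells$death_time <- rep(200, 100)
  dyn_gia <- death_dynamics(p_mitoticCat = 1, p_senescence = 0)
  st4 <- advance(st4, 100, dynamics = dyn_gia)
  cc4 <- count_compartments(st4)
  expect_equal(cc4[["giant"]], 100L)
  expect_true(all(st4$cells$giant_size >= 1L))
  # giants keep their size counter growing and die at their death time
  st4b <- advance(st4, 100 + 50, dynamics = dyn_gia)
  expect_true(all(st4b$cells$giant_size >= 2L))
  st4c <- advance(st4b, 260, dynamics = dyn_gia)
  expect_equal(count_compartments(st4c)[["total"]], 0L)
})

test_that("schedule helpers expand fractionation patterns", {
  s <- schedule_every(5, 2, interval_h = 24)
  expect_equal(s$time, c(0, 24, 48, 72, 96))
  expect_equal(s$dose_Gy, rep(2, 5))
  w <- schedule_weekdays(30, 2)
  expect_equal(nrow(w), 30L)
  expect_equal(w$time[1:6] / 24, c(0, 1, 2, 3, 4, 7))   # weekend skipped
  expect_equal(max(w$time) / 24, 39)                    # six-week course
  expect_error(treatment_schedule(c(10, 5)), "non-decreasing")
})

test_that("re-irradiation keeps the earliest scheduled death", {
  set.seed(81)
  g <- small_grid(61)
  st <- seed_population(200, g)
  st$cells$fate[] <- 1L
  st$cells$death_time <- rep(1e6, 200)         # death far in the future
  # a certain-kill fraction re-dooms everything; death times must shrink
  st2 <- apply_fraction(st, dose_Gy = 5, s_rt = 1e-12,
                        sensitivity = phase_sensitivity_uniform())
  expect_true(all(st2$cells$death_time < 1e6))
  # under the "ignore" policy doomed cells are left untouched
  st3 <- apply_fraction(st, dose_Gy = 5, s_rt = 1e-12,
                        sensitivity = phase_sensitivity_uniform(),
                        refraction = "ignore")
  expect_true(all(st3$cells$death_time == 1e6))
})
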