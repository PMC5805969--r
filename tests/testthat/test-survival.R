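test_that("AlphaR survival reproduces clonogenic fractions and limits", {
  rt <- hct116_rt()
  expect_equal(alphar_survival(0, rt), 1)
  expect_error(alphar_survival(-1, rt), "non-negative")
  # printed HCT116 surviving fractions at 2, 3 and 5 Gy
  expect_equal(round(alphar_survival(2, rt), 2), 0.31)
  expect_equal(round(alphar_survival(3, rt), 2), 0.15)
  expect_equal(round(alphar_survival(5, rt), 2), 0.03)
  # monotone non-increasing in dose
  s <- alphar_survival(seq(0, 20, by = 0.1), rt)
  expect_true(all(diff(s) <= 0))
})

test_that("LQ arm agrees with a literal re-coding of the formula", {
  set.seed(42)
  for (i in 1:100) {
    a <- runif(1, 0, 1); b <- runif(1, 0, 0.2); d <- runif(1, 0, 8)
    p <- alphar_params(alpha = a, beta = b)
    expect_equal(alphar_survival(d, p), exp(-a * d - b * d^2),
                 tolerance = 1e-14)
  }
})

test_that("the two AlphaR arms join continuously at the threshold dose", {
  # derived threshold D_T = alphaR / beta
  p <- alphar_params(alpha0 = 0.2, alphaR = 0.2, beta = 0.05)  # D_T = 4
  expect_equal(p$D_T, 4)
  lq_at_dt <- exp(-(0.2 - 0.2) * 4 - 0.05 * 16)
  post_at_dt <- exp(-0.2 * 4)
  expect_equal(lq_at_dt, post_at_dt)
  eps <- 1e-9
  expect_equal(alphar_survival(4 - eps, p), alphar_survival(4 + eps, p),
               tolerance = 1e-6)
  # post-threshold arm is the single exponential exp(-alpha0 d)
  expect_equal(alphar_survival(10, p), exp(-0.2 * 10))
  # explicit threshold: continuity is preserved by construction
  q <- alphar_params(alpha0 = 0.5, alphaR = 0.3, beta = 0.04, D_T = 3)
  expect_equal(alphar_survival(3 - eps, q), alphar_survival(3 + eps, q),
               tolerance = 1e-6)
  s <- alphar_survival(seq(0, 12, by = 0.05), q)
  expect_true(all(diff(s) <= 1e-15))
})

test_that("CEM43 conversion follows the two-case thermal dose model", {
  expect_equal(cem43(thermal_profile(5, 46)), 40)     # 5 min at 46 C
  expect_equal(cem43(thermal_profile(10, 43)), 10)    # R^0 = 1
  expect_equal(cem43(thermal_profile(30, 39)), 0)     # below 40 C cut-off
  # mixed profile: 2 * 2 + 3 * 4
  expect_equal(cem43(thermal_profile(c(2, 3), c(44, 45))), 16)
  # sub-43 C steps use R = 0.25
  expect_equal(cem43(thermal_profile(16, 42)), 4)
})

test_that("CEM43 is additive over concatenated profiles", {
  set.seed(7)
  for (i in 1:20) {
    p1 <- thermal_profile(runif(3, 0, 30), runif(3, 36, 48))
    p2 <- thermal_profile(runif(2, 0, 30), runif(2, 36, 48))
    expect_equal(cem43(c(p1, p2)), cem43(p1) + cem43(p2), tolerance = 1e-12)
  }
})

test_that("hyperthermia survival has a shoulder then a single exponential", {
  ht <- demo_ht()                       # alpha0 = alphaR = 0.1, beta = 0.005
  expect_equal(ht$D_T, 20)
  expect_equal(ht_survival(0, ht), 1)
  expect_equal(ht_survival(10, ht), exp(-0.5))        # LQ arm: exp(-beta t^2)
  expect_equal(ht_survival(30, ht), exp(-3))          # single-exponential arm
  eps <- 1e-8
  expect_equal(ht_survival(20 - eps, ht), ht_survival(20 + eps, ht),
               tolerance = 1e-6)
})

test_that("combined survival factorizes and is bounded by each modality", {
  ht <- demo_ht()
  cp <- combination_params(alpha_RT = 0.5, beta_RT = 0.042,
                           slope_a = 0.01, ht_params = ht)
  rt <- hct116_rt()
  # limits: no heat -> radiation survival; no radiation -> heat survival
  expect_equal(rtht_survival(2, 0, cp), alphar_survival(2, rt))
  expect_equal(rtht_survival(0, 25, cp), ht_survival(25, ht))
  # direct evaluation with S_HT pinned to 0.5 via a bespoke beta
  ht50 <- alphar_params(alpha0 = 0.1, alphaR = 0.1, beta = log(2) / 1600)
  cp50 <- combination_params(0.5, 0.042, 0.01, ht50)
  expect_equal(ht_survival(40, ht50), 0.5)
  expect_equal(rtht_survival(2, 40, cp50),
               0.5 * exp(-(0.9 * 2) - 0.042 * 4))
  # dominance: combined survival never exceeds either single modality
  set.seed(11)
  for (i in 1:50) {
    d <- runif(1, 0, 6); t43 <- runif(1, 0, 60)
    s <- rtht_survival(d, t43, cp)
    expect_lte(s, ht_survival(t43, ht) + 1e-15)
    expect_lte(s, alphar_survival(d, rt) + 1e-15)
  }
})

test_that("phase sensitivity map satisfies the ratio rule and normalization", {
  f <- c(G1 = 0.40, S = 0.35, G2 = 0.20, M = 0.05)
  for (S in c(0.03, 0.15, 0.31, 0.6)) {
    g <- phase_sensitivity(S, f)
    sp <- S^unclass(g)[c("G1", "S", "G2", "M")]
    # consecutive ratio 1.5 in the order S > G1 > G2 > M
    expect_equal(sp[["S"]] / sp[["G1"]], 1.5, tolerance = 1e-12)
    expect_equal(sp[["G1"]] / sp[["G2"]], 1.5, tolerance = 1e-12)
    expect_equal(sp[["G2"]] / sp[["M"]], 1.5, tolerance = 1e-12)
    # phase-fraction-weighted mean equals the unweighted survival
    expect_lt(abs(sum(f * sp) - S), 1e-10)
    # sensitivity ordering of the exponents
    expect_true(g[["M"]] > g[["G2"]] && g[["G2"]] > g[["G1"]] &&
                  g[["G1"]] > g[["S"]])
    # quiescent cells default to the G1 exponent
    expect_equal(g[["G0"]], g[["G1"]])
  }
})

test_that("phase weighting is a power transform with documented edge cases", {
  g1 <- phase_sensitivity_uniform()
  expect_equal(phase_weighted_survival(0.3, "M", g1), 0.3)  # gamma = 1
  g <- phase_sensitivity(0.03)
  expect_equal(phase_weighted_survival(0.03, "S", g) /
                 phase_weighted_survival(0.03, "G1", g), 1.5,
               tolerance = 1e-12)
  expect_equal(phase_weighted_survival(0, "S", g), 0)  # S = 0 edge case
  expect_error(phase_weighted_survival(0.5, "X", g), "unknown phase")
  man <- phase_sensitivity_manual(c(G1 = 1, S = 0.85, G2 = 1.2, M = 1.39))
  expect_equal(phase_weighted_survival(0.1, "M", man), 0.1^1.39)
})
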