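test_that("the four channels have the loop structure and catalytic updates", {
  p <- network_params(x0 = 50)
  ch <- build_reaction_channels(p)
  expect_named(ch, c("A", "B1", "B2", "B3"))

  # two channels feed the shared downstream species X3
  x3a_producers <- vapply(ch, function(c_) c_$delta[["x3a"]] == 1, logical(1))
  expect_equal(unname(which(x3a_producers)), c(1, 4))
  expect_equal(ch$A$substrate, "x3")
  expect_equal(ch$B3$substrate, "x3")

  for (c_ in ch) {
    d <- c_$delta
    # catalytic: the activator's own counts never change
    if (c_$activator != "x0") expect_equal(d[[c_$activator]], 0L)
    # one substrate copy converts inactive -> active, counter increments
    expect_equal(d[[c_$substrate]], -1L)
    expect_equal(d[[paste0(c_$substrate, "a")]], 1L)
    expect_equal(sum(d[c("fireA", "fireB1", "fireB2", "fireB3")]), 1L)
    # per-species conservation of every update vector
    for (sp in c("x1", "x2", "x3")) {
      expect_equal(d[[sp]] + d[[paste0(sp, "a")]], 0L)
    }
  }
})

test_that("zeroed rate constants and zero stimulus silence the right channels", {
  p <- network_params(x0 = 100, k_a = 0)
  s <- initial_state(p)
  expect_equal(unname(propensities(s, p)["A"]), 0)
  # ... and for every reachable state, since a_A = k_a * x0 * x3
  s$x3 <- 40; s$x2a <- 60
  expect_equal(unname(propensities(s, p)["A"]), 0)

  p0 <- network_params(x0 = 0)
  a <- propensities(initial_state(p0), p0)
  expect_equal(unname(a[c("A", "B1")]), c(0, 0))
})

test_that("validation flags hard errors and structural warnings", {
  ok <- validate_parameters(network_preset("figS1_base"))
  expect_length(ok$errors, 0)
  expect_length(ok$warnings, 0)

  bad <- validate_parameters(list(x0 = 50, x1_total = 100, x2_total = 100,
                                  x3_total = 100, k_a = -1, k_b1 = 1,
                                  k_b2 = 1e-4, k_b3 = 1))
  expect_match(bad$errors, "negative rate constant", all = FALSE)
  expect_error(network_params(x0 = 50, k_a = -1), "negative")

  frac <- validate_parameters(list(x0 = 50, x1_total = 100.5, x2_total = 100,
                                   x3_total = 100, k_a = 1e-5, k_b1 = 1,
                                   k_b2 = 1e-4, k_b3 = 1))
  expect_match(frac$errors, "integer", all = FALSE)

  slowfast <- validate_parameters(list(x0 = 50, x1_total = 100,
                                       x2_total = 100, x3_total = 100,
                                       k_a = 1e-5, k_b1 = 1, k_b2 = 1,
                                       k_b3 = 1))
  expect_length(slowfast$errors, 0)
  expect_match(slowfast$warnings, "slow-fast ordering", all = FALSE)

  entry <- validate_parameters(list(x0 = 50, x1_total = 100, x2_total = 100,
                                    x3_total = 100, k_a = 1e-5, k_b1 = 1e-6,
                                    k_b2 = 1e-4, k_b3 = 1))
  expect_match(entry$warnings, "not faster than type A", all = FALSE)
})

test_that("analytic thresholds reproduce the dominance relations exactly", {
  p <- network_params(x0 = 2e5)  # base values, k_b2 = 1e-4
  cl <- classify_regime_analytic(p)
  # (i)  k_b3 * sqrt(k_b2 x1 x2) / k_a = 1.0 * sqrt(1e-4*100*100) / 1e-5
  expect_equal(cl$threshold_type_a, 1e5, tolerance = 1e-12)
  # (ii) k_b2 x1 x2 / (k_a x3) = 1e-4*100*100 / (1e-5*100)
  expect_equal(cl$threshold_type_b, 1e3, tolerance = 1e-12)
  expect_equal(cl$label, "TYPE_A")

  p$x0 <- 5e4
  expect_equal(classify_regime_analytic(p)$label, "MIXED")
  p$x0 <- 50
  expect_equal(classify_regime_analytic(p)$label, "TYPE_B")
})

test_that("classifier degenerate and limiting cases", {
  p <- network_params(x0 = 50, k_a = 0)
  cl <- classify_regime_analytic(p)
  expect_equal(cl$label, "TYPE_B")
  expect_equal(cl$threshold_type_a, Inf)

  # vanishing slow step pushes both thresholds to zero: any stimulus is
  # eventually in the deterministic regime
  p2 <- network_params(x0 = 1, k_b2 = 1e-16)
  cl2 <- classify_regime_analytic(p2)
  expect_lt(cl2$threshold_type_a, 1)
  expect_equal(classify_regime_analytic(p2)$label, "TYPE_A")
})

test_that("regime label is monotone in the stimulus", {
  rank_ <- c(TYPE_B = 1, MIXED = 2, TYPE_A = 3)
  set.seed(42)
  for (rep_ in 1:20) {
    # draws respect the minimal network's structural ordering
    # (fast-slow-fast, k_b1 > k_a), under which the analytic thresholds
    # are themselves ordered
    p <- network_params(x0 = 1,
                        x1_total = sample(50:200, 1),
                        x2_total = sample(50:200, 1),
                        x3_total = sample(50:200, 1),
                        k_a = 10^stats::runif(1, -7, -4),
                        k_b1 = 1,
                        k_b2 = 10^stats::runif(1, -7, -4),
                        k_b3 = 10^stats::runif(1, -0.3, 0.3))
    labels <- vapply(10^seq(-1, 8, by = 0.5), function(x0) {
      p$x0 <- x0
      classify_regime_analytic(p)$label
    }, character(1))
    expect_true(all(diff(rank_[labels]) >= 0))
    # the deterministic region always lies at larger stimulus
    cl <- classify_regime_analytic(p)
    expect_gte(cl$threshold_type_a, cl$threshold_type_b)
  }
})

test_that("presets land in their regimes", {
  base <- network_preset("figS1_base")
  expect_equal(c(base$x1_total, base$x2_total, base$x3_total),
               c(100, 100, 100))
  expect_equal(base$k_a, 1e-5)
  expect_equal(base$k_b3, 1.0)
  expect_true(is.na(base$x0))

  for (nm in c("weak", "intermediate", "strong")) {
    cl <- classify_regime_analytic(network_preset(nm))
    expect_equal(cl$label,
                 c(weak = "TYPE_B", intermediate = "MIXED",
                   strong = "TYPE_A")[[nm]])
  }
  expect_lt(network_preset("weak")$x0,
            classify_regime_analytic(network_preset("weak"))$threshold_type_b)

  expect_error(network_preset("bogus"), "valid names")
})

test_that("conservation holds over arbitrary firing sequences", {
  p <- network_params(x0 = 30, x1_total = 8, x2_total = 5, x3_total = 7,
                      k_a = 0.01, k_b1 = 0.5, k_b2 = 0.05, k_b3 = 2)
  set.seed(7)
  s <- initial_state(p)
  for (i in 1:200) {
    st <- ssa_step(s, p)
    if (!is.finite(st$tau)) break
    s <- st$state
    expect_equal(s$x1 + s$x1a, p$x1_total)
    expect_equal(s$x2 + s$x2a, p$x2_total)
    expect_equal(s$x3 + s$x3a, p$x3_total)
    expect_equal(s$x1a, s$fireB1)
    expect_equal(s$x2a, s$fireB2)
    expect_equal(s$x3a, s$fireA + s$fireB3)
  }
  # fully absorbed: all substrates exhausted
  expect_equal(s$x1a + s$x2a + s$x3a,
               p$x1_total + p$x2_total + p$x3_total)
})
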