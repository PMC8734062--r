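test_that("continuous iteration count matches published cells and basic identities", {
  expect_equal(halfup2(required_iterations_continuous(0.02, 0.99, log_lr_positive = 0.5)),
               16.97)
  expect_equal(halfup2(required_iterations_continuous(0.2, 0.95, log_lr_positive = 1)),
               4.33)
  # prevalence already at the target: numerator ln(1) = 0
  expect_equal(required_iterations_continuous(0.6, 0.6, log_lr_positive = 1.3), 0)
  # (a, b) and ln LR+ parameterisations agree
  expect_equal(
    required_iterations_continuous(0.1, 0.95, sensitivity = 0.9, specificity = 0.8),
    required_iterations_continuous(0.1, 0.95, log_lr_positive = log(4.5)))
  expect_error(required_iterations_continuous(0.1, 1, log_lr_positive = 1),
               class = "seqppv_argument_error")
  expect_error(required_iterations_continuous(0.1, 0.95, log_lr_positive = 0),
               class = "seqppv_undefined_result")
  expect_error(required_iterations_continuous(0.1, 0.95, sensitivity = 0.4,
                                              specificity = 0.6),
               class = "seqppv_undefined_result")
})

test_that("integer requirement takes the ceiling and brackets the target", {
  plan <- required_iterations(0.9, 0.8, 0.1, 0.95)
  expect_equal(plan$continuous_n, log(171) / log(4.5))
  expect_equal(plan$n_i, 4L)
  expect_equal(plan$feasibility, "feasible")
  expect_equal(plan$n_i, oracle_required_n(0.9, 0.8, 0.1, 0.95))
  expect_gte(plan$achieved_ppv, 0.95)
  expect_lt(sequential_ppv(0.9, 0.8, 0.1, plan$n_i - 1), 0.95)

  # a scenario engineered so the continuous requirement is exactly 2.8 tests
  rho <- plogis(qlogis(0.1) + 2.8 * log(4.5))
  plan28 <- required_iterations(0.9, 0.8, 0.1, rho)
  expect_equal(plan28$continuous_n, 2.8, tolerance = 1e-12)
  expect_equal(plan28$n_i, 3L)
})

test_that("feasibility classification covers all degenerate regimes", {
  expect_equal(required_iterations(0.3, 0.3, 0.1, 0.95)$feasibility,
               "infeasible_negative")
  expect_lt(required_iterations(0.3, 0.3, 0.1, 0.95)$continuous_n, 0)
  expect_equal(required_iterations(0.5, 0.5, 0.1, 0.95)$feasibility,
               "infeasible_uninformative")
  done <- required_iterations(0.9, 0.8, 0.96, 0.95)
  expect_equal(done$feasibility, "already_satisfied")
  expect_equal(done$n_i, 0L)
  expect_equal(done$achieved_ppv, 0.96)
  expect_equal(required_iterations(0.9, 0.8, 0, 0.95)$feasibility, "unreachable")
  expect_true(is.na(required_iterations(0.9, 0.8, 0, 0.95)$n_i))
  expect_error(required_iterations(0.9, 0.8, 0.1, 1),
               class = "seqppv_argument_error")
})

test_that("ceiling bracketing and scan-oracle agreement hold across a random grid", {
  set.seed(2024)
  for (i in 1:200) {
    a <- runif(1, 0.5, 0.99); b <- runif(1, 0.5, 0.99)
    if (a + b <= 1 + 1e-9) next
    phi <- runif(1, 0.005, 0.5)
    rho <- runif(1, max(phi + 0.05, 0.5), 0.995)
    plan <- required_iterations(a, b, phi, rho)
    expect_equal(plan$feasibility, "feasible")
    expect_identical(plan$n_i, oracle_required_n(a, b, phi, rho))
    expect_gte(sequential_ppv(a, b, phi, plan$n_i), rho)
    if (plan$n_i > 1) expect_lt(sequential_ppv(a, b, phi, plan$n_i - 1), rho)
    else expect_lt(phi, rho)
  }
})

test_that("continuous count is the exact algebraic inverse of the power-form posterior", {
  set.seed(99)
  for (i in 1:200) {
    a <- runif(1, 0.05, 0.99); b <- runif(1, 0.05, 0.99)
    if (abs(a + b - 1) < 1e-6) next
    phi <- runif(1, 0.01, 0.99)
    rho <- runif(1, 0.01, 0.99)
    n <- required_iterations_continuous(phi, rho, sensitivity = a, specificity = b)
    expect_equal(oracle_power_form(a, b, phi, n), rho, tolerance = 1e-9)
  }
})

test_that("iteration counts fall with test strength and prevalence, rise with target", {
  n1 <- required_iterations_continuous(0.05, 0.95, log_lr_positive = seq(0.5, 5, 0.5))
  expect_true(all(diff(n1) < 0))
  n2 <- required_iterations_continuous(seq(0.01, 0.9, 0.05), 0.95, log_lr_positive = 1.5)
  expect_true(all(diff(n2) < 0))
  n3 <- required_iterations_continuous(0.05, c(0.5, 0.75, 0.95, 0.99), log_lr_positive = 1.5)
  expect_true(all(diff(n3) > 0))
  # inverse proportionality to ln LR+: doubling it halves the count
  expect_equal(required_iterations_continuous(0.05, 0.95, log_lr_positive = 2),
               required_iterations_continuous(0.05, 0.95, log_lr_positive = 1) / 2)
})

test_that("default reference tables reproduce the published grids", {
  for (target in c(0.99, 0.95, 0.75, 0.50)) {
    regen <- reference_table(target)
    published <- read_published_table(target)
    expect_equal(tidy(regen), tidy(published), tolerance = 1e-12)
  }
})

test_that("reference table cells decrease along both axes and duplicates are deterministic", {
  tab <- reference_table(0.95)
  m <- as.matrix(tibble::as_tibble(tab)[, -1])
  expect_true(all(apply(m, 1, function(r) all(diff(r) < 0)))) # across prevalence
  expect_true(all(apply(m, 2, function(c) all(diff(c) < 0)))) # down ln LR+
  dup <- reference_table(0.95, log_lr_positive = c(1, 1), prevalence = c(0.05, 0.1))
  expect_equal(unlist(dup[1, -1]), unlist(dup[2, -1]))
  expect_error(reference_table(0.95, log_lr_positive = c(-1, 2)),
               class = "seqppv_argument_error")
  expect_error(reference_table(0.95, prevalence = numeric(0)),
               class = "seqppv_argument_error")
})

test_that("tablecloth grid carries integer counts with infeasible markers", {
  single <- tablecloth(0.95, sensitivity = 0.9, specificity = 0.8, prevalence = 0.1)
  expect_equal(nrow(single), 1L)
  expect_equal(single$n_i, 4L)

  tc <- tablecloth(0.95, sensitivity = c(0.3, 0.9), specificity = c(0.3, 0.8),
                   prevalence = c(0.1, 0.95))
  bad <- tc$sensitivity + tc$specificity < 1
  expect_true(all(is.na(tc$n_i[bad & tc$prevalence < 0.95])))
  expect_true(all(tc$feasibility[bad & tc$prevalence < 0.95] == "infeasible_negative"))
  expect_true(all(tc$n_i[tc$prevalence >= 0.95] == 0L))
  expect_true(all(tc$feasibility[tc$prevalence >= 0.95] == "already_satisfied"))
  # never a negative count
  expect_true(all(is.na(tc$n_i) | tc$n_i >= 0L))
  expect_error(tablecloth(0.95, sensitivity = numeric(0)),
               class = "seqppv_argument_error")
})

test_that("plan_iterations() is the data-frame-first face of required_iterations()", {
  df <- tibble::tibble(sensitivity = 0.9, specificity = 0.8,
                       prevalence = c(0.02, 0.1))
  plan <- plan_iterations(df, target = 0.95)
  expect_equal(plan$n_i, c(5L, 4L))
  df2 <- dplyr::mutate(df, target_ppv = c(0.5, 0.99))
  plan2 <- plan_iterations(df2)
  expect_equal(plan2$target_ppv, c(0.5, 0.99))
})
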