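test_that("derived constants match direct evaluation of their formulas", {
  fx <- fixture("set40-fig1a")
  k <- derived_constants(fx$model)
  expect_equal(k$sigma2, 0.4, tolerance = 1e-12)       # 0.0256 / 0.064
  expect_equal(k$sigma_hat2, 0.8, tolerance = 1e-12)
  expect_equal(k$r1_up, 0.03664, tolerance = 1e-4)
  expect_equal(k$mean_co, 1 / 3, tolerance = 1e-12)
  expect_true(k$r1_low <= k$r1_up)
  expect_true(k$d12_low <= k$d12_up)
  expect_true(k$sigma2 <= min(0.8, 0.8) && 0.8 <= k$sigma_hat2 + 1e-15)

  kb <- derived_constants(fixture_model("set40-fig1b"))
  expect_equal(kb$sigma_hat2, 0.05, tolerance = 1e-12)
  expect_equal(kb$sigma2, 0.025, tolerance = 1e-12)

  # toxicant decoupled: starred constants collapse to the raw rates
  m0 <- model_params(patch_params(0.3, 0.6, 0.1, 0.1, 0.1),
                     patch_params(0.15, 0.3, 0.1, 0.1, 0.5),
                     migration_params(0.5, 0.6, rho = 0, alpha = 0.2),
                     toxicant_params(0.5, 0.3, 0.2, 0.3, 0.1, 1), delta = 0)
  k0 <- derived_constants(m0)
  expect_equal(k0$r1_up, 0.3)
  expect_equal(k0$r1_low, 0.3)
  expect_equal(k0$d12_up, 0.5)
  expect_equal(k0$d12_low, 0.5)
})

test_that("extinction criterion selects cases and reproduces margins", {
  e <- extinction_check(fixture_model("set40-fig1a"))
  expect_equal(e$case, "ii")
  expect_equal(e$functional, -0.2092, tolerance = 1e-3)
  expect_true(e$verdict)

  ec <- extinction_check(fixture_model("set40-fig1c"))
  expect_equal(ec$case, "ii")
  expect_equal(ec$functional, -0.0592, tolerance = 1e-3)
  expect_true(ec$verdict)

  # symmetric no-migration reduction: case i, scalar logistic criterion
  mk <- function(xi, mu) model_params(
    patch_params(0.1, 0.1, mu, xi, 0.1), patch_params(0.1, 0.1, mu, xi, 0.1),
    migration_params(0, 0, 0, 0.2),
    toxicant_params(0.5, 0.3, 0.2, 0.3, 0, 1), delta = 0)
  e0 <- extinction_check(mk(0.4, 0.1))
  expect_equal(e0$case, "i")
  expect_equal(e0$functional, 2 * 0.1 - 0.4, tolerance = 1e-12)
  expect_true(e0$verdict)
  expect_false(extinction_check(mk(0.1, 0.1))$verdict)
})

test_that("noise-free extinction follows the two printed inequalities", {
  # constructed case: r1_up = -0.5, r2e = 0.1, d12_up = 0.2, d21 = 0.6
  # -> 0.2*0.1 + (-0.5)*0.6 - (-0.5)*0.1 = -0.23 < 0 and r1_up < 0 -> TRUE
  k <- structure(list(r1_up = -0.5, d12_up = 0.2), class = "derived_constants")
  m <- model_params(patch_params(0.3, 0.6, 0.1, 0.1, 0.1),
                    patch_params(0.1, 0.3, 0.1, 0.1, 0.5),
                    migration_params(0.5, 0.6, 1.2, 0.2),
                    toxicant_params(0.5, 0.3, 0.2, 0.3, 0.1, 1), 0.8)
  expect_true(noise_free_extinction(m, k))
  # r1_up > 0 vetoes regardless of the second inequality
  k2 <- structure(list(r1_up = 0.2, d12_up = 0.2),
                  class = "derived_constants")
  expect_false(noise_free_extinction(m, k2))
  # delta = 0 with positive growth can never fire
  m0 <- model_params(patch_params(0.3, 0.6, 0.1, 0.1, 0.1),
                     patch_params(0.1, 0.3, 0.1, 0.1, 0.5),
                     migration_params(0.5, 0.6, 1.2, 0.2),
                     toxicant_params(0.5, 0.3, 0.2, 0.3, 0.1, 1), delta = 0)
  expect_false(noise_free_extinction(m0))
})

test_that("stochastic permanence compares the worst-case growth to noise", {
  # set40 with low noise: min(0.3 - 0.8*c_o^M, 0.15) ~ 0.0317 > 0.025
  expect_true(stochastic_permanence_check(fixture_model("set40-fig1b")))
  # same rates but high noise: 0.0317 < 0.5*0.8
  expect_false(stochastic_permanence_check(fixture_model("set40-fig1a")))
  k <- derived_constants(fixture_model("set40-fig1b"))
  expect_equal(min(k$r1_low, 0.15), 0.03167, tolerance = 1e-4)
})

test_that("persistence criterion reproduces the printed margins", {
  p <- persistence_mean_check(fixture_model("set40-fig1b"))
  expect_equal(p$case, "ii")
  expect_equal(p$functional, 0.1323, tolerance = 1e-3)
  expect_true(p$verdict)

  p41 <- persistence_mean_check(fixture_model("set41-fig2b"))
  expect_equal(p41$case, "ii")
  expect_equal(p41$functional, 0.2492, tolerance = 1e-3)
  expect_true(p41$verdict)
})

test_that("case functionals are continuous across the case boundary", {
  # with d12_up = d12_low = d21 = d and no toxicant, drive r1e -> r2e:
  # case ii/iii expressions must approach the case i expression
  mk <- function(r1e) model_params(
    patch_params(r1e, r1e, 0.1, 0.1, 0.1),
    patch_params(0.15, 0.15, 0.1, 0.1, 0.5),
    migration_params(0.3, 0.3, 0, 0.2),
    toxicant_params(0.5, 0.3, 0.2, 0.3, 0, 1), delta = 0)
  at <- function(r1e) extinction_check(mk(r1e))$functional
  exact <- at(0.15)                      # case i: 2*0.15 - sigma^2
  expect_equal(extinction_check(mk(0.15))$case, "i")
  for (eps in c(1e-4, 1e-6, 1e-8)) {
    expect_equal(at(0.15 - eps), exact, tolerance = 50 * eps)
    expect_equal(at(0.15 + eps), exact, tolerance = 50 * eps)
  }
  atp <- function(r1e) persistence_mean_check(mk(r1e))$functional
  exactp <- atp(0.15)
  for (eps in c(1e-4, 1e-6)) {
    expect_equal(atp(0.15 - eps), exactp, tolerance = 50 * eps)
    expect_equal(atp(0.15 + eps), exactp, tolerance = 50 * eps)
  }
})

test_that("margins move monotonically with the noise intensities", {
  mk <- function(xi) {
    fx <- fixture("set40")
    model_params(patch_params(0.3, 0.6, 0.1, xi, 0.1),
                 patch_params(0.15, 0.3, 0.1, xi, 0.5),
                 fx$model$migration, fx$model$toxicant, 0.8)
  }
  xis <- seq(0.05, 0.6, by = 0.05)
  ext <- vapply(xis, function(x) extinction_check(mk(x))$functional,
                numeric(1))
  per <- vapply(xis, function(x) persistence_mean_check(mk(x))$functional,
                numeric(1))
  expect_true(all(diff(ext) < 0))
  expect_true(all(diff(per) < 0))
})

test_that("rho = 0 collapses the starred rates to the baseline", {
  fx <- fixture("set40-fig1a")
  m <- fx$model
  m$migration <- migration_params(0.5, 0.6, rho = 0, alpha = 0.2)
  k <- derived_constants(m)
  expect_equal(k$d12_up, 0.5)
  expect_equal(k$d12_low, 0.5)
  e <- extinction_check(m, k)
  # matches the plain-d12 expression directly
  manual <- (k$r1_up + 0.15 - 0.5 - 0.6) +
    sqrt((k$r1_up - 0.15 + 0.6 - 0.5)^2 + 4 * 0.5 * 0.6) - k$sigma2
  expect_equal(e$functional, manual, tolerance = 1e-14)
})

test_that("mean lower bounds implement the average-rate formula", {
  fx <- fixture("set40-fig1b")
  m <- fx$model
  m$patch1 <- patch_params(0.8, 0.6, 0.1, 0.1, 0.1)
  m$delta <- 0.2
  b <- mean_lower_bounds(m)
  eta <- mean_holling_ce(m$toxicant, 0.2)
  expect_equal(b$bound_x1, (0.8 - 0.2 / 3 - 0.5 * (1 + 1.2 * eta)) / 0.1,
               tolerance = 1e-10)
  expect_equal(b$bound_x1, 1.677, tolerance = 2e-3)
  expect_equal(b$bound_x2, (0.15 - 0.6) / 0.5)
  expect_false(b$applicable)   # r2e < d21 here
  # logistic level when fully decoupled
  m2 <- model_params(patch_params(0.3, 0.6, 0.1, 0.1, 0.1),
                     patch_params(0.8, 0.3, 0.1, 0.1, 0.5),
                     migration_params(0, 0.1, 0, 0.2),
                     toxicant_params(0.5, 0.3, 0.2, 0.3, 0.1, 1), delta = 0)
  b2 <- mean_lower_bounds(m2)
  expect_equal(b2$bound_x1, 0.3 / 0.1)
  expect_true(b2$applicable)
})

test_that("p-moment bound evaluates the proof constants", {
  m <- fixture_model("set40-fig1b")
  expect_equal(pmoment_bound(m, 2), 342.25, tolerance = 1e-10)
  # noiseless limit
  m2 <- model_params(patch_params(0.3, 0.6, 0.1, 0, 0.1),
                     patch_params(0.15, 0.3, 0.1, 0, 0.5),
                     migration_params(0.5, 0.6, 1.2, 0.2),
                     toxicant_params(0.5, 0.3, 0.2, 0.3, 0.1, 1), 0.8)
  expect_equal(pmoment_bound(m2, 2), (2 * 0.9 / 0.1)^2)
  expect_error(pmoment_bound(m, 1), "greater than 1")
})

test_that("unpolluted thresholds use the raw rates", {
  m <- model_params(patch_params(0.3, 0.6, 0.1, 0.4, 0.1),
                    patch_params(0.15, 0.3, 0.1, 0.4, 0.5),
                    migration_params(0.5, 0.6, 1.2, 0.2),
                    toxicant_params(0.5, 0.3, 0.2, 0.3, 0.1, 1), 0.8)
  u <- unpolluted_thresholds(m)
  expr <- -0.65 + sqrt(0.0625 + 1.2)
  expect_equal(u$extinction_functional, expr - 0.4, tolerance = 1e-12)
  expect_false(u$extinction_verdict)    # 0.4736 not below sigma^2 = 0.4
  # no migration: expression collapses to 2 max(r1e, r2e)
  m2 <- model_params(patch_params(0.3, 0.6, 0.1, 0.1, 0.1),
                     patch_params(0.15, 0.3, 0.1, 0.1, 0.5),
                     migration_params(0, 0, 0, 0.2),
                     toxicant_params(0.5, 0.3, 0.2, 0.3, 0, 1), 0)
  u2 <- unpolluted_thresholds(m2)
  expect_equal(u2$persistence_functional + 0.05, 0.6, tolerance = 1e-12)
  # symmetric rates and migration: expression is 2 r
  m3 <- model_params(patch_params(0.2, 0.2, 0.1, 0.1, 0.1),
                     patch_params(0.2, 0.2, 0.1, 0.1, 0.1),
                     migration_params(0.3, 0.3, 0, 0.2),
                     toxicant_params(0.5, 0.3, 0.2, 0.3, 0, 1), 0)
  u3 <- unpolluted_thresholds(m3)
  expect_equal(u3$extinction_functional + 0.025, 0.4, tolerance = 1e-12)
})

test_that("classification aggregates with the documented precedence", {
  rep_a <- classify(fixture_model("set40-fig1a"))
  expect_match(rep_a$notes, "extinction \\(case ii\\)")
  rep_b <- classify(fixture_model("set40-fig1b"))
  # permanence fires first in precedence; persistence also holds
  expect_true(rep_b$persistence_verdict)
  expect_match(rep_b$notes, "permanent|persistent")
  # nothing fires: r1e + r2e sits between sigma^2 and sigma_hat^2 while
  # min(r) stays below 0.5 sigma_hat^2
  m <- model_params(patch_params(0.15, 0.15, 0.1, 0.3, 0.1),
                    patch_params(0.15, 0.15, 0.1, 0.3, 0.5),
                    migration_params(0, 0, 0, 0.2),
                    toxicant_params(0.5, 0.3, 0.2, 0.3, 0, 1), 0)
  expect_equal(classify(m)$notes, "inconclusive")
  # tidy/glance surfaces
  td <- tidy(rep_a)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  expect_true(td$verdict[td$criterion == "extinction"])
  gl <- glance(rep_a)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$sigma2, 0.4, tolerance = 1e-12)
  js <- report_json(rep_a)
  expect_true(jsonlite::validate(js))
})
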