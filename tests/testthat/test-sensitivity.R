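test_that("method-of-moments fits reproduce their input moments analytically", {
  g <- gamma_from_moments(436, 11)
  expect_equal(g$shape, (436 / 11)^2)
  expect_equal(g$shape * g$scale, 436, tolerance = 1e-12)
  expect_equal(sqrt(g$shape) * g$scale, 11, tolerance = 1e-12)
  expect_equal(gamma_from_moments(1, 1), list(shape = 1, scale = 1))

  b <- beta_from_moments(0.56, 0.0152)
  expect_equal(b$alpha, 596.67, tolerance = 1e-4)
  expect_equal(b$beta, 468.81, tolerance = 1e-4)
  mean_b <- b$alpha / (b$alpha + b$beta)
  var_b <- b$alpha * b$beta / ((b$alpha + b$beta)^2 * (b$alpha + b$beta + 1))
  expect_equal(mean_b, 0.56, tolerance = 1e-9)
  expect_equal(sqrt(var_b), 0.0152, tolerance = 1e-9)

  l <- lognormal_from_moments(0.8647, 0.08)
  expect_equal(exp(l$mu + l$sigma^2 / 2), 0.8647, tolerance = 1e-9)
  expect_equal(sqrt((exp(l$sigma^2) - 1) * exp(2 * l$mu + l$sigma^2)), 0.08,
               tolerance = 1e-9)

  # moment roundtrip holds for every non-degenerate fixture parameter
  tab <- build_param_table(example_model())
  for (j in which(tab$family != "fixed")) {
    row <- tab[j, ]
    mo <- switch(row$family,
      gamma = { f <- gamma_from_moments(row$mean, row$se)
                c(f$shape * f$scale, sqrt(f$shape) * f$scale) },
      beta = { f <- beta_from_moments(row$mean, row$se)
               n <- f$alpha + f$beta
               c(f$alpha / n, sqrt(f$alpha * f$beta / (n^2 * (n + 1)))) },
      lognormal = { f <- lognormal_from_moments(row$mean, row$se)
                    c(exp(f$mu + f$sigma^2 / 2),
                      sqrt((exp(f$sigma^2) - 1) * exp(2 * f$mu + f$sigma^2))) })
    expect_equal(mo, c(row$mean, row$se), tolerance = 1e-9)
  }
})

test_that("infeasible or degenerate moments are rejected with clear errors", {
  expect_error(beta_from_moments(0.5, 0.6), "infeasible")
  expect_error(beta_from_moments(1.2, 0.1), "\\(0, 1\\)")
  expect_error(gamma_from_moments(-1, 1), "mean")
  expect_error(gamma_from_moments(436, 0), "fixed")
  expect_error(lognormal_from_moments(0.5, 0), "fixed")
})

test_that("sampled means land within Monte-Carlo error of the target", {
  n <- 1e5
  set.seed(42)
  g <- gamma_from_moments(436, 11)
  x <- rgamma(n, shape = g$shape, scale = g$scale)
  expect_lt(abs(mean(x) - 436), 3 * 11 / sqrt(n))
  b <- beta_from_moments(0.56, 0.0152)
  y <- rbeta(n, b$alpha, b$beta)
  expect_lt(abs(mean(y) - 0.56), 3 * 0.0152 / sqrt(n))
  l <- lognormal_from_moments(0.8647, 0.08)
  z <- rlnorm(n, l$mu, l$sigma)
  expect_lt(abs(mean(z) - 0.8647), 3 * 0.08 / sqrt(n))
  # the probability clamp only truncates draws above 1
  expect_equal(pmin(pmax(z, 0), 1), pmin(z, 1))
})

test_that("pinning parameters rewrites exactly the addressed scalar", {
  m <- example_model()
  m2 <- apply_params(m, c("state.glucosamine.cycle_cost" = 2000,
                          "utility.moderate_pain" = 0.40,
                          "disutility.stroke" = 0.06,
                          "ae_cost.mi.first_year" = 5000,
                          "econ.travel_cost" = 100,
                          "state.tka.ae.mi" = 0.05))
  expect_equal(m2$states$glucosamine$cycle_cost, 2000)
  expect_equal(m2$utilities$moderate_pain, 0.40)
  expect_equal(m2$adverse_events$stroke$disutility, -0.06)
  expect_equal(m2$adverse_events$mi$first_year_cost, 5000)
  expect_equal(m2$economics$travel_cost, 100)
  expect_equal(unname(m2$states$tka$ae_incidence["mi"]), 0.05)
  # everything else untouched
  expect_equal(m2$states$etoricoxib, m$states$etoricoxib)
  expect_error(apply_params(m, c("state.ghost.cycle_cost" = 1)), "unknown")
  expect_error(apply_params(m, c("nonsense" = 1)), "unknown")
})

test_that("one-way analysis pins low and high and reports the bar", {
  m <- example_model()
  cmp <- c("glucosamine_before_etoricoxib", "glucosamine_before")
  # etoricoxib sits only in the add-on arm, so its cost moves the increment
  z <- one_way_dsa(m, "state.etoricoxib.cycle_cost", 4000, 6500,
                   comparison = cmp)
  expect_equal(z$bar_width, abs(z$output_at_high - z$output_at_low))
  expect_gt(z$bar_width, 0)
  # glucosamine sits in both arms at the same position: its cost cancels
  # out of the incremental comparison
  zg <- one_way_dsa(m, "state.glucosamine.cycle_cost", 1499.2, 2248.8,
                    comparison = cmp)
  expect_equal(zg$bar_width, 0, tolerance = 1e-6)
  z0 <- one_way_dsa(m, "utility.moderate_pain", 0.56, 0.56, comparison = cmp)
  expect_equal(z0$bar_width, 0)
  expect_error(one_way_dsa(m, "utility.moderate_pain", 0.5, 1.2,
                           comparison = cmp), "outside")
  expect_error(one_way_dsa(m, "not.a.param", 0, 1, comparison = cmp),
               "valid ids")
  expect_error(one_way_dsa(m, "utility.moderate_pain", 0.7, 0.3,
                           comparison = cmp), "low > high")
})

test_that("the tornado is sorted, deduplicated, and led by the pain utility", {
  m <- example_model()
  cmp <- c("glucosamine_before_etoricoxib", "glucosamine_before")
  tor <- tornado_analysis(m, comparison = cmp)
  expect_equal(nrow(tor), 6)
  expect_true(all(diff(tor$bar_width) <= 0))
  # the moderate-pain utility range [0.35, 0.77] dwarfs every cost bar and
  # sits at the top of the diagram alongside the NSAID transition
  # probability (whose default range reaches the no-progression boundary)
  expect_lte(which(tor$parameter == "utility.moderate_pain"), 2)
  bar <- stats::setNames(tor$bar_width, tor$parameter)
  expect_gt(bar[["utility.moderate_pain"]],
            10 * bar[["state.tka.one_time_cost"]])
  # the narrow published TKA cost range is among the narrowest bars
  expect_gte(which(tor$parameter == "state.tka.one_time_cost"), 4)
  expect_warning(
    tor2 <- tornado_analysis(m, params = list(
      list(param = "utility.moderate_pain", low = 0.35, high = 0.77),
      list(param = "utility.moderate_pain", low = 0.35, high = 0.77)),
      comparison = cmp),
    "duplicate")
  expect_equal(nrow(tor2), 1)
  expect_equal(nrow(tornado_analysis(m, params = list(), comparison = cmp)), 0)
})

test_that("PSA is deterministic given a seed and parameter streams are stable", {
  m <- generate_model(3, seed = 5)
  p1 <- run_psa(m, n_iter = 5, seed = 99)
  p2 <- run_psa(m, n_iter = 5, seed = 99)
  expect_identical(p1$results, p2$results)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(m, n_iter = 5, seed = 100)
  expect_false(identical(p1$draws, p3$draws))
  # per-parameter substreams: a subset registry reproduces the same columns
  tab <- build_param_table(m)
  full <- sample_params(tab, 7, seed = 3)
  sub <- sample_params(tab[c(2, 5, 9), ], 7, seed = 3)
  expect_identical(full[, colnames(sub)], sub)
  expect_error(run_psa(m, n_iter = 0), "n_iter")
})

test_that("a zero-variance PSA reproduces the base case exactly", {
  m <- generate_model(3, seed = 2)
  m$uncertainty$default_se_frac <- 0
  for (k in names(m$adverse_events)) {
    m$adverse_events[[k]]$acute_cost_se <- 0
    m$adverse_events[[k]]$first_year_cost_se <- 0
    m$adverse_events[[k]]$subsequent_year_cost_se <- 0
    m$adverse_events[[k]]$disutility_se <- 0
  }
  m$utilities$no_pain_se <- 0
  m$utilities$moderate_pain_se <- 0
  m$economics$travel_cost_se <- 0
  m$economics$food_cost_se <- 0
  expect_true(all(build_param_table(m)$family == "fixed"))
  psa <- run_psa(m, n_iter = 3, seed = 1)
  base <- run_all_strategies(m)
  for (s in base$strategy) {
    r <- psa$results[psa$results$strategy == s, ]
    expect_equal(r$cost, rep(base$cost[base$strategy == s], 3))
    expect_equal(r$qaly, rep(base$qaly[base$strategy == s], 3))
  }
})

test_that("PSA sample means track the base means on the fixture", {
  m <- example_model()
  tab <- build_param_table(m)
  draws <- sample_params(tab, 1000, seed = 7)
  for (j in seq_len(nrow(tab))) {
    if (tab$family[j] == "fixed") next
    se_mc <- 3 * tab$se[j] / sqrt(1000)
    mu <- mean(draws[, tab$id[j]])
    # lognormal transition draws are clamped to [0, 1], which can only
    # pull the mean down; allow that one-sided effect
    if (tab$family[j] == "lognormal")
      expect_lt(mu, tab$mean[j] + se_mc)
    else
      expect_lt(abs(mu - tab$mean[j]), se_mc + 1e-12)
  }
})

test_that("infeasible beta moments surface as a named PSA error", {
  m <- generate_model(3, seed = 13, infeasible_se = TRUE)
  expect_error(run_psa(m, n_iter = 2, seed = 1), "infeasible")
  expect_error(run_psa(m, n_iter = 2, seed = 1), "state\\.")
})

test_that("the CE plane classifies quadrants with favourable ties", {
  fake <- structure(list(results = data.frame(
    iteration = rep(1:4, each = 2),
    strategy = rep(c("a", "b"), 4),
    cost = c(90, 100, 110, 100, 100, 100, 95, 100),
    qaly = c(1.2, 1.0, 1.3, 1.0, 1.1, 1.0, 0.9, 1.0))), class = "oa_psa")
  pl <- ce_plane(fake, "a", "b")
  expect_identical(pl$points$quadrant,
                   c("lower_right", "upper_right", "lower_right", "lower_left"))
  expect_equal(unname(pl$proportions["lower_right"]), 0.5)
  expect_equal(sum(pl$proportions), 1)
})

test_that("degenerate CEAC is a step function at the deterministic ICER", {
  # two riskless strategies: ICER = 50,000/QALY
  fake <- structure(list(results = data.frame(
    iteration = rep(1:3, each = 2),
    strategy = rep(c("a", "b"), 3),
    cost = rep(c(150000, 100000), 3),
    qaly = rep(c(3, 2), 3))), class = "oa_psa")
  cv <- ceac(fake, wtp_grid = c(0, 25000, 49999, 50000, 60000), "a", "b")
  expect_equal(cv$prob, c(0, 0, 0, 1, 1))
  # multi-way probabilities partition to one at every grid point
  mw <- ceac(fake, wtp_grid = c(0, 50000, 100000))
  expect_equal(mw$a + mw$b, rep(1, 3))
  # when one strategy wins both dimensions in every draw its curve is 1
  fake2 <- structure(list(results = data.frame(
    iteration = rep(1:2, each = 2), strategy = rep(c("a", "b"), 2),
    cost = rep(c(90, 100), 2), qaly = rep(c(2, 1), 2))), class = "oa_psa")
  expect_equal(ceac(fake2, wtp_grid = seq(0, 1e5, 2.5e4), "a", "b")$prob,
               rep(1, 5))
  expect_error(ceac(fake2, wtp_grid = numeric(), "a", "b"), "empty")
})
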