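test_that("specificity ratio matches its closed forms", {
  sym <- specificity_ratio(0.5, 2, 2)
  expect_equal(sym$rs, 1)
  expect_equal(specificity_ratio(1, 5, 0.5)$rs, 0)

  rsc <- specificity_ratio(0.27, 5.0, 0.5)
  expect_equal(rsc$rs1, 27.04, tolerance = 0.001)
  expect_equal(rsc$rs2, 2.704, tolerance = 0.001)
  expect_equal(rsc$rs, 14.87, tolerance = 0.001)
  expect_equal(rsc$rs, (rsc$rs1 + rsc$rs2) / 2)
  expect_error(specificity_ratio(0, 5, 0.5), "fraction")
})

test_that("free time solves the bound-fraction balance", {
  expect_equal(free_time(0.5, 0, 1, 0), 0.5)
  expect_warning(tf1 <- free_time(1, 2, 5, 0.5), "degenerate")
  expect_equal(tf1, 0)
  expect_equal(free_time(0.66, 14.87, 5.0, 0.5), 0.395, tolerance = 0.002)
  # numerically solving the balance equation gives the same value
  rs <- 14.87; tau_tb <- 0.5; tau_sb <- 5.0; F_b <- 0.66
  n_tr <- 1 + rs
  balance <- function(tf) {
    (n_tr * tau_tb + tau_sb) /
      (n_tr * tau_tb + tau_sb + (n_tr + 1) * tf) - F_b
  }
  tf_num <- stats::uniroot(balance, c(1e-6, 100), tol = 1e-12)$root
  expect_equal(free_time(F_b, rs, tau_sb, tau_tb), tf_num, tolerance = 1e-6)
})

test_that("search time and sampling interval follow the trial calculus", {
  expect_equal(search_time(0, 0.5, 0.2)$tau_search, 0.5 + 2 * 0.2)
  expect_equal(search_time(0, 0, 0)$tau_search, 0)
  expect_equal(search_time(14.87, 0.5, 0.395)$tau_search, 14.6,
               tolerance = 0.01)
  expect_equal(sampling_interval(15, 5, 100, 100), 20)
  expect_equal(sampling_interval(14.6, 5.0, 3702, 4355), 16.7,
               tolerance = 0.02)
  expect_equal(sampling_interval(15, 5, 3702, 2 * 4355),
               sampling_interval(15, 5, 3702, 4355) / 2)
})

test_that("occupancy is tau_sb / SI with a saturation warning", {
  expect_equal(occupancy(5.0, 17), 0.294, tolerance = 0.001)
  expect_equal(occupancy(4.4, 4.7), 0.936, tolerance = 0.001)
  expect_equal(occupancy(5, 5), 1)
  expect_warning(occ <- occupancy(6, 5), "exceeds 1")
  expect_equal(occ, 1.2)
  expect_error(occupancy(5, 0), "positive")
})

test_that("derived trials and free time reproduce the input bound fraction", {
  withr::with_seed(101, {
    for (i in 1:1000) {
      F_b <- runif(1, 0.05, 0.95)
      f_sb <- runif(1, 0.05, 0.95)
      tau_tb <- runif(1, 0.05, 2)
      tau_sb <- tau_tb * runif(1, 1.5, 30)
      kin <- derive_search_kinetics(F_b, f_sb, tau_sb, tau_tb,
                                    N_targets = 1000, N_molecules = 1000)
      F_back <- (kin$n_trials * tau_tb + tau_sb) /
        (kin$n_trials * tau_tb + tau_sb + (kin$n_trials + 1) * kin$tau_free)
      expect_equal(F_back, F_b, tolerance = 1e-12)
    }
  })
})

test_that("occupancy responds monotonically to copy number and target count", {
  occ_at <- function(N_targets, N_molecules) {
    derive_search_kinetics(0.5, 0.25, 5, 0.5, N_targets, N_molecules)$occupancy
  }
  expect_true(occ_at(1000, 2000) > occ_at(1000, 1000))
  expect_true(occ_at(2000, 1000) < occ_at(1000, 1000))
})

test_that("Monte-Carlo error propagation behaves like the delta method", {
  kin <- list(F_bound = 0.66, f_sb = 0.27, tau_sb = 5, tau_tb = 0.5,
              N_targets = 3702, N_molecules = 4355)
  none <- propagate_errors(kin, n_draws = 500, seed = 1)
  expect_true(all(none$se == 0))

  kin$N_molecules_se <- 300
  prop <- propagate_errors(kin, n_draws = 20000, seed = 2)
  si <- prop[prop$quantity == "sampling_interval", ]
  rel_in <- 300 / 4355
  expect_lt(abs(si$se / si$value - rel_in) / rel_in, 0.1)
  again <- propagate_errors(kin, n_draws = 20000, seed = 2)
  expect_identical(prop, again)
})

test_that("the bundled remodeler table carries the expected structure", {
  rk <- remodeler_kinetics()
  expect_setequal(rk$factor, c("RSC", "SWI/SNF", "INO80", "ISW2"))
  expect_true(all(rk$tau_tb_source == "assumed"))
  expect_true(all(rk$f_sb > 0 & rk$f_sb < 1))
  expect_true(all(rk$SI > rk$tau_sb))
})
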