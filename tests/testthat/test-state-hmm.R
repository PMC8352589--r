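test_that("Baum-Welch recovers state D values and transition rates", {
  sim <- hmm_fixture(n_traj = 800, seed = 5)
  model <- fit_hmm_two_state(sim$trajectories, seed = 2)
  expect_lt(abs(model$D[["bound"]] - 0.03) / 0.03, 0.15)
  expect_lt(abs(model$D[["free"]] - 1.0) / 1.0, 0.15)
  # true per-frame switching probability 1 - exp(-10 * 0.01) = 0.095
  expect_lt(abs(model$transition["bound", "free"] - 0.095), 0.02)
  expect_false(model$degenerate)
  # EM log-likelihood is non-decreasing over iterations
  expect_true(all(diff(model$loglik_trace) > -1e-6 * abs(model$loglik)))
})

test_that("no-transition data yields near-zero off-diagonal probabilities", {
  sim <- hmm_fixture(n_traj = 500, seed = 6, k_off = 0, k_on = 0)
  model <- fit_hmm_two_state(sim$trajectories, seed = 3)
  expect_lte(model$transition["bound", "free"], 0.02)
  expect_lte(model$transition["free", "bound"], 0.02)
})

test_that("Viterbi decoding is accurate and deterministic for separated states", {
  sim <- hmm_fixture(n_traj = 800, seed = 5)
  model <- fit_hmm_two_state(sim$trajectories, seed = 2)
  expect_gte(label_accuracy(sim, model), 0.95)
  a <- classify_displacements(model, sim$trajectories)
  b <- classify_displacements(model, sim$trajectories)
  expect_identical(a, b)
  # two-localization tracks carry one displacement and are excluded
  short <- tibble::tibble(track_id = 1, frame = 0:1, x_um = c(0, 1),
                          y_um = 0)
  expect_equal(nrow(classify_displacements(model, short)), 0L)
})

test_that("trajectory sub-classification follows the consecutive-run rule", {
  lab <- function(states) tibble::tibble(track_id = 1,
                                         step = seq_along(states),
                                         state = states)
  tran <- subclassify_trajectories(lab(c("bound", "bound", "free", "free")))
  expect_equal(tran$class, "transitioning")
  expect_equal(tran$n_bf, 1L)
  expect_equal(tran$n_fb, 0L)

  alt <- subclassify_trajectories(lab(c("bound", "free", "bound", "free")))
  expect_equal(alt$class, "mixed_unclassified")

  expect_equal(subclassify_trajectories(lab(rep("bound", 3)))$class,
               "bound_only")
  expect_equal(subclassify_trajectories(lab(rep("free", 2)))$class,
               "free_only")
})

test_that("symmetric kinetics give balanced transition directions", {
  sim <- hmm_fixture(n_traj = 800, seed = 5)
  model <- fit_hmm_two_state(sim$trajectories, seed = 2)
  cls <- subclassify_trajectories(classify_displacements(model, sim$trajectories))
  summ <- class_summary(cls)
  n_tr <- sum(summ$transitions$n)
  frac_bf <- summ$transitions$frac[summ$transitions$direction == "bound->free"]
  expect_lt(abs(frac_bf - 0.5), 3 * sqrt(0.25 / n_tr))
})

test_that("remodeler-like kinetics transition far more often than H2B-like", {
  remodeler <- hmm_fixture(n_traj = 500, seed = 7, k_off = 10, k_on = 10)
  h2b <- hmm_fixture(n_traj = 500, seed = 8, k_off = 0.3, k_on = 1.2)
  frac_transitioning <- function(sim) {
    model <- fit_hmm_two_state(sim$trajectories, seed = 4)
    cls <- subclassify_trajectories(
      classify_displacements(model, sim$trajectories))
    summ <- class_summary(cls)$classes
    summ$pct[summ$class == "transitioning"] / 100
  }
  f_rem <- frac_transitioning(remodeler)
  f_h2b <- frac_transitioning(h2b)
  expect_gt(f_rem, 2 * f_h2b)
})

test_that("bound segments of transitioning tracks move like bound-only tracks", {
  sim <- hmm_fixture(n_traj = 1200, seed = 9, k_off = 5, k_on = 5)
  model <- fit_hmm_two_state(sim$trajectories, seed = 2)
  lab <- classify_displacements(model, sim$trajectories)
  cls <- subclassify_trajectories(lab)
  disp <- sim$trajectories |>
    dplyr::arrange(track_id, frame) |>
    dplyr::group_by(track_id) |>
    dplyr::reframe(step = frame[-1],
                   r = sqrt(diff(x_um)^2 + diff(y_um)^2)) |>
    dplyr::inner_join(lab, by = c("track_id", "step")) |>
    dplyr::inner_join(dplyr::select(cls, track_id, class), by = "track_id")
  med_bound_only <- median(disp$r[disp$class == "bound_only" &
                                    disp$state == "bound"])
  med_trans_bound <- median(disp$r[disp$class == "transitioning" &
                                     disp$state == "bound"])
  expect_lt(abs(med_trans_bound - med_bound_only) / med_bound_only, 0.1)
})
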