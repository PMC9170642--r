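test_that("controller and observer specs validate their parameters", {
  expect_error(controller_spec("greedy_avoid", reaction_latency = -1), "latency")
  expect_error(controller_spec("greedy_avoid", max_pointer_speed = 0), "pointer_speed")
  expect_error(controller_spec("teleport"), "arg")
  expect_error(observer_spec(-1), "capacity")
  expect_error(observer_spec(2.5), "capacity")
})

test_that("greedy pointer flees the most imminent threat", {
  cfg <- moa_config()
  spec <- controller_spec("greedy_avoid", reaction_latency = 0,
                          max_pointer_speed = 600, motor_noise_sd = 0)
  # single hazard approaching head-on from the left -> move right
  st <- make_moa_state(user = c(400, 400),
                       pos = matrix(c(200, 400), 1),
                       vel = matrix(c(150, 0), 1), activation = 0)
  p <- greedy_avoid_pointer(st, spec, cfg)
  expect_gt(p[1], 400)
  expect_equal(p[2], 400)
  # all hazards receding -> hold position
  st <- make_moa_state(user = c(400, 400),
                       pos = matrix(c(200, 400, 400, 600), 2, byrow = TRUE),
                       vel = matrix(c(-100, 0, 0, 100), 2, byrow = TRUE),
                       activation = c(0, 0))
  expect_equal(greedy_avoid_pointer(st, spec, cfg), c(400, 400))
  # unfilled hazards are not threats at zero latency
  st <- make_moa_state(user = c(400, 400),
                       pos = matrix(c(200, 400), 1),
                       vel = matrix(c(150, 0), 1), activation = 5)
  expect_equal(greedy_avoid_pointer(st, spec, cfg), c(400, 400))
  # ... but are threats once latency covers their activation
  spec_lag <- controller_spec("greedy_avoid", reaction_latency = 6,
                              max_pointer_speed = 600, motor_noise_sd = 0)
  expect_gt(greedy_avoid_pointer(st, spec_lag, cfg)[1], 400)
})

test_that("greedy threat choice matches a brute-force TTC oracle", {
  cfg <- moa_config()
  spec <- controller_spec("greedy_avoid", reaction_latency = 0,
                          max_pointer_speed = 600, motor_noise_sd = 0)
  # brute-force time to first user overlap by tiny-step integration
  ttc_brute <- function(user, p, v, dt = 1e-4, horizon = 30) {
    t <- 0
    while (t < horizon) {
      p <- p + v * dt
      t <- t + dt
      if (sqrt(sum((p - user)^2)) < 40) return(t)
    }
    Inf
  }
  set.seed(71)
  agree <- 0
  for (i in 1:25) {
    user <- c(400, 400)
    ang <- runif(2, 0, 2 * pi)
    d <- runif(2, 100, 350)
    pos <- rbind(user + d[1] * c(cos(ang[1]), sin(ang[1])),
                 user + d[2] * c(cos(ang[2]), sin(ang[2])))
    # aim roughly at the user with random speeds
    vel <- rbind((user - pos[1, ]) / d[1] * runif(1, 80, 400),
                 (user - pos[2, ]) / d[2] * runif(1, 80, 400))
    st <- make_moa_state(user = user, pos = pos, vel = vel,
                         activation = c(0, 0))
    t1 <- ttc_brute(user, pos[1, ], vel[1, ])
    t2 <- ttc_brute(user, pos[2, ], vel[2, ])
    if (abs(t1 - t2) < 0.05) next   # skip near-ties
    worst <- if (t1 < t2) 1 else 2
    p <- greedy_avoid_pointer(st, spec, cfg)
    move <- p - user
    away <- user - pos[worst, ]
    expect_gt(sum(move * away), 0)  # moves away from the sooner threat
    agree <- agree + 1
  }
  expect_gt(agree, 15)
})

test_that("capacity-k selection hits its closed-form expected accuracy", {
  cfg <- mot_config()
  st <- mot_begin_movement(mot_init_trial(cfg, 11))
  st <- moabattery:::mot_advance_exact(st, cfg, cfg$move_duration)
  # k = 5: always perfect
  set.seed(1)
  expect_setequal(capacity_k_select(st, observer_spec(5), cfg),
                  st$target_indices)
  # enumeration oracle vs closed form, all k
  for (k in 0:5) {
    expect_equal(enum_capacity_expected_correct(k),
                 k + (5 - k)^2 / (10 - k), tolerance = 1e-12)
  }
  # Monte-Carlo agreement for k = 0 and k = 3 at modest n
  for (k in c(0, 3)) {
    set.seed(100 + k)
    hits <- replicate(3000, {
      sel <- capacity_k_select(st, observer_spec(k), cfg)
      length(intersect(sel, st$target_indices))
    })
    se <- sd(hits) / sqrt(length(hits))
    expect_lt(abs(mean(hits) - enum_capacity_expected_correct(k)), 3 * se)
  }
})

test_that("skill ordering: greedy beats stationary; latency hurts", {
  cfg <- moa_config()
  mean_surv <- function(ctrl, seeds) {
    mean(vapply(seeds, function(s)
      moa_run_trial(cfg, ctrl, s)$survival_time, 1))
  }
  seeds <- 1:200
  m_greedy <- mean_surv(controller_spec("greedy_avoid", 0, 600, 0), seeds)
  m_stat <- mean_surv(controller_spec("stationary"), seeds)
  m_lag <- mean_surv(controller_spec("greedy_avoid", 0.5, 600, 0), seeds)
  expect_gt(m_greedy, m_stat)
  expect_gte(m_greedy, m_lag)
})

test_that("mean survival is non-increasing in hazard speed cap", {
  ctrl <- controller_spec("greedy_avoid", 0.25, 600, 2)
  means <- sapply(c(170, 340, 680), function(vmax) {
    cfg <- moa_config(speed_max = vmax)
    mean(vapply(1:200, function(s)
      moa_run_trial(cfg, ctrl, s)$survival_time, 1))
  })
  expect_true(all(diff(means) <= 0))
})

test_that("null cohorts show no group difference; designed ones do", {
  null_spec <- cohort_spec(
    group_a = group_params(40, "a"), group_b = group_params(40, "b"),
    group_effect = "none", master_seed = 101)
  tab <- simulate_cohort(null_spec, tasks = c("mot", "dsst"))
  expect_equal(nrow(tab), 80)
  a <- tab$mot_mean_accuracy[tab$group == "a"]
  b <- tab$mot_mean_accuracy[tab$group == "b"]
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 3 * se)

  des <- cohort_spec(
    group_a = group_params(40, "hi", capacity_mean = 4, capacity_sd = 0),
    group_b = group_params(40, "lo", capacity_mean = 2, capacity_sd = 0),
    group_effect = "capacity 4 vs 2", master_seed = 102)
  tab <- simulate_cohort(des, tasks = "mot")
  hi <- mean(tab$mot_mean_accuracy[tab$group == "hi"])
  lo <- mean(tab$mot_mean_accuracy[tab$group == "lo"])
  expect_gt(hi, lo)
  # closed-form observer accuracies bracket the group means
  expect_lt(abs(hi - enum_capacity_expected_correct(4) / 5), 0.05)
  expect_lt(abs(lo - enum_capacity_expected_correct(2) / 5), 0.05)
})

test_that("cohort simulation is deterministic in the master seed", {
  spec <- cohort_spec(group_a = group_params(3, "a"),
                      group_b = group_params(3, "b"), master_seed = 55)
  t1 <- simulate_cohort(spec)
  t2 <- simulate_cohort(spec)
  expect_identical(t1, t2)
  expect_true(all(!is.na(t1$moa_score_s)))
  expect_true(all(t1$dsst_score >= 0 & t1$dsst_score <= 93))
})
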