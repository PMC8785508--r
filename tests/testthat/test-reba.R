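test_that("lookup tables are total over their declared index ranges", {
  a <- expand.grid(trunk = 1:5, neck = 1:3, legs = 1:4)
  sa <- reba_table_a(a$trunk, a$neck, a$legs)
  expect_false(anyNA(sa))
  expect_true(all(sa %in% 1:9))
  b <- expand.grid(upper_arm = 1:6, lower_arm = 1:2, wrist = 1:3)
  sb <- reba_table_b(b$upper_arm, b$lower_arm, b$wrist)
  expect_false(anyNA(sb))
  expect_true(all(sb %in% 1:9))
  cc <- expand.grid(score_a = 1:12, score_b = 1:12)
  sc <- reba_table_c(cc$score_a, cc$score_b)
  expect_false(anyNA(sc))
  expect_true(all(sc %in% 1:12))
  # table C is monotone in both inputs
  m <- matrix(sc, 12, 12)
  expect_true(all(diff(m) >= 0) && all(t(diff(t(m))) >= 0))
})

test_that("extreme and hand-traced postures score as expected", {
  expect_equal(reba_table_a(1, 1, 1), 1)
  expect_equal(reba_table_a(5, 3, 4), 9)
  expect_equal(reba_table_b(1, 1, 1), 1)
  expect_equal(reba_table_b(6, 2, 3), 9)
  low <- data.frame(trunk = 1, neck = 1, legs = 1, upper_arm = 1,
                    lower_arm = 1, wrist = 1, load_force = 0, coupling = 0,
                    activity = 0)
  expect_equal(reba_score(low)$reba, 1)
  high <- data.frame(trunk = 5, neck = 3, legs = 4, upper_arm = 6,
                     lower_arm = 2, wrist = 3, load_force = 3, coupling = 3,
                     activity = 3)
  expect_equal(reba_score(high)$reba, 15)
  # hand-traced interior case: A(3,2,2)=5 +1 -> 6; B(4,2,2)=6 +2 -> 8;
  # C(6,8)=9; +1 activity -> 10
  mid <- data.frame(trunk = 3, neck = 2, legs = 2, upper_arm = 4,
                    lower_arm = 2, wrist = 2, load_force = 1, coupling = 2,
                    activity = 1)
  out <- reba_score(mid)
  expect_equal(out$score_a, 6)
  expect_equal(out$score_b, 8)
  expect_equal(out$score_c, 9)
  expect_equal(out$reba, 10)
})

test_that("final score is monotone in each adjustment", {
  set.seed(4)
  obs <- data.frame(trunk = sample(1:5, 30, TRUE),
                    neck = sample(1:3, 30, TRUE),
                    legs = sample(1:4, 30, TRUE),
                    upper_arm = sample(1:6, 30, TRUE),
                    lower_arm = sample(1:2, 30, TRUE),
                    wrist = sample(1:3, 30, TRUE),
                    load_force = sample(0:2, 30, TRUE),
                    coupling = sample(0:2, 30, TRUE),
                    activity = sample(0:2, 30, TRUE))
  base <- reba_score(obs)$reba
  for (adj in c("load_force", "coupling", "activity")) {
    bumped <- obs
    bumped[[adj]] <- bumped[[adj]] + 1
    expect_true(all(reba_score(bumped)$reba >= base), label = adj)
  }
})

test_that("out-of-range joints are rejected by name", {
  expect_error(reba_table_a(6, 1, 1), "trunk")
  expect_error(reba_table_b(1, 3, 1), "lower_arm")
  expect_error(reba_table_c(13, 1), "score_a")
})

test_that("action levels condense to four ordered categories", {
  expect_equal(as.character(reba_action_level(c(1, 15))),
               c("low", "very_high"))
  expect_equal(as.character(reba_action_level(c(3, 4, 7, 8, 10, 11))),
               c("low", "moderate", "moderate", "high", "high", "very_high"))
  expect_false(is.unsorted(reba_action_level(1:15)))
  # configurable binning
  expect_equal(as.character(reba_action_level(4, breaks = c(1, 3, 7))),
               "high")
})

test_that("profile-to-REBA bridge stays in range and tracks posture", {
  profiles <- random_profiles(200, seed = 9)
  final <- reba_from_profile(profiles)
  expect_true(all(final %in% 1:15))
  worst <- make_profile(posture_a = 9, posture_b = 8, coupling = 4,
                        static_activity = 4, repetitive_activity = 4,
                        rapid_movement = 4, load_weight = 4, load_time = 4)
  expect_equal(reba_from_profile(worst), 15)
  expect_equal(reba_from_profile(make_profile()), 1)
  expect_length(reba_from_profile(make_profile()[0, ]), 0)
})
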