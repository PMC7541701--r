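test_that("exactly 25 valid plays exist, in (hand, call) order", {
  plays <- morra_plays()
  expect_equal(nrow(plays), 25)
  expect_equal(plays$label, rownames(payoff_wins_fixture()))
  v <- validate_play(plays$hand, plays$call)
  expect_true(all(v$valid))
})

test_that("play validation distinguishes the beginner errors", {
  cases <- list(
    list(hand = 1, call = 7, reason = "call exceeds hand+5"),
    list(hand = 3, call = 3, reason = "call equals hand"),
    list(hand = 5, call = 4, reason = "call below hand"),
    list(hand = 0, call = 4, reason = "hand out of range"),
    list(hand = 6, call = 8, reason = "hand out of range"),
    list(hand = 2, call = 11, reason = "call out of range"),
    list(hand = 2, call = 1, reason = "call out of range")
  )
  for (cs in cases) {
    v <- validate_play(cs$hand, cs$call)
    expect_false(v$valid, info = cs$reason)
    expect_equal(v$reason, cs$reason)
  }
  expect_true(validate_play(1, 2)$valid)
  expect_error(validate_play(1.5, 3), class = "morrarand_error_input")
  expect_error(validate_play("1", 3), class = "morrarand_error_input")
})

test_that("round adjudication follows the call-the-sum rule", {
  # B calls the sum, A does not
  r <- adjudicate_round(hand_a = 1, call_a = 3, hand_b = 1, call_b = 2)
  expect_equal(r$winner, "B")
  expect_equal(r$sum, 2)
  # both call the sum: nobody scores
  expect_equal(adjudicate_round(1, 2, 1, 2)$winner, "none")
  # neither calls the sum
  expect_equal(adjudicate_round(2, 6, 3, 7)$winner, "none")
  # invalid plays are rejected with the reason attached
  expect_error(adjudicate_round(1, 7, 1, 2), class = "morrarand_error_input")
})

test_that("the payoff matrix reproduces the printed winning combinations", {
  pm <- unclass(build_payoff_matrix())
  fixture <- payoff_wins_fixture()
  expect_equal(dimnames(pm), dimnames(fixture))
  expect_equal(pm == "B", fixture)
  expect_equal(unname(rowSums(pm == "B")), rep(4, 25))
  expect_equal(sum(pm == "B"), 100)
})

test_that("payoff matrix is mirror-antisymmetric and matches adjudication", {
  pm <- unclass(build_payoff_matrix())
  # B-win in cell (p, q) iff A-win in the mirrored cell (q, p)
  expect_equal(unname(pm == "B"), unname(t(pm == "A")))
  expect_equal(unname(pm == "none"), unname(t(pm == "none")))
  # spot-check oracle equivalence on a random subset of pairs
  plays <- morra_plays()
  set.seed(11)
  for (k in 1:50) {
    i <- sample(25, 1); j <- sample(25, 1)
    adj <- adjudicate_round(plays$hand[j], plays$call[j],
                            plays$hand[i], plays$call[i])
    expect_equal(pm[i, j], adj$winner)
  }
})

test_that("matches stop exactly at the target score and are seed-reproducible", {
  m1 <- simulate_match(morra_agent("a"), morra_agent("b"),
                       target_score = 1, seed = 5)
  expect_equal(max(m1$scores), 1L)
  expect_equal(m1$rounds$winner[nrow(m1$rounds)], names(which.max(m1$scores)))
  # only the final round scores for the winner when target is 1
  expect_equal(sum(m1$rounds$winner != "none"), 1)

  m2 <- simulate_match(morra_agent("a"), morra_agent("b"),
                       target_score = 7, seed = 99)
  m3 <- simulate_match(morra_agent("a"), morra_agent("b"),
                       target_score = 7, seed = 99)
  expect_identical(m2$rounds, m3$rounds)
  expect_identical(m2$scores, m3$scores)
  # scores match the per-round winners; exactly one side reaches the target
  expect_equal(unname(m2$scores[["A"]]), sum(m2$rounds$winner == "A"))
  expect_equal(unname(m2$scores[["B"]]), sum(m2$rounds$winner == "B"))
  expect_equal(max(m2$scores), 7L)
  expect_lt(min(m2$scores), 7L)
})

test_that("team mode substitutes the loser and keeps the scorer on", {
  # B always calls the sum correctly against A's fixed wrong call
  always_b <- function(prev) c(hand = 1L, call = 2L)
  always_a <- function(prev) c(hand = 1L, call = 3L)  # sum is 2, A never hits
  side_a <- list(morra_agent("a1", play = always_a),
                 morra_agent("a2", play = always_a))
  side_b <- list(morra_agent("b1", play = always_b),
                 morra_agent("b2", play = always_b))
  m <- simulate_match(side_a, side_b, target_score = 3, seed = 1)
  expect_equal(m$rounds$winner, rep("B", 3))
  expect_equal(m$rounds$player_b, rep("b1", 3))          # scorer stays
  expect_equal(m$rounds$player_a, c("a1", "a2", "a1"))   # loser alternates
  expect_true(m$team_mode)
})

test_that("invalid agent plays are resampled (or abort) per policy", {
  flaky <- local({
    n <- 0
    function(prev) {
      n <<- n + 1
      if (n %% 2 == 1) c(hand = 1L, call = 7L) else c(hand = 1L, call = 2L)
    }
  })
  m <- simulate_match(morra_agent("f", play = flaky), morra_agent("b"),
                      target_score = 1, seed = 3)
  expect_gt(m$n_invalid, 0)
  expect_true(all(validate_play(m$rounds$hand_a, m$rounds$call_a)$valid))

  flaky2 <- function(prev) c(hand = 1L, call = 7L)
  expect_error(
    simulate_match(morra_agent("f", play = flaky2), morra_agent("b"),
                   target_score = 1, seed = 3, on_invalid = "abort"),
    class = "morrarand_error_input"
  )
})

test_that("long-run B win rate matches the exhaustive payoff expectation", {
  pm <- unclass(build_payoff_matrix())
  expected_b <- mean(pm == "B")  # uniform play over all 625 pairs
  m <- simulate_match(morra_agent("a"), morra_agent("b"),
                      target_score = 100, seed = 17)
  observed_b <- mean(m$rounds$winner == "B")
  expect_lt(abs(observed_b - expected_b), 0.05)
})

test_that("hand sequences extract per player, respecting the bench", {
  m <- simulate_match(morra_agent("a"), morra_agent("b"),
                      target_score = 5, seed = 2)
  seqs <- extract_hand_sequences(m)
  lens <- table(seqs$participant_id)
  expect_equal(unname(as.integer(lens)), rep(nrow(m$rounds), 2))

  # fabricated 6-round team record with a substitution at round 4
  fake <- structure(list(
    rounds = tibble::tibble(
      round = 1:6,
      player_a = c("a1", "a1", "a1", "a2", "a2", "a2"),
      player_b = rep("b1", 6),
      hand_a = rep(1L, 6), call_a = rep(3L, 6),
      hand_b = rep(2L, 6), call_b = rep(3L, 6),
      sum = rep(3L, 6), winner = rep("B", 6)),
    scores = c(A = 0L, B = 6L), target_score = 6L, team_mode = TRUE,
    n_invalid = 0L), class = "morra_match")
  seqs <- extract_hand_sequences(fake)
  lens <- sort(as.integer(table(seqs$participant_id)))
  expect_equal(lens, c(3L, 3L, 6L))
  expect_equal(sum(lens), 2 * nrow(fake$rounds))
  # positions are contiguous within each player
  by_player <- split(seqs$position, seqs$participant_id)
  for (p in by_player) expect_equal(p, seq_along(p))
})

test_that("match records round-trip through disk", {
  m <- simulate_match(morra_agent("a"), morra_agent("b"),
                      target_score = 4, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_match(m, path)
  m2 <- read_match(path)
  expect_equal(m2$rounds, m$rounds)
  expect_equal(m2$scores, m$scores)
  expect_equal(m2$target_score, m$target_score)
  expect_equal(m2$team_mode, m$team_mode)
})
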