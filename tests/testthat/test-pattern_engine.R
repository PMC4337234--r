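test_that("node scores reduce the six variables to four nodes", {
  a <- average_coders(coding_row(fill = 0,
    neg_view_self = 3, neg_hope = 2, neg_relationships = 1,
    neg_emotion = 2, neg_behavior = 1, neg_somatic = 0))
  nd <- node_scores(a, "negative")
  expect_equal(nd$cognitive, 2) # mean(3, 2, 1)
  expect_equal(nd$emotion, 2)
  expect_equal(nd$behavior, 1)
  expect_equal(nd$somatic, 0)

  zero <- node_scores(average_coders(coding_row(fill = 0)), "positive")
  expect_true(all(zero[c("cognitive", "emotion", "behavior", "somatic")] == 0))

  # constant half-point inputs keep the half-point mean
  b <- average_coders(rbind(
    coding_row(fill = 2), coding_row(coder = "B", fill = 3)))
  expect_equal(node_scores(b, "negative")$cognitive, 2.5)
})

test_that("strength sums the four nodes and activation counts the engaged ones", {
  nodes <- c(3, 3, 3, 1)
  expect_equal(pattern_strength(nodes), 10)
  expect_equal(activation_score(nodes), 3L)
  expect_equal(pattern_strength(c(0, 0, 0, 0)), 0)
  expect_equal(pattern_strength(c(3, 3, 3, 3)), 12)
  expect_equal(activation_score(c(1.5, 1.5, 1.5, 1.5)), 0L)
  expect_equal(activation_score(c(2, 2, 3, 2)), 4L)
  # the averaged half-point below the floor does not activate; 2.0 does
  expect_equal(activation_score(c(1.5, 2, 1.99, 2.0)), 2L)
})

test_that("strength and activation are monotone in every input rating", {
  set.seed(11)
  for (rep in 1:50) {
    base <- runif(4, 0, 3)
    j <- sample(4, 1)
    bump <- base
    bump[j] <- min(3, base[j] + runif(1, 0, 3 - base[j] + 0.001))
    expect_gte(pattern_strength(bump), pattern_strength(base))
    expect_gte(activation_score(bump), activation_score(base))
  }
})

test_that("raising one node across the threshold adds exactly one activation", {
  set.seed(12)
  for (rep in 1:25) {
    base <- runif(4, 0, 1.9)
    j <- sample(4, 1)
    crossed <- base
    crossed[j] <- runif(1, 2, 3)
    expect_equal(activation_score(crossed), activation_score(base) + 1L)
  }
})

test_that("equal activation does not imply equal strength", {
  a <- c(2, 2, 0, 0)
  b <- c(3, 3, 1.5, 1.5)
  expect_equal(activation_score(a), activation_score(b))
  expect_false(pattern_strength(a) == pattern_strength(b))
})

test_that("session profiles score both valences from disjoint inputs", {
  row <- coding_row(fill = 0,
    neg_view_self = 3, neg_hope = 3, neg_relationships = 3,
    neg_emotion = 3, neg_behavior = 3, neg_somatic = 3)
  prof <- session_profiles(average_coders(row))
  neg <- prof[prof$valence == "negative", ]
  pos <- prof[prof$valence == "positive", ]
  expect_equal(neg$strength, 12)
  expect_equal(neg$activation, 4L)
  expect_equal(pos$strength, 0)
  expect_equal(pos$activation, 0L)

  # perturbing negative ratings never touches the positive profile
  row2 <- coding_row(fill = 0, neg_emotion = 2)
  prof2 <- session_profiles(average_coders(row2))
  expect_equal(
    prof2[prof2$valence == "positive", c("strength", "activation")],
    pos[, c("strength", "activation")],
    ignore_attr = TRUE
  )
})

test_that("all-zero codings give both profiles zero", {
  prof <- session_profiles(average_coders(coding_row(fill = 0)))
  expect_true(all(prof$strength == 0))
  expect_true(all(prof$activation == 0L))
})

test_that("per-variable cognitive activation is a distinct, documented mode", {
  get_neg <- function(p) p$activation[p$valence == "negative"]

  # mean carried over the threshold by one extreme variable: node-mean
  # activates (mean (3 + 1.5 + 1.5)/3 = 2), the per-variable majority rule
  # does not (only view_self reaches 2)
  a <- average_coders(rbind(
    coding_row(fill = 0, neg_view_self = 3, neg_hope = 1,
      neg_relationships = 1),
    coding_row(coder = "B", fill = 0, neg_view_self = 3, neg_hope = 2,
      neg_relationships = 2)))
  expect_equal(get_neg(session_profiles(a)), 1L)
  expect_equal(
    get_neg(session_profiles(a, cognitive_activation = "per-variable")), 0L)

  # two of three variables at threshold but a low mean: only the
  # per-variable rule activates (mean (2 + 2 + 0)/3 = 1.33)
  b <- average_coders(coding_row(fill = 0,
    neg_view_self = 2, neg_hope = 2, neg_relationships = 0))
  expect_equal(get_neg(session_profiles(b)), 0L)
  expect_equal(
    get_neg(session_profiles(b, cognitive_activation = "per-variable")), 1L)
})

test_that("activation points pair the two valences per session", {
  df <- rbind(
    coding_row("p1", 1, "A", fill = 0, pos_emotion = 2, pos_behavior = 2),
    coding_row("p1", 3, "A", fill = 0, neg_emotion = 3)
  )
  pts <- activation_points(session_profiles(average_coders(df)))
  expect_equal(pts$x, c(2L, 0L))
  expect_equal(pts$y, c(0L, 1L))
})
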