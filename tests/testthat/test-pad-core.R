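# Unit and property tests for the PAD arithmetic layer.

test_that("score_pad matches an independent transcription of the formulas", {
  expect_equal(score_pad(rep(0, 12)), c(P = 0, A = 0, D = 0))
  expect_equal(score_pad(c(4, 0, 0, -4, 0, 0, 4, 0, 0, -4, 0, 0)),
               c(P = 4, A = 0, D = 0))

  # oracle: direct item-by-item evaluation, written independently of the
  # vectorized implementation
  oracle <- function(v) {
    p <- (v[[1]] - v[[4]] + v[[7]] - v[[10]]) / 4
    a <- (-v[[2]] + v[[5]] - v[[8]] + v[[11]]) / 4
    d <- (v[[3]] - v[[6]] + v[[9]] - v[[12]]) / 4
    c(P = p, A = a, D = d)
  }
  set.seed(101)
  for (i in 1:20) {
    v <- round(runif(12, -4, 4), 3)
    expect_equal(score_pad(v), oracle(v))
  }
})

test_that("score_pad rejects malformed input, naming the offender", {
  expect_error(score_pad(rep(0, 11)), "12")
  expect_error(score_pad(c(rep(0, 7), 5, rep(0, 4))), "V8")
  expect_error(score_pad(c(rep(0, 2), NA, rep(0, 9))), "index 3")
})

test_that("scoring is linear and range-bounded", {
  set.seed(7)
  for (i in 1:25) {
    x <- runif(12, -2, 2); y <- runif(12, -2, 2)
    a <- runif(1, -1, 1); b <- runif(1, -1, 1)
    expect_equal(score_pad(a * x + b * y),
                 a * score_pad(x) + b * score_pad(y))
    expect_true(all(abs(score_pad(x)) <= 4))
  }
})

test_that("classify_octant maps sign triples per the octant table", {
  expect_identical(classify_octant(c(0.8000, 0.2071, -0.0571))$label,
                   "Dependent")
  expect_identical(classify_octant(c(-0.4595, 0.2667, 0.1214))$label,
                   "Disgust")
  oc <- classify_octant(c(0, 0, 0))
  expect_identical(oc$label, "Boring")
  expect_true(oc$zero_flag)
  expect_identical(classify_octant(c(0, 0, 0), "positive")$label, "Joyful")

  # random vectors in every octant agree with the sign-pattern table
  oct <- pad_octants()
  set.seed(11)
  for (k in seq_len(nrow(oct))) {
    for (i in 1:5) {
      pad <- c(oct$sP[k], oct$sA[k], oct$sD[k]) * runif(3, 0.01, 4)
      res <- classify_octant(pad)
      expect_identical(res$label, oct$label[k])
      expect_false(res$zero_flag)
    }
  }
})

test_that("proximity is a Euclidean metric and matches printed spot values", {
  expect_equal(round(proximity(c(0.1963, 0.0786, -0.0333), "Surprise"), 4),
               2.2466, tolerance = 0)   # printed 2.2467; within last-digit slack
  expect_equal(round(proximity(c(0.5524, 0.2119, 0.1214), "Joyful"), 4),
               2.7569)
  expect_equal(proximity(c(1.72, 1.71, 0.22), "Surprise"), 0)
  set.seed(23)
  for (i in 1:25) {
    x <- runif(3, -4, 4); y <- runif(3, -4, 4); z <- runif(3, -4, 4)
    dxy <- proximity(x, y)
    expect_gte(dxy, 0)
    expect_equal(dxy, proximity(y, x))
    expect_lte(proximity(x, z), dxy + proximity(y, z) + 1e-12)
  }
})

test_that("proximity_profile matches per-norm proximity", {
  pad <- c(0.3, -0.2, 0.5)
  prof <- proximity_profile(pad)
  for (lab in names(prof)) {
    expect_equal(unname(prof[lab]), proximity(pad, lab))
  }
})

test_that("nearest_emotion picks the minimum and flags exact ties", {
  ne <- nearest_emotion(c(-0.4595, 0.2667, 0.1214))
  expect_identical(ne$label, "Fear")
  expect_equal(round(ne$distance, 4), 0.8989)
  expect_false(ne$tie_flag)

  norms <- pad_norms()
  ne0 <- nearest_emotion(c(norms$PN[4], norms$AN[4], norms$DN[4]))
  expect_identical(ne0$label, "Dependent")
  expect_equal(ne0$distance, 0)
  expect_false(ne0$tie_flag)

  # point on the perpendicular bisector of two custom norms: distances are
  # exactly equal, the earlier-listed label must win with tie_flag set
  two <- data.frame(label = c("A", "B"), PN = c(1, -1), AN = 0, DN = 0)
  expect_equal(proximity(c(0, 2, 0), two[1, ]), proximity(c(0, 2, 0), two[2, ]))
  tie <- nearest_emotion(c(0, 2, 0), two)
  expect_identical(tie$label, "A")
  expect_true(tie$tie_flag)

  expect_error(nearest_emotion(c(0, 0, 0), data.frame()), "non-empty")
})

test_that("smd reproduces printed effect sizes and its algebra", {
  expect_identical(sprintf("%.2f", smd(0.8000, -0.2500)), "1.00")
  expect_identical(sprintf("%.2f", smd(1.2056, 0.4958)), "0.42")
  expect_equal(smd(1.3, 1.3), 0)
  expect_error(smd(0, 0), "undefined")
  set.seed(31)
  for (i in 1:50) {
    a <- runif(1, -3, 3); b <- runif(1, -3, 3)
    if (a == 0 && b == 0) next
    s <- smd(a, b)
    expect_lte(abs(s), 1)
    expect_equal(s, -smd(b, a))
    if (sign(a) * sign(b) < 0 || a == 0 || b == 0) {
      expect_equal(abs(s), 1)
    } else {
      expect_lt(abs(s), 1)
    }
  }
})

test_that("pleasure bands honor shared nodes and out-of-range flags", {
  expect_identical(classify_pleasure_band(-0.25, "painting")$band, "Unpleased")
  expect_identical(classify_pleasure_band(0.25, "painting")$band, "Pleased")
  expect_identical(classify_pleasure_band(0, "painting")$band, "General")
  expect_identical(classify_pleasure_band(0, "interior")$band, "General")
  expect_identical(classify_pleasure_band(0.4190, "interior")$band, "General")
  expect_identical(classify_pleasure_band(0.5, "interior")$band, "Pleased")
  oor <- classify_pleasure_band(1.6, "painting")
  expect_identical(oor$band, "Pleased")
  expect_true(oor$out_of_range)
  expect_false(classify_pleasure_band(1.2, "painting")$out_of_range)
})

test_that("aggregate_group averages per group x stimulus", {
  rec <- function(pid, sex, stim, pad) {
    items <- c(pad[1], -pad[2], pad[3], -pad[1], pad[2], -pad[3],
               pad[1], -pad[2], pad[3], -pad[1], pad[2], -pad[3])
    df <- data.frame(participant_id = pid, group = "young", sex = sex,
                     stimulus_id = stim, stringsAsFactors = FALSE)
    df[paste0("v", 1:12)] <- as.list(items)
    df
  }
  one <- rec("p1", "male", "s1", c(1, 0.5, -0.25))
  agg1 <- aggregate_group(one, groups = "young")
  expect_equal(unlist(agg1[c("P", "A", "D")], use.names = FALSE),
               c(1, 0.5, -0.25))
  expect_equal(agg1$n, 1L)

  two <- rbind(one, rec("p2", "female", "s1", c(0, 1, 0)))
  agg2 <- aggregate_group(two, groups = c("young", "young-man"))
  yg <- agg2[agg2$group == "young", ]
  expect_equal(unlist(yg[c("P", "A", "D")], use.names = FALSE),
               c(0.5, 0.75, -0.125))
  # young-man subset only sees p1
  ym <- agg2[agg2$group == "young-man", ]
  expect_equal(ym$P, 1)
  # empty cells are absent, never zero
  expect_false("elderly" %in% aggregate_group(two)$group)
})

test_that("aggregate_group recovers a synthetic target within sampling error", {
  target <- data.frame(group = "young", stimulus_id = "s1",
                       P = 0.9, A = -0.4, D = 0.3)
  recs <- generate_ratings(target, n_raters = 40, noise_sd = 0.5, seed = 99)
  agg <- aggregate_group(recs, groups = "young")
  # direct-mean oracle over the generated records
  pads <- t(apply(as.matrix(recs[paste0("v", 1:12)]), 1, score_pad))
  expect_equal(agg$P, mean(pads[, 1]))
  expect_equal(agg$A, mean(pads[, 2]))
  expect_equal(agg$D, mean(pads[, 3]))
  # scoring averages four items: per-dimension sd = noise_sd / 2
  bound <- 4 * (0.5 / 2) / sqrt(40)
  expect_true(all(abs(unlist(agg[c("P", "A", "D")]) -
                        unlist(target[c("P", "A", "D")])) < bound))
})

test_that("stimulus_map collapses images to styles both ways", {
  target <- data.frame(group = rep("elderly", 2),
                       stimulus_id = c("img1", "img2"),
                       P = c(1, 2), A = 0, D = 0)
  recs <- generate_ratings(target, n_raters = 6, noise_sd = 0, seed = 5)
  map <- c(img1 = "styleX", img2 = "styleX")
  pf <- aggregate_group(recs, groups = "elderly", stimulus_map = map)
  expect_identical(pf$stimulus_id, "styleX")
  expect_equal(pf$P, 1.5)
  pooled <- aggregate_group(recs, groups = "elderly", stimulus_map = map,
                            participant_first = FALSE)
  expect_equal(pooled$P, 1.5)  # balanced design: both groupings agree
})

test_that("run_pad_pipeline composes and upholds its invariants", {
  expect_equal(nrow(run_pad_pipeline(
    as_rating_records(data.frame(participant_id = character(),
                                 group = character(), sex = character(),
                                 stimulus_id = character(),
                                 setNames(rep(list(numeric()), 12),
                                          paste0("v", 1:12)))))), 0L)

  targets <- data.frame(group = c("young", "young"),
                        stimulus_id = c("a", "b"),
                        P = c(0.9, -0.6), A = c(0.3, 0.4), D = c(0.2, 0.1))
  recs <- generate_ratings(targets, n_raters = 30, noise_sd = 0.4, seed = 12)
  res <- run_pad_pipeline(recs, groups = c("young", "young-man"))
  expect_s3_class(res, "preference_result")
  expect_equal(nrow(res), 4L)
  prox <- as.matrix(res[grep("^prox_", names(res))])
  for (i in seq_len(nrow(res))) {
    expect_equal(res$nearest_distance[i], min(prox[i, ]))
    expect_equal(unname(prox[i, paste0("prox_", res$nearest_emotion[i])]),
                 res$nearest_distance[i])
  }
  # deterministic given inputs
  expect_identical(res, run_pad_pipeline(recs, groups = c("young", "young-man")))
})

test_that("a cohort generated at a norm point recovers that norm", {
  norms <- pad_norms()
  i <- match("Relaxed", norms$label)
  target <- data.frame(group = "young", stimulus_id = "s",
                       P = norms$PN[i], A = norms$AN[i], D = norms$DN[i])
  recs <- generate_ratings(target, n_raters = 40, noise_sd = 0.3, seed = 42)
  res <- run_pad_pipeline(recs, groups = "young")
  expect_identical(res$nearest_emotion, "Relaxed")
  expect_lt(res$nearest_distance, 0.2)
})
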