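# Stimulus pool construction and the within-participant design.

test_that("pool has the full study structure: 160 stimuli in 5 lists of 16 pairs", {
  pool <- build_stimulus_pool(80, seed = 7)
  expect_equal(nrow(pool), 160)
  expect_equal(sort(unique(pool$list_id)), LETTERS[1:5])
  per_list <- table(pool$list_id)
  expect_true(all(per_list == 32)) # 16 pairs x 2 members
  expect_equal(sum(table(pool$pair_id) == 2), 80)
  expect_true(all(vapply(
    pool$formant_freq,
    function(m) all(m > 90 & m < 8000), logical(1)
  )))
  expect_true(all(vapply(
    pool$syllable_env,
    function(e) all(e >= 0), logical(1)
  )))
})

test_that("pool generation is deterministic and rejects invalid sizes", {
  p1 <- build_stimulus_pool(5, seed = 3)
  p2 <- build_stimulus_pool(5, seed = 3)
  expect_identical(p1, p2)
  p3 <- build_stimulus_pool(5, seed = 4)
  expect_false(identical(p1$formant_freq[[1]], p3$formant_freq[[1]]))
  expect_error(build_stimulus_pool(7, seed = 1), "divisible by 5")
})

test_that("paired sentences are more similar than non-paired sentences", {
  pool <- fix_pool5()
  track_cor <- function(i, j) {
    cor(
      as.numeric(pool$formant_freq[[i]]),
      as.numeric(pool$formant_freq[[j]])
    )
  }
  within <- vapply(seq_len(5), function(p) {
    track_cor(2 * p - 1, 2 * p)
  }, numeric(1))
  set.seed(1)
  between <- replicate(20, {
    ij <- sample.int(10, 2)
    while (pool$pair_id[ij[1]] == pool$pair_id[ij[2]]) {
      ij <- sample.int(10, 2)
    }
    track_cor(ij[1], ij[2])
  })
  expect_gt(min(within), max(between))
})

test_that("condition assignment reproduces the full design counts", {
  pool <- memo("pool80", function() build_stimulus_pool(80, seed = 7))
  d <- assign_conditions(pool, participant_index = 1, seed = 11)
  expect_equal(nrow(d), 96)
  expect_equal(as.integer(table(d$block)), rep(16L, 6))
  cells <- dplyr::count(d, stimulus_type, prior)
  expect_equal(nrow(cells), 6)
  expect_true(all(cells$n == 16))
  expect_equal(sum(d$prior != "P0"), 64)
  expect_equal(sum(d$prior == "P0"), 32)
  expect_false(any(duplicated(d$sentence_id)))
})

test_that("incorrect-prior trials display the unheard pair mate", {
  pool <- fix_pool10()
  d <- assign_conditions(pool, 2, seed = 5)
  pm <- d[d$prior == "P-", ]
  expect_true(all(!is.na(pm$displayed_sentence_id)))
  expect_true(all(pm$displayed_sentence_id != pm$sentence_id))
  shown_pair <- pool$pair_id[match(pm$displayed_sentence_id, pool$sentence_id)]
  expect_equal(shown_pair, pm$pair_id)
  expect_true(all(is.na(d$displayed_sentence_id[d$prior == "P0"])))
  pp <- d[d$prior == "P+", ]
  expect_equal(pp$displayed_sentence_id, pp$sentence_id)
})

test_that("list-to-condition mapping rotates as a Latin square", {
  pool <- fix_pool10()
  role_of <- function(d, stim, prior) {
    unique(d$list_id[d$stimulus_type == stim & d$prior == prior])
  }
  roles <- c("SWS_P+", "SWS_P-", "NVS_P+", "NVS_P-", "P0")
  mat <- t(vapply(1:5, function(p) {
    d <- assign_conditions(pool, p, seed = 3)
    c(
      role_of(d, "SWS", "P+"), role_of(d, "SWS", "P-"),
      role_of(d, "NVS", "P+"), role_of(d, "NVS", "P-"),
      role_of(d, "SWS", "P0")
    )
  }, character(5)))
  # every list serves every role exactly once across participants 1..5
  for (col in 1:5) expect_setequal(mat[, col], LETTERS[1:5])
  for (row in 1:5) expect_setequal(mat[row, ], LETTERS[1:5])
  # P0 uses one list for both stimulus types
  d <- assign_conditions(pool, 1, seed = 3)
  expect_length(unique(d$list_id[d$prior == "P0"]), 1)
})

test_that("design invariants hold across participants and seeds", {
  pool <- fix_pool10()
  for (p in c(1, 4, 9)) {
    for (s in c(2, 17)) {
      d <- assign_conditions(pool, p, s)
      expect_equal(nrow(d), 12) # 6 cells x 2 pairs per list
      expect_true(all(dplyr::count(d, stimulus_type, prior)$n == 2))
      expect_false(any(duplicated(d$sentence_id)))
    }
  }
  expect_error(
    assign_conditions(dplyr::select(pool, -list_id), 1, 1),
    "malformed"
  )
})

test_that("clarity ratings stay ordinal and respond to the latent shift", {
  pool <- memo("pool80", function() build_stimulus_pool(80, seed = 7))
  eff <- condition_effects(rating_shift = c("P+" = 2))
  ok <- vapply(1:100, function(pp) {
    d <- simulate_ratings(assign_conditions(pool, pp, seed = 7), eff, seed = pp)
    stopifnot(all(d$clarity_1 %in% 1:4), all(d$clarity_2 %in% 1:4))
    m <- tapply(d$clarity_2, d$prior, mean)
    m[["P+"]] > m[["P0"]] && m[["P+"]] > m[["P-"]]
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("neutral effects leave second-presentation ratings exchangeable", {
  pool <- fix_pool10()
  eff0 <- condition_effects()
  # pool clarity_2 over many participants; prior-wise means must agree
  ms <- vapply(1:60, function(pp) {
    d <- simulate_ratings(assign_conditions(pool, pp, seed = 19), eff0, seed = 1000 + pp)
    tapply(d$clarity_2, d$prior, mean)
  }, numeric(3))
  grand <- rowMeans(ms)
  expect_lt(max(grand) - min(grand), 0.15)
})
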