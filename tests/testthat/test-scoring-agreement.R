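test_that("category follows the score sign convention", {
  expect_identical(category_from_score(3L), "change")
  expect_identical(category_from_score(0L), "neutral")
  expect_identical(category_from_score(-5L), "sustain")
  expect_error(category_from_score(6L), "score")
})

test_that("mock scorer applies the signed lexicon rule deterministically", {
  expect_identical(mock_score_utterance("I really want to quit"), 3L)
  expect_identical(mock_score_utterance(""), 0L)
  expect_identical(mock_score_utterance("the weather is grey"), 0L)
  # clipping to the scale
  lex <- c(yes = 4L, more = 4L)
  expect_identical(mock_score_utterance("yes yes more", lexicon = lex), 5L)
  # determinism and totality of category_from_score(mock_score(.))
  texts <- c("I can't keep doing this", "maybe", "", "WANT want want",
             "n/a", "punctuation!!! everywhere...")
  s1 <- vapply(texts, mock_score_utterance, integer(1))
  s2 <- vapply(texts, mock_score_utterance, integer(1))
  expect_identical(s1, s2)
  expect_true(all(category_from_score(s1) %in%
                    c("change", "neutral", "sustain")))
})

test_that("score_sessions fills client rows only, with matching categories", {
  set <- session_set(list(text_session()))
  scored <- score_sessions(set)
  utt <- scored$sessions[[1]]$utterances
  expect_false(anyNA(utt$score[utt$speaker == "client"]))
  expect_true(all(is.na(utt$score[utt$speaker == "therapist"])))
  cl <- utt$speaker == "client"
  expect_identical(utt$category[cl], category_from_score(utt$score[cl]))
})

test_that("agreement reproduces analytic and direct-formula kappa values", {
  a <- rep("change", 10)
  expect_equal(agreement(a, a)$kappa, 1.0)
  expect_true(agreement(a, a)$degenerate)
  # analytic case: p_o = 0.5, p_e = 0.5, kappa = 0
  b <- c(rep("change", 5), rep("neutral", 5))
  res <- agreement(a, b)
  expect_equal(res$accuracy, 0.5)
  expect_equal(res$kappa, 0.0)
  expect_false(res$degenerate)
  # 20-item 3-category fixture vs direct formula
  x <- c("change", "neutral", "sustain", "change", "change", "neutral",
         "sustain", "sustain", "change", "neutral", "change", "sustain",
         "neutral", "neutral", "change", "sustain", "change", "neutral",
         "sustain", "change")
  y <- c("change", "neutral", "neutral", "change", "sustain", "neutral",
         "sustain", "change", "change", "neutral", "neutral", "sustain",
         "neutral", "change", "change", "sustain", "sustain", "neutral",
         "sustain", "change")
  expect_equal(agreement(x, y)$kappa, cohen_kappa_direct(x, y),
               tolerance = 1e-12)
  expect_error(agreement(x, y[-1]), "length")
})

test_that("kappa is invariant to consistent relabeling and near 0 for noise", {
  set.seed(42)
  cats <- c("change", "neutral", "sustain")
  x <- sample(cats, 1000, replace = TRUE)
  y <- sample(cats, 1000, replace = TRUE)
  k1 <- agreement(x, y)$kappa
  expect_lt(abs(k1), 0.15)
  relabel <- c(change = "sustain", neutral = "change", sustain = "neutral")
  expect_equal(agreement(relabel[x], relabel[y])$kappa, k1, tolerance = 1e-12)
})

test_that("cohen kappa matches an independent library computation", {
  skip_if_not_installed("e1071")
  set.seed(7)
  cats <- c("change", "neutral", "sustain")
  x <- sample(cats, 200, replace = TRUE)
  y <- ifelse(runif(200) < 0.6, x, sample(cats, 200, replace = TRUE))
  tab <- table(factor(x, cats), factor(y, cats))
  expect_equal(agreement(x, y)$kappa,
               e1071::classAgreement(tab)$kappa, tolerance = 1e-10)
})

test_that("fleiss kappa matches direct evaluation and boundary structure", {
  # all raters agree on every item
  counts <- matrix(c(4, 0, 0, 0, 4, 0, 0, 0, 4), 3, 3, byrow = TRUE)
  expect_equal(fleiss_kappa(counts, 4), 1.0)
  # every item split 50/50 between two categories -> below chance
  split <- matrix(c(2, 2, 2, 2, 2, 2), 3, 2, byrow = TRUE)
  expect_lt(fleiss_kappa(split, 4), 0)
  # fixed 4-item, 3-rater, 3-category fixture vs direct formula
  fx <- matrix(c(3, 0, 0,
                 1, 2, 0,
                 0, 1, 2,
                 1, 1, 1), 4, 3, byrow = TRUE)
  expect_equal(fleiss_kappa(fx, 3), fleiss_kappa_direct(fx, 3),
               tolerance = 1e-12)
  expect_error(fleiss_kappa(fx, 4), "sum")
})
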