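test_that("jsonl round trip is the identity on session sets", {
  utt1 <- rbind(utterance("client", "I want to quit", score = 3L,
                          category = "change"),
                utterance("therapist", "tell me more"),
                utterance("client", NA_character_, score = 0L))
  utt2 <- rbind(utterance("client", "not ready", score = -2L),
                utterance("client", "maybe", score = 0L),
                utterance("client", "ok", score = 1L))
  set <- session_set(list(session("a", "high", utt1),
                          session("b", "low", utt2)))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_sessions(set, path, "jsonl")
  back <- read_sessions(path, "jsonl")
  expect_sets_equal(set, back)
  # absent text stays NA, never coerced to ""
  expect_true(is.na(back$sessions[[1]]$utterances$text[3]))
})

test_that("csv round trip preserves order, labels and missing fields", {
  set <- generate_dataset(synthetic_spec(n_high = 2, n_low = 1, seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sessions(set, path, "csv")
  back <- read_sessions(path, "csv")
  expect_sets_equal(set, back)
  expect_true(all(is.na(back$sessions[[1]]$utterances$text)))
})

test_that("empty session set writes and reads back as empty", {
  set <- session_set(list())
  for (fmt in c("jsonl", "csv")) {
    path <- withr::local_tempfile()
    write_sessions(set, path, fmt)
    expect_length(read_sessions(path, fmt)$sessions, 0L)
  }
})

test_that("score bounds and category/sign consistency are enforced", {
  expect_error(utterance("client", "x", score = 7L), "score")
  expect_error(utterance("client", "x", score = -6L), "score")
  expect_error(utterance("client", "x", category = "sustain", score = 3L),
               "contradicts")
  # csv reader names the violated constraint with session context
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("session_id,quality,index,speaker,text,category,score",
               "s1,high,0,client,hello,,7"), path)
  expect_error(read_sessions(path, "csv"), "score")
})

test_that("csv reader names missing required columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("session_id,quality,speaker", "s1,high,client"), path)
  expect_error(read_sessions(path, "csv"), "index")
})

test_that("annomi_csv maps talk types to categories without scores", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "transcript_id,mi_quality,interlocutor,utterance_text,client_talk_type",
    "t1,high,therapist,how are you,",
    "t1,high,client,i keep drinking,sustain",
    "t1,high,client,but i want to stop,change",
    "t2,low,client,whatever,neutral"), path)
  set <- read_sessions(path, "annomi_csv")
  expect_length(set$sessions, 2L)
  s1 <- set$sessions[[1]]
  expect_identical(s1$quality, "high")
  expect_identical(s1$utterances$category, c(NA, "sustain", "change"))
  expect_true(all(is.na(s1$utterances$score)))
  # unmapped column -> format error naming the column
  expect_error(
    read_sessions(path, "annomi_csv",
                  column_map = list(session_id = "nope", quality = "mi_quality",
                                    speaker = "interlocutor",
                                    text = "utterance_text",
                                    category = "client_talk_type")),
    "nope")
})

test_that("session ids must be unique across a set and indices re-base to 0", {
  s <- text_session("dup")
  expect_error(session_set(list(s, s)), "duplicate")
  expect_identical(s$utterances$index, 0:2)
})

test_that("client_scores keeps only client utterances, in order", {
  utt <- rbind(utterance("client", score = 2L),
               utterance("therapist", "hm"),
               utterance("client", score = -1L))
  s <- session("s", "high", utt)
  expect_identical(client_scores(s), c(2, -1))
})
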