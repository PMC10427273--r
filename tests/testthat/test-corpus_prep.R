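test_that("read_chart_csv parses ranks, years and stems lyrics", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_chart(path, list(rank = c(1L, 2L),
                                 song = c("A", "B"),
                                 artist = c("X", "Y"),
                                 year = c(1999L, 1999L),
                                 lyrics = c("love love hate", "the the")))
  cp <- read_chart_csv(path)
  expect_s3_class(cp, "lyric_corpus")
  expect_equal(n_songs(cp), 2L)
  expect_setequal(cp$songs$rank, c(1L, 2L))
  expect_identical(cp$songs$bag[[1]][order(names(cp$songs$bag[[1]]))],
                   c(hate = 1L, love = 2L))
  expect_true(all(is.na(cp$songs$genre)))
})

test_that("empty lyrics give W = 0 (flagged for downstream exclusion)", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_chart(path, list(rank = 1L, song = "A", artist = "X",
                                 year = 2000L, lyrics = ""))
  cp <- read_chart_csv(path)
  expect_identical(cp$songs$W, 0L)
})

test_that("chart reader errors name the missing column / bad row", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(Rank = 1, Song = "A", Year = 2000,
                              Lyrics = "x"), path, row.names = FALSE)
  expect_error(read_chart_csv(path), "Artist")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_fixture_chart(path2, list(rank = "first", song = "A", artist = "X",
                                  year = 2000L, lyrics = "x"))
  expect_error(read_chart_csv(path2), "rank at row 1")
})

test_that("hand-stemmed oracle matches the chart reader's bags", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_chart(path, list(rank = 1L, song = "A", artist = "X",
                                 year = 2000L,
                                 lyrics = "Happily hating, lovely loves"))
  cp <- read_chart_csv(path)
  toks <- c("happily", "hating", "lovely", "loves")
  oracle <- table(stem_words(toks))
  got <- cp$songs$bag[[1]]
  expect_identical(got[order(names(got))],
                   structure(as.integer(oracle), names = names(oracle)))
})

test_that("bow reader reconstructs bags from index:count pairs", {
  bow <- withr::local_tempfile(fileext = ".txt")
  meta <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# comment", "%the,love,hate",
               "TRA,MXM,1:4,3:2", "TRB,MXM2,2:1"), bow)
  utils::write.csv(data.frame(track_id = c("TRA", "TRB"),
                              artist = c("X", "Y"),
                              year = c(2001, 2002),
                              genre = c("rock", "")), meta,
                   row.names = FALSE)
  cp <- read_bow_corpus(bow, meta)
  b <- cp$songs$bag[[1]]
  expect_identical(b[order(names(b))], c(hate = 2L, the = 4L))
  expect_identical(cp$songs$W[1], 6L)
  expect_true(is.na(cp$songs$genre[2]))  # empty genre becomes missing
})

test_that("bow reader drops tracks without metadata and flags bad input", {
  bow <- withr::local_tempfile(fileext = ".txt")
  meta <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("%the,love", "TRA,M1,1:1", "TRX,M2,2:3"), bow)
  utils::write.csv(data.frame(track_id = "TRA", artist = "X", year = 2001,
                              genre = ""), meta, row.names = FALSE)
  cp <- read_bow_corpus(bow, meta)
  expect_identical(cp$songs$song_id, "TRA")
  expect_match(corpus_log(cp)[[1]]$detail, "1 tracks dropped")

  writeLines(c("%the,love", "TRA,M1,5:1"), bow)
  expect_error(read_bow_corpus(bow, meta), "outside vocabulary")
  writeLines(c("%the,love", "TRA,M1,1:1", "TRA,M2,1:1"), bow)
  expect_error(read_bow_corpus(bow, meta), "duplicate track ID")
})

test_that("write -> read round trip preserves bags exactly", {
  set.seed(11)
  vocab <- c("the", "love", "hate", "happi", "run", "stone7")
  rows <- data.frame(year = rep(2000:2001, each = 3),
                     rank = rep(1:3, 2), artist = "A",
                     love = rpois(6, 2), hate = rpois(6, 1),
                     filler = rpois(6, 5) + 1)
  cp <- build_toy_corpus(rows)
  chart <- withr::local_tempfile(fileext = ".csv")
  write_chart_csv(cp, chart)
  cp2 <- read_chart_csv(chart)
  expect_identical(lapply(cp2$songs$bag, function(b) b[order(names(b))]),
                   lapply(cp$songs$bag, function(b) b[order(names(b))]))
  bow <- withr::local_tempfile(fileext = ".txt")
  meta <- withr::local_tempfile(fileext = ".csv")
  write_bow_corpus(cp, bow, meta)
  cp3 <- read_bow_corpus(bow, meta)
  expect_identical(lapply(cp3$songs$bag, function(b) b[order(names(b))]),
                   lapply(cp$songs$bag, function(b) b[order(names(b))]))
})

test_that("detect_english agrees with a brute-force token scan", {
  expect_true(detect_english(c(the = 1L, love = 2L)))
  expect_false(detect_english(structure(integer(0), names = character(0))))
  expect_false(detect_english(c(le = 3L, chat = 1L)))
  set.seed(42)
  vocab <- c("the", "them", "love", "hate", "le", "chat", "der")
  for (i in 1:200) {
    bag <- random_bag(vocab)
    tokens <- rep(names(bag), bag)
    expect_identical(detect_english(bag), "the" %in% tokens)
  }
})

test_that("filter_years keeps years with strictly more than min_songs", {
  rows <- data.frame(year = c(rep(2000L, 3), rep(2001L, 2), 2002L),
                     rank = NA_integer_, artist = "A",
                     love = 1L, hate = 0L, filler = 3L)
  cp <- build_toy_corpus(rows)
  out <- filter_years(cp, min_songs = 2L)
  expect_identical(out$years, 2000L)          # 3 > 2 kept; 2 and 1 dropped
  expect_identical(filter_years(cp, min_songs = 0L)$years, cp$years)
  empty <- subset_corpus(cp, rep(FALSE, n_songs(cp)))
  expect_identical(n_songs(filter_years(empty, 500L)), 0L)
  # invariant: output never contains a year at or below the threshold
  for (ms in 0:3) {
    tab <- table(filter_years(cp, ms)$songs$year)
    expect_true(all(tab > ms))
  }
})

test_that("artist fingerprint clustering merges case/punctuation variants", {
  idx <- cluster_artist_names(c("madonna", "Madonna", "MADONNA", "Madonna"))
  expect_length(unique(idx$map), 1L)
  expect_identical(unname(artist_unit(idx, "MADONNA")), "madonna")

  idx2 <- cluster_artist_names(c("Dr. Dre", "dr dre"))
  expect_length(unique(idx2$map), 1L)
  # oracle: fingerprints coincide after lowercasing/punct-strip/token-sort
  expect_identical(artist_fingerprint("Dr. Dre"), artist_fingerprint("dr dre"))
})

test_that("clustering is idempotent and order-invariant", {
  names1 <- c("Beyonce", "beyonce", "The Beatles", "beatles the", "Cher")
  idx <- cluster_artist_names(names1)
  units <- unique(unname(idx$map))
  idx_re <- cluster_artist_names(units)
  expect_identical(unname(artist_unit(idx_re, units)), units)
  for (i in 1:5) {
    idx_p <- cluster_artist_names(sample(names1))
    expect_identical(sort(unique(unname(idx_p$map))), sort(units))
  }
})

test_that("split_collaborations follows the solo-set rule", {
  solo <- c("eminem", "dr dre", "madonna")
  expect_identical(split_collaborations("Eminem and Dr. Dre", solo),
                   c("eminem", "dr dre"))
  expect_identical(split_collaborations("Simon and Garfunkel", solo),
                   "simon and garfunkel")
  expect_identical(split_collaborations("Madonna", solo), "madonna")
  expect_identical(split_collaborations("Eminem, Madonna", solo),
                   c("eminem", "madonna"))
  expect_error(split_collaborations("   ", solo), "empty artist name")
})

test_that("resolve_artists writes units back into the corpus", {
  rows <- data.frame(year = 2000L, rank = NA_integer_,
                     artist = c("Madonna", "MADONNA", "Simon and Garfunkel"),
                     love = 1L, hate = 0L, filler = 2L)
  cp <- build_toy_corpus(rows)
  cp <- resolve_artists(cp)
  expect_identical(cp$songs$artist_unit,
                   c("madonna", "madonna", "simon and garfunkel"))
})
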