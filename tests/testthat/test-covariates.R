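# a ranked chart world with fully controlled counts:
# year y, ranks 1..n_per_year, negative count = base[y] + (rank index - 1)
make_chart_world <- function(years, n_per_year, hate_base = 0L,
                             artists = NULL, year_drift = 0L) {
  rows <- do.call(rbind, lapply(seq_along(years), function(i) {
    data.frame(year = years[i], rank = seq_len(n_per_year),
               artist = if (is.null(artists)) "A" else
                 artists[(seq_len(n_per_year) - 1) %% length(artists) + 1],
               love = 2L,
               hate = hate_base + seq_len(n_per_year) - 1L +
                 year_drift * (i - 1L),
               filler = 50L)
  }))
  build_toy_corpus(rows)
}

test_that("prestige roster uses a strict appearance threshold", {
  rows <- data.frame(year = rep(2000:2010, each = 2), rank = NA_integer_,
                     artist = rep(c("star", "minor"), 11),
                     love = 1L, hate = 0L, filler = 5L)
  rows$artist[rows$year == 2010] <- "star"   # star: 12, minor: 10
  cp <- build_toy_corpus(rows)
  roster <- prestigious_artists(cp, min_appearances = 10L)
  expect_identical(roster$artists, "star")
  roster11 <- prestigious_artists(cp, min_appearances = 12L)
  expect_length(roster11$artists, 0L)
  empty <- subset_corpus(cp, rep(FALSE, n_songs(cp)))
  expect_length(prestigious_artists(empty)$artists, 0L)
})

test_that("roster equals a brute-force tally on random assignments", {
  set.seed(5)
  artists <- sample(letters[1:6], 120, replace = TRUE)
  rows <- data.frame(year = rep(2000:2005, each = 20), rank = NA_integer_,
                     artist = artists, love = 0L, hate = 0L, filler = 3L)
  cp <- build_toy_corpus(rows)
  tab <- table(artists)
  expect_identical(prestigious_artists(cp, 15L)$artists,
                   sort(names(tab)[tab > 15]))
})

test_that("success covariate averages top-k songs over the window", {
  lex <- toy_lexicon()
  cp <- make_chart_world(2000:2003, 15L)
  # constant case: all top-10 songs share the same count
  cp_const <- make_chart_world(2000:2003, 15L)
  cp_const$songs$bag <- lapply(cp_const$songs$bag, function(b) {
    b["hate"] <- 5L; b
  })
  cp_const$songs$W <- vapply(cp_const$songs$bag, sum, integer(1))
  expect_equal(success_covariate(cp_const, lex, 2003, "negative"), 5)
  # 3 years x top-10 with counts 0..9 each year -> mean 4.5
  expect_equal(success_covariate(cp, lex, 2003, "negative"), 4.5)
  # window error when history is incomplete
  expect_error(success_covariate(cp, lex, 2000, "negative"),
               "lag year")
  expect_error(success_covariate(cp, lex, 2002, "negative", window = 3L),
               "1999")
})

test_that("toy corpus with counts 1..30 over 30 averaged songs gives 15.5", {
  rows <- do.call(rbind, lapply(0:2, function(j) {
    data.frame(year = 2000L + j, rank = 1:10, artist = "A", love = 0L,
               hate = j * 10L + 1:10, filler = 40L)
  }))
  cp <- build_toy_corpus(rows)
  expect_equal(success_covariate(cp, toy_lexicon(), 2003, "negative"),
               mean(1:30))
})

test_that("prestige covariate averages roster songs; empty roster is NA", {
  lex <- toy_lexicon()
  rows <- data.frame(year = c(2000L, 2000L, 2001L, 2002L),
                     rank = c(1L, 2L, 1L, 1L),
                     artist = c("big", "small", "small", "small"),
                     love = 0L, hate = c(7L, 3L, 4L, 5L), filler = 20L)
  cp <- build_toy_corpus(rows)
  roster <- structure(list(artists = "big", threshold = 0L, source = "toy"),
                      class = "prestige_roster")
  expect_equal(prestige_covariate(cp, roster, lex, 2003, "negative"), 7)
  empty_roster <- structure(list(artists = character(0), threshold = 10L,
                                 source = "toy"), class = "prestige_roster")
  expect_message(
    val <- prestige_covariate(cp, empty_roster, lex, 2003, "negative"),
    "no prestigious songs")
  expect_true(is.na(val))
})

test_that("prestige equals a brute-force filtered mean on a random corpus", {
  set.seed(21)
  rows <- data.frame(year = rep(2000:2004, each = 8), rank = NA_integer_,
                     artist = sample(c("a", "b", "c"), 40, replace = TRUE),
                     love = rpois(40, 2), hate = rpois(40, 3),
                     filler = 30L)
  cp <- build_toy_corpus(rows)
  roster <- structure(list(artists = c("a", "c"), threshold = 0L,
                           source = "toy"), class = "prestige_roster")
  got <- prestige_covariate(cp, roster, toy_lexicon(), 2004, "negative")
  sel <- rows$year %in% 2001:2003 & rows$artist %in% c("a", "c")
  expect_equal(got, mean(rows$hate[sel]))
})

test_that("unbiased covariate averages all songs in the window", {
  lex <- toy_lexicon()
  rows <- data.frame(year = rep(2000:2002, each = 2), rank = NA_integer_,
                     artist = "A", love = 0L, hate = c(0L, 6L), filler = 10L)
  cp <- build_toy_corpus(rows)
  expect_equal(unbiased_covariate(cp, lex, 2003, "negative"), 3)
  rows$hate <- 3L
  expect_equal(unbiased_covariate(build_toy_corpus(rows), lex, 2003,
                                  "negative"), 3)
})

test_that("success equals unbiased when the corpus has exactly top_k songs", {
  cp <- make_chart_world(2000:2003, 10L)
  lex <- toy_lexicon()
  expect_equal(success_covariate(cp, lex, 2003, "negative", top_k = 10L),
               unbiased_covariate(cp, lex, 2003, "negative"))
})

test_that("covariates are translation-consistent in the polarity counts", {
  lex <- toy_lexicon()
  cp <- make_chart_world(2000:2003, 12L)
  shift <- make_chart_world(2000:2003, 12L, hate_base = 4L)
  for (f in list(
    function(x) success_covariate(x, lex, 2003, "negative"),
    function(x) unbiased_covariate(x, lex, 2003, "negative"))) {
    expect_equal(f(shift), f(cp) + 4)
  }
})

test_that("build_design drops the first window years and standardizes", {
  cp <- make_chart_world(2000:2004, 12L,
                         artists = c("a", "b", "c", "d"), year_drift = 2L)
  lex <- toy_lexicon()
  d <- build_design(cp, cp, lex, "negative", min_appearances = 2L)
  expect_setequal(unique(d$year), c(2003L, 2004L))
  expect_equal(nrow(d), 24L)
  for (v in c("success", "prestige", "unbiased", "rank")) {
    expect_equal(mean(d[[v]]), 0, tolerance = 1e-12)
    expect_equal(sd(d[[v]]), 1, tolerance = 1e-12)
  }
  # no look-ahead: covariates of year y never involve songs of year >= y
  d_raw <- build_design(cp, cp, lex, "negative", min_appearances = 2L,
                        standardize = "none")
  expect_equal(attr(d, "scaling")$center[["success"]],
               mean(d_raw$success))
  for (y in unique(d_raw$year)) {
    past <- subset_corpus(cp, cp$songs$year < y)
    expect_equal(unique(d_raw$success[d_raw$year == y]),
                 success_covariate(past, lex, y, "negative"))
    expect_equal(unique(d_raw$unbiased[d_raw$year == y]),
                 unbiased_covariate(past, lex, y, "negative"))
  }
})

test_that("rank enters only negative-polarity designs by default", {
  cp <- make_chart_world(2000:2004, 12L, artists = c("a", "b"))
  lex <- toy_lexicon()
  d_neg <- build_design(cp, cp, lex, "negative", min_appearances = 1L)
  d_pos <- build_design(cp, cp, lex, "positive", min_appearances = 1L)
  expect_true("rank" %in% names(d_neg))
  expect_false("rank" %in% names(d_pos))
})

test_that("design covariates equal per-row recomputation on a sim corpus", {
  cfg <- small_sim_config(seed = 314)
  sim <- simulate_corpus(cfg)
  lex <- synthetic_vocabulary(cfg)$lexicon
  d <- build_design(sim$corpus, sim$corpus, lex, "positive",
                    standardize = "none",
                    min_appearances = cfg$prestige_threshold)
  roster <- prestigious_artists(sim$corpus, cfg$prestige_threshold)
  for (y in unique(d$year)) {
    expect_equal(unique(d$success[d$year == y]),
                 success_covariate(sim$corpus, lex, y, "positive"))
    expect_equal(unique(d$prestige[d$year == y]),
                 prestige_covariate(sim$corpus, roster, lex, y, "positive"))
    expect_equal(unique(d$unbiased[d$year == y]),
                 unbiased_covariate(sim$corpus, lex, y, "positive"))
  }
  # row count: songs in fully-windowed years with W > 0
  ok_years <- setdiff(sim$corpus$years, head(sim$corpus$years, cfg$window))
  expect_equal(nrow(d), sum(sim$corpus$songs$year %in% ok_years &
                              sim$corpus$songs$W > 0))
})

test_that("design round-trips through CSV with its sidecar metadata", {
  cp <- make_chart_world(2000:2004, 10L, artists = c("a", "b"))
  d <- build_design(cp, cp, toy_lexicon(), "negative", min_appearances = 1L)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_design(d, csv, js)
  d2 <- read_design(csv, js)
  expect_equal(d2$success, d$success)
  expect_equal(attr(d2, "scaling")$center[["success"]],
               attr(d, "scaling")$center[["success"]])
})
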