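# fixture builders shared across test files; everything is generated in
# code, nothing binary is stored

write_fixture_chart <- function(path, rows) {
  df <- data.frame(Rank = rows$rank, Song = rows$song, Artist = rows$artist,
                   Year = rows$year, Lyrics = rows$lyrics)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# tiny two-class lexicon used throughout the unit tests
toy_lexicon <- function() {
  make_lexicon(pos_exact = c("love", "happi"), neg_exact = c("hate", "sad"))
}

# a hand-built corpus: counts fully controlled, no randomness
# spec_rows: data.frame(year, rank, artist, love, hate, filler)
build_toy_corpus <- function(spec_rows, provenance = "chart") {
  n <- nrow(spec_rows)
  bags <- lapply(seq_len(n), function(i) {
    b <- c(love = spec_rows$love[i], hate = spec_rows$hate[i],
           the = spec_rows$filler[i])
    b <- b[b > 0]
    structure(as.integer(b), names = names(b))
  })
  df <- make_songs_df(
    song_id = sprintf("toy_%03d", seq_len(n)),
    title = sprintf("t%d", seq_len(n)),
    artist_raw = as.character(spec_rows$artist),
    artist_unit = as.character(spec_rows$artist),
    year = spec_rows$year,
    genre = if (!is.null(spec_rows$genre)) spec_rows$genre else NA_character_,
    rank = if (!is.null(spec_rows$rank)) spec_rows$rank else NA_integer_,
    bag = bags)
  new_corpus(df, provenance)
}

# random bags over a small vocabulary, for brute-force comparisons
random_bag <- function(vocab, max_count = 5L) {
  k <- sample.int(length(vocab), sample.int(length(vocab), 1))
  stems <- vocab[k]
  structure(sample.int(max_count, length(stems), replace = TRUE),
            names = stems)
}

quiet_fit <- function(...) suppressWarnings(fit_model(...))

small_sim_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_years = 8L, songs_per_year = 30L, mean_words = 120,
         n_artists = 20L, n_genres = 3L, seed = seed),
    list(...))
  do.call(sim_config, args)
}
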