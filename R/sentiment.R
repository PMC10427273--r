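#' Load positive/negative emotion lexicons
#'
#' Lexicon files are plain text, one pattern per line; `#` starts a comment
#' line and blank lines are ignored. A trailing `*` marks a prefix pattern
#' (the wildcard convention of dictionary-style sentiment lexicons): it
#' matches any stem beginning with the prefix. All entries are stemmed with
#' the same stemmer as the corpus so that matching happens in stem space;
#' prefix patterns keep their (unstemmed) prefix because stemming a prefix
#' fragment is not meaningful.
#'
#' Any overlap between the expanded positive and negative sets — an exact
#' stem appearing in both lists, or a stem of one polarity matched by a
#' prefix pattern of the other — is a load-time error: a word must never be
#' double-counted.
#'
#' @param pos_path file of positive-emotion patterns.
#' @param neg_path file of negative-emotion patterns.
#' @param variant stemmer variant, see [stem_words()].
#' @return a `lexicon`: list with `pos_exact`, `pos_prefix`, `neg_exact`,
#'   `neg_prefix`, and a `source` descriptor.
#' @export
load_lexicon <- function(pos_path, neg_path, variant = "porter") {
  pos <- parse_lexicon_file(pos_path, variant)
  neg <- parse_lexicon_file(neg_path, variant)
  lex <- structure(list(pos_exact = pos$exact, pos_prefix = pos$prefix,
                        neg_exact = neg$exact, neg_prefix = neg$prefix,
                        source = paste(pos_path, neg_path, sep = " + ")),
                   class = "lexicon")
  conflicts <- lexicon_conflicts(lex)
  if (length(conflicts) > 0L) {
    stop("lexicon overlap between positive and negative lists: ",
         paste(utils::head(conflicts, 5), collapse = ", "))
  }
  lex
}

parse_lexicon_file <- function(path, variant) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines <- tolower(lines)
  wild <- endsWith(lines, "*")
  prefix <- unique(sub("\\*$", "", lines[wild]))
  exact <- unique(stem_words(lines[!wild], variant = variant))
  prefix <- prefix[nzchar(prefix)]
  # a prefix subsumed by a shorter prefix of the same polarity is redundant
  list(exact = sort(exact), prefix = sort(prefix))
}

#' Build a lexicon directly from stem sets (no files)
#' @param pos_exact,neg_exact exact stem sets.
#' @param pos_prefix,neg_prefix prefix patterns (no trailing `*`).
#' @return a `lexicon`.
#' @export
make_lexicon <- function(pos_exact = character(0), neg_exact = character(0),
                         pos_prefix = character(0), neg_prefix = character(0)) {
  lex <- structure(list(pos_exact = sort(unique(pos_exact)),
                        pos_prefix = sort(unique(pos_prefix)),
                        neg_exact = sort(unique(neg_exact)),
                        neg_prefix = sort(unique(neg_prefix)),
                        source = "in-memory"),
                   class = "lexicon")
  conflicts <- lexicon_conflicts(lex)
  if (length(conflicts) > 0L) {
    stop("lexicon overlap between positive and negative lists: ",
         paste(utils::head(conflicts, 5), collapse = ", "))
  }
  lex
}

lexicon_conflicts <- function(lex) {
  hits <- intersect(lex$pos_exact, lex$neg_exact)
  pref_hit <- function(stems, prefixes) {
    if (length(stems) == 0L || length(prefixes) == 0L) return(character(0))
    stems[vapply(stems, function(s) any(startsWith(s, prefixes)), logical(1))]
  }
  hits <- c(hits,
            pref_hit(lex$pos_exact, lex$neg_prefix),
            pref_hit(lex$neg_exact, lex$pos_prefix),
            intersect(lex$pos_prefix, lex$neg_prefix),
            # one polarity's prefix extends the other's: overlapping cones
            pref_hit(lex$pos_prefix, lex$neg_prefix),
            pref_hit(lex$neg_prefix, lex$pos_prefix))
  unique(hits)
}

#' Number of patterns per polarity
#' @param lex a `lexicon`.
#' @return named integer vector with elements `pos` and `neg`.
#' @export
lexicon_sizes <- function(lex) {
  c(pos = length(lex$pos_exact) + length(lex$pos_prefix),
    neg = length(lex$neg_exact) + length(lex$neg_prefix))
}

match_polarity <- function(stems, exact, prefixes) {
  hit <- stems %in% exact
  if (length(prefixes) > 0L && any(!hit)) {
    hit[!hit] <- vapply(stems[!hit],
                        function(s) any(startsWith(s, prefixes)), logical(1))
  }
  hit
}

#' Sentiment counts for one bag of stems
#'
#' Each word is classified as positive, negative or neither; disjointness of
#' the lexicon guarantees no word counts twice.
#'
#' @param bag named integer vector of stem counts.
#' @param lexicon a `lexicon`.
#' @return named numeric vector `c(k_pos, k_neg, W)`.
#' @export
score_bag <- function(bag, lexicon) {
  if (length(bag) == 0L) return(c(k_pos = 0L, k_neg = 0L, W = 0L))
  stems <- names(bag)
  kp <- sum(bag[match_polarity(stems, lexicon$pos_exact, lexicon$pos_prefix)])
  kn <- sum(bag[match_polarity(stems, lexicon$neg_exact, lexicon$neg_prefix)])
  c(k_pos = as.integer(kp), k_neg = as.integer(kn), W = as.integer(sum(bag)))
}

#' Sentiment counts for every song in a corpus
#'
#' @param corpus a `lyric_corpus`.
#' @param lexicon a `lexicon`.
#' @return data.frame with columns song_id, year, k_pos, k_neg, W.
#' @export
score_corpus <- function(corpus, lexicon) {
  sc <- t(vapply(corpus$songs$bag, score_bag, c(k_pos = 0, k_neg = 0, W = 0),
                 lexicon = lexicon))
  data.frame(song_id = corpus$songs$song_id,
             year = corpus$songs$year,
             k_pos = as.integer(sc[, "k_pos"]),
             k_neg = as.integer(sc[, "k_neg"]),
             W = as.integer(sc[, "W"]),
             stringsAsFactors = FALSE)
}

#' Yearly relative frequency of one stem
#'
#' `value(year)` is the total count of the stem across that year's songs
#' divided by the total word count of the year. Years with zero total words
#' are omitted (and noted in the result's attributes).
#'
#' @param corpus a `lyric_corpus`.
#' @param stem single stem to track (e.g. "love").
#' @return data.frame (year, value), one row per year with words.
#' @export
yearly_word_frequency <- function(corpus, stem) {
  years <- corpus$years
  cnt <- vapply(corpus$songs$bag, function(b) {
    v <- b[stem]; if (is.na(v)) 0L else as.integer(v)
  }, integer(1))
  num <- tapply(cnt, corpus$songs$year, sum)
  den <- tapply(corpus$songs$W, corpus$songs$year, sum)
  keep <- den > 0
  out <- data.frame(year = as.integer(names(num))[keep],
                    value = as.numeric(num[keep] / den[keep]))
  attr(out, "omitted_years") <- as.integer(names(num))[!keep]
  attr(out, "denominator") <- "total words per year"
  out
}

#' Yearly proportion of positive (or negative) emotion words
#'
#' `value(year) = sum(k_polarity) / sum(W)` over the year's songs.
#'
#' @param corpus a `lyric_corpus`.
#' @param lexicon a `lexicon`.
#' @param polarity `"positive"` or `"negative"`.
#' @return data.frame (year, value).
#' @export
yearly_valence_proportion <- function(corpus, lexicon,
                                      polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  sc <- score_corpus(corpus, lexicon)
  k <- if (polarity == "positive") sc$k_pos else sc$k_neg
  num <- tapply(k, sc$year, sum)
  den <- tapply(sc$W, sc$year, sum)
  keep <- den > 0
  out <- data.frame(year = as.integer(names(num))[keep],
                    value = as.numeric(num[keep] / den[keep]))
  attr(out, "omitted_years") <- as.integer(names(num))[!keep]
  attr(out, "denominator") <- "total words per year"
  out
}

#' Export a trend series as CSV and (optionally) a vector plot
#' @param series data.frame (year, value) from a trend function.
#' @param csv_path output CSV path.
#' @param plot_path optional PDF path for a simple line plot.
#' @param main plot title.
#' @export
export_trend <- function(series, csv_path, plot_path = NULL, main = "trend") {
  utils::write.csv(series, csv_path, row.names = FALSE)
  if (!is.null(plot_path)) {
    grDevices::pdf(plot_path, width = 6, height = 4)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(series$year, series$value, type = "b", pch = 16, cex = 0.6,
         xlab = "year", ylab = "proportion", main = main)
  }
  invisible(csv_path)
}
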