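#' Corpus container
#'
#' A corpus is a data frame of songs plus provenance metadata. Each song
#' carries an opaque `song_id`, a `title`, the raw artist string
#' (`artist_raw`), a normalised `artist_unit`, the calendar `year`, an
#' optional `genre`, an optional chart `rank` (1 = best-selling, 100 =
#' least-selling), a bag of stem counts (`bag`, a named integer vector) and
#' the total word count `W` (the sum of the bag).
#'
#' @param songs data.frame with columns song_id, title, artist_raw,
#'   artist_unit, year, genre, rank, bag (list column), W.
#' @param provenance one of "chart", "bow", "synthetic".
#' @return an object of class `lyric_corpus`.
#' @export
new_corpus <- function(songs, provenance = c("chart", "bow", "synthetic")) {
  provenance <- match.arg(provenance)
  needed <- c("song_id", "title", "artist_raw", "artist_unit", "year",
              "genre", "rank", "bag", "W")
  missing_cols <- setdiff(needed, names(songs))
  if (length(missing_cols) > 0L) {
    stop("corpus is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(songs$song_id)) stop("song_id values must be unique")
  w_chk <- vapply(songs$bag, function(b) sum(as.integer(b)), integer(1))
  if (!all(w_chk == songs$W)) stop("W must equal the sum of bag counts")
  ok_rank <- is.na(songs$rank) | (songs$rank >= 1L & songs$rank <= 100L)
  if (!all(ok_rank)) stop("rank must be in [1, 100] or missing")
  structure(
    list(songs = songs,
         years = sort(unique(as.integer(songs$year))),
         provenance = provenance,
         log = list()),
    class = "lyric_corpus")
}

#' @export
print.lyric_corpus <- function(x, ...) {
  yrs <- if (length(x$years)) paste0(min(x$years), "-", max(x$years)) else "none"
  cat(sprintf("<lyric_corpus> %d songs, years %s, provenance: %s\n",
              nrow(x$songs), yrs, x$provenance))
  invisible(x)
}

#' Number of songs in a corpus
#' @param corpus a `lyric_corpus`.
#' @return integer count.
#' @export
n_songs <- function(corpus) nrow(corpus$songs)

#' Structured filter log of a corpus
#'
#' Every filtering operation appends a record with the step name and the
#' number of songs before and after, mirroring the data-funnel style of
#' corpus-preparation reports.
#'
#' @param corpus a `lyric_corpus`.
#' @return list of log records.
#' @export
corpus_log <- function(corpus) corpus$log

log_step <- function(corpus, step, before, after, detail = NULL) {
  corpus$log <- c(corpus$log, list(list(step = step, before = before,
                                        after = after, detail = detail)))
  corpus
}

empty_bag <- function() structure(integer(0), names = character(0))

#' Assemble a song table for [new_corpus()]
#'
#' Convenience constructor that recycles scalar fields, attaches the bag
#' list column and computes `W` as the sum of each bag.
#'
#' @param song_id,title,artist_raw,artist_unit,year,genre,rank per-song
#'   fields (scalars are recycled).
#' @param bag list of named integer vectors (stem -> count).
#' @return data.frame suitable for [new_corpus()].
#' @export
make_songs_df <- function(song_id, title, artist_raw, artist_unit, year,
                          genre, rank, bag) {
  df <- data.frame(song_id = as.character(song_id),
                   title = as.character(title),
                   artist_raw = as.character(artist_raw),
                   artist_unit = as.character(artist_unit),
                   year = as.integer(year),
                   genre = as.character(genre),
                   rank = as.integer(rank),
                   stringsAsFactors = FALSE)
  df$bag <- bag
  df$W <- vapply(bag, function(b) sum(as.integer(b)), integer(1))
  df
}

#' Keep only songs for which a predicate holds
#' @param corpus a `lyric_corpus`.
#' @param keep logical vector, one entry per song.
#' @param step label recorded in the filter log.
#' @return filtered `lyric_corpus`.
#' @export
subset_corpus <- function(corpus, keep, step = "subset") {
  stopifnot(length(keep) == nrow(corpus$songs))
  before <- nrow(corpus$songs)
  corpus$songs <- corpus$songs[keep, , drop = FALSE]
  rownames(corpus$songs) <- NULL
  corpus$years <- sort(unique(corpus$songs$year))
  log_step(corpus, step, before, nrow(corpus$songs))
}
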