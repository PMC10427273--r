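#' Read a chart-style lyric table (CSV)
#'
#' One row per song with chart rank (1-100), title, artist, year and raw
#' lyric text. Lyrics are tokenised and stemmed into bags of stem counts.
#' Chart sources carry no genre information, so `genre` is set to missing.
#'
#' @param path CSV file path.
#' @param columns named character vector mapping the roles
#'   `rank`, `song`, `artist`, `year`, `lyrics` to column names in the file.
#' @param variant stemmer variant, see [stem_words()].
#' @return a `lyric_corpus` with provenance `"chart"`. Songs whose lyrics
#'   stem to an empty bag get `W = 0`; they are kept here and excluded (and
#'   logged) by downstream modelling steps.
#' @export
read_chart_csv <- function(path,
                           columns = c(rank = "Rank", song = "Song",
                                       artist = "Artist", year = "Year",
                                       lyrics = "Lyrics"),
                           variant = "porter") {
  if (!file.exists(path)) stop("file not found: ", path)
  roles <- c("rank", "song", "artist", "year", "lyrics")
  if (!all(roles %in% names(columns))) {
    stop("columns mapping must name: ", paste(roles, collapse = ", "))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  for (role in roles) {
    if (!columns[[role]] %in% names(raw)) {
      stop("missing mandatory column: ", columns[[role]])
    }
  }
  n <- nrow(raw)
  parse_int <- function(x, what) {
    out <- suppressWarnings(as.integer(x))
    bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
    if (length(bad) > 0L) {
      stop(sprintf("non-integer %s at row %d: '%s'", what, bad[1], x[bad[1]]))
    }
    out
  }
  rank <- parse_int(raw[[columns[["rank"]]]], "rank")
  year <- parse_int(raw[[columns[["year"]]]], "year")
  if (anyNA(year)) stop("non-integer year at row ", which(is.na(year))[1])
  lyr <- raw[[columns[["lyrics"]]]]
  bags <- lapply(lyr, function(t) {
    if (is.na(t)) empty_bag() else tokenize_and_stem(t, variant = variant)
  })
  artist <- raw[[columns[["artist"]]]]
  df <- make_songs_df(
    song_id = sprintf("chart_%05d", seq_len(n)),
    title = raw[[columns[["song"]]]],
    artist_raw = artist, artist_unit = artist,
    year = year, genre = NA_character_, rank = rank, bag = bags)
  cp <- new_corpus(df, "chart")
  log_step(cp, "read_chart_csv", n, n, detail = path)
}

#' Read a sparse bag-of-words corpus with a metadata table
#'
#' The bag-of-words file follows the musixmatch "mxm" text convention:
#' lines starting `#` are comments; a single line starting `%` lists the
#' vocabulary as comma-separated stems (1-based indices); every other line
#' is `trackID,mxmID,idx:cnt,idx:cnt,...`. Metadata is a CSV with columns
#' `track_id, artist, year, genre`; tracks missing from the metadata table,
#' or with a missing year or artist, are dropped and logged.
#'
#' @param bow_path path to the bag-of-words file.
#' @param meta_path path to the metadata CSV.
#' @return a `lyric_corpus` with provenance `"bow"`.
#' @export
read_bow_corpus <- function(bow_path, meta_path) {
  if (!file.exists(bow_path)) stop("file not found: ", bow_path)
  if (!file.exists(meta_path)) stop("file not found: ", meta_path)
  lines <- readLines(bow_path)
  keep <- !startsWith(lines, "#")
  lines <- lines[keep & nzchar(lines)]
  vocab_line <- which(startsWith(lines, "%"))
  if (length(vocab_line) != 1L) {
    stop("expected exactly one vocabulary line starting with '%'")
  }
  vocab <- strsplit(sub("^%", "", lines[vocab_line]), ",", fixed = TRUE)[[1]]
  track_lines <- lines[-vocab_line]
  n <- length(track_lines)
  ids <- character(n); mxm <- character(n); bags <- vector("list", n)
  for (i in seq_len(n)) {
    parts <- strsplit(track_lines[i], ",", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("malformed track line at line ", i)
    ids[i] <- parts[1]; mxm[i] <- parts[2]
    if (length(parts) > 2L) {
      kv <- strsplit(parts[-(1:2)], ":", fixed = TRUE)
      idx <- vapply(kv, function(p) as.integer(p[1]), integer(1))
      cnt <- vapply(kv, function(p) as.integer(p[2]), integer(1))
      if (anyNA(idx) || any(idx < 1L) || any(idx > length(vocab))) {
        stop("word index outside vocabulary at line ", i)
      }
      bags[[i]] <- structure(cnt, names = vocab[idx])
    } else {
      bags[[i]] <- empty_bag()
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate track ID: ", ids[duplicated(ids)][1])
  }
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("track_id", "artist", "year", "genre")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  m <- match(ids, meta$track_id)
  year <- suppressWarnings(as.integer(meta$year[m]))
  artist <- meta$artist[m]
  genre <- meta$genre[m]
  genre[!is.na(genre) & !nzchar(genre)] <- NA_character_
  usable <- !is.na(m) & !is.na(year) & !is.na(artist) & nzchar(artist)
  df <- make_songs_df(song_id = ids, title = mxm, artist_raw = artist,
                      artist_unit = artist, year = year,
                      genre = genre, rank = NA_integer_, bag = bags)
  cp <- new_corpus(df[usable, , drop = FALSE], "bow")
  cp <- log_step(cp, "read_bow_corpus", n, sum(usable),
                 detail = sprintf("%d tracks dropped (no metadata/year/artist)",
                                  sum(!usable)))
  cp
}

#' Write a corpus in the chart CSV dialect
#'
#' The lyric column is reconstructed from the bag by repeating each stem
#' `count` times, so a read/write/read round trip preserves bags exactly
#' (stems are already fully stemmed, hence fixed points of the stemmer).
#'
#' @param corpus a `lyric_corpus` with ranks.
#' @param path output CSV path.
#' @export
write_chart_csv <- function(corpus, path) {
  lyr <- vapply(corpus$songs$bag, function(b) {
    paste(rep(names(b), b), collapse = " ")
  }, character(1))
  out <- data.frame(Rank = corpus$songs$rank, Song = corpus$songs$title,
                    Artist = corpus$songs$artist_raw,
                    Year = corpus$songs$year, Lyrics = lyr)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a corpus in the sparse bag-of-words dialect (plus metadata CSV)
#'
#' @param corpus a `lyric_corpus`.
#' @param bow_path output path for the bag-of-words file.
#' @param meta_path output path for the metadata CSV.
#' @export
write_bow_corpus <- function(corpus, bow_path, meta_path) {
  vocab <- sort(unique(unlist(lapply(corpus$songs$bag, names))))
  lines <- c("# bag-of-words corpus",
             paste0("%", paste(vocab, collapse = ",")))
  body <- vapply(seq_len(nrow(corpus$songs)), function(i) {
    b <- corpus$songs$bag[[i]]
    kv <- if (length(b)) {
      paste0(match(names(b), vocab), ":", as.integer(b), collapse = ",")
    } else ""
    id <- corpus$songs$song_id[i]
    if (nzchar(kv)) paste(id, id, kv, sep = ",") else paste(id, id, sep = ",")
  }, character(1))
  writeLines(c(lines, body), bow_path)
  meta <- data.frame(track_id = corpus$songs$song_id,
                     artist = corpus$songs$artist_raw,
                     year = corpus$songs$year,
                     genre = ifelse(is.na(corpus$songs$genre), "",
                                    corpus$songs$genre))
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(bow_path)
}

#' English-language heuristic
#'
#' A song counts as English iff the stem "the" occurs at least once in its
#' bag — the standard cheap heuristic for bag-of-words lyric corpora.
#'
#' @param bag named integer vector of stem counts.
#' @return TRUE iff `bag["the"] >= 1`.
#' @export
detect_english <- function(bag) {
  !is.na(bag["the"]) && bag[["the"]] >= 1L
}

#' Drop songs that fail the English heuristic
#' @param corpus a `lyric_corpus`.
#' @return filtered corpus (logged).
#' @export
filter_english <- function(corpus) {
  keep <- vapply(corpus$songs$bag, detect_english, logical(1))
  subset_corpus(corpus, keep, step = "filter_english")
}

#' Keep only years with more than `min_songs` songs
#'
#' The inequality is strict: a year with exactly `min_songs` songs is
#' dropped.
#'
#' @param corpus a `lyric_corpus`.
#' @param min_songs threshold (default 500).
#' @return filtered corpus (logged).
#' @export
filter_years <- function(corpus, min_songs = 500L) {
  tab <- table(corpus$songs$year)
  ok_years <- as.integer(names(tab)[tab > min_songs])
  subset_corpus(corpus, corpus$songs$year %in% ok_years,
                step = sprintf("filter_years(>%d)", min_songs))
}

# ---- artist-name normalisation ------------------------------------------

#' Fingerprint of an artist name
#'
#' Lowercase, strip accents and punctuation, collapse whitespace, sort
#' tokens. All raw variants sharing a fingerprint are merged into one
#' artist unit.
#'
#' @param name raw artist string(s).
#' @return character fingerprint(s).
#' @export
artist_fingerprint <- function(name) {
  vapply(name, function(x) {
    x <- tolower(x)
    x <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT", sub = "")
    if (is.na(x)) x <- ""
    x <- gsub("[^a-z0-9 ]+", " ", x)
    toks <- strsplit(trimws(gsub(" +", " ", x)), " ", fixed = TRUE)[[1]]
    paste(sort(toks[nzchar(toks)]), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Cluster raw artist names into canonical artist units
#'
#' Key-collision clustering on [artist_fingerprint()]: all raw names with
#' the same fingerprint become one unit, whose canonical form is the most
#' frequent raw variant (ties broken lexicographically), normalised to
#' lowercase with collapsed punctuation.
#'
#' @param names character vector of raw artist strings (with repeats; the
#'   frequencies drive canonical-form selection).
#' @return an `artist_index`: list with `map` (raw name -> unit) and
#'   `units` (fingerprint -> canonical unit).
#' @export
cluster_artist_names <- function(names) {
  if (length(names) == 0L) stop("names must be non-empty")
  fp <- artist_fingerprint(names)
  canon <- character(0)
  for (f in unique(fp)) {
    variants <- names[fp == f]
    tab <- sort(table(variants), decreasing = TRUE)
    best <- names(tab)[tab == max(tab)]
    raw_best <- sort(best)[1]
    canon[f] <- normalize_artist(raw_best)
  }
  uniq <- unique(names)
  map <- canon[artist_fingerprint(uniq)]
  names(map) <- uniq
  structure(list(map = map, units = canon), class = "artist_index")
}

normalize_artist <- function(x) {
  x <- tolower(x)
  x <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT", sub = "")
  if (is.na(x)) x <- ""
  x <- gsub("[^a-z0-9 ]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Map a raw artist name to its clustered unit
#' @param index an `artist_index` from [cluster_artist_names()].
#' @param name raw artist string(s).
#' @return canonical unit(s); unseen names are normalised by fingerprint.
#' @export
artist_unit <- function(index, name) {
  hit <- index$map[name]
  miss <- is.na(hit)
  if (any(miss)) {
    fp <- artist_fingerprint(name[miss])
    fromfp <- index$units[fp]
    fromfp[is.na(fromfp)] <- vapply(name[miss][is.na(fromfp)],
                                    normalize_artist, character(1),
                                    USE.NAMES = FALSE)
    hit[miss] <- fromfp
  }
  unname(hit)
}

# separators follow the common chart conventions; "," always splits
collab_separators <- c("featuring", "feat.", "feat", "and", "AND", "with")

#' Split a collaboration artist string into member units
#'
#' If the name contains no separator it is a single unit. If separators are
#' present and every part resolves to a known solo unit, the parts are
#' treated as single artists occasionally collaborating. Otherwise the whole
#' string is one stable-collaboration unit.
#'
#' @param name raw artist string.
#' @param solo_set character vector of known solo artist units.
#' @param index optional `artist_index` used to resolve parts.
#' @return character vector of artist units (length 1 for a single artist or
#'   a stable collaboration; length > 1 for an occasional collaboration).
#' @export
split_collaborations <- function(name, solo_set, index = NULL) {
  if (length(name) != 1L || is.na(name) || !nzchar(trimws(name))) {
    stop("empty artist name")
  }
  toks <- strsplit(trimws(name), "[[:space:]]+")[[1]]
  # commas glued to tokens always split
  toks <- unlist(strsplit(gsub(",", " , ", paste(toks, collapse = " ")),
                          "[[:space:]]+"))
  is_sep <- toks %in% c(collab_separators, ",")
  if (!any(is_sep)) {
    unit <- if (is.null(index)) normalize_artist(name) else {
      artist_unit(index, name)
    }
    return(unit)
  }
  grp <- cumsum(is_sep)
  parts <- vapply(split(toks[!is_sep], grp[!is_sep]),
                  paste, character(1), collapse = " ")
  parts <- parts[nzchar(parts)]
  resolve <- function(p) {
    if (is.null(index)) normalize_artist(p) else artist_unit(index, p)
  }
  units <- vapply(parts, resolve, character(1), USE.NAMES = FALSE)
  if (length(units) > 0L && all(units %in% solo_set)) {
    units
  } else {
    resolve(name)   # stable collaboration: one unit for the whole string
  }
}

#' Resolve artist units for a whole corpus
#'
#' Clusters raw names, builds the solo set (names without separators),
#' splits collaborations, and writes the resulting `artist_unit` back into
#' the corpus. Occasional collaborations between known solo artists are
#' attributed to the first listed member (the lead artist).
#'
#' @param corpus a `lyric_corpus`.
#' @return corpus with normalised `artist_unit` column.
#' @export
resolve_artists <- function(corpus) {
  raw <- corpus$songs$artist_raw
  index <- cluster_artist_names(raw)
  has_sep <- vapply(raw, function(x) {
    toks <- strsplit(trimws(gsub(",", " , ", x)), "[[:space:]]+")[[1]]
    any(toks %in% c(collab_separators, ","))
  }, logical(1))
  solo_set <- unique(artist_unit(index, raw[!has_sep]))
  corpus$songs$artist_unit <- vapply(raw, function(x) {
    split_collaborations(x, solo_set, index)[1]
  }, character(1), USE.NAMES = FALSE)
  log_step(corpus, "resolve_artists", nrow(corpus$songs), nrow(corpus$songs),
           detail = sprintf("%d artist units", length(unique(corpus$songs$artist_unit))))
}
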