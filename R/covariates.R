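#' Roster of prestigious artists
#'
#' Prestigious artists are those appearing strictly more than
#' `min_appearances` times in the chart corpus (counting chart entries,
#' i.e. songs).
#'
#' @param chart_corpus a `lyric_corpus` with resolved artist units.
#' @param min_appearances threshold (default 10; "more than 10" is strict).
#' @return a `prestige_roster`: list with `artists`, `threshold`, `source`.
#' @export
prestigious_artists <- function(chart_corpus, min_appearances = 10L) {
  tab <- table(chart_corpus$songs$artist_unit)
  structure(list(artists = sort(names(tab)[tab > min_appearances]),
                 threshold = as.integer(min_appearances),
                 source = chart_corpus$provenance),
            class = "prestige_roster")
}

#' @export
print.prestige_roster <- function(x, ...) {
  cat(sprintf("<prestige_roster> %d artists (> %d chart entries)\n",
              length(x$artists), x$threshold))
  invisible(x)
}

polarity_counts <- function(corpus, lexicon, polarity, mode = "count") {
  sc <- score_corpus(corpus, lexicon)
  k <- if (polarity == "positive") sc$k_pos else sc$k_neg
  if (mode == "proportion") {
    k <- ifelse(sc$W > 0, k / sc$W, NA_real_)
  }
  data.frame(song_id = sc$song_id, year = sc$year, k = k, W = sc$W,
             stringsAsFactors = FALSE)
}

check_window <- function(corpus, year, window) {
  lags <- (year - 1L):(year - window)
  missing <- setdiff(lags, corpus$years)
  if (length(missing) > 0L) {
    stop("lag year(s) absent from corpus: ", paste(missing, collapse = ", "))
  }
  lags
}

#' Success-bias covariate
#'
#' Mean per-song polarity word count over the top-`top_k`-ranked songs of
#' each of the `window` years strictly preceding `year` (so up to
#' `window * top_k` songs enter the mean).
#'
#' @param chart_corpus ranked `lyric_corpus`.
#' @param lexicon a `lexicon`.
#' @param year focal calendar year.
#' @param polarity `"positive"` or `"negative"`.
#' @param window number of preceding years (default 3).
#' @param top_k chart depth defining "successful" (default 10).
#' @param mode `"count"` (raw per-song word counts, the default) or
#'   `"proportion"` (k/W, a length-adjusted sensitivity mode).
#' @return scalar covariate value.
#' @export
success_covariate <- function(chart_corpus, lexicon, year,
                              polarity = c("positive", "negative"),
                              window = 3L, top_k = 10L, mode = "count") {
  polarity <- match.arg(polarity)
  lags <- check_window(chart_corpus, year, window)
  pc <- polarity_counts(chart_corpus, lexicon, polarity, mode)
  rank <- chart_corpus$songs$rank
  sel <- pc$year %in% lags & !is.na(rank) & rank <= top_k
  if (!any(sel)) stop("no ranked songs in window before year ", year)
  mean(pc$k[sel])
}

#' Prestige-bias covariate
#'
#' Mean per-song polarity word count over songs by roster artists in the
#' `window` years strictly preceding `year`. Returns `NA` (with a message)
#' if the window contains no prestigious songs.
#'
#' @inheritParams success_covariate
#' @param corpus source `lyric_corpus` (normally the chart corpus).
#' @param roster a `prestige_roster`.
#' @return scalar covariate value or `NA_real_`.
#' @export
prestige_covariate <- function(corpus, roster, lexicon, year,
                               polarity = c("positive", "negative"),
                               window = 3L, mode = "count") {
  polarity <- match.arg(polarity)
  lags <- check_window(corpus, year, window)
  pc <- polarity_counts(corpus, lexicon, polarity, mode)
  sel <- pc$year %in% lags & corpus$songs$artist_unit %in% roster$artists
  if (!any(sel)) {
    message("no prestigious songs in window before year ", year)
    return(NA_real_)
  }
  mean(pc$k[sel])
}

#' Unbiased-transmission covariate
#'
#' Mean per-song polarity word count over ALL songs in the `window` years
#' strictly preceding `year` — the random-copying baseline: a word's
#' adoption tracks its recent population frequency.
#'
#' @inheritParams prestige_covariate
#' @return scalar covariate value.
#' @export
unbiased_covariate <- function(corpus, lexicon, year,
                               polarity = c("positive", "negative"),
                               window = 3L, mode = "count") {
  polarity <- match.arg(polarity)
  lags <- check_window(corpus, year, window)
  pc <- polarity_counts(corpus, lexicon, polarity, mode)
  sel <- pc$year %in% lags
  if (!any(sel)) stop("no songs in window before year ", year)
  mean(pc$k[sel])
}

#' Assemble model-ready design rows
#'
#' One row per target-corpus song whose year has a complete lag window.
#' Success and prestige are always computed from the chart corpus (charts
#' define success and prestige even when modelling a different corpus);
#' the unbiased covariate is computed from the target corpus itself. Songs
#' with `W = 0` are excluded and logged. The first `window` years of the
#' target corpus are dropped by construction.
#'
#' @param target_corpus corpus whose songs form the rows.
#' @param chart_corpus ranked corpus supplying success/prestige (may be the
#'   same object as `target_corpus`).
#' @param lexicon a `lexicon`.
#' @param polarity `"positive"` or `"negative"`.
#' @param window lag window in years (default 3).
#' @param top_k chart depth for success (default 10).
#' @param min_appearances prestige threshold (default 10).
#' @param mode covariate mode, `"count"` or `"proportion"`.
#' @param standardize `"sample"` (z-score each covariate column, default),
#'   `"none"`, or `"fixed"` (use the constants in `center`/`scale`).
#' @param center,scale named numeric vectors (names from success, prestige,
#'   unbiased, rank) used when `standardize = "fixed"`.
#' @param include_rank attach the chart rank as a content-bias predictor;
#'   default: only for negative polarity when ranks exist (a negativity
#'   content bias is hypothesised, a positivity one is not).
#' @param roster optional `prestige_roster`; computed from `chart_corpus`
#'   when omitted.
#' @return a `design` data.frame: song_id, year, k, W, success, prestige,
#'   unbiased, rank (optional), artist, genre, plus attributes `scaling`
#'   (centers/scales applied), `polarity`, `window`, `dropped` (log).
#' @export
build_design <- function(target_corpus, chart_corpus, lexicon,
                         polarity = c("positive", "negative"),
                         window = 3L, top_k = 10L, min_appearances = 10L,
                         mode = "count",
                         standardize = c("sample", "none", "fixed"),
                         center = NULL, scale = NULL,
                         include_rank = NULL, roster = NULL) {
  polarity <- match.arg(polarity)
  standardize <- match.arg(standardize)
  if (is.null(roster)) {
    roster <- prestigious_artists(chart_corpus, min_appearances)
  }
  has_rank <- any(!is.na(target_corpus$songs$rank))
  if (is.null(include_rank)) {
    include_rank <- (polarity == "negative") && has_rank
  }
  chart_years <- chart_corpus$years
  target_years <- target_corpus$years
  usable_years <- target_years[
    vapply(target_years, function(y) {
      all(((y - 1L):(y - window)) %in% chart_years) &&
        all(((y - 1L):(y - window)) %in% target_years)
    }, logical(1))]
  if (length(usable_years) == 0L) stop("no years with a complete lag window")

  cov_tab <- do.call(rbind, lapply(usable_years, function(y) {
    data.frame(
      year = y,
      success = success_covariate(chart_corpus, lexicon, y, polarity,
                                  window, top_k, mode),
      prestige = prestige_covariate(chart_corpus, roster, lexicon, y,
                                    polarity, window, mode),
      unbiased = unbiased_covariate(target_corpus, lexicon, y, polarity,
                                    window, mode))
  }))

  sc <- polarity_counts(target_corpus, lexicon, polarity, mode = "count")
  songs <- target_corpus$songs
  keep <- songs$year %in% usable_years & songs$W > 0L
  n_w0 <- sum(songs$year %in% usable_years & songs$W == 0L)
  rows <- data.frame(song_id = songs$song_id[keep],
                     year = songs$year[keep],
                     k = sc$k[keep], W = sc$W[keep],
                     artist = songs$artist_unit[keep],
                     genre = songs$genre[keep],
                     stringsAsFactors = FALSE)
  m <- match(rows$year, cov_tab$year)
  rows$success <- cov_tab$success[m]
  rows$prestige <- cov_tab$prestige[m]
  rows$unbiased <- cov_tab$unbiased[m]
  if (include_rank) rows$rank <- as.numeric(songs$rank[keep])

  # rows whose window had no prestigious songs carry NA prestige: drop, log
  n_na <- sum(is.na(rows$prestige))
  rows <- rows[!is.na(rows$prestige), , drop = FALSE]
  if (nrow(rows) == 0L) stop("zero usable design rows")

  covs <- c("success", "prestige", "unbiased", if (include_rank) "rank")
  ctr <- stats::setNames(rep(0, length(covs)), covs)
  scl <- stats::setNames(rep(1, length(covs)), covs)
  if (standardize == "sample") {
    for (v in covs) {
      ctr[v] <- mean(rows[[v]])
      s <- stats::sd(rows[[v]])
      scl[v] <- if (is.finite(s) && s > 0) s else 1
      rows[[v]] <- (rows[[v]] - ctr[v]) / scl[v]
    }
  } else if (standardize == "fixed") {
    for (v in covs) {
      if (!is.null(center) && v %in% names(center)) ctr[v] <- center[[v]]
      if (!is.null(scale) && v %in% names(scale)) scl[v] <- scale[[v]]
      rows[[v]] <- (rows[[v]] - ctr[v]) / scl[v]
    }
  }
  rownames(rows) <- NULL
  structure(rows,
            class = c("design", "data.frame"),
            scaling = list(center = ctr, scale = scl, mode = standardize),
            polarity = polarity, window = as.integer(window),
            dropped = list(zero_word_songs = n_w0,
                           missing_prestige = n_na))
}

#' Write a design table and its sidecar scaling metadata
#' @param design a `design` from [build_design()].
#' @param csv_path output CSV path.
#' @param meta_path output JSON path for scaling constants and settings.
#' @export
write_design <- function(design, csv_path, meta_path = NULL) {
  utils::write.csv(as.data.frame(design), csv_path, row.names = FALSE)
  if (!is.null(meta_path)) {
    sc <- attr(design, "scaling")
    jsonlite::write_json(
      list(polarity = attr(design, "polarity"),
           window = attr(design, "window"),
           center = as.list(sc$center), scale = as.list(sc$scale),
           standardize = sc$mode,
           dropped = attr(design, "dropped")),
      meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Read back a design table written by [write_design()]
#' @param csv_path design CSV.
#' @param meta_path optional sidecar JSON.
#' @return a `design` data.frame.
#' @export
read_design <- function(csv_path, meta_path = NULL) {
  rows <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  cls <- c("design", "data.frame")
  out <- structure(rows, class = cls)
  if (!is.null(meta_path) && file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(out, "scaling") <- list(center = unlist(meta$center),
                                 scale = unlist(meta$scale),
                                 mode = meta$standardize)
    attr(out, "polarity") <- meta$polarity
    attr(out, "window") <- meta$window
  }
  out
}
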