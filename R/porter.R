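#' Porter-family stemmer
#'
#' Reduce English words to their stems with the classic Porter (1980)
#' suffix-stripping algorithm, including the two widely adopted departures
#' from the published description (\code{abli -> able} generalised to
#' \code{bli -> ble}, and \code{logi -> log}).
#'
#' The default \code{"porter"} variant adds one harmonisation rule on top of
#' the classic algorithm: words ending in \code{-ily} (length >= 5) drop the
#' trailing \code{ly} before stemming, so that adverbs stem together with
#' their adjectives ("happily", "happy" and "happiness" all become "happi").
#' The classic behaviour, which maps "happily" to "happili", is available as
#' variant \code{"porter-classic"}.
#'
#' @param words character vector of lowercase tokens.
#' @param variant \code{"porter"} (default, with the -ily rule) or
#'   \code{"porter-classic"}.
#' @return character vector of stems, same length as \code{words}.
#' @examples
#' stem_words(c("happily", "happy", "happiness"))
#' stem_words(c("loved", "loving", "loves"))
#' @export
stem_words <- function(words, variant = c("porter", "porter-classic")) {
  variant <- match.arg(variant)
  if (length(words) == 0L) return(character(0))
  uw <- unique(words)
  stems <- vapply(uw, porter_stem_one, character(1),
                  ily_rule = (variant == "porter"), USE.NAMES = FALSE)
  stems[match(words, uw)]
}

# ---- internal: single-word Porter stemmer -------------------------------

# y is a consonant at position i iff it is word-initial or preceded by a vowel
p_is_cons <- function(ch, i) {
  c <- ch[i]
  if (c %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (c == "y") {
    if (i == 1L) return(TRUE)
    return(!p_is_cons(ch, i - 1L))
  }
  TRUE
}

p_cons_mask <- function(stem) {
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n == 0L) return(logical(0))
  m <- logical(n)
  for (i in seq_len(n)) {
    c <- ch[i]
    if (c %in% c("a", "e", "i", "o", "u")) {
      m[i] <- FALSE
    } else if (c == "y") {
      m[i] <- if (i == 1L) TRUE else !m[i - 1L]
    } else {
      m[i] <- TRUE
    }
  }
  m
}

# measure m: number of VC alternations in [C](VC)^m[V]
p_measure <- function(stem) {
  m <- p_cons_mask(stem)
  if (length(m) == 0L) return(0L)
  r <- rle(m)$values
  if (length(r) > 0L && r[1]) r <- r[-1]          # drop leading C block
  if (length(r) > 0L && !r[length(r)]) r <- r[-length(r)]  # trailing V block
  length(r) %/% 2L
}

p_has_vowel <- function(stem) any(!p_cons_mask(stem))

p_double_cons <- function(stem) {
  n <- nchar(stem)
  if (n < 2L) return(FALSE)
  a <- substr(stem, n - 1L, n - 1L); b <- substr(stem, n, n)
  if (a != b) return(FALSE)
  m <- p_cons_mask(stem)
  m[n]
}

# *o: stem ends cvc where final c is not w, x or y
p_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  m <- p_cons_mask(stem)
  if (!(m[n - 2L] && !m[n - 1L] && m[n])) return(FALSE)
  !(substr(stem, n, n) %in% c("w", "x", "y"))
}

p_ends <- function(w, suf) {
  n <- nchar(w); k <- nchar(suf)
  n >= k && substr(w, n - k + 1L, n) == suf
}

p_chop <- function(w, k) substr(w, 1L, nchar(w) - k)

porter_stem_one <- function(w, ily_rule = TRUE) {
  if (nchar(w) <= 2L) return(w)
  if (grepl("[^a-z]", w)) return(w)   # digits/apostrophes: leave untouched

  # -ily adverbs stem with their -y adjectives (see ?stem_words)
  if (ily_rule && nchar(w) >= 5L && p_ends(w, "ily")) {
    w <- paste0(p_chop(w, 3L), "i")
    if (nchar(w) <= 2L) return(w)
  }

  # step 1a
  if (p_ends(w, "sses")) w <- p_chop(w, 2L)
  else if (p_ends(w, "ies")) w <- p_chop(w, 2L)
  else if (!p_ends(w, "ss") && p_ends(w, "s")) w <- p_chop(w, 1L)

  # step 1b
  step1b2 <- FALSE
  if (p_ends(w, "eed")) {
    if (p_measure(p_chop(w, 3L)) > 0L) w <- p_chop(w, 1L)
  } else if (p_ends(w, "ed")) {
    st <- p_chop(w, 2L)
    if (p_has_vowel(st)) { w <- st; step1b2 <- TRUE }
  } else if (p_ends(w, "ing")) {
    st <- p_chop(w, 3L)
    if (p_has_vowel(st)) { w <- st; step1b2 <- TRUE }
  }
  if (step1b2) {
    if (p_ends(w, "at") || p_ends(w, "bl") || p_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (p_double_cons(w) &&
               !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
      w <- p_chop(w, 1L)
    } else if (p_measure(w) == 1L && p_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c
  if (p_ends(w, "y") && p_has_vowel(p_chop(w, 1L))) {
    w <- paste0(p_chop(w, 1L), "i")
  }

  # step 2 (longest matching suffix only), m > 0
  s2 <- list(
    c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
    c("anci", "ance"), c("izer", "ize"), c("bli", "ble"), c("alli", "al"),
    c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
    c("ation", "ate"), c("ator", "ate"), c("alism", "al"),
    c("iveness", "ive"), c("fulness", "ful"), c("ousness", "ous"),
    c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble"), c("logi", "log")
  )
  w <- p_apply_rules(w, s2, min_m = 1L)

  # step 3, m > 0
  s3 <- list(
    c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
    c("ical", "ic"), c("ful", ""), c("ness", "")
  )
  w <- p_apply_rules(w, s3, min_m = 1L)

  # step 4, m > 1 (ion only after s or t)
  s4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
          "ion", "ism", "ate", "iti", "ous", "ive", "ize", "ou", "er",
          "ic", "al")
  for (suf in s4) {
    if (p_ends(w, suf)) {
      st <- p_chop(w, nchar(suf))
      ok <- p_measure(st) > 1L
      if (suf == "ion") {
        last <- if (nchar(st) > 0L) substr(st, nchar(st), nchar(st)) else ""
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) w <- st
      break
    }
  }

  # step 5a
  if (p_ends(w, "e")) {
    st <- p_chop(w, 1L)
    m <- p_measure(st)
    if (m > 1L || (m == 1L && !p_cvc(st))) w <- st
  }
  # step 5b
  if (p_measure(w) > 1L && p_double_cons(w) &&
      p_ends(w, "l")) {
    w <- p_chop(w, 1L)
  }
  w
}

p_apply_rules <- function(w, rules, min_m) {
  # longest matching suffix wins; shorter ones are not tried afterwards
  best <- NULL; best_len <- -1L
  for (r in rules) {
    if (p_ends(w, r[1]) && nchar(r[1]) > best_len) {
      best <- r; best_len <- nchar(r[1])
    }
  }
  if (is.null(best)) return(w)
  st <- p_chop(w, nchar(best[1]))
  if (p_measure(st) >= min_m) paste0(st, best[2]) else w
}

#' Tokenize raw lyric text
#'
#' Lowercases, strips punctuation and splits on whitespace. Apostrophes
#' inside words are removed ("don't" becomes "dont"); tokens containing
#' digits are kept as-is and never stemmed.
#'
#' @param text character scalar (may be empty or NA).
#' @return character vector of tokens (possibly empty).
#' @export
tokenize <- function(text) {
  if (length(text) != 1L) stop("tokenize() expects a single string")
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  x <- gsub("'", "", x, fixed = TRUE)
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), " +")[[1]]
  toks[nzchar(toks)]
}

#' Tokenize and stem lyric text into a bag of stem counts
#'
#' @param text raw lyric text (single string).
#' @param variant stemmer variant passed to [stem_words()].
#' @return named integer vector: stem -> count. Empty text gives an empty
#'   bag (length-0 named integer vector).
#' @examples
#' tokenize_and_stem("Happily hating")
#' @export
tokenize_and_stem <- function(text, variant = "porter") {
  toks <- tokenize(text)
  if (length(toks) == 0L) {
    return(structure(integer(0), names = character(0)))
  }
  stems <- stem_words(toks, variant = variant)
  tab <- table(stems)
  structure(as.integer(tab), names = names(tab))
}
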