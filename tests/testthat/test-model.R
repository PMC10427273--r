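make_flat_design <- function(n = 20, W = 10, k = NULL, seed = 1) {
  set.seed(seed)
  data.frame(song_id = paste0("s", seq_len(n)), year = 2000L,
             k = if (is.null(k)) rbinom(n, W, 0.4) else k,
             W = W, artist = "a", genre = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("log_likelihood matches closed forms", {
  rows <- data.frame(k = 0, W = 10, artist = "a", genre = NA, year = 2000)
  ll <- log_likelihood(list(alpha = 0, beta = NULL), rows)
  expect_equal(ll, 10 * log(0.5))
  # p = 0 with k > 0 gives -Inf, never an error
  rows2 <- data.frame(k = 3, W = 10, artist = "a", genre = NA, year = 2000)
  expect_identical(log_likelihood(list(alpha = -Inf, beta = NULL), rows2),
                   -Inf)
  expect_identical(log_likelihood(list(alpha = -Inf, beta = NULL), rows),
                   0)   # k = 0 at p = 0 is certain
})

test_that("aggregated likelihood = Bernoulli sum + binomial coefficient", {
  set.seed(2)
  for (i in 1:20) {
    W <- sample(2:30, 1); k <- sample(0:W, 1)
    eta <- rnorm(1); p <- plogis(eta)
    rows <- data.frame(k = k, W = W, x = 1, artist = "a", genre = NA,
                       year = 2000)
    agg <- log_likelihood(list(alpha = eta, beta = NULL), rows)
    bern <- k * log(p) + (W - k) * log(1 - p)
    expect_equal(agg, bern + lchoose(W, k))
  }
})

test_that("log_likelihood matches a brute-force per-row loop", {
  set.seed(3)
  n <- 30
  rows <- data.frame(k = rbinom(n, 20, 0.3), W = 20,
                     x1 = rnorm(n), x2 = rnorm(n),
                     artist = sample(c("a", "b"), n, TRUE),
                     genre = sample(c("g1", "g2"), n, TRUE),
                     year = sample(2000:2001, n, TRUE))
  params <- list(alpha = -0.5, beta = c(x1 = 0.3, x2 = -0.2),
                 a_artist = c(a = 0.1, b = -0.1),
                 a_genre = c(g1 = 0.05, g2 = -0.05),
                 a_year = c("2000" = 0.2, "2001" = -0.2))
  got <- log_likelihood(params, rows)
  for (i in seq_len(n)) {
    eta <- -0.5 + 0.3 * rows$x1[i] - 0.2 * rows$x2[i] +
      params$a_artist[[rows$artist[i]]] +
      params$a_genre[[rows$genre[i]]] +
      params$a_year[[as.character(rows$year[i])]]
    expect_equal(got[i], dbinom(rows$k[i], rows$W[i], plogis(eta),
                                log = TRUE))
  }
})

test_that("log_prior closed forms and shape", {
  spec <- model_spec("positive")
  p0 <- list(alpha = 0, beta = c(success = 0))
  expect_equal(log_prior(p0, spec),
               dnorm(0, 0, 1.5, log = TRUE) + dnorm(0, 0, 1, log = TRUE))
  p1 <- list(alpha = 0, beta = c(success = 0.5))
  p2 <- list(alpha = 0, beta = c(success = 1.0))
  expect_gt(log_prior(p1, spec), log_prior(p2, spec))
  # sigma <= 0 is impossible
  p3 <- list(alpha = 0, beta = NULL, a_artist = c(a = 0.1),
             sigma = list(artist = -1))
  expect_identical(log_prior(p3, spec), -Inf)
})

test_that("prior density integrates to 1 on a 2-parameter toy spec", {
  spec <- model_spec("positive")
  f <- Vectorize(function(a, b) {
    exp(log_prior(list(alpha = a, beta = c(success = b)), spec))
  })
  inner <- Vectorize(function(a) {
    integrate(function(b) f(a, b), -8, 8)$value
  })
  total <- integrate(inner, -12, 12)$value
  expect_equal(total, 1, tolerance = 1e-4)
})

test_that("splitting a row changes the likelihood only by a constant", {
  rows1 <- data.frame(k = 7, W = 20, x = 0.4, artist = "a", genre = NA,
                      year = 2000)
  rows2 <- data.frame(k = c(3, 4), W = c(8, 12), x = 0.4, artist = "a",
                      genre = NA, year = 2000)
  const <- NULL
  for (alpha in c(-1, 0, 0.7)) {
    for (b in c(-0.5, 0.2)) {
      p <- list(alpha = alpha, beta = c(x = b))
      diff <- sum(log_likelihood(p, rows2)) - sum(log_likelihood(p, rows1))
      if (is.null(const)) const <- diff
      expect_equal(diff, const)
    }
  }
  expect_equal(const, lchoose(8, 3) + lchoose(12, 4) - lchoose(20, 7))
})

test_that("with flat groups and no slopes the MLE of p is sum(k)/sum(W)", {
  rows <- make_flat_design(n = 40, W = 25, seed = 4)
  phat <- sum(rows$k) / sum(rows$W)
  # the score in alpha vanishes at logit(phat): sum(k - W p) = 0
  eps <- 1e-6
  ll <- function(a) sum(log_likelihood(list(alpha = a, beta = NULL), rows))
  score <- (ll(qlogis(phat) + eps) - ll(qlogis(phat) - eps)) / (2 * eps)
  expect_equal(score, 0, tolerance = 1e-4)
  expect_lt(ll(qlogis(phat) + 0.1), ll(qlogis(phat)))
})

test_that("summarize_fit interval bounds equal sorted-draw order statistics", {
  set.seed(9)
  draws <- cbind(alpha = rnorm(500), b_success = rnorm(500, 2, 0.5),
                 sigma_artist = rexp(500))
  fake <- structure(list(draws = draws), class = "bias_fit")
  s <- summarize_fit(fake, ci_mass = 0.89)
  for (p in colnames(draws)) {
    q <- quantile(draws[, p], c(0.055, 0.945), type = 7)
    row <- s[s$parameter == p, ]
    expect_equal(row$lower, unname(q[1]))
    expect_equal(row$upper, unname(q[2]))
  }
  expect_false(s$excludes_zero[s$parameter == "alpha"])
  expect_true(s$excludes_zero[s$parameter == "b_success"])
})

test_that("odds interpretation is 100*(exp(beta)-1)", {
  expect_equal(odds_interpretation(0.04), 100 * (exp(0.04) - 1))
  expect_equal(round(odds_interpretation(0.04)), 4)
  expect_equal(odds_interpretation(0), 0)
  expect_equal(odds_interpretation(-0.02), 100 * (exp(-0.02) - 1))
  expect_equal(odds_interpretation(-0.02), -1.9801327, tolerance = 1e-6)
})

test_that("compiled posterior gradient matches the R reference and finite differences", {
  set.seed(19)
  n <- 120
  design <- data.frame(song_id = paste0("s", 1:n),
                       year = rep(2000:2003, n / 4),
                       k = rbinom(n, 40, 0.15), W = 40,
                       success = rnorm(n), unbiased = rnorm(n),
                       artist = sample(letters[1:15], n, TRUE),
                       genre = sample(c("g1", "g2", "g3"), n, TRUE))
  spec <- model_spec("negative", effects = c("success", "unbiased"))
  for (centering in c("auto", "centered", "non-centered")) {
    spec$centering <- centering
    ctx <- lyricbias:::build_model_context(design, spec)
    P <- length(lyricbias:::param_layout(ctx))
    for (i in 1:5) {
      th <- rnorm(P, 0, 0.6)
      a <- lyricbias:::lp_grad(th, ctx)
      b <- lyricbias:::lp_grad_r(th, ctx)
      expect_equal(a$lp, b$lp, tolerance = 1e-10)
      expect_equal(a$grad, b$grad, tolerance = 1e-8)
    }
    th <- rnorm(P, 0, 0.4)
    lg <- lyricbias:::lp_grad(th, ctx)
    for (j in sample(P, 6)) {
      e <- 1e-5
      tp <- th; tp[j] <- tp[j] + e
      tm <- th; tm[j] <- tm[j] - e
      num <- (lyricbias:::lp_grad(tp, ctx)$lp -
                lyricbias:::lp_grad(tm, ctx)$lp) / (2 * e)
      expect_equal(lg$grad[j], num, tolerance = 1e-4)
    }
  }
})

test_that("the sampler is reproducible given a seed", {
  rows <- make_flat_design(n = 30, W = 15, seed = 6)
  rows$artist <- rep(c("a", "b", "c"), 10)
  spec <- model_spec("positive", groups = "artist", chains = 2L,
                     iter = 120L, warmup = 120L)
  f1 <- quiet_fit(spec, rows, seed = 99L)
  f2 <- quiet_fit(spec, rows, seed = 99L)
  expect_identical(f1$draws, f2$draws)
  f3 <- quiet_fit(spec, rows, seed = 100L)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("intercept-only posterior concentrates on the empirical rate", {
  set.seed(12)
  n <- 150L; W <- 60; q <- 0.3
  rows <- data.frame(song_id = paste0("s", 1:n), year = rep(2000:2004, n / 5),
                     k = rbinom(n, W, q), W = W,
                     artist = rep(letters[1:10], n / 10),
                     genre = NA_character_)
  spec <- model_spec("positive", chains = 2L, iter = 250L, warmup = 250L)
  f <- quiet_fit(spec, rows, seed = 5L)
  phat <- sum(rows$k) / sum(rows$W)
  expect_equal(mean(plogis(f$draws[, "alpha"])), phat, tolerance = 0.02)
  # genre was all-missing, so it must have been dropped
  expect_false(any(grepl("genre", colnames(f$draws))))
  # pointwise log-likelihood has draws x rows shape
  expect_identical(dim(f$loglik), c(2L * 250L, n))
})

test_that("a well-identified song-level slope is recovered", {
  set.seed(13)
  n <- 400; W <- 80
  x <- rnorm(n)
  artist <- sample(letters[1:8], n, TRUE)
  a_art <- setNames(rnorm(8, 0, 0.2), letters[1:8])
  eta <- -1.2 + 0.35 * x + a_art[artist]
  rows <- data.frame(song_id = paste0("s", 1:n),
                     year = rep(2000:2007, each = n / 8),
                     k = rbinom(n, W, plogis(eta)), W = W,
                     x = x, artist = artist, genre = NA_character_)
  spec <- model_spec("positive", effects = character(0),
                     chains = 2L, iter = 250L, warmup = 250L)
  spec$effects <- "x"   # song-level covariate under the same machinery
  f <- quiet_fit(spec, rows, seed = 14L)
  s <- summarize_fit(f)
  b <- s[s$parameter == "b_x", ]
  expect_gt(b$upper, 0.35 - 0.15)
  expect_lt(b$lower, 0.35 + 0.15)
  expect_lt(abs(b$mean - 0.35), 0.12)
})

test_that("degenerate designs fail loudly", {
  rows <- make_flat_design(n = 20, W = 10, seed = 7)
  rows$success <- 1.0   # constant covariate
  spec <- model_spec("positive", effects = "success", chains = 1L,
                     iter = 120L, warmup = 120L)
  expect_error(quiet_fit(spec, rows, seed = 1L), "constant covariate")
  spec2 <- model_spec("positive", groups = "artist", chains = 1L,
                      iter = 120L, warmup = 120L)
  expect_error(quiet_fit(spec2, rows, seed = 1L), "fewer than 2 levels")
})

test_that("model_spec validates inputs", {
  expect_error(model_spec("positive", effects = "fame"), "unknown effects")
  expect_error(model_spec("positive", groups = "label"), "unknown groups")
  ms <- standard_model_set("negative", has_rank = TRUE)
  expect_named(ms, c("null", "success", "prestige", "content", "full",
                     "full_unbiased"))
  expect_setequal(ms$full_unbiased,
                  c("success", "prestige", "rank", "unbiased"))
  ms_pos <- standard_model_set("positive", has_rank = TRUE)
  expect_false("content" %in% names(ms_pos))
  expect_false("rank" %in% ms_pos$full)
})
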