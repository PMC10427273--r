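#' Model specification for the aggregated binomial multilevel model
#'
#' Each word of a song is modelled as a Bernoulli trial of being positive
#' (or negative); words are aggregated within songs, so song i contributes
#' k_i successes out of W_i trials with
#' \deqn{logit(p_i) = \alpha + a_{artist[i]} + a_{genre[i]} + a_{year[i]} +
#'   \sum_j \beta_j x_{ij}}
#' Group intercepts get adaptively regularising priors
#' a_g ~ Normal(0, sigma_g), sigma_g ~ Exponential(1); the global intercept
#' alpha ~ Normal(0, 1.5) and slopes beta ~ Normal(0, 1) are weakly
#' regularising on the log-odds scale.
#'
#' @param polarity `"positive"` or `"negative"`.
#' @param effects subset of `c("success", "prestige", "unbiased", "rank")`.
#' @param groups subset of `c("artist", "genre", "year")`; factors absent
#'   from the design (e.g. genre in chart data) are dropped automatically
#'   at fitting time.
#' @param priors list with elements `alpha = c(location, scale)`,
#'   `beta = c(location, scale)`, `sigma_rate` (Exponential rate for the
#'   group sds).
#' @param chains,iter,warmup sampler settings (post-warmup draws per chain
#'   = `iter`).
#' @param l_range inclusive range of leapfrog steps per trajectory (drawn
#'   uniformly each iteration); the default 24-48 is long enough to
#'   traverse the intercept-versus-group-mean ridge these models have.
#' @param centering `"auto"` (default) parameterises data-rich grouping
#'   factors (many observations per level, e.g. year and genre) in centred
#'   form and sparse ones (e.g. artists, mostly one or two songs each) in
#'   non-centred form — the standard reparameterisation needed for
#'   convergence in these hierarchies; `"non-centered"` or `"centered"`
#'   force one form for all factors.
#' @return a `model_spec`.
#' @export
model_spec <- function(polarity = c("positive", "negative"),
                       effects = character(0),
                       groups = c("artist", "genre", "year"),
                       priors = list(alpha = c(0, 1.5), beta = c(0, 1),
                                     sigma_rate = 1),
                       chains = 4L, iter = 1000L, warmup = 500L,
                       centering = c("auto", "non-centered", "centered"),
                       l_range = c(24L, 48L)) {
  centering <- match.arg(centering)
  stopifnot(length(l_range) == 2L, l_range[1] >= 1L,
            l_range[2] >= l_range[1])
  polarity <- match.arg(polarity)
  bad <- setdiff(effects, c("success", "prestige", "unbiased", "rank"))
  if (length(bad) > 0L) stop("unknown effects: ", paste(bad, collapse = ", "))
  bad <- setdiff(groups, c("artist", "genre", "year"))
  if (length(bad) > 0L) stop("unknown groups: ", paste(bad, collapse = ", "))
  structure(list(polarity = polarity, effects = effects, groups = groups,
                 priors = priors, chains = as.integer(chains),
                 iter = as.integer(iter), warmup = as.integer(warmup),
                 centering = centering,
                 l_range = as.integer(l_range)),
            class = "model_spec")
}

# ---- design -> numeric context ------------------------------------------

build_model_context <- function(design, spec) {
  n <- nrow(design)
  if (n == 0L) stop("empty design")
  for (v in spec$effects) {
    if (!v %in% names(design)) stop("design lacks effect column: ", v)
    if (!all(is.finite(design[[v]]))) stop("non-finite covariate: ", v)
    if (stats::sd(design[[v]]) == 0) {
      stop("degenerate design: constant covariate '", v, "'")
    }
  }
  X <- if (length(spec$effects)) {
    as.matrix(design[spec$effects])
  } else {
    matrix(numeric(0), nrow = n, ncol = 0)
  }
  storage.mode(X) <- "double"
  groups <- list()
  for (g in spec$groups) {
    col <- design[[g]]
    if (g == "genre" && (is.null(col) || all(is.na(col)))) next  # chart case
    if (is.null(col)) next
    col <- as.character(col)
    col[is.na(col)] <- "(none)"
    lev <- sort(unique(col))
    cmode <- if (is.null(spec$centering)) "auto" else spec$centering
    cent <- switch(cmode, "centered" = TRUE, "non-centered" = FALSE,
                   n / length(lev) > 20)   # auto: centred when data-rich
    groups[[g]] <- list(idx = match(col, lev), levels = lev,
                        n_levels = length(lev), centered = cent)
  }
  ctx <- list(k = as.numeric(design$k), W = as.numeric(design$W), X = X,
              groups = groups, n = n, spec = spec)
  ctx$cpp <- list(
    k = ctx$k, W = ctx$W, X = X,
    group_idx = lapply(groups, function(g) as.integer(g$idx)),
    group_sizes = vapply(groups, function(g) as.integer(g$n_levels),
                         integer(1), USE.NAMES = FALSE),
    centered = vapply(groups, function(g) isTRUE(g$centered), logical(1),
                      USE.NAMES = FALSE),
    prior_alpha = as.numeric(spec$priors$alpha),
    prior_beta = as.numeric(spec$priors$beta),
    sigma_rate = as.numeric(spec$priors$sigma_rate),
    lchoose_sum = sum(lchoose(ctx$W, ctx$k)))
  if (length(groups) == 0L) ctx$cpp$group_sizes <- integer(0)
  ctx
}

param_layout <- function(ctx) {
  p_eff <- ncol(ctx$X)
  nm <- c("alpha",
          if (p_eff) paste0("b_", colnames(ctx$X)))
  for (g in names(ctx$groups)) {
    pre <- if (isTRUE(ctx$groups[[g]]$centered)) "a_" else "z_"
    nm <- c(nm, paste0(pre, g, "[", seq_len(ctx$groups[[g]]$n_levels), "]"))
  }
  nm <- c(nm, if (length(ctx$groups)) paste0("log_sigma_", names(ctx$groups)))
  nm
}

unpack_params <- function(theta, ctx) {
  p_eff <- ncol(ctx$X)
  pos <- 1L
  alpha <- theta[pos]; pos <- pos + 1L
  beta <- if (p_eff) theta[pos:(pos + p_eff - 1L)] else numeric(0)
  pos <- pos + p_eff
  z <- list()
  for (g in names(ctx$groups)) {
    L <- ctx$groups[[g]]$n_levels
    z[[g]] <- theta[pos:(pos + L - 1L)]; pos <- pos + L
  }
  ls <- stats::setNames(numeric(length(ctx$groups)), names(ctx$groups))
  for (g in names(ctx$groups)) { ls[g] <- theta[pos]; pos <- pos + 1L }
  list(alpha = alpha, beta = beta, z = z, log_sigma = ls)
}

linpred <- function(pp, ctx) {
  eta <- rep(pp$alpha, ctx$n)
  if (ncol(ctx$X)) eta <- eta + drop(ctx$X %*% pp$beta)
  for (g in names(ctx$groups)) {
    scale <- if (isTRUE(ctx$groups[[g]]$centered)) 1 else
      exp(pp$log_sigma[g])
    eta <- eta + scale * pp$z[[g]][ctx$groups[[g]]$idx]
  }
  eta
}

# joint log density of the non-centred parameterisation with its gradient;
# sigma is sampled on the log scale (Jacobian included). The hot path is
# compiled (src/lp_grad.cpp); lp_grad_r() is the independent reference
# implementation the tests cross-check against.
lp_grad <- function(theta, ctx) {
  .lp_grad_cpp(theta, ctx$cpp)
}

lp_grad_r <- function(theta, ctx) {
  pp <- unpack_params(theta, ctx)
  pr <- ctx$spec$priors
  eta <- linpred(pp, ctx)
  p <- stats::plogis(eta)
  ll <- sum(stats::dbinom(ctx$k, ctx$W, p, log = TRUE))
  lp <- ll -
    (pp$alpha - pr$alpha[1])^2 / (2 * pr$alpha[2]^2) -
    sum((pp$beta - pr$beta[1])^2) / (2 * pr$beta[2]^2)
  d_eta <- ctx$k - ctx$W * p
  g_alpha <- sum(d_eta) - (pp$alpha - pr$alpha[1]) / pr$alpha[2]^2
  g_beta <- if (ncol(ctx$X)) {
    drop(crossprod(ctx$X, d_eta)) - (pp$beta - pr$beta[1]) / pr$beta[2]^2
  } else numeric(0)
  g_z <- list(); g_ls <- stats::setNames(numeric(length(ctx$groups)),
                                         names(ctx$groups))
  for (g in names(ctx$groups)) {
    gi <- ctx$groups[[g]]
    sig <- exp(pp$log_sigma[g])
    s_de <- drop(rowsum(d_eta, gi$idx, reorder = TRUE))
    if (isTRUE(gi$centered)) {
      a <- pp$z[[g]]
      lp <- lp - sum(a^2) / (2 * sig^2) - gi$n_levels * pp$log_sigma[g] -
        pr$sigma_rate * sig + pp$log_sigma[g]
      g_z[[g]] <- s_de - a / sig^2
      g_ls[g] <- sum(a^2) / sig^2 - gi$n_levels - pr$sigma_rate * sig + 1
    } else {
      lp <- lp - sum(pp$z[[g]]^2) / 2 - pr$sigma_rate * sig +
        pp$log_sigma[g]
      g_z[[g]] <- sig * s_de - pp$z[[g]]
      g_ls[g] <- sig * sum(pp$z[[g]] * s_de) - pr$sigma_rate * sig + 1
    }
  }
  grad <- c(g_alpha, g_beta, unlist(g_z, use.names = FALSE), g_ls)
  list(lp = unname(lp), grad = unname(grad))
}

# ---- exported likelihood / prior (user-facing building blocks) ----------

#' Per-row aggregated binomial log-likelihood
#'
#' @param params list with elements `alpha` (scalar), `beta` (named vector,
#'   names matching effect columns of `rows`), and optionally `a_artist`,
#'   `a_genre`, `a_year` (named by group level).
#' @param rows a design data.frame with columns k, W, the effect columns
#'   named in `params$beta`, and artist/genre/year columns for any group
#'   effects supplied.
#' @return numeric vector of per-row log-likelihoods, including the
#'   binomial coefficient term; rows with probability exactly 0 or 1 and an
#'   incompatible count get `-Inf`, never an error.
#' @export
log_likelihood <- function(params, rows) {
  n <- nrow(rows)
  eta <- rep(params$alpha, n)
  for (v in names(params$beta)) {
    eta <- eta + params$beta[[v]] * rows[[v]]
  }
  for (g in c("artist", "genre", "year")) {
    a <- params[[paste0("a_", g)]]
    if (!is.null(a)) {
      lev <- as.character(rows[[g]])
      eff <- a[lev]
      eff[is.na(eff)] <- 0
      eta <- eta + unname(eff)
    }
  }
  stats::dbinom(rows$k, rows$W, stats::plogis(eta), log = TRUE)
}

#' Joint log prior of the model parameters
#'
#' Normal(0, 1.5) for the intercept, Normal(0, 1) for slopes, Normal(0,
#' sigma_g) for group intercepts and Exponential(1) for each group sd
#' (defaults; overridable through the spec priors).
#'
#' @param params list as in [log_likelihood()] plus `sigma` (named vector
#'   of group sds).
#' @param spec a [model_spec()].
#' @return scalar log prior density (including normalising constants);
#'   `-Inf` if any sigma is not positive.
#' @export
log_prior <- function(params, spec = model_spec()) {
  pr <- spec$priors
  lp <- stats::dnorm(params$alpha, pr$alpha[1], pr$alpha[2], log = TRUE)
  if (length(params$beta)) {
    lp <- lp + sum(stats::dnorm(unlist(params$beta), pr$beta[1], pr$beta[2],
                                log = TRUE))
  }
  for (g in c("artist", "genre", "year")) {
    a <- params[[paste0("a_", g)]]
    if (is.null(a)) next
    sig <- params$sigma[[g]]
    if (is.null(sig) || !is.finite(sig) || sig <= 0) return(-Inf)
    lp <- lp + sum(stats::dnorm(a, 0, sig, log = TRUE)) +
      stats::dexp(sig, pr$sigma_rate, log = TRUE)
  }
  lp
}

# ---- Hamiltonian Monte Carlo --------------------------------------------

leapfrog <- function(theta, r, eps, inv_mass, ctx, grad) {
  r <- r + 0.5 * eps * grad
  theta <- theta + eps * inv_mass * r
  lg <- lp_grad(theta, ctx)
  r <- r + 0.5 * eps * lg$grad
  list(theta = theta, r = r, lp = lg$lp, grad = lg$grad)
}

find_initial_eps <- function(theta, ctx, inv_mass) {
  eps <- 0.1
  lg <- lp_grad(theta, ctx)
  r <- stats::rnorm(length(theta)) / sqrt(inv_mass)
  h0 <- lg$lp - 0.5 * sum(inv_mass * r^2)
  st <- leapfrog(theta, r, eps, inv_mass, ctx, lg$grad)
  h1 <- st$lp - 0.5 * sum(inv_mass * st$r^2)
  if (!is.finite(h1)) { a <- -1 } else { a <- if (h1 - h0 > log(0.5)) 1 else -1 }
  for (i in 1:50) {
    eps <- eps * 2^a
    st <- leapfrog(theta, r, eps, inv_mass, ctx, lg$grad)
    h1 <- st$lp - 0.5 * sum(inv_mass * st$r^2)
    ok <- is.finite(h1) && a * (h1 - h0) > a * log(0.5)
    if (!ok) break
  }
  eps
}

hmc_chain <- function(ctx, init, n_warmup, n_iter, seed,
                      target_accept = 0.85, l_range = c(24L, 48L)) {
  set.seed(seed)
  P <- length(init)
  theta <- init
  inv_mass <- rep(1, P)
  eps <- find_initial_eps(theta, ctx, inv_mass)
  mu <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  adapt_count <- 0L
  win_lo <- floor(n_warmup * 0.25); win_hi <- floor(n_warmup * 0.75)
  win_draws <- matrix(NA_real_, nrow = max(win_hi - win_lo, 1L), ncol = P)
  draws <- matrix(NA_real_, nrow = n_iter, ncol = P)
  accept <- 0
  log_eps_hist <- numeric(n_warmup)
  reject_streak <- 0L; rescues <- 0L
  lg <- lp_grad(theta, ctx)
  total <- n_warmup + n_iter
  for (it in seq_len(total)) {
    r0 <- stats::rnorm(P) / sqrt(inv_mass)
    L <- sample(l_range[1]:l_range[2], 1L)
    st <- list(theta = theta, r = r0, lp = lg$lp, grad = lg$grad)
    h0 <- lg$lp - 0.5 * sum(inv_mass * r0^2)
    diverged <- FALSE
    for (l in seq_len(L)) {
      st <- leapfrog(st$theta, st$r, eps, inv_mass, ctx, st$grad)
      if (!is.finite(st$lp)) { diverged <- TRUE; break }
    }
    h1 <- if (diverged) -Inf else st$lp - 0.5 * sum(inv_mass * st$r^2)
    a_prob <- min(1, exp(h1 - h0))
    if (!is.finite(a_prob)) a_prob <- 0
    if (stats::runif(1) < a_prob) {
      theta <- st$theta
      lg <- list(lp = st$lp, grad = st$grad)
    }
    if (it <= n_warmup) {
      adapt_count <- adapt_count + 1L
      h_bar <- (1 - 1 / (adapt_count + t0)) * h_bar +
        (target_accept - a_prob) / (adapt_count + t0)
      log_eps <- mu - sqrt(adapt_count) / gamma * h_bar
      w <- adapt_count^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      log_eps_hist[it] <- log_eps
      if (it > win_lo && it <= win_hi) {
        win_draws[it - win_lo, ] <- theta
      }
      if (it == win_hi && win_hi > win_lo + 10L) {
        v <- apply(win_draws[seq_len(it - win_lo), , drop = FALSE], 2,
                   stats::var)
        v[!is.finite(v) | v <= 0] <- 1e-6
        # shrink noisy per-coordinate estimates toward their median: with
        # ~10^3 coordinates and a few hundred warmup draws the raw
        # variances are unstable
        v <- 0.8 * v + 0.2 * stats::median(v)
        inv_mass <- v   # kinetic T = r' M^-1 r / 2 with M^-1 = posterior var
        eps <- find_initial_eps(theta, ctx, inv_mass)
        mu <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0; adapt_count <- 0L
      }
      if (it == n_warmup) {
        # freeze eps where adaptation settled: the tail of warmup, not the
        # whole dual-averaging history (the posterior gets stiffer as the
        # chain descends the sigma funnel, so early values overshoot)
        tail_n <- max(25L, floor(n_warmup * 0.1))
        eps <- 0.9 * exp(mean(log_eps_hist[(n_warmup - tail_n + 1L):n_warmup]))
      }
    } else {
      draws[it - n_warmup, ] <- theta
      accept <- accept + a_prob
      # emergency valve: a frozen chain (every trajectory divergent) is
      # worse than a rare capped step-size adjustment
      reject_streak <- if (a_prob < 0.01) reject_streak + 1L else 0L
      if (reject_streak >= 25L && rescues < 3L) {
        eps <- eps / 2
        rescues <- rescues + 1L
        reject_streak <- 0L
      }
    }
  }
  list(draws = draws, accept_rate = accept / n_iter, eps = eps,
       rescues = rescues)
}

# ---- convergence diagnostics --------------------------------------------

split_chain_stats <- function(chain_list) {
  # split each chain in half, then compute the standard potential scale
  # reduction factor and a Geyer initial-monotone effective sample size
  halves <- list()
  for (ch in chain_list) {
    n <- length(ch)
    h <- n %/% 2L
    halves <- c(halves, list(ch[seq_len(h)], ch[(n - h + 1L):n]))
  }
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  var_plus <- (n - 1) / n * W + B / n
  if (W <= 0 || !is.finite(W)) {
    # degenerate (frozen) chains: flag rather than crash or mask
    return(c(rhat = if (B > 0) Inf else 1, ess = 1))
  }
  rhat <- sqrt(var_plus / W)
  # combined-chain autocorrelation ESS
  rho_sum <- 0
  max_lag <- min(n - 1L, 200L)
  rho <- rep(0, max_lag)
  for (ch in halves) {
    ac <- stats::acf(ch, lag.max = max_lag, plot = FALSE,
                     demean = TRUE)$acf[-1]
    rho <- rho + vars_weight(ch) * ac
  }
  rho <- rho / sum(vapply(halves, vars_weight, numeric(1)))
  if (var_plus > 0) rho <- 1 - (W - W * rho) / var_plus
  # Geyer initial positive, monotone sequence on paired sums
  pair <- rho[seq(1, max_lag - 1, by = 2)] + rho[seq(2, max_lag, by = 2)]
  cum <- 0; prev <- Inf
  for (p in pair) {
    if (!is.finite(p)) break
    p <- min(p, prev)
    if (p < 0) break
    cum <- cum + p
    prev <- p
  }
  ess <- m * n / (1 + 2 * cum)
  c(rhat = rhat, ess = max(min(ess, m * n), 1))
}

vars_weight <- function(ch) stats::var(ch)

#' Fit the aggregated binomial multilevel model
#'
#' Posterior sampling by Hamiltonian Monte Carlo with a diagonal mass
#' matrix adapted during warmup, dual-averaging step-size adaptation, and a
#' non-centred parameterisation of the group intercepts (the standard cure
#' for the funnel geometries these hierarchies produce). Group sds are
#' sampled on the log scale with the Jacobian included.
#'
#' @param spec a [model_spec()].
#' @param design a design data.frame from [build_design()] (columns k, W,
#'   effect columns, artist/genre/year).
#' @param seed integer seed; the same seed reproduces the draws exactly.
#' @return a `bias_fit`: list with `draws` (total draws x parameters, with
#'   `sigma_*` columns on the natural scale and group intercepts
#'   `a_<group>[level]`), `loglik` (draws x rows pointwise log-likelihood,
#'   binomial coefficient included), `diagnostics` (rhat/ess per
#'   parameter), `accept_rate`, `spec`, `seed`, `par_names`.
#' @export
fit_model <- function(spec, design, seed = 1L) {
  ctx <- build_model_context(design, spec)
  for (g in names(ctx$groups)) {
    if (ctx$groups[[g]]$n_levels < 2L) {
      stop("grouping factor '", g, "' has fewer than 2 levels")
    }
  }
  nm <- param_layout(ctx)
  P <- length(nm)
  set.seed(seed)
  chain_seeds <- (as.integer(seed) * 7L + 13L * seq_len(spec$chains)) %% 2147483629L
  chains <- vector("list", spec$chains)
  for (c in seq_len(spec$chains)) {
    init <- stats::rnorm(P, 0, 0.1)
    init[startsWith(nm, "log_sigma")] <- log(0.5)
    lg0 <- lp_grad(init, ctx)
    if (!is.finite(lg0$lp) || !all(is.finite(lg0$grad))) {
      stop("non-finite log posterior at initialization")
    }
    l_range <- if (is.null(spec$l_range)) c(24L, 48L) else spec$l_range
    chains[[c]] <- hmc_chain(ctx, init, spec$warmup, spec$iter,
                             seed = chain_seeds[c], l_range = l_range)
  }
  raw <- lapply(chains, `[[`, "draws")
  diag_tab <- t(vapply(seq_len(P), function(j) {
    split_chain_stats(lapply(raw, function(d) d[, j]))
  }, c(rhat = 0, ess = 0)))
  diagnostics <- data.frame(parameter = nm, rhat = diag_tab[, "rhat"],
                            ess = diag_tab[, "ess"])
  if (any(diagnostics$rhat > 1.01, na.rm = TRUE)) {
    warning("convergence: some Rhat > 1.01 (max = ",
            round(max(diagnostics$rhat, na.rm = TRUE), 3), ")")
  }
  if (any(diagnostics$ess < 400, na.rm = TRUE)) {
    warning("convergence: some effective sample sizes < 400 (min = ",
            round(min(diagnostics$ess, na.rm = TRUE)), ")")
  }
  all_draws <- do.call(rbind, raw)
  colnames(all_draws) <- nm
  # natural-scale draws: sigma_g and centred group intercepts a_g = sigma*z
  nat <- all_draws
  for (g in names(ctx$groups)) {
    sig <- exp(all_draws[, paste0("log_sigma_", g)])
    if (isTRUE(ctx$groups[[g]]$centered)) {
      ac <- startsWith(nm, paste0("a_", g, "["))
      colnames(nat)[which(ac)] <-
        paste0("a_", g, "[", ctx$groups[[g]]$levels, "]")
    } else {
      zc <- startsWith(nm, paste0("z_", g, "["))
      nat[, zc] <- all_draws[, zc, drop = FALSE] * sig
      colnames(nat)[which(zc)] <-
        paste0("a_", g, "[", ctx$groups[[g]]$levels, "]")
    }
    nat[, paste0("log_sigma_", g)] <- sig
    colnames(nat)[match(paste0("log_sigma_", g), colnames(nat))] <-
      paste0("sigma_", g)
  }
  loglik <- pointwise_loglik(all_draws, ctx)
  structure(list(draws = nat, raw_draws = all_draws, loglik = loglik,
                 diagnostics = diagnostics,
                 accept_rate = vapply(chains, `[[`, numeric(1), "accept_rate"),
                 spec = spec, seed = seed, par_names = colnames(nat),
                 n_chains = spec$chains, n_iter = spec$iter,
                 groups = lapply(ctx$groups, `[[`, "levels")),
            class = "bias_fit")
}

pointwise_loglik <- function(draws, ctx) {
  D <- nrow(draws)
  ETA <- matrix(draws[, "alpha"], nrow = ctx$n, ncol = D, byrow = TRUE)
  if (ncol(ctx$X)) {
    bcols <- paste0("b_", colnames(ctx$X))
    ETA <- ETA + ctx$X %*% t(draws[, bcols, drop = FALSE])
  }
  for (g in names(ctx$groups)) {
    if (isTRUE(ctx$groups[[g]]$centered)) {
      ac <- paste0("a_", g, "[", seq_len(ctx$groups[[g]]$n_levels), "]")
      A <- t(draws[, ac, drop = FALSE])
    } else {
      zc <- paste0("z_", g, "[", seq_len(ctx$groups[[g]]$n_levels), "]")
      A <- t(draws[, zc, drop = FALSE] *
               exp(draws[, paste0("log_sigma_", g)]))
    }
    ETA <- ETA + A[ctx$groups[[g]]$idx, , drop = FALSE]
  }
  LL <- stats::dbinom(ctx$k, ctx$W, stats::plogis(ETA), log = TRUE)
  t(LL)   # draws x rows
}

#' @export
print.bias_fit <- function(x, ...) {
  cat(sprintf("<bias_fit> %s polarity, %d chains x %d draws, %d parameters\n",
              x$spec$polarity, x$n_chains, x$n_iter, ncol(x$draws)))
  cat(sprintf("  max Rhat %.3f, min ESS %.0f, mean accept %.2f\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess),
              mean(x$accept_rate)))
  print(summarize_fit(x))
  invisible(x)
}

#' Posterior summaries with equal-tailed credible intervals
#'
#' @param fit a `bias_fit`.
#' @param ci_mass credible mass (default 0.89, the conventional default for
#'   this literature's reporting style).
#' @param params which parameters to summarise; default: intercept, slopes
#'   and group sds (not the per-level intercepts).
#' @return data.frame: parameter, mean, lower, upper, excludes_zero.
#' @export
summarize_fit <- function(fit, ci_mass = 0.89, params = NULL) {
  if (nrow(fit$draws) < 100L) stop("need at least 100 draws to summarise")
  nm <- colnames(fit$draws)
  if (is.null(params)) {
    params <- nm[nm == "alpha" | startsWith(nm, "b_") |
                   startsWith(nm, "sigma_")]
  }
  a <- (1 - ci_mass) / 2
  out <- do.call(rbind, lapply(params, function(p) {
    d <- fit$draws[, p]
    q <- unname(stats::quantile(d, c(a, 1 - a), type = 7))
    data.frame(parameter = p, mean = mean(d), lower = q[1], upper = q[2],
               excludes_zero = (q[1] > 0 || q[2] < 0))
  }))
  rownames(out) <- NULL
  out
}

#' Interpret a log-odds coefficient as a percent change in odds
#'
#' A one-unit increase in the predictor multiplies the odds by exp(beta),
#' i.e. changes them by `100 * (exp(beta) - 1)` percent.
#'
#' @param beta log-odds coefficient.
#' @return percent change in the odds.
#' @examples
#' odds_interpretation(0.04)  # ~ +4%
#' @export
odds_interpretation <- function(beta) {
  stopifnot(is.finite(beta))
  100 * (exp(beta) - 1)
}

#' Serialise a fit to a directory (draws CSV, diagnostics and spec JSON)
#' @param fit a `bias_fit`.
#' @param dir output directory (created if needed).
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(fit$draws),
                   file.path(dir, "draws.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(diagnostics = fit$diagnostics, accept_rate = fit$accept_rate,
         seed = fit$seed),
    file.path(dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(fit$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' The standard model set for one polarity
#'
#' null (varying intercepts only), single-bias models, the full model, and
#' the full model plus unbiased transmission. The content-bias (rank)
#' predictor applies only to negative polarity and only when the design
#' carries ranks.
#'
#' @param polarity `"positive"` or `"negative"`.
#' @param has_rank does the design include a rank column?
#' @return named list of effect vectors.
#' @export
standard_model_set <- function(polarity, has_rank = FALSE) {
  use_rank <- (polarity == "negative") && has_rank
  ms <- list(null = character(0),
             success = "success",
             prestige = "prestige")
  if (use_rank) ms$content <- "rank"
  ms$full <- c("success", "prestige", if (use_rank) "rank")
  ms$full_unbiased <- c(ms$full, "unbiased")
  ms
}
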