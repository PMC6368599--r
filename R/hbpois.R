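#' Fit a grouped hierarchical Bayesian Poisson model
#'
#' Fits the model \eqn{y_{un} \sim \mathrm{Poisson}(\exp(\eta_{un}))} with
#' \eqn{\eta = B X^\top + \log(\mathrm{offset})}, where every unit \eqn{u}
#' (a diagnosis, or an exposure--event design) has its own coefficient vector
#' \eqn{B_{u\cdot}} over a design matrix \eqn{X} shared across units.
#' Coefficients are partially pooled: \eqn{B_{uj} \sim N(0, \sigma_{g(j)})}
#' with one scale per declared coefficient group and half-normal hyperpriors
#' \eqn{\sigma_g \sim N_+(0, c_g)} on the scales.
#'
#' Sampling uses a No-U-Turn Hamiltonian Monte Carlo sampler with
#' dual-averaging step-size adaptation and windowed diagonal-metric
#' adaptation. Convergence is assessed with split R-hat, divergence counts
#' and tree-depth saturation; a fit is declared converged iff all R-hat
#' values are below 1.1, no post-warmup iteration saturated the maximum tree
#' depth, and there were zero post-warmup divergences.
#'
#' @param y matrix of counts (units x observations), or a vector for a
#'   single unit.
#' @param offset matrix (or vector) of positive exposures, same shape as `y`.
#' @param X design matrix (observations x coefficients).
#' @param coef_groups integer or factor of length `ncol(X)` assigning each
#'   coefficient to a scale group.
#' @param group_scales positive numeric, one half-normal hyperprior scale per
#'   group level (in the order of the group levels).
#' @param between_scales optional numeric of length `nlevels(coef_groups)`
#'   (or named by group level). A finite entry turns that group into a
#'   compound-symmetry group: the member coefficients of each unit get a
#'   joint \eqn{MVN(0, \sigma_w^2 I + \sigma_b^2 J)} prior, with
#'   \eqn{\sigma_w \sim N_+(0, \mathrm{group\_scales}_g)} and
#'   \eqn{\sigma_b \sim N_+(0, \mathrm{between\_scales}_g)}. This is the
#'   exact marginalisation of a shared per-unit intercept over a complete
#'   set of level indicators and keeps the sampled likelihood full rank.
#' @param mask optional 0/1 matrix marking which cells of `y` enter the
#'   likelihood; defaults to all cells with `offset > 0`.
#' @param control a [sampler_control()] list.
#' @return an object of class `"hbpois"` with posterior draws, the
#'   convergence report and the model inputs.
#' @seealso [hdi()], [rope_decision()], [check_convergence()]
#' @examples
#' fit <- hbpois(y = matrix(c(10, 50), 1), offset = matrix(c(100, 500), 1),
#'               X = cbind(intercept = c(1, 1)), coef_groups = 1,
#'               group_scales = 3,
#'               control = sampler_control(n_warmup = 200, n_draws = 200,
#'                                         seed = 1))
#' coef(fit)
#' @export
hbpois <- function(y, offset, X, coef_groups, group_scales,
                   between_scales = NULL, mask = NULL,
                   control = sampler_control()) {
  if (is.vector(y)) y <- matrix(y, nrow = 1L)
  if (is.vector(offset)) offset <- matrix(offset, nrow = 1L)
  y <- as.matrix(y); offset <- as.matrix(offset); X <- as.matrix(X)
  storage.mode(y) <- "double"; storage.mode(offset) <- "double"
  storage.mode(X) <- "double"
  U <- nrow(y); N <- ncol(y); K <- ncol(X)
  if (!all(dim(offset) == dim(y)))
    stop("`offset` must have the same shape as `y`")
  if (nrow(X) != N) stop("`X` must have one row per observation column of `y`")
  if (is.null(mask)) mask <- (offset > 0) * 1
  mask <- as.matrix(mask) * 1
  if (any(y[mask > 0] < 0)) stop("counts must be non-negative")
  if (any(offset[mask > 0] <= 0)) stop("offsets must be positive where used")
  gfac <- as.factor(coef_groups)
  gf <- as.integer(gfac)
  if (length(gf) != K) stop("`coef_groups` must have length ncol(X)")
  G <- nlevels(gfac)
  group_scales <- as.numeric(group_scales)
  if (length(group_scales) != G) stop("need one scale per coefficient group")
  if (any(group_scales <= 0)) stop("hyperprior scales must be positive")
  if (is.null(between_scales)) between_scales <- rep(NA_real_, G)
  if (!is.null(names(between_scales))) {
    bs <- rep(NA_real_, G)
    bs[match(names(between_scales), levels(gfac))] <- between_scales
    between_scales <- bs
  }
  gtype <- as.integer(is.finite(between_scales))
  stopifnot(control$n_chains >= 2, control$n_warmup >= 20,
            control$n_draws >= 1)

  logoff <- matrix(0, U, N)
  logoff[mask > 0] <- log(offset[mask > 0])

  # hyperprior scale per tau parameter and tau names, in group order
  cscale <- numeric(0); tau_names <- character(0)
  for (g in seq_len(G)) {
    if (gtype[g] == 1L) {
      cscale <- c(cscale, group_scales[g], between_scales[g])
      tau_names <- c(tau_names, paste0("log_sigma:", levels(gfac)[g],
                                       c(":within", ":between")))
    } else {
      cscale <- c(cscale, group_scales[g])
      tau_names <- c(tau_names, paste0("log_sigma:", levels(gfac)[g]))
    }
  }
  Tn <- length(cscale)

  theta0 <- .hbpois_init(y, offset, mask, X, gf, gtype)
  P <- U * K + Tn

  chains <- vector("list", control$n_chains)
  seed0 <- as.numeric(control$seed)
  for (ch in seq_len(control$n_chains)) {
    chain_seed <- (seed0 * 48271 + ch * 69621) %% 2147483647 + 1
    jit <- .hash_runif(P, chain_seed, -0.05, 0.05)
    chains[[ch]] <- .nuts_chain(y, logoff, mask, X, gf - 1L, gtype, cscale,
                                theta0 + jit, control$n_warmup,
                                control$n_draws, control$max_tree_depth,
                                chain_seed)
  }

  draws <- array(NA_real_, c(control$n_draws, control$n_chains, P))
  for (ch in seq_along(chains)) draws[, ch, ] <- chains[[ch]]$draws
  unit_names <- rownames(y)
  if (is.null(unit_names)) unit_names <- paste0("u", seq_len(U))
  coef_names <- colnames(X)
  if (is.null(coef_names)) coef_names <- paste0("x", seq_len(K))
  dimnames(draws) <- list(NULL, NULL, c(
    as.vector(outer(unit_names, coef_names, paste, sep = ":")), tau_names))

  rh <- apply(draws, 3, split_rhat)
  n_div <- sum(vapply(chains, function(c) sum(c$divergent), integer(1)))
  saturated <- any(vapply(chains, function(c)
    any(c$treedepth >= control$max_tree_depth), logical(1)))
  report <- convergence_report(max_rhat = max(rh), n_divergences = n_div,
                               treedepth_saturated = saturated)

  structure(list(
    draws = draws, rhat = rh, convergence = report,
    converged = check_convergence(report),
    y = y, offset = offset, mask = mask, X = X,
    coef_groups = gf, group_scales = group_scales,
    unit_names = unit_names, coef_names = coef_names,
    control = control,
    stepsize = vapply(chains, function(c) c$stepsize, numeric(1))),
    class = "hbpois")
}

#' Sampler settings for [hbpois()]
#'
#' Desk-scale defaults: 4 chains with 500 warm-up and 1000 retained
#' iterations each.
#'
#' @param n_chains number of chains (at least 2).
#' @param n_warmup warm-up (adaptation) iterations per chain, discarded.
#' @param n_draws retained post-warmup iterations per chain.
#' @param max_tree_depth NUTS doubling limit.
#' @param seed master seed; per-chain seeds are derived deterministically.
#' @export
sampler_control <- function(n_chains = 4, n_warmup = 500, n_draws = 1000,
                            max_tree_depth = 10, seed = 1) {
  list(n_chains = as.integer(n_chains), n_warmup = as.integer(n_warmup),
       n_draws = as.integer(n_draws),
       max_tree_depth = as.integer(max_tree_depth), seed = seed)
}

# crude but safe initialisation: put each unit's intercept-like columns at
# its crude log rate, everything else at zero; scale parameters at the
# spread of the initial coefficients within their group
.hbpois_init <- function(y, offset, mask, X, gf, gtype) {
  U <- nrow(y); K <- ncol(X); G <- max(gf)
  B <- matrix(0, U, K)
  tot_y <- rowSums(y * mask); tot_off <- rowSums(offset * mask)
  crude <- log((tot_y + 0.5) / pmax(tot_off, 1e-12))
  const_col <- which(apply(X, 2, function(c) all(c == 1)))[1]
  if (!is.na(const_col)) {
    B[, const_col] <- crude
  } else {
    # complete sets of level indicators act as per-level intercepts
    for (g in seq_len(G)) {
      cols <- which(gf == g)
      sub <- X[, cols, drop = FALSE]
      if (all(sub %in% c(0, 1)) && all(rowSums(sub) == 1))
        B[, cols] <- matrix(crude, U, length(cols))
    }
  }
  tau <- numeric(0)
  for (g in seq_len(G)) {
    v <- as.vector(B[, gf == g, drop = FALSE])
    s <- if (length(v) > 1) stats::sd(v) else abs(v)
    if (!is.finite(s)) s <- 0
    t1 <- log(max(s, 0.1))
    tau <- c(tau, if (gtype[g] == 1L) c(t1, t1) else t1)
  }
  c(as.vector(B), tau)
}

# small deterministic uniform stream independent of R's global RNG
.hash_runif <- function(n, seed, lo, hi) {
  x <- numeric(n)
  s <- seed %% 2147483647
  if (s <= 0) s <- s + 2147483646
  for (i in seq_len(n)) {
    s <- (s * 48271) %% 2147483647
    x[i] <- s / 2147483647
  }
  lo + (hi - lo) * x
}

#' Split R-hat convergence statistic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift also inflates the statistic.
#'
#' @param x draws matrix (iterations x chains).
#' @return the split R-hat value (1 at perfect mixing).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  mu <- colMeans(sub)
  s2 <- apply(sub, 2, stats::var)
  W <- mean(s2)
  B <- nn * stats::var(mu)
  if (W == 0) return(1)
  sqrt((nn - 1) / nn + B / (W * nn))
}

#' Convergence report for a sampled model
#'
#' @param max_rhat largest split R-hat over all parameters.
#' @param n_divergences post-warmup divergent transitions, all chains.
#' @param treedepth_saturated whether any post-warmup iteration hit the
#'   maximum tree depth.
#' @export
convergence_report <- function(max_rhat, n_divergences, treedepth_saturated) {
  structure(list(max_rhat = max_rhat,
                 n_divergences = as.integer(n_divergences),
                 treedepth_saturated = isTRUE(treedepth_saturated)),
            class = "convergence_report")
}

#' Convergence decision rule
#'
#' A model counts as converged if and only if all R-hat values are below
#' 1.1, the tree depth never saturated after warm-up, and there were zero
#' divergences.
#'
#' @param report a [convergence_report()].
#' @return `TRUE` or `FALSE`.
#' @export
check_convergence <- function(report) {
  report$max_rhat < 1.1 && !report$treedepth_saturated &&
    report$n_divergences == 0L
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("max R-hat %.3f | divergences %d | treedepth saturated: %s\n",
              x$max_rhat, x$n_divergences, x$treedepth_saturated))
  invisible(x)
}

#' Highest density interval
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws.
#'
#' @param x numeric draws (at least 100).
#' @param mass posterior mass in (0, 1); default 0.95.
#' @return list with `lower`, `upper`, `mass`, of class `"credible_interval"`.
#' @export
hdi <- function(x, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1)
    stop("`mass` must be a single value in (0, 1)")
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 100) stop("hdi() needs at least 100 draws")
  xs <- sort(x)
  m <- ceiling(mass * n)
  i <- seq_len(n - m + 1)
  w <- xs[i + m - 1] - xs[i]
  j <- which.min(w)
  structure(list(lower = xs[j], upper = xs[j + m - 1], mass = mass),
            class = "credible_interval")
}

#' @export
print.credible_interval <- function(x, ...) {
  cat(sprintf("%.0f%% HDI [%.4g, %.4g]\n", 100 * x$mass, x$lower, x$upper))
  invisible(x)
}

#' Region-of-practical-equivalence decision
#'
#' @param interval a `credible_interval` (or list with `lower`/`upper`).
#' @param rope list with `lower < upper` delimiting the open region of
#'   values treated as practically null.
#' @return `"excludes"` if the interval and the region are disjoint,
#'   `"overlaps"` otherwise.
#' @export
rope_decision <- function(interval, rope) {
  stopifnot(rope$lower < rope$upper, interval$lower <= interval$upper)
  if (interval$upper <= rope$lower || interval$lower >= rope$upper)
    "excludes" else "overlaps"
}

#' @export
print.hbpois <- function(x, ...) {
  cat(sprintf(
    "Hierarchical Bayesian Poisson fit: %d unit(s) x %d obs, %d coefficients\n",
    nrow(x$y), ncol(x$y), ncol(x$X)))
  cat(sprintf("%d chains x %d draws (warmup %d)\n", x$control$n_chains,
              x$control$n_draws, x$control$n_warmup))
  print(x$convergence)
  invisible(x)
}

#' @export
summary.hbpois <- function(object, mass = 0.95, ...) {
  dm <- apply(object$draws, 3, identity)  # iterations*chains x P
  med <- apply(dm, 2, stats::median)
  his <- apply(dm, 2, function(v) unlist(hdi(v, mass)[c("lower", "upper")]))
  out <- data.frame(parameter = dimnames(object$draws)[[3]], median = med,
                    hdi_lower = his[1, ], hdi_upper = his[2, ],
                    rhat = object$rhat, row.names = NULL)
  out
}

#' @export
coef.hbpois <- function(object, ...) {
  U <- length(object$unit_names); K <- length(object$coef_names)
  dm <- .draws_matrix(object)
  med <- apply(dm[, seq_len(U * K), drop = FALSE], 2, stats::median)
  matrix(med, U, K, dimnames = list(object$unit_names, object$coef_names))
}

# flatten draws to (chains*iterations) x P
.draws_matrix <- function(fit) {
  d <- fit$draws
  matrix(d, nrow = dim(d)[1] * dim(d)[2], ncol = dim(d)[3],
         dimnames = list(NULL, dimnames(d)[[3]]))
}

#' Posterior draws of the coefficient array
#'
#' @param fit an [hbpois()] fit.
#' @return array (draws x units x coefficients); scale draws are available
#'   via `sigma_draws()`.
#' @export
coef_draws <- function(fit) {
  U <- length(fit$unit_names); K <- length(fit$coef_names)
  dm <- .draws_matrix(fit)
  array(dm[, seq_len(U * K)], c(nrow(dm), U, K),
        dimnames = list(NULL, fit$unit_names, fit$coef_names))
}

#' Posterior draws of the group scale parameters
#' @param fit an [hbpois()] fit.
#' @export
sigma_draws <- function(fit) {
  U <- length(fit$unit_names); K <- length(fit$coef_names)
  dm <- .draws_matrix(fit)
  exp(dm[, (U * K + 1):ncol(dm), drop = FALSE])
}

#' Posterior-predictive case counts
#'
#' Simulates one Poisson count per cell per posterior draw from the fitted
#' linear predictor (with its offset), i.e. new data from the estimated
#' model including parameter uncertainty.
#'
#' @param object an [hbpois()] fit.
#' @param nsim number of posterior draws to use (default: all).
#' @param seed optional seed applied via the R RNG.
#' @param ... unused.
#' @return array (draws x units x observations); masked cells are `NA`.
#' @export
simulate.hbpois <- function(object, nsim = NULL, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  bd <- coef_draws(object)
  nd <- dim(bd)[1]
  use <- if (is.null(nsim)) seq_len(nd) else
    seq_len(nd)[round(seq(1, nd, length.out = min(nsim, nd)))]
  U <- dim(bd)[2]; N <- ncol(object$y)
  out <- array(NA_real_, c(length(use), U, N))
  lo <- matrix(0, U, N)
  lo[object$mask > 0] <- log(object$offset[object$mask > 0])
  tX <- t(object$X)
  for (k in seq_along(use)) {
    eta <- bd[use[k], , , drop = FALSE]
    dim(eta) <- c(U, dim(bd)[3])
    lam <- exp(eta %*% tX + lo)
    cnt <- .rpois_safe(lam)
    cnt[object$mask == 0] <- NA_real_
    out[k, , ] <- cnt
  }
  out
}

# Poisson sampler robust to very large means (normal approximation far
# beyond the integer range)
.rpois_safe <- function(lam) {
  out <- lam
  big <- lam > 1e8
  if (any(!big)) out[!big] <- stats::rpois(sum(!big), lam[!big])
  if (any(big)) out[big] <- round(stats::rnorm(sum(big), lam[big],
                                               sqrt(lam[big])))
  out
}
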