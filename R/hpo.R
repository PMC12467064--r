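# Bayesian optimization of the pruned-BiLSTM hyperparameters (M, P):
# Gaussian-process surrogate with an ARD Matern 5/2 kernel, refit by marginal
# likelihood each trial, and an expected-improvement acquisition with an
# exploration safeguard (EI-plus), maximized over the integer search box.

# ARD Matern 5/2 kernel matrix between rows of (already length-scaled) inputs
matern52 <- function(A, B, ls, sf2) {
  As <- sweep(A, 2, ls, "/")
  Bs <- sweep(B, 2, ls, "/")
  d2 <- outer(rowSums(As^2), rowSums(Bs^2), "+") - 2 * tcrossprod(As, Bs)
  r <- sqrt(pmax(d2, 0))
  sf2 * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
}

# negative log marginal likelihood of a GP with Matern 5/2 ARD kernel
gp_nll <- function(theta, X, y) {
  ls <- exp(theta[1:2]); sf2 <- exp(2 * theta[3]); sn2 <- exp(2 * theta[4])
  n <- nrow(X)
  K <- matern52(X, X, ls, sf2) + diag(sn2 + 1e-8, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
}

# fit hyperparameters by L-BFGS-B from a couple of deterministic starts
gp_fit <- function(X, y) {
  starts <- list(c(log(0.3), log(0.3), log(1), log(0.1)),
                 c(log(1), log(1), log(1), log(0.01)))
  lower <- c(log(0.03), log(0.03), log(0.05), log(1e-4))
  upper <- c(log(10), log(10), log(10), log(1))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, gp_nll, X = X, y = y, method = "L-BFGS-B",
            lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  theta <- if (is.null(best)) starts[[1]] else best$par
  ls <- exp(theta[1:2]); sf2 <- exp(2 * theta[3]); sn2 <- exp(2 * theta[4])
  K <- matern52(X, X, ls, sf2) + diag(sn2 + 1e-8, nrow(X))
  ch <- chol(K)
  list(ls = ls, sf2 = sf2, sn2 = sn2, chol = ch, X = X, y = y,
       alpha = backsolve(ch, forwardsolve(t(ch), y)))
}

# posterior mean and sd of the latent function at new points
gp_posterior <- function(gp, Xs) {
  Ks <- matern52(gp$X, Xs, gp$ls, gp$sf2)
  mu <- drop(crossprod(Ks, gp$alpha))
  v <- forwardsolve(t(gp$chol), Ks)
  var <- pmax(gp$sf2 - colSums(v^2), 0)
  list(mu = mu, sd = sqrt(var))
}

expected_improvement <- function(mu, sd, best) {
  imp <- mu - best
  ei <- ifelse(sd > 1e-12,
               imp * pnorm(imp / sd) + sd * dnorm(imp / sd),
               pmax(imp, 0))
  pmax(ei, 0)
}

# 4-point Latin-hypercube initial design on the unit box (seeded caller RNG)
lhs_design <- function(n, d) {
  sapply(seq_len(d), function(j) (sample.int(n) - runif(n)) / n)
}

#' Bayesian optimization over an integer box
#'
#' Maximizes `objective(M, P)` with a Gaussian-process surrogate (ARD Matern
#' 5/2 kernel, hyperparameters refit by marginal likelihood after every
#' trial) and an expected-improvement acquisition evaluated exhaustively over
#' the integer grid. The "plus" safeguard keeps the search from stalling:
#' when the acquisition maximum is negligible or lands on an evaluated point,
#' the proposal falls back to the unevaluated point of highest posterior
#' uncertainty. Four Latin-hypercube points seed the model; failing
#' objectives are recorded as failed trials and the search continues.
#' Deterministic given `seed`.
#'
#' @param objective function of two integers returning a finite score to
#'   maximize.
#' @param bounds named list with integer ranges, e.g.
#'   `list(M = c(15, 50), P = c(20, 100))`.
#' @param n_trials total number of objective evaluations.
#' @param seed RNG seed.
#' @param n_init number of initial space-filling trials.
#' @return An `hpo_trace`: list with the `trials` tibble (`trial`, `M`, `P`,
#'   `objective`, `proposal`, `failed`), `bounds` and the `best` trial row.
#' @export
bayes_optimize <- function(objective, bounds = list(M = c(15L, 50L), P = c(20L, 100L)),
                           n_trials = 30L, seed = 1L, n_init = 4L) {
  stopifnot(is.function(objective), n_trials >= n_init, n_init >= 2)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  if (any(hi <= lo)) abort("degenerate bounds", class = "gaitphase_config_error")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  grid <- as.matrix(expand.grid(M = lo[1]:hi[1], P = lo[2]:hi[2]))
  unit <- function(pts) sweep(sweep(pts, 2, lo, "-"), 2, hi - lo, "/")
  grid_u <- unit(grid)
  key <- function(p) paste(p[1], p[2])
  evaluated <- character(0)

  nearest_free <- function(target_u) {
    free <- !(apply(grid, 1, key) %in% evaluated)
    if (!any(free)) return(NULL)
    d2 <- rowSums(sweep(grid_u, 2, target_u, "-")^2)
    d2[!free] <- Inf
    grid[which.min(d2), ]
  }

  trials <- tibble::tibble(trial = integer(0), M = integer(0), P = integer(0),
                           objective = numeric(0), proposal = character(0),
                           failed = logical(0))
  init_u <- lhs_design(n_init, 2)

  for (i in seq_len(n_trials)) {
    if (i <= n_init) {
      pt <- nearest_free(init_u[i, ])
      kind <- "initial"
    } else {
      done <- trials[!trials$failed, ]
      if (nrow(done) < 2) {
        pt <- nearest_free(runif(2))
        kind <- "random"
      } else {
        Xo <- unit(cbind(done$M, done$P))
        mu_y <- mean(done$objective)
        sd_y <- max(sd(done$objective), 1e-8)
        gp <- gp_fit(Xo, (done$objective - mu_y) / sd_y)
        free <- !(apply(grid, 1, key) %in% evaluated)
        post <- gp_posterior(gp, grid_u[free, , drop = FALSE])
        ei <- expected_improvement(post$mu, post$sd,
                                   max((done$objective - mu_y) / sd_y))
        if (max(ei) > 1e-8) {
          pt <- grid[free, , drop = FALSE][which.max(ei), ]
          kind <- "ei"
        } else {
          # EI-plus escape: the model is certain everywhere it can propose;
          # explore the most uncertain unevaluated point instead
          pt <- grid[free, , drop = FALSE][which.max(post$sd), ]
          kind <- "explore"
        }
      }
    }
    if (is.null(pt)) break
    evaluated <- c(evaluated, key(pt))
    val <- tryCatch(objective(pt[1], pt[2]), error = function(e) NA_real_)
    failed <- !is.finite(val)
    trials <- dplyr::bind_rows(trials, tibble::tibble(
      trial = i, M = as.integer(pt[1]), P = as.integer(pt[2]),
      objective = if (failed) NA_real_ else val,
      proposal = kind, failed = failed))
  }
  ok <- trials[!trials$failed, ]
  if (!nrow(ok)) abort("every trial failed", class = "gaitphase_data_error")
  structure(list(trials = trials, bounds = bounds,
                 best = ok[which.max(ok$objective), ]),
            class = "hpo_trace")
}

#' @export
print.hpo_trace <- function(x, ...) {
  cat(sprintf("<hpo_trace> %d trials (%d failed); best objective %.4f at (M=%d, P=%d)\n",
              nrow(x$trials), sum(x$trials$failed), x$best$objective,
              x$best$M, x$best$P))
  invisible(x)
}

#' @export
tidy.hpo_trace <- function(x, ...) x$trials

#' @export
glance.hpo_trace <- function(x, ...) {
  tibble::tibble(n_trials = nrow(x$trials), n_failed = sum(x$trials$failed),
                 best_M = x$best$M, best_P = x$best$P,
                 best_objective = x$best$objective)
}

#' Optimize the pruned BiLSTM on validation accuracy
#'
#' Runs [bayes_optimize()] with the objective "validation frame accuracy of
#' [build_pruned_bilstm()] trained under `cfg`", over the standard search box
#' M in \[15, 50\], P in \[20, 100\]. Every trained candidate's accuracy and
#' parameter count enter the returned trace, feeding the Trade-Off-Score
#' ranking; the best candidate's fitted model is attached.
#'
#' @param train,val `sequence_dataset`s.
#' @param cfg a [train_config()].
#' @param seed RNG seed (also used for each candidate's training).
#' @param n_trials number of optimization trials.
#' @return An `hpo_trace` whose `trials` gain an `n_parameters` column and
#'   which carries the `best_model` (a `gait_model`).
#' @export
optimize_pruned <- function(train, val, cfg = train_config(), seed = 1L,
                            n_trials = 30L) {
  best_acc <- -Inf
  best_model <- NULL
  objective <- function(M, P) {
    model <- train_model(build_pruned_bilstm(M, P), train, val, cfg, seed = seed)
    acc <- evaluate(model, val)$accuracy
    if (acc > best_acc) {
      best_acc <<- acc
      best_model <<- model
    }
    acc
  }
  trace <- bayes_optimize(objective, n_trials = n_trials, seed = seed)
  trace$trials$n_parameters <- vapply(seq_len(nrow(trace$trials)), function(i) {
    count_parameters(build_pruned_bilstm(trace$trials$M[i], trace$trials$P[i]))
  }, numeric(1))
  trace$best_model <- best_model
  trace
}
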