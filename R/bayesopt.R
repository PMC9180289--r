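## Gaussian-process expected-improvement optimizer for the hyperparameter
## search. Points live in the unit cube; integers are decoded by flooring,
## log-scale parameters by exponential interpolation. The surrogate is a
## squared-exponential GP whose lengthscale and noise are chosen from a small
## grid by marginal likelihood.

decode_point <- function(u, space) {
  out <- list()
  for (i in seq_along(space)) {
    def <- space[[i]]
    v <- switch(def$type,
      int = {
        lo <- as.integer(def$lower)
        hi <- as.integer(def$upper)
        min(hi, lo + as.integer(floor(u[i] * (hi - lo + 1L))))
      },
      num = def$lower + u[i] * (def$upper - def$lower),
      lognum = exp(log(def$lower) + u[i] * (log(def$upper) - log(def$lower)))
    )
    out[[names(space)[i]]] <- v
  }
  out
}

gp_fit <- function(X, y) {
  n <- nrow(X)
  mu <- mean(y)
  sdy <- sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  z <- (y - mu) / sdy
  d2 <- as.matrix(stats::dist(X))^2
  best <- NULL
  for (ell in c(0.15, 0.3, 0.6, 1.2)) {
    for (noise in c(1e-4, 1e-2, 0.1)) {
      K <- exp(-0.5 * d2 / ell^2) + diag(noise + 1e-8, n)
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) next
      alpha <- backsolve(ch, forwardsolve(t(ch), z))
      ll <- -0.5 * sum(z * alpha) - sum(log(diag(ch))) - n / 2 * log(2 * pi)
      if (is.null(best) || ll > best$ll) {
        best <- list(
          ll = ll, ell = ell, noise = noise, chol = ch, alpha = alpha,
          X = X, mu = mu, sdy = sdy
        )
      }
    }
  }
  best
}

gp_predict <- function(gp, Xnew) {
  cross <- matrix(0, nrow(gp$X), nrow(Xnew))
  for (j in seq_len(nrow(Xnew))) {
    d2 <- colSums((t(gp$X) - Xnew[j, ])^2)
    cross[, j] <- exp(-0.5 * d2 / gp$ell^2)
  }
  mean_z <- drop(crossprod(cross, gp$alpha))
  v <- forwardsolve(t(gp$chol), cross)
  var_z <- pmax(1e-12, 1 + gp$noise - colSums(v^2))
  list(
    mean = gp$mu + gp$sdy * mean_z,
    sd = gp$sdy * sqrt(var_z)
  )
}

expected_improvement <- function(pred, best) {
  imp <- best - pred$mean
  z <- imp / pred$sd
  imp * pnorm(z) + pred$sd * dnorm(z)
}

#' Bayesian hyperparameter optimization over cross-validation
#'
#' Minimizes [cv_objective()] over the spec's search space with a
#' Gaussian-process surrogate and expected-improvement acquisition: a
#' maximin Latin-hypercube initial design, then one proposal per iteration
#' chosen as the EI maximizer over a random candidate set (with local
#' refinement around the incumbent). Reproducible under the spec seed. If
#' the whole space is a single point it is evaluated once.
#'
#' @param spec A [model_spec()].
#' @param table Feature table to cross-validate on.
#' @return List with `hyperparams` (best evaluated point), `score` (its CV
#'   RMSE) and `trace` (data frame of every evaluated point and score).
#' @export
bayes_optimize <- function(spec, table) {
  space <- spec$search_space
  if (length(space) == 0L) stop("empty search space")
  budget <- spec$opt_budget
  d <- length(space)
  free <- vapply(space, function(p) p$lower < p$upper, logical(1))
  set.seed(substream_seed(spec$seed, "bayesopt"))

  evals <- list()
  scores <- numeric(0)
  eval_point <- function(u) {
    hp <- decode_point(u, space)
    s <- cv_objective(spec, hp, table)
    evals[[length(evals) + 1L]] <<- list(u = u, hyperparams = hp, score = s)
    scores <<- c(scores, s)
    s
  }

  if (!any(free)) {
    ## Degenerate space: a single configuration, evaluated once.
    eval_point(rep(0, d))
  } else {
    n_init <- min(budget, max(4L, 2L * sum(free)))
    U <- lhs::maximinLHS(n_init, d)
    for (i in seq_len(n_init)) eval_point(U[i, ])
    while (length(scores) < budget) {
      finite <- is.finite(scores)
      if (any(finite) && sum(finite) >= 2L) {
        Xobs <- do.call(rbind, lapply(evals, function(e) e$u))
        yobs <- scores
        ## Failed evaluations enter the surrogate as a pessimistic value.
        if (any(!finite)) {
          worst <- max(yobs[finite])
          spread <- sd(yobs[finite])
          yobs[!finite] <- worst + 2 * max(spread, 1e-8, na.rm = TRUE)
        }
        gp <- gp_fit(Xobs, yobs)
        n_cand <- 256L
        cand <- matrix(runif(n_cand * d), n_cand, d)
        ## Local candidates around the incumbent sharpen late exploitation.
        inc <- evals[[which.min(scores)]]$u
        local <- matrix(
          pmin(1, pmax(0, rep(inc, each = 64L) +
            rnorm(64L * d, 0, 0.08))), 64L, d
        )
        cand <- rbind(cand, local)
        cand[, !free] <- 0
        if (!is.null(gp)) {
          pred <- gp_predict(gp, cand)
          ei <- expected_improvement(pred, min(yobs))
          u_next <- cand[which.max(ei), ]
        } else {
          u_next <- cand[1L, ]
        }
      } else {
        u_next <- runif(d)
        u_next[!free] <- 0
      }
      eval_point(u_next)
    }
  }

  if (all(!is.finite(scores))) {
    stop("Bayesian optimization exhausted its budget with no finite score")
  }
  best <- which.min(scores)
  trace <- data.frame(
    eval = seq_along(scores),
    score = scores
  )
  hp_df <- do.call(rbind, lapply(evals, function(e) {
    as.data.frame(e$hyperparams)
  }))
  trace <- cbind(trace, hp_df)
  list(
    hyperparams = evals[[best]]$hyperparams,
    score = scores[best],
    trace = trace
  )
}
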