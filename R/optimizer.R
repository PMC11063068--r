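# Model-based optimization over the encoded search space: Gaussian-process
# surrogate with a Matern-3/2 kernel, batch UCB proposals with exponentially
# distributed trade-off parameters, and multi-fidelity warm starts.

matern32 <- function(D, ell) {
  a <- sqrt(3) * D / ell
  (1 + a) * exp(-a)
}

pdist <- function(X, Y = X) {
  # Euclidean distance matrix between rows
  xn <- rowSums(X^2); yn <- rowSums(Y^2)
  D2 <- outer(xn, yn, `+`) - 2 * tcrossprod(X, Y)
  sqrt(pmax(D2, 0))
}

encode_records <- function(records, space) {
  X <- t(vapply(records$config, function(cfg) to_unit_vector(space, cfg),
                numeric(encoding_dim(space))))
  if (encoding_dim(space) == 1L) X <- matrix(X, ncol = 1L)
  X
}

encode_fidelity <- function(lf_min, lf_max, fidelity) {
  lf <- log(fidelity)
  if (lf_max - lf_min < 1e-12) return(rep(0.5, length(fidelity)))
  (lf - lf_min) / (lf_max - lf_min)
}

#' Fit the Gaussian-process surrogate
#'
#' Fits a Gaussian process with an isotropic Matern-3/2 kernel to the observed
#' (configuration, fidelity, objective) records. Configurations enter as
#' unit-cube encodings ([to_unit_vector()]) with the log training budget
#' appended as one extra coordinate, so observations from cheaper fidelities
#' inform the surrogate without being conflated with expensive ones. Kernel
#' hyperparameters (length-scale, signal variance, noise variance) are
#' estimated by maximizing the marginal likelihood.
#'
#' @param records A tibble of evaluation records with list-column `config` and
#'   numeric columns `fidelity`, `objective` (at least 2 rows).
#' @param space The `genarch_space` the configurations live in.
#' @return An object of class `genarch_surrogate` with a
#'   [predict][predict.genarch_surrogate] method returning mean and standard
#'   deviation.
#' @export
fit_surrogate <- function(records, space) {
  if (is.null(records) || nrow(records) < 2L) {
    rlang::abort("fitting the surrogate requires at least 2 evaluation records",
                 class = "genarch_insufficient_data")
  }
  Xc <- encode_records(records, space)
  lf <- log(records$fidelity)
  lf_min <- min(lf); lf_max <- max(lf)
  X <- cbind(Xc, encode_fidelity(lf_min, lf_max, records$fidelity))
  y <- records$objective
  n <- length(y)
  my <- mean(y)
  yc <- y - my
  vy <- stats::var(y)
  sur <- list(X = X, y = y, my = my, space = space,
              lf_min = lf_min, lf_max = lf_max, constant = FALSE)
  if (!is.finite(vy) || vy < 1e-12) {
    sur$constant <- TRUE
    class(sur) <- "genarch_surrogate"
    return(sur)
  }
  D <- pdist(X)
  nll <- function(theta) {
    ell <- exp(theta[1]); sf2 <- exp(theta[2]); sn2 <- exp(theta[3])
    K <- sf2 * matern32(D, ell) + diag(sn2, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), yc))
    as.numeric(0.5 * sum(yc * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi))
  }
  starts <- list(c(log(0.5), log(vy), log(max(vy * 1e-3, 1e-7))),
                 c(log(2), log(vy), log(max(vy * 1e-2, 1e-6))))
  best <- NULL
  for (s in starts) {
    op <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B",
                   lower = c(log(0.05), log(vy * 1e-4), log(1e-9)),
                   upper = c(log(20), log(vy * 100), log(max(vy, 1e-8)))),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  theta <- if (is.null(best)) starts[[1]] else best$par
  ell <- exp(theta[1]); sf2 <- exp(theta[2]); sn2 <- exp(theta[3])
  K <- sf2 * matern32(D, ell) + diag(sn2, n)
  ch <- chol(K)
  sur$ell <- ell; sur$sf2 <- sf2; sur$sn2 <- sn2
  sur$chol <- ch
  sur$alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  class(sur) <- "genarch_surrogate"
  sur
}

# Xnew: matrix of encoded points incl. fidelity coordinate
surrogate_predict_units <- function(sur, Xnew) {
  if (sur$constant) {
    return(tibble::tibble(mean = rep(sur$my, nrow(Xnew)),
                          sd = rep(0, nrow(Xnew))))
  }
  Ks <- sur$sf2 * matern32(pdist(Xnew, sur$X), sur$ell)
  mu <- sur$my + as.numeric(Ks %*% sur$alpha)
  V <- forwardsolve(t(sur$chol), t(Ks))
  # predictive variance of a new observation: latent variance plus noise, so
  # the uncertainty honestly covers what an evaluation would return
  var <- pmax(sur$sf2 - colSums(V^2), 0) + sur$sn2
  tibble::tibble(mean = mu, sd = sqrt(var))
}

#' Predict objective mean and uncertainty for configurations
#'
#' @param object A `genarch_surrogate`.
#' @param configs A configuration, a list of configurations, or a tibble of
#'   configurations (one per row).
#' @param fidelity Training budget at which to predict (defaults to the
#'   largest budget seen during fitting).
#' @param ... Unused.
#' @return A tibble with columns `mean` and `sd`.
#' @export
predict.genarch_surrogate <- function(object, configs, fidelity = NULL, ...) {
  if (is.data.frame(configs)) {
    configs <- lapply(seq_len(nrow(configs)), function(i) as_config(configs[i, ]))
  } else if (!is.null(names(configs))) {
    configs <- list(as_config(configs))
  }
  fidelity <- fidelity %||% exp(object$lf_max)
  Xc <- t(vapply(configs, function(cfg) to_unit_vector(object$space, cfg),
                 numeric(encoding_dim(object$space))))
  if (encoding_dim(object$space) == 1L) Xc <- matrix(Xc, ncol = 1L)
  fcol <- rep(encode_fidelity(object$lf_min, object$lf_max, fidelity),
              length.out = nrow(Xc))
  surrogate_predict_units(object, cbind(Xc, fcol))
}

#' @method glance genarch_surrogate
#' @export
glance.genarch_surrogate <- function(x, ...) {
  tibble::tibble(n_obs = nrow(x$X), constant = x$constant,
                 length_scale = x$ell %||% NA_real_,
                 signal_var = x$sf2 %||% NA_real_,
                 noise_var = x$sn2 %||% NA_real_)
}

new_mbo_state <- function(space, records, current_fidelity, q = 3L) {
  structure(list(space = space, records = records,
                 current_fidelity = current_fidelity, q = q),
            class = "genarch_mbo")
}

empty_records <- function() {
  tibble::tibble(config = list(), fidelity = numeric(), objective = numeric(),
                 origin = character(), iteration = integer(), trace = list())
}

#' Propose a batch of configurations by qUCB
#'
#' Draws one exploration weight `lambda` per proposal from an exponential
#' distribution (rate 1 by default) and, for each, maximizes the upper
#' confidence bound `mean + lambda * sd` over the unit cube by random search
#' (1000 candidates) followed by coordinate-wise refinement of the best
#' candidates. Different lambdas make different exploration-exploitation
#' trade-offs, which is what makes the batch diverse; decoded duplicates are
#' re-drawn.
#'
#' @param state A `genarch_mbo` state (provides space and current fidelity).
#' @param surrogate A fitted `genarch_surrogate`.
#' @param q Number of proposals (>= 1).
#' @param seed Optional integer seed; fixed seed gives identical proposals.
#' @param rate Rate of the exponential distribution for `lambda`.
#' @param n_candidates Random-search budget per proposal.
#' @return A list of `q` configurations (named lists).
#' @export
propose_batch <- function(state, surrogate, q = state$q, seed = NULL, rate = 1,
                          n_candidates = 1000L) {
  stopifnot(inherits(state, "genarch_mbo"), inherits(surrogate, "genarch_surrogate"),
            q >= 1)
  space <- state$space
  d <- encoding_dim(space)
  fcoord <- encode_fidelity(surrogate$lf_min, surrogate$lf_max,
                            state$current_fidelity)
  optimize_one <- function(lambda) {
    U <- matrix(stats::runif(n_candidates * d), n_candidates, d)
    pr <- surrogate_predict_units(surrogate, cbind(U, rep(fcoord, n_candidates)))
    sc <- pr$mean + lambda * pr$sd
    top <- order(sc, decreasing = TRUE)[seq_len(min(10L, n_candidates))]
    best_u <- U[top[1], ]; best_s <- sc[top[1]]
    grid <- seq(0, 1, length.out = 11L)
    for (t in top) {
      u <- U[t, ]
      for (sweep_i in 1:2) {
        for (k in seq_len(d)) {
          Cand <- matrix(rep(u, each = length(grid)), length(grid), d)
          Cand[, k] <- grid
          prk <- surrogate_predict_units(surrogate,
                                         cbind(Cand, rep(fcoord, nrow(Cand))))
          sck <- prk$mean + lambda * prk$sd
          j <- which.max(sck)
          u[k] <- grid[j]
        }
      }
      pru <- surrogate_predict_units(surrogate, matrix(c(u, fcoord), 1L))
      su <- pru$mean + lambda * pru$sd
      if (su > best_s) { best_s <- su; best_u <- u }
    }
    best_u
  }
  run <- function() {
    out <- list()
    keys <- character(0)
    tries <- 0L
    while (length(out) < q && tries < q + 10L) {
      tries <- tries + 1L
      lambda <- stats::rexp(1, rate = rate)
      cfg <- from_unit_vector(space, optimize_one(lambda))
      key <- paste(vapply(cfg, function(v) format(v, digits = 10), character(1)),
                   collapse = "|")
      if (!key %in% keys) {
        keys <- c(keys, key)
        out[[length(out) + 1L]] <- cfg
      }
    }
    while (length(out) < q) {
      cfg <- as_config(sample_configs(space, 1L))
      out[[length(out) + 1L]] <- cfg
    }
    out
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Run model-based optimization
#'
#' Evaluates a space-filling (Latin hypercube) initial design, then iterates:
#' fit the surrogate on all records, propose `q` configurations by
#' [propose_batch()], evaluate each at the current fidelity, append. Failed
#' objective evaluations score 0 (with a logged diagnostic) so a long search
#' survives individual build or training failures.
#'
#' @param objective_fn Function `(config, fidelity) -> objective in [0, 1]`,
#'   or `-> list(objective =, trace =)` to store the validation trace.
#' @param space A `genarch_space`.
#' @param iterations Number of proposal batches (>= 0).
#' @param q Proposals per batch.
#' @param init_design Size of the initial design; default
#'   `max(8, 4 * n_numeric_dims)`. Skipped when `warm_records` supplies at
#'   least 2 records.
#' @param fidelity Training budget (abstract units: steps or wall-seconds)
#'   passed to `objective_fn` and recorded with each evaluation.
#' @param seed Integer seed governing the whole run (design, proposals, and
#'   any randomness inside `objective_fn`).
#' @param warm_records Records from a lower-fidelity run (a records tibble or
#'   a `genarch_mbo` state, e.g. from [warm_start()]); carried into the
#'   surrogate with their fidelity coordinates preserved.
#' @return A `genarch_mbo` state holding the full evaluation history.
#' @export
run_mbo <- function(objective_fn, space, iterations, q = 3L, init_design = NULL,
                    fidelity = 1, seed = 1L, warm_records = NULL) {
  stopifnot(iterations >= 0, q >= 1, fidelity > 0)
  if (inherits(warm_records, "genarch_mbo")) warm_records <- warm_records$records
  records <- if (is.null(warm_records)) empty_records() else warm_records
  n_warm <- nrow(records)
  eval_one <- function(cfg, origin, iter) {
    res <- tryCatch(objective_fn(cfg, fidelity), error = function(e) {
      message(sprintf("objective evaluation failed (%s); scoring 0",
                      conditionMessage(e)))
      list(objective = 0, trace = NULL)
    })
    if (!is.list(res)) res <- list(objective = res, trace = NULL)
    obj <- res$objective
    if (!is.finite(obj)) obj <- 0
    obj <- min(max(obj, 0), 1)
    tibble::tibble(config = list(cfg), fidelity = fidelity, objective = obj,
                   origin = origin, iteration = iter,
                   trace = list(res$trace))
  }
  withr::with_seed(seed, {
    if (n_warm < 2L) {
      n_num <- sum(vapply(space$defs, function(d) d$kind %in% c("float", "integer"),
                          logical(1)))
      n_init <- init_design %||% max(8L, 4L * n_num)
      if (n_init < 2L) {
        rlang::abort("init_design must be >= 2 when no warm records are supplied")
      }
      d <- encoding_dim(space)
      U <- lhs::randomLHS(n_init, d)
      for (i in seq_len(n_init)) {
        cfg <- from_unit_vector(space, U[i, ])
        records <- dplyr::bind_rows(records, eval_one(cfg, "init", 0L))
      }
    }
    state <- new_mbo_state(space, records, fidelity, q)
    for (it in seq_len(iterations)) {
      sur <- fit_surrogate(state$records, space)
      props <- propose_batch(state, sur, q = q)
      for (cfg in props) {
        state$records <- dplyr::bind_rows(state$records,
                                          eval_one(cfg, "propose", it))
      }
    }
    state
  })
}

#' Warm-start a higher-fidelity optimization stage
#'
#' Returns a new optimization state at the increased training budget carrying
#' every previous record (fidelity coordinates preserved), so the next
#' [run_mbo()] stage refits the surrogate on all of them and skips the initial
#' design: the cheap evaluations steer where the expensive ones go.
#'
#' @param previous_state A `genarch_mbo` state.
#' @param new_fidelity New training budget; must exceed the previous one.
#' @return A `genarch_mbo` state.
#' @export
warm_start <- function(previous_state, new_fidelity) {
  stopifnot(inherits(previous_state, "genarch_mbo"))
  if (new_fidelity <= previous_state$current_fidelity) {
    rlang::abort("new_fidelity must exceed the previous fidelity")
  }
  new_mbo_state(previous_state$space, previous_state$records, new_fidelity,
                previous_state$q)
}

#' Extract the scalar objective from a validation trace
#'
#' Phase 1 (short training budget) uses the highest balanced accuracy seen
#' anywhere in the trace. Phase 2 (long budget) uses the *second*-highest
#' value among the last 20 validation evaluations, which avoids rewarding
#' models whose noisy training produced a single outlier; a window with fewer
#' than 2 entries falls back to its maximum.
#'
#' @param trace A validation trace (tibble with a `balanced_accuracy` column)
#'   or a numeric vector of accuracies.
#' @param phase 1 or 2.
#' @return Objective value in `[0, 1]`.
#' @export
extract_objective <- function(trace, phase = 1) {
  acc <- if (is.data.frame(trace)) trace$balanced_accuracy else as.numeric(trace)
  if (length(acc) == 0L) rlang::abort("validation trace is empty")
  stopifnot(phase %in% c(1, 2))
  if (phase == 1) return(max(acc))
  w <- utils::tail(acc, 20L)
  if (length(w) < 2L) return(max(w))
  sort(w, decreasing = TRUE)[2]
}

#' Best configuration of an optimization state
#'
#' @param state A `genarch_mbo` state.
#' @param fidelity Optional: restrict to records at this fidelity.
#' @return A list with `config`, `objective`, `fidelity`.
#' @export
best_config <- function(state, fidelity = NULL) {
  rec <- state$records
  if (!is.null(fidelity)) rec <- dplyr::filter(rec, .data$fidelity == !!fidelity)
  i <- which.max(rec$objective)
  list(config = rec$config[[i]], objective = rec$objective[i],
       fidelity = rec$fidelity[i])
}

#' @export
print.genarch_mbo <- function(x, ...) {
  cat(sprintf("<genarch_mbo> %d evaluations, current fidelity %g, best objective %.4f\n",
              nrow(x$records), x$current_fidelity,
              if (nrow(x$records)) max(x$records$objective) else NA_real_))
  invisible(x)
}

#' Tidy an optimization state into one row per evaluation
#'
#' @param x A `genarch_mbo` state.
#' @param ... Unused.
#' @return A tibble with the hyperparameter columns plus `fidelity`,
#'   `objective`, `origin`, `iteration`.
#' @method tidy genarch_mbo
#' @export
tidy.genarch_mbo <- function(x, ...) {
  cfgs <- dplyr::bind_rows(lapply(x$records$config, tibble::as_tibble))
  dplyr::bind_cols(cfgs,
                   x$records[, c("fidelity", "objective", "origin", "iteration")])
}

#' One-row summary of an optimization state
#'
#' @param x A `genarch_mbo` state.
#' @param ... Unused.
#' @return A tibble with evaluation counts and the best objective per run.
#' @method glance genarch_mbo
#' @export
glance.genarch_mbo <- function(x, ...) {
  tibble::tibble(n_evaluations = nrow(x$records),
                 n_fidelities = length(unique(x$records$fidelity)),
                 current_fidelity = x$current_fidelity,
                 best_objective = if (nrow(x$records)) max(x$records$objective) else NA_real_)
}

#' Plot optimization progress
#'
#' Objective value against evaluation index, coloured by fidelity, with the
#' running best overlaid.
#'
#' @param object A `genarch_mbo` state.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot genarch_mbo
#' @export
autoplot.genarch_mbo <- function(object, ...) {
  df <- tibble::tibble(eval = seq_len(nrow(object$records)),
                       objective = object$records$objective,
                       fidelity = factor(object$records$fidelity))
  df$running_best <- cummax(df$objective)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eval, y = .data$objective)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$fidelity)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$running_best), linetype = 2) +
    ggplot2::labs(x = "evaluation", y = "validation balanced accuracy",
                  colour = "fidelity") +
    ggplot2::theme_minimal()
}
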