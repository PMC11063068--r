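# Budgeted training: validation cadence, plateau-based learning-rate halving,
# early stopping, and the largest-fitting-batch search.

#' Find the largest usable batch size
#'
#' Binary search (O(log cap) probes) for the largest batch size the `fits`
#' probe accepts, then a 10% safety margin is subtracted (floor, minimum 1) to
#' avoid failures near the memory boundary.
#'
#' @param fits Monotone predicate `function(batch_size) -> TRUE/FALSE`
#'   (accepting `b` implies accepting every smaller size).
#' @param cap Upper bound on the search (>= 1).
#' @return Integer batch size.
#' @examples
#' find_max_batch_size(function(b) b <= 1000, cap = 4096)  # 900
#' @export
find_max_batch_size <- function(fits, cap) {
  stopifnot(is.function(fits), cap >= 1)
  cap <- as.integer(cap)
  if (!isTRUE(fits(1L))) {
    rlang::abort("even batch size 1 does not fit", class = "genarch_cannot_fit")
  }
  if (isTRUE(fits(cap))) {
    largest <- cap
  } else {
    lo <- 1L; hi <- cap
    while (hi - lo > 1L) {
      mid <- lo + (hi - lo) %/% 2L
      if (isTRUE(fits(mid))) lo <- mid else hi <- mid
    }
    largest <- lo
  }
  max(1L, as.integer(floor(0.9 * largest)))
}

trace_accuracies <- function(trace) {
  if (is.data.frame(trace)) trace$balanced_accuracy else as.numeric(trace)
}

#' Plateau-based learning-rate schedule
#'
#' Replays the validation trace and halves the learning rate every time 3
#' consecutive evaluations fail to exceed the best balanced accuracy seen
#' before them; the stagnation counter resets after a halving (the running
#' best does not). Returns the learning rate the *next* training interval
#' should use.
#'
#' @param trace A validation trace (tibble with `balanced_accuracy` and
#'   `learning_rate` columns, or a numeric accuracy vector with
#'   `initial_lr` supplied).
#' @param initial_lr Learning rate before the first halving; defaults to the
#'   trace's first recorded rate.
#' @param patience Number of consecutive non-improving evaluations that
#'   trigger a halving.
#' @return The next learning rate.
#' @export
schedule_lr <- function(trace, initial_lr = NULL, patience = 3L) {
  acc <- trace_accuracies(trace)
  if (length(acc) == 0L) rlang::abort("validation trace is empty")
  lr <- initial_lr %||%
    (if (is.data.frame(trace)) trace$learning_rate[1] else
       rlang::abort("initial_lr required when trace is a bare accuracy vector"))
  best <- -Inf
  counter <- 0L
  for (a in acc) {
    if (a > best) {
      best <- a
      counter <- 0L
    } else {
      counter <- counter + 1L
      if (counter == patience) {
        lr <- lr / 2
        counter <- 0L
      }
    }
  }
  lr
}

#' Early-stopping rule
#'
#' `TRUE` iff the last `patience` (default 10) validation evaluations each
#' failed to improve the running-best balanced accuracy.
#'
#' @inheritParams schedule_lr
#' @param patience Consecutive non-improving evaluations that stop training.
#' @return Logical flag.
#' @export
should_stop <- function(trace, patience = 10L) {
  acc <- trace_accuracies(trace)
  if (length(acc) < patience) return(FALSE)
  best <- -Inf
  counter <- 0L
  for (a in acc) {
    if (a > best) {
      best <- a
      counter <- 0L
    } else {
      counter <- counter + 1L
    }
  }
  counter >= patience
}

#' Specify a training budget
#'
#' @param amount Budget size: number of training steps (`mode = "steps"`) or
#'   wall-clock seconds (`mode = "time"`, translated to steps via a timed
#'   warm-up step so the validation cadence stays hardware-independent).
#' @param mode `"steps"` or `"time"`.
#' @param target_validation_evals Approximate number of validation evaluations
#'   to spread over the budget (about 20 in a short first search phase, about
#'   100 in the longer second phase).
#' @return A `genarch_budget` list.
#' @export
train_budget <- function(amount, mode = c("steps", "time"),
                         target_validation_evals = 20L) {
  mode <- match.arg(mode)
  stopifnot(amount > 0, target_validation_evals >= 1)
  structure(list(mode = mode, amount = amount,
                 target_validation_evals = as.integer(target_validation_evals)),
            class = "genarch_budget")
}

#' Train a model under a budget
#'
#' Trains with the model's gradient-descent algorithm and multi-class
#' cross-entropy, validating every `budget$amount / target_validation_evals`
#' steps on batches drawn from the validation stream. After each validation
#' the learning rate is updated by [schedule_lr()] and training stops early
#' when [should_stop()] fires. A non-finite loss aborts with the trace
#' collected so far (carried in a warning).
#'
#' @param model A `genarch_model` from [instantiate()].
#' @param train_stream Generator from [new_batch_stream()] over the training
#'   role.
#' @param val_stream Generator over the validation role (its own seed, same
#'   sampling semantics as training).
#' @param budget A `genarch_budget`.
#' @param val_batches Validation batches drawn per evaluation (the validation
#'   subsample).
#' @return A `genarch_trace` tibble with columns `samples_seen`,
#'   `balanced_accuracy`, `learning_rate`.
#' @export
train_with_budget <- function(model, train_stream, val_stream, budget,
                              val_batches = 2L) {
  stopifnot(inherits(model, "genarch_model"), inherits(budget, "genarch_budget"))
  steps <- if (budget$mode == "steps") {
    as.integer(budget$amount)
  } else {
    warm <- train_stream()
    t0 <- proc.time()[["elapsed"]]
    fit_one_step(model, warm$one_hot, warm$labels)
    dt <- max(proc.time()[["elapsed"]] - t0, 1e-4)
    max(1L, as.integer(floor(budget$amount / dt)))
  }
  cadence <- max(1L, steps %/% budget$target_validation_evals)
  initial_lr <- model$lr
  trace <- tibble::tibble(samples_seen = integer(), balanced_accuracy = numeric(),
                          learning_rate = numeric())
  samples_seen <- 0L
  validate <- function() {
    k <- NULL
    conf <- NULL
    for (i in seq_len(val_batches)) {
      vb <- val_stream()
      if (is.null(conf)) {
        k <- length(vb$classes)
        conf <- matrix(0L, k, k)
      }
      P <- predict(model, vb$one_hot)
      pred <- max.col(P, ties.method = "first")
      for (j in seq_along(vb$labels)) {
        conf[vb$labels[j], pred[j]] <- conf[vb$labels[j], pred[j]] + 1L
      }
    }
    class_balanced_accuracy(conf)
  }
  for (s in seq_len(steps)) {
    b <- train_stream()
    loss <- fit_one_step(model, b$one_hot, b$labels)
    samples_seen <- samples_seen + length(b$labels)
    if (!is.finite(loss)) {
      warning(sprintf("non-finite loss at step %d; aborting training", s))
      break
    }
    if (s %% cadence == 0L) {
      acc <- validate()
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        samples_seen = samples_seen, balanced_accuracy = acc,
        learning_rate = model$lr))
      model$lr <- schedule_lr(trace, initial_lr = initial_lr)
      if (should_stop(trace)) break
    }
  }
  class(trace) <- c("genarch_trace", class(trace))
  trace
}

#' Plot a validation trace
#'
#' Balanced accuracy over samples seen, with the learning-rate schedule on a
#' secondary panel-like colour scale.
#'
#' @param object A `genarch_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot genarch_trace
#' @export
autoplot.genarch_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$samples_seen,
                                       y = .data$balanced_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$learning_rate))) +
    ggplot2::labs(x = "training samples seen", y = "validation balanced accuracy",
                  colour = "learning rate") +
    ggplot2::theme_minimal()
}
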