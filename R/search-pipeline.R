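# High-level glue: the two-phase (multi-fidelity) architecture search over a
# dataset manifest, and final training of the selected configuration.

#' Objective function over a dataset manifest
#'
#' Returns the `(config, fidelity) -> objective` closure used by
#' [run_architecture_search()]: build the plan, instantiate it, train for
#' `fidelity` steps with class-balanced batches, and score the validation
#' trace with [extract_objective()]. Configurations whose plans cannot be
#' built (e.g. a dilated kernel exceeding the remaining sequence length)
#' raise, which [run_mbo()] records as objective 0.
#'
#' @param manifest Dataset manifest tibble (`class_name`, `file`, `role`).
#' @param space A `genarch_space` (provides L and conditioning).
#' @param batch_size Training batch size (divisible by the class count).
#' @param phase Objective-extraction phase passed to [extract_objective()].
#' @param target_validation_evals Validation evaluations spread over the
#'   budget.
#' @param val_batches Validation batches per evaluation.
#' @return A function `(config, fidelity) -> list(objective, trace)`.
#' @export
manifest_objective <- function(manifest, space, batch_size = 24L, phase = 1,
                               target_validation_evals = 6L, val_batches = 3L) {
  train <- manifest[manifest$role == "train", ]
  val <- manifest[manifest$role == "validation", ]
  n_classes <- length(unique(manifest$class_name))
  function(config, fidelity) {
    plan <- build_plan(config, space, n_classes = n_classes)
    seed_model <- sample.int(.Machine$integer.max, 1L)
    seed_train <- sample.int(.Machine$integer.max, 1L)
    model <- instantiate(plan, seed = seed_model)
    ts <- new_batch_stream(train, space$sequence_length, batch_size,
                           seed = seed_train)
    vs <- new_batch_stream(val, space$sequence_length, batch_size,
                           seed = seed_train + 1L)
    trace <- train_with_budget(model, ts, vs,
                               train_budget(fidelity, "steps",
                                            target_validation_evals),
                               val_batches = val_batches)
    if (nrow(trace) == 0L) return(list(objective = 0, trace = trace))
    list(objective = extract_objective(trace, phase = phase), trace = trace)
  }
}

#' Run a two-phase architecture search
#'
#' The full loop: model-based optimization at a short training budget `t1`
#' (objective: best validation balanced accuracy anywhere in the trace), then
#' a warm-started continuation at the longer budget `t2` (objective:
#' second-highest of the last 20 validation evaluations), where the surrogate
#' carries every `t1` record. Finally the best configuration found at `t2`
#' (falling back to the overall best) is returned.
#'
#' @param manifest Dataset manifest tibble (`class_name`, `file`, `role`).
#' @param space A `genarch_space` from [define_search_space()].
#' @param phase_budgets Length-2 numeric: training steps per evaluation in
#'   phase 1 and phase 2 (`t2 > t1`).
#' @param iterations Length-2 integer: proposal batches per phase.
#' @param q Configurations proposed simultaneously per batch.
#' @param init_design Initial-design size for phase 1.
#' @param batch_size Training batch size.
#' @param seed Integer seed governing the whole search.
#' @param target_validation_evals Length-2: validation evaluations per phase.
#' @return A list with `state` (final `genarch_mbo` with both phases'
#'   records), `best` (config/objective/fidelity), `phase_budgets`.
#' @export
run_architecture_search <- function(manifest, space, phase_budgets = c(40, 120),
                                    iterations = c(3L, 3L), q = 3L,
                                    init_design = 8L, batch_size = 24L,
                                    seed = 1L,
                                    target_validation_evals = c(6L, 12L)) {
  stopifnot(length(phase_budgets) == 2L, phase_budgets[2] > phase_budgets[1])
  obj1 <- manifest_objective(manifest, space, batch_size, phase = 1,
                             target_validation_evals = target_validation_evals[1])
  st1 <- run_mbo(obj1, space, iterations = iterations[1], q = q,
                 init_design = init_design, fidelity = phase_budgets[1],
                 seed = seed)
  # the longer phase scores on a larger validation subsample: its objective
  # decides the final selection, so estimate noise matters more here
  obj2 <- manifest_objective(manifest, space, batch_size, phase = 2,
                             target_validation_evals = target_validation_evals[2],
                             val_batches = 4L)
  st2 <- run_mbo(obj2, space, iterations = iterations[2], q = q,
                 fidelity = phase_budgets[2], seed = seed + 1L,
                 warm_records = warm_start(st1, phase_budgets[2]))
  high <- st2$records[st2$records$fidelity == phase_budgets[2], ]
  ranked <- if (nrow(high) && max(high$objective) > 0) {
    high[order(high$objective, decreasing = TRUE), ]
  } else {
    st2$records[order(st2$records$objective, decreasing = TRUE), ]
  }
  keys <- vapply(ranked$config, function(cfg) {
    paste(format(unlist(cfg), digits = 10), collapse = "|")
  }, character(1))
  ranked <- ranked[!duplicated(keys), ]
  best <- list(config = ranked$config[[1]], objective = ranked$objective[1],
               fidelity = ranked$fidelity[1])
  list(state = st2, best = best,
       top_configs = ranked$config[seq_len(min(3L, nrow(ranked)))],
       phase_budgets = phase_budgets)
}

#' Train the selected configuration(s) and evaluate on the test split
#'
#' Retrains one or several candidate configurations from scratch. When given
#' several (e.g. `$top_configs` from [run_architecture_search()]), each is
#' trained and scored on the *validation* split (deterministic enumeration of
#' all validation windows), and only the winner is evaluated on the test
#' split. Re-scoring retrained candidates on held-out validation data guards
#' against the winner's curse: the search's objective is a noisy,
#' selection-biased estimate, so the single top-scoring record is not always
#' the configuration that retrains best.
#'
#' @param config A configuration, or a list of candidate configurations.
#' @param space The `genarch_space` it belongs to.
#' @param manifest Dataset manifest tibble.
#' @param steps Training steps for the final fit.
#' @param batch_size Training batch size.
#' @param seed Integer seed.
#' @param target_validation_evals Validation cadence of the final fit.
#' @return A list with `model`, `trace`, `confusion`, `balanced_accuracy`
#'   (test), `validation_accuracy`, `selected` (index of the winning
#'   candidate), and `candidates` (per-candidate validation accuracies).
#' @export
train_final_model <- function(config, space, manifest, steps = 400L,
                              batch_size = 24L, seed = 1L,
                              target_validation_evals = 20L) {
  configs <- if (!is.null(names(config))) list(config) else config
  stopifnot(length(configs) >= 1L)
  classes <- unique(manifest$class_name)
  L <- space$sequence_length
  val_tbl <- iterate_test_samples(manifest[manifest$role == "validation", ], L)
  if (nrow(val_tbl) > 600L) {
    # deterministic thinning keeps candidate scoring cheap on large splits
    val_tbl <- val_tbl[unique(round(seq(1L, nrow(val_tbl), length.out = 600L))), ]
  }
  fits <- vector("list", length(configs))
  val_acc <- numeric(length(configs))
  for (i in seq_along(configs)) {
    plan <- build_plan(configs[[i]], space, n_classes = length(classes))
    model <- instantiate(plan, seed = seed + 10L * i)
    ts <- new_batch_stream(manifest[manifest$role == "train", ], L, batch_size,
                           seed = seed + 10L * i + 1L)
    vs <- new_batch_stream(manifest[manifest$role == "validation", ], L,
                           batch_size, seed = seed + 10L * i + 2L)
    trace <- train_with_budget(model, ts, vs,
                               train_budget(steps, "steps",
                                            target_validation_evals),
                               val_batches = 3L)
    val_acc[i] <- evaluate_model(model, val_tbl, L,
                                 classes = classes)$balanced_accuracy
    fits[[i]] <- list(model = model, trace = trace)
  }
  sel <- which.max(val_acc)
  test_tbl <- iterate_test_samples(manifest[manifest$role == "test", ], L)
  ev <- evaluate_model(fits[[sel]]$model, test_tbl, L, classes = classes)
  list(model = fits[[sel]]$model, trace = fits[[sel]]$trace,
       confusion = ev$confusion, balanced_accuracy = ev$balanced_accuracy,
       validation_accuracy = val_acc[sel], selected = sel,
       candidates = val_acc)
}
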