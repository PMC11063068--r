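# Hyperparameter definitions and the genomics search space.

#' Hyperparameter definitions
#'
#' Constructors for the typed hyperparameter definitions a [search space][define_search_space]
#' is made of. Numeric kinds carry an ordered `(lower, upper)` bound pair and an
#' optional log-scale flag (sampling and encoding then operate on the log
#' scale); categorical kinds carry a duplicate-free value set.
#'
#' @param name Hyperparameter identifier.
#' @param lower,upper Bounds for numeric kinds (`lower <= upper`; equal bounds
#'   give a degenerate, collapsed range).
#' @param values Character vector of allowed values (categorical).
#' @param log_scale Optimize on a logarithmic scale? Requires positive bounds.
#' @param component Which model component the hyperparameter controls
#'   (`"general"`, `"conv"`, `"dense"`, `"rnn"`, `"gap"`).
#' @param families Model families (`"gap"`, `"rnn"`) the definition applies to.
#' @return An object of class `hp_def`.
#' @examples
#' hp_float("learning_rate", 1e-6, 1e-2, log_scale = TRUE)
#' hp_cat("optimizer", c("adam", "adagrad", "rmsprop", "sgd"))
#' @name hp_def
NULL

new_hp_def <- function(name, kind, lower = NULL, upper = NULL, values = NULL,
                       log_scale = FALSE, component = "general",
                       families = c("gap", "rnn")) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  component <- match.arg(component, c("general", "conv", "dense", "rnn", "gap"))
  families <- match.arg(families, c("gap", "rnn"), several.ok = TRUE)
  if (kind %in% c("float", "integer")) {
    stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1L,
              length(upper) == 1L, is.finite(lower), is.finite(upper))
    if (lower > upper) {
      rlang::abort(sprintf("'%s': lower bound (%g) exceeds upper bound (%g)",
                           name, lower, upper))
    }
    if (log_scale && lower <= 0) {
      rlang::abort(sprintf("'%s': log scale requires strictly positive bounds", name))
    }
  } else {
    lower <- upper <- NULL
  }
  if (kind == "categorical") {
    stopifnot(is.character(values), length(values) >= 1L)
    if (anyDuplicated(values)) {
      rlang::abort(sprintf("'%s': categorical value set has duplicates", name))
    }
  }
  if (kind == "boolean") values <- c(FALSE, TRUE)
  structure(
    list(name = name, kind = kind, lower = lower, upper = upper,
         values = values, log_scale = isTRUE(log_scale),
         component = component, families = families),
    class = "hp_def"
  )
}

#' @rdname hp_def
#' @export
hp_float <- function(name, lower, upper, log_scale = FALSE,
                     component = "general", families = c("gap", "rnn")) {
  new_hp_def(name, "float", lower, upper, log_scale = log_scale,
             component = component, families = families)
}

#' @rdname hp_def
#' @export
hp_int <- function(name, lower, upper, component = "general",
                   families = c("gap", "rnn")) {
  stopifnot(lower == round(lower), upper == round(upper))
  new_hp_def(name, "integer", lower, upper, component = component,
             families = families)
}

#' @rdname hp_def
#' @export
hp_bool <- function(name, component = "general", families = c("gap", "rnn")) {
  new_hp_def(name, "boolean", component = component, families = families)
}

#' @rdname hp_def
#' @export
hp_cat <- function(name, values, component = "general",
                   families = c("gap", "rnn")) {
  new_hp_def(name, "categorical", values = values, component = component,
             families = families)
}

#' Build a search space from hyperparameter definitions
#'
#' Low-level constructor used both by [define_search_space()] and by tests that
#' need small custom spaces (e.g. two-dimensional toy objectives for the
#' optimizer).
#'
#' @param defs List of [hp_def] objects; names must be unique.
#' @param sequence_length Input sequence length in nucleotides (may be `NA` for
#'   abstract spaces).
#' @param model_family `"gap"`, `"rnn"`, or `NA` for abstract spaces.
#' @param residual Whether residual (shortcut) convolutional blocks are used.
#'   Model family and the residual flag are run-level conditioning constants,
#'   not searched dimensions: the crossed design optimizes each combination in
#'   an independent run.
#' @return An object of class `genarch_space`.
#' @export
new_search_space <- function(defs, sequence_length = NA_real_,
                             model_family = NA_character_, residual = FALSE) {
  stopifnot(is.list(defs), all(vapply(defs, inherits, logical(1), "hp_def")))
  nms <- vapply(defs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) rlang::abort("duplicate hyperparameter names in space")
  names(defs) <- nms
  structure(
    list(defs = defs, sequence_length = sequence_length,
         model_family = model_family, residual = isTRUE(residual)),
    class = "genarch_space"
  )
}

#' @export
print.genarch_space <- function(x, ...) {
  cat(sprintf("<genarch_space> %d hyperparameters (L = %s, family = %s, residual = %s)\n",
              length(x$defs), format(x$sequence_length), x$model_family, x$residual))
  for (d in x$defs) {
    rng <- if (d$kind %in% c("float", "integer")) {
      sprintf("[%g, %g]%s", d$lower, d$upper, if (d$log_scale) " (log)" else "")
    } else {
      paste0("{", paste(d$values, collapse = ", "), "}")
    }
    cat(sprintf("  %-22s %-11s %s\n", d$name, d$kind, rng))
  }
  invisible(x)
}

#' Define the genomic architecture search space
#'
#' Returns the reference hyperparameter space over convolutional, embedding
#' (global-average-pooling or recurrent) and fully connected stages of a DNA
#' sequence classifier. Ranges follow the published reference space; the upper
#' bounds of the last-layer dilation factor and the total max-pooling factor
#' depend on sequence length (`2^4` for reads up to 250 nt, `2^7` for long
#' contigs), since longer inputs both allow and require more aggressive
#' downsampling.
#'
#' The model family (`gap` vs `rnn`) and the residual-block flag are *not*
#' searched dimensions: they condition the space (e.g. the skip ratio only
#' exists for the GAP family) and the optimization is run separately for each
#' combination, in a fully crossed design.
#'
#' @param sequence_length Input length L in nucleotides (>= 16, so the smallest
#'   admissible kernel fits).
#' @param model_family `"gap"` (convolutions summarized by global average
#'   pooling) or `"rnn"` (convolutions followed by a recurrent stack).
#' @param residual Use residual convolutional blocks?
#' @param overrides Optional named list of per-hyperparameter range overrides:
#'   a `c(lower, upper)` pair for numeric entries or a character vector of
#'   values for categorical ones. Used e.g. by [desk_profile()] to scale the
#'   space down for CPU-only runs.
#' @return A `genarch_space`.
#' @examples
#' sp <- define_search_space(150, "gap", residual = FALSE)
#' sp$defs$max_pooling_end$upper   # 16 for read-length input
#' @export
define_search_space <- function(sequence_length,
                                model_family = c("gap", "rnn"),
                                residual = FALSE,
                                overrides = list()) {
  model_family <- match.arg(model_family)
  stopifnot(is.numeric(sequence_length), length(sequence_length) == 1L)
  if (sequence_length < 16) {
    rlang::abort("sequence_length must be >= 16 (the minimum first-layer kernel size)")
  }
  dp_upper <- if (sequence_length <= 250) 2^4 else 2^7
  defs <- list(
    hp_float("learning_rate", 1e-6, 1e-2, log_scale = TRUE),
    hp_bool("reverse_complement"),
    hp_cat("optimizer", c("adam", "adagrad", "rmsprop", "sgd")),
    hp_int("n_conv_layers", 1, 20, component = "conv"),
    hp_int("n_conv_blocks", 1, 10, component = "conv"),
    hp_float("kernel_size_0", 2^4, 2^11, log_scale = TRUE, component = "conv"),
    hp_float("kernel_size_end", 2^4, 2^11, log_scale = TRUE, component = "conv"),
    hp_float("filters_0", 2^1, 2^6, log_scale = TRUE, component = "conv"),
    hp_float("filters_end", 2^1, 2^6, log_scale = TRUE, component = "conv"),
    hp_float("dilation_end", 1, dp_upper, log_scale = TRUE, component = "conv"),
    hp_float("max_pooling_end", 1, dp_upper, log_scale = TRUE, component = "conv"),
    hp_float("batchnorm_momentum", 0, 0.99, component = "conv"),
    hp_float("leaky_relu_alpha", 0, 1, component = "conv"),
    hp_int("n_dense_layers", 0, 5, component = "dense"),
    hp_float("dense_units", 2^4, 2^11, log_scale = TRUE, component = "dense"),
    hp_float("dense_dropout", 0, 0.99, component = "dense"),
    hp_cat("dense_activation", c("relu", "tanh", "sigmoid"), component = "dense"),
    hp_cat("recurrent_type", c("lstm", "gru"), component = "rnn", families = "rnn"),
    hp_int("n_recurrent_layers", 1, 3, component = "rnn", families = "rnn"),
    hp_bool("bidirectional", component = "rnn", families = "rnn"),
    hp_float("recurrent_units", 2^4, 2^11, log_scale = TRUE, component = "rnn",
             families = "rnn"),
    hp_float("skip_ratio", 0, 1, component = "gap", families = "gap")
  )
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  for (nm in names(overrides)) {
    if (!nm %in% names(defs)) {
      rlang::abort(sprintf("override for unknown hyperparameter '%s'", nm))
    }
    d <- defs[[nm]]
    ov <- overrides[[nm]]
    if (d$kind %in% c("float", "integer")) {
      stopifnot(is.numeric(ov), length(ov) == 2L)
      defs[[nm]] <- new_hp_def(d$name, d$kind, ov[[1]], ov[[2]],
                               log_scale = d$log_scale, component = d$component,
                               families = d$families)
    } else if (d$kind == "categorical") {
      stopifnot(is.character(ov), all(ov %in% d$values))
      defs[[nm]] <- new_hp_def(d$name, "categorical", values = ov,
                               component = d$component, families = d$families)
    } else {
      rlang::abort(sprintf("cannot override boolean hyperparameter '%s'", nm))
    }
  }
  defs <- defs[vapply(defs, function(d) model_family %in% d$families, logical(1))]
  new_search_space(defs, sequence_length = sequence_length,
                   model_family = model_family, residual = residual)
}

# --- transforms -------------------------------------------------------------

hp_fwd <- function(def, x) if (def$log_scale) log(x) else x
hp_inv <- function(def, t) if (def$log_scale) exp(t) else t

round_half_up <- function(x) floor(x + 0.5)

#' Sample hyperparameter configurations
#'
#' Draws `n` configurations uniformly at random from the space: numeric
#' hyperparameters uniformly on their (log-transformed where flagged) scale,
#' integers uniformly over their range, booleans and categoricals uniformly
#' over their value sets.
#'
#' @param space A `genarch_space`.
#' @param n Number of configurations (>= 1).
#' @param seed Optional integer seed; a fixed seed makes the draw reproducible.
#' @return A tibble with one row per configuration and one column per
#'   hyperparameter.
#' @examples
#' sp <- define_search_space(150, "gap")
#' sample_configs(sp, 3, seed = 1)
#' @export
sample_configs <- function(space, n, seed = NULL) {
  stopifnot(inherits(space, "genarch_space"), n >= 1)
  draw <- function() {
    cols <- lapply(space$defs, function(d) {
      switch(d$kind,
        float = {
          lo <- hp_fwd(d, d$lower); hi <- hp_fwd(d, d$upper)
          # clamp guards against exp(log(x)) roundoff at the bounds
          pmin(pmax(hp_inv(d, stats::runif(n, lo, hi)), d$lower), d$upper)
        },
        integer = d$lower + sample.int(d$upper - d$lower + 1L, n, replace = TRUE) - 1L,
        boolean = sample(c(FALSE, TRUE), n, replace = TRUE),
        categorical = {
          if (length(d$values) == 1L) rep(d$values, n)
          else sample(d$values, n, replace = TRUE)
        }
      )
    })
    tibble::as_tibble(cols)
  }
  if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
}

#' Coerce a configuration to a named list
#'
#' Accepts a named list or a one-row data frame (e.g. a row of
#' [sample_configs()] output).
#' @param config A named list or one-row data frame.
#' @return A named list of hyperparameter values.
#' @export
as_config <- function(config) {
  if (is.data.frame(config)) {
    stopifnot(nrow(config) == 1L)
    config <- as.list(config)
  }
  stopifnot(is.list(config), !is.null(names(config)), all(nzchar(names(config))))
  config
}

#' Validate a configuration against a space
#'
#' Diagnoses rather than throws: returns a character vector with one message
#' per violated invariant (missing value, out-of-range value, wrong type,
#' value supplied for a hyperparameter that does not exist in this space, such
#' as the GAP skip ratio under the RNN family).
#'
#' @inheritParams sample_configs
#' @param config A configuration (named list or one-row data frame).
#' @return Character vector of diagnostics; empty iff the configuration is
#'   valid.
#' @export
validate_config <- function(space, config) {
  config <- as_config(config)
  out <- character(0)
  extra <- setdiff(names(config), names(space$defs))
  for (nm in extra) {
    out <- c(out, sprintf("'%s' is not applicable in this space", nm))
  }
  for (d in space$defs) {
    v <- config[[d$name]]
    if (is.null(v) || length(v) != 1L || (is.atomic(v) && is.na(v))) {
      out <- c(out, sprintf("'%s' is missing", d$name))
      next
    }
    if (d$kind %in% c("float", "integer")) {
      if (!is.numeric(v)) {
        out <- c(out, sprintf("'%s' must be numeric", d$name))
      } else if (v < d$lower || v > d$upper) {
        out <- c(out, sprintf("'%s' = %g outside range [%g, %g]",
                              d$name, v, d$lower, d$upper))
      } else if (d$kind == "integer" && v != round(v)) {
        out <- c(out, sprintf("'%s' must be an integer", d$name))
      }
    } else if (d$kind == "boolean") {
      if (!is.logical(v)) out <- c(out, sprintf("'%s' must be logical", d$name))
    } else {
      if (!is.character(v) || !v %in% d$values) {
        out <- c(out, sprintf("'%s' must be one of {%s}", d$name,
                              paste(d$values, collapse = ", ")))
      }
    }
  }
  out
}

encoding_dim <- function(space) {
  sum(vapply(space$defs, function(d) {
    if (d$kind == "categorical") length(d$values) else 1L
  }, integer(1)))
}

#' Encode a configuration as a point in the unit cube
#'
#' Numeric hyperparameters are mapped affinely onto `[0, 1]` on their
#' (log-transformed where flagged) scale, booleans to `{0, 1}`, categoricals to
#' one-hot blocks in value-set order. The encoding dimension is fixed per
#' space, so encoded configurations feed the Gaussian-process surrogate
#' directly.
#'
#' @inheritParams validate_config
#' @return Numeric vector in `[0, 1]^d`.
#' @seealso [from_unit_vector()] for the inverse.
#' @export
to_unit_vector <- function(space, config) {
  config <- as_config(config)
  diag <- validate_config(space, config)
  if (length(diag)) {
    rlang::abort(c("invalid configuration", diag))
  }
  unlist(lapply(space$defs, function(d) {
    v <- config[[d$name]]
    switch(d$kind,
      float = ,
      integer = {
        lo <- hp_fwd(d, d$lower); hi <- hp_fwd(d, d$upper)
        if (hi == lo) 0 else (hp_fwd(d, v) - lo) / (hi - lo)
      },
      boolean = as.numeric(v),
      categorical = as.numeric(d$values == v)
    )
  }), use.names = FALSE)
}

#' Decode a unit-cube point into a configuration
#'
#' Inverse of [to_unit_vector()]: integer kinds are decoded by rounding (half
#' away from zero) after the inverse transform and clamped to their range;
#' booleans by thresholding at 0.5; categoricals by the arg-max of their
#' one-hot block, ties resolved in favour of the first listed value. Any point
#' of the unit cube therefore decodes to a valid configuration.
#'
#' @inheritParams sample_configs
#' @param v Numeric vector in `[0, 1]^d` where `d` is the space's encoding
#'   dimension.
#' @return A configuration (named list).
#' @export
from_unit_vector <- function(space, v) {
  d_tot <- encoding_dim(space)
  if (!is.numeric(v) || length(v) != d_tot) {
    rlang::abort(sprintf("expected a numeric vector of length %d, got %d",
                         d_tot, length(v)))
  }
  out <- list()
  i <- 1L
  for (d in space$defs) {
    if (d$kind == "categorical") {
      k <- length(d$values)
      out[[d$name]] <- d$values[which.max(v[i:(i + k - 1L)])]
      i <- i + k
    } else if (d$kind == "boolean") {
      out[[d$name]] <- v[i] >= 0.5
      i <- i + 1L
    } else {
      lo <- hp_fwd(d, d$lower); hi <- hp_fwd(d, d$upper)
      val <- hp_inv(d, lo + min(max(v[i], 0), 1) * (hi - lo))
      if (d$kind == "integer") {
        val <- as.integer(min(max(round_half_up(val), d$lower), d$upper))
      } else {
        val <- min(max(val, d$lower), d$upper)
      }
      out[[d$name]] <- val
      i <- i + 1L
    }
  }
  out
}

#' CPU-scale range overrides for desk experiments
#'
#' A reduced profile of the reference space (smaller kernels, fewer filters and
#' units, learning rates that move within tens of steps) intended for
#' laptop/CI-scale smoke runs of the full search loop on synthetic fixtures.
#' Pass the result as `overrides` to [define_search_space()].
#'
#' @return Named list of range overrides.
#' @export
desk_profile <- function() {
  list(
    learning_rate = c(3e-4, 1e-2),
    n_conv_layers = c(1, 4),
    n_conv_blocks = c(1, 3),
    kernel_size_0 = c(16, 32),
    kernel_size_end = c(16, 32),
    filters_0 = c(2, 12),
    filters_end = c(2, 12),
    dilation_end = c(1, 4),
    max_pooling_end = c(1, 8),
    batchnorm_momentum = c(0, 0.9),
    leaky_relu_alpha = c(0, 0.3),
    n_dense_layers = c(0, 2),
    dense_units = c(16, 64),
    dense_dropout = c(0, 0.5),
    recurrent_units = c(16, 64),
    n_recurrent_layers = c(1, 2)
  )
}
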