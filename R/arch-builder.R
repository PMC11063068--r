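# Deterministic expansion of a hyperparameter configuration into a
# backend-independent architecture plan, plus closed-form parameter counting.

#' Resolve the convolutional block structure
#'
#' The number of convolutional blocks `N_cb` is the `n_conv_blocks`
#' hyperparameter unless the requested total layer count `n_conv_layers` is
#' smaller, in which case every block has a single layer. The per-block layer
#' count `s_cb` is the rounded ratio (half away from zero), so the realized
#' total `N_c = N_cb * s_cb` approximates `n_conv_layers` while keeping every
#' block the same integer depth.
#'
#' @param n_c Requested total number of convolutional layers (1-20).
#' @param n_cb Requested number of convolutional blocks (1-10).
#' @return A list with `N_cb`, `s_cb`, `N_c`.
#' @examples
#' resolve_block_structure(9, 7)   # 7 blocks of 1 layer -> depth 7
#' resolve_block_structure(20, 3)  # 3 blocks of 7 layers -> depth 21
#' @export
resolve_block_structure <- function(n_c, n_cb) {
  stopifnot(n_c >= 1, n_cb >= 1, n_c == round(n_c), n_cb == round(n_cb))
  N_cb <- if (n_c <= n_cb) n_c else n_cb
  s_cb <- round_half_up(n_c / N_cb)
  list(N_cb = as.integer(N_cb), s_cb = as.integer(s_cb),
       N_c = as.integer(N_cb * s_cb))
}

#' Per-layer filter counts
#'
#' The filter count is interpolated exponentially from `f_0` (first layer) to
#' `f_end` (last layer) and materialized by ceiling. Under residual blocks the
#' count must be constant within each block (the shortcut addition requires
#' matching widths), so the interpolation proceeds block-wise; otherwise it is
#' layer-wise. A single-layer network uses `ceiling(f_0)`.
#'
#' @param f_0,f_end First/last layer filter counts (may be fractional; the
#'   search treats them as continuous).
#' @param structure Block structure from [resolve_block_structure()].
#' @param res_block Residual blocks in use?
#' @return Integer vector of length `N_c`.
#' @examples
#' st <- list(N_cb = 2L, s_cb = 2L, N_c = 4L)
#' filters_per_layer(4, 32, st, res_block = TRUE)   # 4 4 32 32
#' filters_per_layer(4, 32, st, res_block = FALSE)  # 4 8 16 32
#' @export
filters_per_layer <- function(f_0, f_end, structure, res_block = FALSE) {
  N_c <- structure$N_c; N_cb <- structure$N_cb; s_cb <- structure$s_cb
  if (N_c == 1L) return(as.integer(ceiling(f_0)))
  i <- seq_len(N_c) - 1
  j <- if (res_block) {
    if (N_cb == 1L) rep(0, N_c) else floor(i / s_cb) / (N_cb - 1)
  } else {
    i / (N_c - 1)
  }
  as.integer(ceiling(f_0 * (f_end / f_0)^j))
}

#' Per-layer kernel sizes
#'
#' Kernel widths are interpolated exponentially from `k_0` to `k_end` over the
#' realized layers and materialized by ceiling; a single-layer network uses
#' `ceiling(k_0)`.
#'
#' @param k_0,k_end First/last layer kernel sizes (continuous).
#' @param N_c Realized total number of convolutional layers.
#' @return Integer vector of length `N_c`.
#' @examples
#' kernels_per_layer(16, 128, 4)  # 16 32 64 128
#' @export
kernels_per_layer <- function(k_0, k_end, N_c) {
  if (N_c == 1L) return(as.integer(ceiling(k_0)))
  i <- seq_len(N_c) - 1
  as.integer(ceiling(k_0 * (k_end / k_0)^(i / (N_c - 1))))
}

#' Per-layer dilation factors
#'
#' Within each convolutional block the dilation factor grows exponentially
#' from 1 (first layer of the block) to `d_end` (last layer of the block),
#' materialized by ceiling; the pattern repeats across blocks. Single-layer
#' blocks (`s_cb = 1`) are degenerate and use dilation 1 throughout (the
#' growth "from 1" never starts).
#'
#' @param d_end Last-in-block dilation factor (>= 1, continuous).
#' @param structure Block structure from [resolve_block_structure()].
#' @return Integer vector of length `N_c`.
#' @examples
#' dilations_per_layer(8, list(N_cb = 1L, s_cb = 4L, N_c = 4L))  # 1 2 4 8
#' @export
dilations_per_layer <- function(d_end, structure) {
  stopifnot(d_end >= 1)
  N_c <- structure$N_c; s_cb <- structure$s_cb
  if (s_cb == 1L) return(rep(1L, N_c))
  q <- (seq_len(N_c) - 1) %% s_cb
  as.integer(ceiling(d_end^(q / (s_cb - 1))))
}

#' Plan the max-pooling factors between convolutional layers
#'
#' Max-pooling layers with power-of-two size (= stride) are placed after
#' convolutional layers so that the sequence length shrinks exponentially
#' along the model, with total reduction `2^round(log2(p_end))`. The exponent
#' budget is spread as evenly as possible over the `N_c` candidate sites, with
#' the remainder assigned to the latest sites so early layers keep full
#' resolution.
#'
#' @param p_end Total max-pooling factor (>= 1, continuous).
#' @param N_c Number of convolutional layers (candidate pooling sites).
#' @return Integer vector of `N_c` power-of-two factors (1 = no pooling) whose
#'   product is `2^round(log2(p_end))`.
#' @examples
#' plan_pooling(16, 2)  # 4 4
#' plan_pooling(8, 2)   # 2 4 (remainder to the later site)
#' @export
plan_pooling <- function(p_end, N_c) {
  stopifnot(p_end >= 1, N_c >= 1)
  e_tot <- round_half_up(log2(p_end))
  base <- e_tot %/% N_c
  rem <- e_tot %% N_c
  exps <- rep(base, N_c)
  if (rem > 0) exps[(N_c - rem + 1L):N_c] <- exps[(N_c - rem + 1L):N_c] + 1L
  as.integer(2^exps)
}

#' Number of convolutional blocks tapped by global average pooling
#'
#' The skip ratio `r_s` drops the leading fraction of block outputs; the last
#' `max(1, ceiling((1 - r_s) * N_cb))` blocks are global-average pooled and
#' concatenated. At least one block is always tapped.
#'
#' @param r_s Skip ratio in `[0, 1]`.
#' @param N_cb Number of convolutional blocks.
#' @return Integer count of tapped blocks.
#' @examples
#' pooled_block_count(0.72, 7)  # 2
#' @export
pooled_block_count <- function(r_s, N_cb) {
  stopifnot(r_s >= 0, r_s <= 1, N_cb >= 1)
  as.integer(max(1, ceiling((1 - r_s) * N_cb)))
}

#' Expand a configuration into an architecture plan
#'
#' Deterministically assembles the three-stage template: (i) `N_cb`
#' convolutional blocks of `s_cb` layers each, with exponentially interpolated
#' filter counts and kernel sizes, per-block exponential dilation, batch
#' normalization and leaky-ReLU activation, interleaved max-pooling, and
#' optional residual shortcuts; (ii) either global average pooling over the
#' tapped suffix of blocks (GAP family) or a recurrent stack whose per-position
#' outputs are flattened (RNN family); (iii) a fully connected stack with
#' dropout, ending in an `n_classes` softmax output. When the
#' reverse-complement flag is set, both strands pass through the shared trunk
#' and their embeddings are concatenated before the dense stack.
#'
#' Every dilated kernel must fit into the sequence length remaining at its
#' layer (receptive extent `dilation * (kernel - 1) + 1`); configurations
#' violating this raise a build error naming the offending layer.
#'
#' @param config A configuration (named list or one-row data frame).
#' @param space The `genarch_space` the configuration belongs to.
#' @param n_classes Number of output classes (>= 2).
#' @return An object of class `genarch_plan`.
#' @examples
#' sp <- define_search_space(150, "gap")
#' cfg <- as_config(sample_configs(sp, 1, seed = 42))
#' cfg$kernel_size_0 <- 16; cfg$kernel_size_end <- 24; cfg$dilation_end <- 1
#' plan <- build_plan(cfg, sp, n_classes = 3)
#' @export
build_plan <- function(config, space, n_classes) {
  config <- as_config(config)
  stopifnot(n_classes >= 2)
  diag <- validate_config(space, config)
  if (length(diag)) rlang::abort(c("invalid configuration", diag))
  L <- space$sequence_length
  st <- resolve_block_structure(config$n_conv_layers, config$n_conv_blocks)
  filt <- filters_per_layer(config$filters_0, config$filters_end, st,
                            res_block = space$residual)
  kern <- kernels_per_layer(config$kernel_size_0, config$kernel_size_end, st$N_c)
  dil <- dilations_per_layer(config$dilation_end, st)
  pool <- plan_pooling(config$max_pooling_end, st$N_c)

  # receptive-extent check, walking the length through the pooling sites
  len <- L
  for (i in seq_len(st$N_c)) {
    extent <- dil[i] * (kern[i] - 1) + 1
    if (extent > len) {
      rlang::abort(sprintf(
        paste0("receptive extent of conv layer %d (dilation %d x kernel %d ",
               "-> %d) exceeds the sequence length %d remaining at that layer"),
        i, dil[i], kern[i], extent, len), class = "genarch_receptive_error")
    }
    len <- len %/% pool[i]
    if (len < 1) {
      rlang::abort(sprintf("pooling after conv layer %d reduces the sequence length below 1", i),
                   class = "genarch_receptive_error")
    }
  }

  blocks <- lapply(seq_len(st$N_cb), function(b) {
    idx <- ((b - 1L) * st$s_cb + 1L):(b * st$s_cb)
    list(layers = lapply(idx, function(i) {
      list(filters = filt[i], kernel = kern[i], dilation = dil[i],
           batchnorm_momentum = config$batchnorm_momentum,
           leaky_alpha = config$leaky_relu_alpha)
    }), pool_after = pool[idx])
  })

  head <- if (identical(space$model_family, "rnn")) {
    list(kind = "rnn",
         rnn_stack = list(type = config$recurrent_type,
                          n_layers = as.integer(config$n_recurrent_layers),
                          units = as.integer(ceiling(config$recurrent_units)),
                          bidirectional = isTRUE(config$bidirectional)))
  } else {
    m <- pooled_block_count(config$skip_ratio, st$N_cb)
    list(kind = "gap", gap_taps = (st$N_cb - m + 1L):st$N_cb)
  }

  nd <- as.integer(config$n_dense_layers)
  dense <- if (nd > 0) {
    lapply(seq_len(nd), function(i) {
      list(units = as.integer(ceiling(config$dense_units)),
           activation = config$dense_activation,
           dropout = config$dense_dropout)
    })
  } else list()

  structure(
    list(input_length = as.integer(L), alphabet_size = 4L,
         use_reverse_complement = isTRUE(config$reverse_complement),
         residual = isTRUE(space$residual),
         structure = st, conv_blocks = blocks, head = head,
         dense_stack = dense, n_classes = as.integer(n_classes),
         optimizer = config$optimizer, learning_rate = config$learning_rate),
    class = "genarch_plan"
  )
}

#' @export
print.genarch_plan <- function(x, ...) {
  st <- x$structure
  cat(sprintf("<genarch_plan> L = %d, %d conv layers (%d blocks x %d)%s\n",
              x$input_length, st$N_c, st$N_cb, st$s_cb,
              if (x$residual) ", residual" else ""))
  for (b in seq_along(x$conv_blocks)) {
    bl <- x$conv_blocks[[b]]
    for (l in seq_along(bl$layers)) {
      ly <- bl$layers[[l]]
      cat(sprintf("  block %d conv %d: %d filters, kernel %d, dilation %d, pool %d\n",
                  b, l, ly$filters, ly$kernel, ly$dilation, bl$pool_after[l]))
    }
  }
  if (x$head$kind == "gap") {
    cat(sprintf("  GAP over blocks {%s}\n", paste(x$head$gap_taps, collapse = ", ")))
  } else {
    r <- x$head$rnn_stack
    cat(sprintf("  %s%s x %d, %d units, flattened\n",
                if (r$bidirectional) "bi-" else "", toupper(r$type),
                r$n_layers, r$units))
  }
  for (d in x$dense_stack) {
    cat(sprintf("  dense %d (%s, dropout %.2f)\n", d$units, d$activation, d$dropout))
  }
  cat(sprintf("  softmax output, %d classes%s\n", x$n_classes,
              if (x$use_reverse_complement) " (reverse-complement fused)" else ""))
  invisible(x)
}

# sequence lengths at block boundaries and at the trunk output
plan_lengths <- function(plan) {
  len <- plan$input_length
  block_out <- integer(length(plan$conv_blocks))
  for (b in seq_along(plan$conv_blocks)) {
    for (p in plan$conv_blocks[[b]]$pool_after) len <- len %/% p
    block_out[b] <- len
  }
  list(block_out = block_out, final = len)
}

# width of the embedding fed to the dense stack (single strand)
embedding_width <- function(plan) {
  if (plan$head$kind == "gap") {
    sum(vapply(plan$head$gap_taps, function(b) {
      ly <- plan$conv_blocks[[b]]$layers
      ly[[length(ly)]]$filters
    }, integer(1)))
  } else {
    r <- plan$head$rnn_stack
    dirs <- if (r$bidirectional) 2L else 1L
    plan_lengths(plan)$final * r$units * dirs
  }
}

#' Count trainable parameters of a plan
#'
#' Closed-form accounting using the standard layer formulas: a convolution
#' contributes `(kernel * in_channels + 1) * filters` weights plus `2 *
#' filters` trainable batch-norm scale/shift parameters; a residual projection
#' (width-1 convolution, used when a block changes channel count)
#' `(in_channels + 1) * out_channels`; a dense layer `(in + 1) * units`; LSTM
#' and GRU layers the usual 4- and 3-gate formulas, doubled when
#' bidirectional. The total equals the instantiated model's trainable count.
#'
#' @param plan A `genarch_plan`.
#' @return A list with `total` and a `by_stage` breakdown (`conv`, `head`,
#'   `dense`, `output`); an empty dense stack contributes 0 to `dense`, the
#'   classification layer is accounted separately under `output`.
#' @export
count_parameters <- function(plan) {
  stopifnot(inherits(plan, "genarch_plan"))
  conv <- 0; head_n <- 0; dense_n <- 0
  in_ch <- plan$alphabet_size
  for (b in seq_along(plan$conv_blocks)) {
    block_in <- in_ch
    for (ly in plan$conv_blocks[[b]]$layers) {
      conv <- conv + (ly$kernel * in_ch + 1) * ly$filters + 2 * ly$filters
      in_ch <- ly$filters
    }
    if (plan$residual && block_in != in_ch) {
      conv <- conv + (block_in + 1) * in_ch  # 1x1 projection on the skip path
    }
  }
  if (plan$head$kind == "rnn") {
    r <- plan$head$rnn_stack
    dirs <- if (r$bidirectional) 2L else 1L
    gates <- if (r$type == "lstm") 4L else 3L
    inp <- in_ch
    for (l in seq_len(r$n_layers)) {
      head_n <- head_n + dirs * gates * ((inp + r$units) * r$units + r$units)
      inp <- r$units * dirs
    }
  }
  width <- embedding_width(plan) * (if (plan$use_reverse_complement) 2L else 1L)
  for (d in plan$dense_stack) {
    dense_n <- dense_n + (width + 1) * d$units
    width <- d$units
  }
  out_n <- (width + 1) * plan$n_classes
  list(total = conv + head_n + dense_n + out_n,
       by_stage = list(conv = conv, head = head_n, dense = dense_n,
                       output = out_n))
}

#' Serialize / restore an architecture plan
#'
#' Plans serialize to JSON with stable key order, so equal configurations give
#' byte-identical serializations (diffing and caching rely on this).
#'
#' @param plan A `genarch_plan`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `plan_to_json()`: the JSON string (invisibly when written to a
#'   file); `plan_from_json()`: the restored `genarch_plan`.
#' @export
plan_to_json <- function(plan, path = NULL) {
  stopifnot(inherits(plan, "genarch_plan"))
  js <- jsonlite::toJSON(unclass(plan), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname plan_to_json
#' @param json JSON string or file path produced by [plan_to_json()].
#' @export
plan_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- paste(readLines(json), collapse = "\n")
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$structure <- lapply(x$structure, as.integer)
  x$conv_blocks <- lapply(x$conv_blocks, function(b) {
    b$pool_after <- as.integer(unlist(b$pool_after))
    b$layers <- lapply(b$layers, function(ly) {
      ly$filters <- as.integer(ly$filters)
      ly$kernel <- as.integer(ly$kernel)
      ly$dilation <- as.integer(ly$dilation)
      ly
    })
    b
  })
  if (identical(x$head$kind, "gap")) x$head$gap_taps <- as.integer(unlist(x$head$gap_taps))
  x$input_length <- as.integer(x$input_length)
  x$alphabet_size <- as.integer(x$alphabet_size)
  x$n_classes <- as.integer(x$n_classes)
  structure(x, class = "genarch_plan")
}
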