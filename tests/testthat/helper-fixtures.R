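# Shared fixtures built in code, memoised per test session.

the_fixture_cache <- new.env(parent = emptyenv())

tiny_fixture <- function() {
  if (is.null(the_fixture_cache$tiny)) {
    the_fixture_cache$tiny <- fixture_suite("tiny",
                                            dir = file.path(tempdir(), "genarch-tiny"),
                                            seed = 13)
  }
  the_fixture_cache$tiny
}

small_fixture <- function() {
  if (is.null(the_fixture_cache$small)) {
    the_fixture_cache$small <- fixture_suite("small",
                                             dir = file.path(tempdir(), "genarch-small"),
                                             seed = 13)
  }
  the_fixture_cache$small
}

# hand-built minimal plan for backend tests (bypasses Table-1 kernel minima on
# purpose: plan invariants only require kernel >= 1)
tiny_test_plan <- function(head_kind = "gap", residual = FALSE, rc = FALSE,
                           rnn_type = "lstm", bidir = FALSE,
                           pool = c(1L, 2L), dil = c(1L, 2L), n_dense = 1L,
                           dropout = 0, input_length = 12L) {
  st <- list(N_cb = 1L, s_cb = 2L, N_c = 2L)
  blocks <- list(list(
    layers = list(
      list(filters = 3L, kernel = 3L, dilation = dil[1],
           batchnorm_momentum = 0.5, leaky_alpha = 0.1),
      list(filters = 3L, kernel = 3L, dilation = dil[2],
           batchnorm_momentum = 0.5, leaky_alpha = 0.1)
    ),
    pool_after = pool))
  head <- if (head_kind == "gap") {
    list(kind = "gap", gap_taps = 1L)
  } else {
    list(kind = "rnn", rnn_stack = list(type = rnn_type, n_layers = 2L,
                                        units = 4L, bidirectional = bidir))
  }
  dense <- if (n_dense > 0) {
    list(list(units = 5L, activation = "tanh", dropout = dropout))
  } else {
    list()
  }
  structure(list(input_length = as.integer(input_length), alphabet_size = 4L,
                 use_reverse_complement = rc, residual = residual,
                 structure = st, conv_blocks = blocks, head = head,
                 dense_stack = dense, n_classes = 3L,
                 optimizer = "sgd", learning_rate = 0.1),
            class = "genarch_plan")
}

# a config guaranteed to build at L = 150 (used where the test is about
# something other than the receptive-extent rule)
buildable_config <- function(space, seed = 1) {
  cfg <- as_config(sample_configs(space, 1, seed = seed))
  cfg$kernel_size_0 <- 16
  cfg$kernel_size_end <- 20
  cfg$dilation_end <- 1
  cfg$max_pooling_end <- 2
  cfg
}

# brute-force re-evaluation of the printed interpolation formulas, written
# independently of the package implementation (scalar loops, no vectorization)
oracle_block_structure <- function(n_c, n_cb) {
  N_cb <- if (n_c <= n_cb) n_c else n_cb
  s_cb <- floor(n_c / N_cb + 0.5)
  list(N_cb = N_cb, s_cb = s_cb, N_c = N_cb * s_cb)
}

oracle_filters <- function(f0, fend, N_cb, s_cb, res_block) {
  N_c <- N_cb * s_cb
  if (N_c == 1) return(ceiling(f0))
  out <- numeric(N_c)
  for (i in 0:(N_c - 1)) {
    j <- if (res_block) {
      if (N_cb == 1) 0 else floor(i / s_cb) * (1 / (N_cb - 1))
    } else {
      i / (N_c - 1)
    }
    out[i + 1] <- ceiling(f0 * (fend / f0)^j)
  }
  out
}

oracle_kernels <- function(k0, kend, N_c) {
  if (N_c == 1) return(ceiling(k0))
  out <- numeric(N_c)
  for (i in 0:(N_c - 1)) out[i + 1] <- ceiling(k0 * (kend / k0)^(i / (N_c - 1)))
  out
}

oracle_dilations <- function(dend, N_cb, s_cb) {
  N_c <- N_cb * s_cb
  out <- numeric(N_c)
  for (i in 0:(N_c - 1)) {
    q <- i %% s_cb
    out[i + 1] <- if (s_cb == 1) 1 else ceiling(dend^(q / (s_cb - 1)))
  }
  out
}
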