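# Streaming class-labelled genomic subsequences from FASTA collections:
# one-hot encoding, reverse complements, class-balanced training batches with
# random start offsets, and deterministic test iteration.

#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning the records as
#' a tibble. Nucleotides are case-insensitive; multi-record files are allowed.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return A tibble with columns `header`, `sequence`, `width`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  recs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) {
                     rlang::abort(sprintf("failed to parse FASTA file '%s': %s",
                                          path, conditionMessage(e)))
                   })
  if (length(recs) == 0L) {
    rlang::abort(sprintf("FASTA file '%s' is empty or contains no records", path))
  }
  tibble::tibble(header = names(recs),
                 sequence = as.character(recs),
                 width = Biostrings::width(recs))
}

onehot_lookup <- local({
  lk <- integer(128)
  lk[utf8ToInt("A")] <- 1L; lk[utf8ToInt("a")] <- 1L
  lk[utf8ToInt("C")] <- 2L; lk[utf8ToInt("c")] <- 2L
  lk[utf8ToInt("G")] <- 3L; lk[utf8ToInt("g")] <- 3L
  lk[utf8ToInt("T")] <- 4L; lk[utf8ToInt("t")] <- 4L
  lk
})

#' One-hot encode a nucleotide sequence
#'
#' Channels are ordered A, C, G, T. Ambiguous IUPAC codes (N, R, Y, ...) are
#' encoded as all-zero columns: they keep the sequence length but contribute
#' nothing to the convolutions.
#'
#' @param sequence A nucleotide string of length >= `L`.
#' @param L Number of positions to encode (the first `L` characters).
#' @return An `L x 4` numeric matrix; each row sums to 1 (unambiguous base) or
#'   0 (ambiguous).
#' @examples
#' one_hot("ACGT", 4)
#' @export
one_hot <- function(sequence, L = nchar(sequence)) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < L) {
    rlang::abort(sprintf("sequence of length %d is shorter than L = %d",
                         nchar(sequence), L))
  }
  codes <- utf8ToInt(substr(sequence, 1L, L))
  idx <- ifelse(codes <= 127L, onehot_lookup[codes], 0L)
  M <- matrix(0, L, 4L)
  hit <- idx > 0L
  M[cbind(which(hit), idx[hit])] <- 1
  M
}

# vectorized one-hot of many equal-length windows -> array (n, L, 4)
encode_windows <- function(sequences, L) {
  n <- length(sequences)
  X <- array(0, c(n, L, 4L))
  for (i in seq_len(n)) X[i, , ] <- one_hot(sequences[[i]], L)
  X
}

#' Reverse complement
#'
#' For a character sequence, the complement read in reverse (IUPAC ambiguity
#' codes are complemented too). For a one-hot matrix (`L x 4`) or batch array
#' (`n x L x 4`), positions are reversed and the A/T and C/G channels swapped;
#' the two forms commute with [one_hot()].
#'
#' @param x A nucleotide string, an `L x 4` one-hot matrix, or an `n x L x 4`
#'   batch array.
#' @return Same kind as the input.
#' @examples
#' reverse_complement("AAC")  # "GTT"
#' @export
reverse_complement <- function(x) {
  if (is.character(x)) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  } else if (is.matrix(x)) {
    x[nrow(x):1, 4:1, drop = FALSE]
  } else if (is.array(x) && length(dim(x)) == 3L) {
    rc_batch(x)
  } else {
    rlang::abort("expected a character sequence, an L x 4 matrix, or an n x L x 4 array")
  }
}

# consecutive non-overlapping L-window start positions (1-based) within a
# record of length `len`, beginning at 0-based `offset`
window_starts <- function(len, offset, L) {
  n_win <- (len - offset) %/% L
  if (n_win <= 0L) return(integer(0))
  offset + (seq_len(n_win) - 1L) * L + 1L
}

check_datasets <- function(datasets) {
  stopifnot(is.data.frame(datasets), all(c("class_name", "file") %in% names(datasets)))
  if (nrow(datasets) == 0L) rlang::abort("dataset table is empty")
  missing <- datasets$file[!file.exists(datasets$file)]
  if (length(missing)) {
    rlang::abort(c("dataset files not found:", missing))
  }
  invisible(datasets)
}

#' Create a class-balanced training batch stream
#'
#' Returns a generator function; each call yields one `genarch_batch` with
#' exactly `batch_size / n_classes` samples per class (minority classes are
#' oversampled simply because every class contributes equally to every batch
#' while larger classes recycle their files less often). On each file visit a
#' fresh random start offset is drawn and consecutive non-overlapping
#' `L`-windows are emitted until the file is exhausted; windows never span
#' record boundaries. The stream owns its RNG state, so a fixed seed gives an
#' identical batch sequence.
#'
#' @param datasets A tibble with columns `class_name`, `file` (e.g. a manifest
#'   filtered to one role).
#' @param L Window length in nucleotides.
#' @param batch_size Total batch size; must be divisible by the class count.
#' @param seed Integer seed for the stream.
#' @return A function `function() -> genarch_batch`.
#' @export
new_batch_stream <- function(datasets, L, batch_size, seed = 1L) {
  check_datasets(datasets)
  classes <- unique(datasets$class_name)
  k <- length(classes)
  if (batch_size %% k != 0L) {
    rlang::abort(sprintf("batch_size (%d) must be divisible by the class count (%d)",
                         batch_size, k))
  }
  per_class <- batch_size %/% k
  env <- new.env(parent = emptyenv())
  env$seq_cache <- list()
  env$buffers <- stats::setNames(vector("list", k), classes)
  env$rng <- NULL
  get_records <- function(file) {
    if (is.null(env$seq_cache[[file]])) {
      env$seq_cache[[file]] <- read_fasta(file)$sequence
    }
    env$seq_cache[[file]]
  }
  refill <- function(cl) {
    files <- datasets$file[datasets$class_name == cl]
    wins <- character(0)
    guard <- 0L
    while (length(wins) == 0L) {
      guard <- guard + 1L
      if (guard > 100L) {
        rlang::abort(sprintf("class '%s' has no record of length >= %d", cl, L))
      }
      f <- files[[sample.int(length(files), 1L)]]
      recs <- get_records(f)
      rec <- recs[[sample.int(length(recs), 1L)]]
      len <- nchar(rec)
      if (len < L) next
      offset <- sample.int(len - L + 1L, 1L) - 1L
      starts <- window_starts(len, offset, L)
      if (length(starts) == 0L) next
      wins <- substring(rec, starts, starts + L - 1L)
    }
    wins
  }
  function() {
    # the stream keeps a private RNG state so interleaved callers stay
    # reproducible
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(env$rng)) set.seed(seed) else
      assign(".Random.seed", env$rng, envir = globalenv())
    seqs <- character(0)
    labels <- integer(0)
    for (ci in seq_along(classes)) {
      need <- per_class
      taken <- character(0)
      while (need > 0L) {
        buf <- env$buffers[[classes[ci]]]
        if (is.null(buf) || length(buf) == 0L) buf <- refill(classes[ci])
        take <- min(need, length(buf))
        taken <- c(taken, buf[seq_len(take)])
        env$buffers[[classes[ci]]] <- buf[-seq_len(take)]
        need <- need - take
      }
      seqs <- c(seqs, taken)
      labels <- c(labels, rep(ci, per_class))
    }
    env$rng <- get(".Random.seed", envir = globalenv())
    structure(list(one_hot = encode_windows(seqs, L),
                   labels = labels,
                   classes = classes,
                   per_class_counts = stats::setNames(rep(per_class, length(classes)),
                                                      classes)),
              class = "genarch_batch")
  }
}

#' Sample one class-balanced training batch
#'
#' Convenience wrapper around [new_batch_stream()] drawing a single batch.
#'
#' @inheritParams new_batch_stream
#' @return A `genarch_batch`: list with `one_hot` (array `batch x L x 4`),
#'   `labels` (integer class indices), `classes`, `per_class_counts`.
#' @export
sample_training_batch <- function(datasets, L, batch_size, seed = 1L) {
  new_batch_stream(datasets, L, batch_size, seed = seed)()
}

#' Deterministically enumerate test samples
#'
#' Iterates files in listed order; within each record, consecutive
#' non-overlapping `L`-windows start at the first position and any trailing
#' fragment shorter than `L` is discarded. No randomness: two calls give
#' identical streams.
#'
#' @inheritParams new_batch_stream
#' @return A tibble with columns `class_name`, `file`, `record`, `start`
#'   (1-based), `sequence`.
#' @export
iterate_test_samples <- function(datasets, L) {
  check_datasets(datasets)
  out <- list()
  for (i in seq_len(nrow(datasets))) {
    recs <- read_fasta(datasets$file[i])
    for (r in seq_len(nrow(recs))) {
      n_win <- recs$width[r] %/% L
      if (n_win == 0L) next
      starts <- (seq_len(n_win) - 1L) * L + 1L
      out[[length(out) + 1L]] <- tibble::tibble(
        class_name = datasets$class_name[i],
        file = datasets$file[i],
        record = recs$header[r],
        start = starts,
        sequence = substring(recs$sequence[r], starts, starts + L - 1L))
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(class_name = character(), file = character(),
                          record = character(), start = integer(),
                          sequence = character()))
  }
  dplyr::bind_rows(out)
}

#' Class-balanced accuracy from a confusion matrix
#'
#' The mean over classes of per-class recall (rows = true classes, columns =
#' predicted). Its complement is the class-balanced misclassification rate.
#' Because test sets are typically imbalanced, this is the headline metric
#' for all evaluations.
#'
#' @param confusion Square numeric matrix of counts, rows = true classes.
#' @return Value in `[0, 1]`.
#' @examples
#' cm <- rbind(c(8, 1, 1), c(0, 5, 5), c(2, 0, 8))
#' class_balanced_accuracy(cm)  # 0.70
#' @export
class_balanced_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  rs <- rowSums(confusion)
  if (any(rs == 0)) {
    rlang::abort("every true class must have at least one sample")
  }
  mean(diag(confusion) / rs)
}

#' Evaluate a model on an enumerated sample table
#'
#' Runs batched prediction over the output of [iterate_test_samples()] and
#' returns the confusion matrix and class-balanced accuracy.
#'
#' @param model A `genarch_model`.
#' @param samples A tibble as returned by [iterate_test_samples()].
#' @param L Window length the model expects.
#' @param classes Class labels in model output order (defaults to the order of
#'   first appearance in `samples`).
#' @param chunk_size Prediction batch size.
#' @return A list with `confusion` and `balanced_accuracy`.
#' @export
evaluate_model <- function(model, samples, L, classes = unique(samples$class_name),
                           chunk_size = 256L) {
  stopifnot(nrow(samples) > 0L)
  truth <- match(samples$class_name, classes)
  pred <- integer(nrow(samples))
  idx <- split(seq_len(nrow(samples)),
               ceiling(seq_len(nrow(samples)) / chunk_size))
  for (ii in idx) {
    X <- encode_windows(samples$sequence[ii], L)
    P <- predict(model, X)
    pred[ii] <- max.col(P, ties.method = "first")
  }
  k <- length(classes)
  confusion <- matrix(0L, k, k, dimnames = list(true = classes, predicted = classes))
  for (i in seq_along(truth)) {
    confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
  }
  list(confusion = confusion,
       balanced_accuracy = class_balanced_accuracy(confusion))
}
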