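write_tmp_fasta <- function(lines, name = "tmp.fasta") {
  path <- file.path(tempdir(), name)
  writeLines(lines, path)
  path
}

test_that("FASTA reading preserves record order and folds case", {
  p <- write_tmp_fasta(c(">rec1 first", "ACGTACGT", ">rec2 second", "ggggcccc"),
                       "two.fasta")
  recs <- read_fasta(p)
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$header, c("rec1 first", "rec2 second"))
  expect_equal(recs$width, c(8L, 8L))
  # lowercase input one-hot-encodes identically to uppercase
  expect_equal(one_hot(recs$sequence[2], 8), one_hot("GGGGCCCC", 8))

  empty <- write_tmp_fasta(character(0), "empty.fasta")
  expect_error(read_fasta(empty), "empty|parse")
  expect_error(read_fasta(file.path(tempdir(), "nope.fasta")), "not found")
})

test_that("one-hot encoding is A,C,G,T ordered with zeroed ambiguity codes", {
  expect_equal(one_hot("ACGT", 4), diag(4))
  m <- one_hot("ACNN", 4)
  expect_equal(m[1:2, ], diag(4)[1:2, ])
  expect_equal(m[3:4, ], matrix(0, 2, 4))
  expect_equal(one_hot("acgt", 4), diag(4))
  expect_error(one_hot("ACG", 4), "shorter")

  withr::with_seed(5, {
    s <- paste(sample(c("A", "C", "G", "T", "N", "R"), 150, replace = TRUE,
                      prob = c(rep(0.23, 4), 0.04, 0.04)), collapse = "")
    M <- one_hot(s, 150)
    rs <- rowSums(M)
    expect_true(all(rs %in% c(0, 1)))
    chars <- strsplit(s, "")[[1]]
    expect_equal(rs, as.numeric(chars %in% c("A", "C", "G", "T")))
  })
})

test_that("reverse complement works on strings and one-hot forms and commutes", {
  expect_equal(reverse_complement("AAC"), "GTT")
  expect_equal(reverse_complement("ACGT"), "ACGT")
  withr::with_seed(6, {
    for (i in 1:100) {
      s <- paste(sample(c("A", "C", "G", "T", "N"), 40, replace = TRUE,
                        prob = c(rep(0.24, 4), 0.04)), collapse = "")
      expect_equal(one_hot(reverse_complement(s), 40),
                   reverse_complement(one_hot(s, 40)))
    }
  })
  # batch form matches the matrix form
  X <- array(0, c(2, 4, 4))
  X[1, , ] <- one_hot("ACGT", 4); X[2, , ] <- one_hot("AACC", 4)
  R <- reverse_complement(X)
  expect_equal(R[2, , ], one_hot(reverse_complement("AACC"), 4))
})

test_that("training batches are exactly class-balanced and reproducible", {
  fx <- tiny_fixture()
  train <- fx$manifest[fx$manifest$role == "train", ]
  b <- sample_training_batch(train, L = 150, batch_size = 12, seed = 3)
  expect_equal(unname(b$per_class_counts), rep(4L, 3))
  expect_equal(dim(b$one_hot), c(12L, 150L, 4L))
  expect_equal(as.vector(table(b$labels)), rep(4L, 3))
  # every position row sums to at most 1
  expect_true(all(apply(b$one_hot, c(1, 2), sum) %in% c(0, 1)))

  b2 <- sample_training_batch(train, L = 150, batch_size = 12, seed = 3)
  expect_identical(b$one_hot, b2$one_hot)
  expect_error(sample_training_batch(train, 150, 10, seed = 1), "divisible")
})

test_that("windows within a file visit are consecutive and non-overlapping", {
  # windowing arithmetic: genome length 2L + 1, offset 1 -> two disjoint
  # windows covering [2, L+1) and [L+2, 2L+1)
  expect_equal(genarch:::window_starts(2 * 50 + 1, 1L, 50), c(2L, 52L))
  expect_equal(genarch:::window_starts(3 * 50 + 7, 0L, 50), c(1L, 51L, 101L))
  expect_equal(genarch:::window_starts(49, 0L, 50), integer(0))
  # every emitted window is a verbatim substring at a visit offset, and
  # batches draw real genome content
  withr::with_seed(8, {
    genome <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                    collapse = "")
  })
  p <- write_tmp_fasta(c(">g", genome), "windows.fasta")
  ds <- tibble::tibble(class_name = "only", file = p)
  b <- sample_training_batch(ds, L = 50, batch_size = 4, seed = 4)
  pos <- vapply(1:4, function(i) {
    w <- paste(c("A", "C", "G", "T")[apply(b$one_hot[i, , ], 1, which.max)],
               collapse = "")
    as.integer(regexpr(w, genome, fixed = TRUE))
  }, integer(1))
  expect_true(all(pos > 0))
  # consecutive windows from the same visit sit exactly L apart
  expect_true(any(diff(pos) == 50L))
})

test_that("minority classes are oversampled to equal batch shares", {
  withr::with_seed(9, {
    big <- replicate(10, paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                               collapse = ""))
    small <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                   collapse = "")
  })
  paths <- c(vapply(seq_along(big), function(i) {
    write_tmp_fasta(c(">b", big[i]), sprintf("big%02d.fasta", i))
  }, character(1)), write_tmp_fasta(c(">s", small), "small.fasta"))
  ds <- tibble::tibble(class_name = c(rep("major", 10), "minor"), file = paths)
  stream <- new_batch_stream(ds, L = 150, batch_size = 10, seed = 2)
  for (i in 1:5) {
    b <- stream()
    expect_equal(as.vector(table(b$labels)), c(5L, 5L))
  }
})

test_that("test iteration is deterministic, exhaustive, and drops tail fragments", {
  L <- 50
  withr::with_seed(10, {
    g1 <- paste(sample(c("A", "C", "G", "T"), 3 * L + 7, replace = TRUE),
                collapse = "")
    g2 <- paste(sample(c("A", "C", "G", "T"), L - 1, replace = TRUE),
                collapse = "")
  })
  p1 <- write_tmp_fasta(c(">g1", g1), "it1.fasta")
  p2 <- write_tmp_fasta(c(">g2", g2), "it2.fasta")
  ds <- tibble::tibble(class_name = c("a", "b"), file = c(p1, p2))
  s1 <- iterate_test_samples(ds, L)
  expect_equal(nrow(s1), 3L)
  expect_equal(s1$start, c(1L, 51L, 101L))
  expect_equal(s1$sequence[2], substr(g1, 51, 100))
  expect_identical(s1, iterate_test_samples(ds, L))

  fx <- tiny_fixture()
  test_tbl <- iterate_test_samples(fx$manifest[fx$manifest$role == "test", ], 150)
  expect_equal(nrow(test_tbl), 3 * (5000 %/% 150))
})

test_that("class-balanced accuracy averages per-class recall", {
  expect_equal(class_balanced_accuracy(diag(c(5, 9, 2))), 1)
  cm <- rbind(c(8, 1, 1), c(0, 5, 5), c(2, 0, 8))
  expect_equal(class_balanced_accuracy(cm), 0.70)
  expect_error(class_balanced_accuracy(rbind(c(1, 0), c(0, 0))),
               "at least one sample")

  # uniform random predictions on balanced classes score about 1/3
  withr::with_seed(12, {
    accs <- replicate(200, {
      truth <- rep(1:3, each = 30)
      pred <- sample(1:3, 90, replace = TRUE)
      cm <- table(factor(truth, levels = 1:3), factor(pred, levels = 1:3))
      class_balanced_accuracy(unclass(cm))
    })
    expect_equal(mean(accs), 1 / 3, tolerance = 0.02)
  })
})
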