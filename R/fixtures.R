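# Synthetic genome collections with class-discriminative planted motifs, so
# the whole search loop is exercisable without downloading any data.

#' Specify a synthetic genome class
#'
#' @param class_name Class label.
#' @param motifs Character vector of k-mers planted in this class's genomes.
#' @param density Expected motif insertions per 1000 nt (Poisson-distributed
#'   counts, uniform positions; insertions overwrite the background so genome
#'   length stays exact, and overlaps resolve last-writer-wins).
#' @param background Per-base composition over A, C, G, T (sums to 1).
#' @return A `motif_spec` list.
#' @export
motif_spec <- function(class_name, motifs, density,
                       background = c(0.25, 0.25, 0.25, 0.25)) {
  stopifnot(is.character(class_name), length(class_name) == 1L,
            is.character(motifs), length(motifs) >= 1L,
            density >= 0, length(background) == 4L)
  if (abs(sum(background) - 1) > 1e-8) {
    rlang::abort("background composition must sum to 1")
  }
  if (!all(strsplit(paste(motifs, collapse = ""), "")[[1]] %in% c("A", "C", "G", "T"))) {
    rlang::abort("motif alphabet must be a subset of {A, C, G, T}")
  }
  structure(list(class_name = class_name, motifs = motifs, density = density,
                 background = background),
            class = "motif_spec")
}

#' Generate per-class FASTA genome files
#'
#' Each genome is i.i.d. background sequence with the class's motifs
#' overwritten at Poisson-placed positions at the requested density. Output is
#' byte-identical under a fixed seed.
#'
#' @param specs List of [motif_spec()] objects, one per class.
#' @param files_per_class Number of genome files per class.
#' @param genome_length Genome length in nucleotides (>= 10 x the longest
#'   motif).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return A tibble with columns `class_name`, `file`.
#' @export
generate_genomes <- function(specs, files_per_class, genome_length, out_dir,
                             seed = 1L) {
  if (inherits(specs, "motif_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "motif_spec")),
            files_per_class >= 1, genome_length >= 1)
  max_motif <- max(vapply(specs, function(s) max(nchar(s$motifs)), integer(1)))
  if (genome_length < 10 * max_motif) {
    rlang::abort(sprintf(
      "genome_length (%d) must be at least 10 x the longest motif (%d nt)",
      genome_length, max_motif))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bases <- c("A", "C", "G", "T")
  out <- withr::with_seed(seed, {
    rows <- list()
    for (sp in specs) {
      for (i in seq_len(files_per_class)) {
        chars <- sample(bases, genome_length, replace = TRUE, prob = sp$background)
        n_ins <- stats::rpois(1L, genome_length / 1000 * sp$density)
        if (n_ins > 0L) {
          for (j in seq_len(n_ins)) {
            motif <- sp$motifs[[sample.int(length(sp$motifs), 1L)]]
            mlen <- nchar(motif)
            pos <- sample.int(genome_length - mlen + 1L, 1L)
            chars[pos:(pos + mlen - 1L)] <- strsplit(motif, "")[[1]]
          }
        }
        path <- file.path(out_dir, sprintf("%s_%02d.fasta", sp$class_name, i))
        writeLines(c(sprintf(">%s_%02d synthetic genome", sp$class_name, i),
                     paste(chars, collapse = "")), path)
        rows[[length(rows) + 1L]] <- tibble::tibble(class_name = sp$class_name,
                                                    file = path)
      }
    }
    dplyr::bind_rows(rows)
  })
  out
}

#' Split files into train/validation/test manifests
#'
#' File-level partition per class in the requested proportions, using
#' largest-remainder rounding so the parts are disjoint, exhaustive, and as
#' close to the fractions as integer counts allow.
#'
#' @param files A tibble with columns `class_name`, `file` (e.g. from
#'   [generate_genomes()]).
#' @param fractions Length-3 numeric `(train, validation, test)` summing to 1.
#' @return A manifest tibble with columns `class_name`, `file`, `role`.
#' @examples
#' \dontrun{
#' make_split(files, c(0.7, 0.2, 0.1))  # 10 files -> 7/2/1 per class
#' }
#' @export
make_split <- function(files, fractions = c(0.7, 0.2, 0.1)) {
  stopifnot(is.data.frame(files), all(c("class_name", "file") %in% names(files)),
            length(fractions) == 3L, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-8) rlang::abort("fractions must sum to 1")
  roles <- c("train", "validation", "test")
  out <- list()
  for (cl in unique(files$class_name)) {
    fs <- files$file[files$class_name == cl]
    n <- length(fs)
    n_parts <- sum(fractions > 0)
    if (n < n_parts) {
      rlang::abort(sprintf("class '%s' has %d files but the split needs %d parts",
                           cl, n, n_parts))
    }
    exact <- n * fractions
    counts <- floor(exact)
    rem <- n - sum(counts)
    if (rem > 0) {
      order_by_frac <- order(exact - counts, decreasing = TRUE)
      counts[order_by_frac[seq_len(rem)]] <- counts[order_by_frac[seq_len(rem)]] + 1
    }
    # every non-empty part gets at least one file
    for (p in which(fractions > 0 & counts == 0)) {
      donor <- which.max(counts)
      counts[donor] <- counts[donor] - 1
      counts[p] <- counts[p] + 1
    }
    role_vec <- rep(roles, counts)
    out[[cl]] <- tibble::tibble(class_name = cl, file = fs, role = role_vec)
  }
  dplyr::bind_rows(out)
}

#' Write / read a dataset manifest
#'
#' The manifest is a YAML file mapping each class to its FASTA files per role
#' (train / validation / test).
#'
#' @param manifest A manifest tibble (`class_name`, `file`, `role`).
#' @param path YAML file path.
#' @return `write_manifest()` the path invisibly; `read_manifest()` the
#'   manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("class_name", "file", "role") %in% names(manifest)))
  lst <- lapply(split(manifest, manifest$class_name), function(df) {
    lapply(split(df$file, df$role), as.list)
  })
  yaml::write_yaml(list(classes = lst), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lst <- yaml::read_yaml(path)
  rows <- list()
  for (cl in names(lst$classes)) {
    for (role in names(lst$classes[[cl]])) {
      fs <- unlist(lst$classes[[cl]][[role]])
      if (length(fs)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(class_name = cl, file = fs,
                                                    role = role)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Default planted-motif classes
#'
#' Three classes, one disjoint 8-mer each, uniform background. The default
#' density of 25 insertions per 1000 nt makes individual 150-nt windows
#' classifiable: a window then contains at least one motif with probability
#' about `1 - exp(-3.75) = 0.98`, so the balanced-accuracy ceiling of a
#' window-level classifier is about 0.985 (windows with no motif carry no
#' signal). At the densities of a few per 1000 the ceiling drops well below
#' 0.9 even for a perfect classifier.
#'
#' @param density Insertions per 1000 nt.
#' @return List of three [motif_spec()] objects.
#' @export
default_motif_classes <- function(density = 25) {
  list(
    motif_spec("alpha", "TTACGGAT", density),
    motif_spec("beta", "CAGTCTAC", density),
    motif_spec("gamma", "GGATACCG", density)
  )
}

#' Ready-to-use synthetic fixture bundle
#'
#' Generates a complete multi-class genome collection with a 70/20/10
#' file-level split and a manifest, sized for interactive testing: `tiny` is 3
#' classes x 6 files x 5 kb (seconds to generate), `small` is 3 classes x 30
#' files x 50 kb.
#'
#' @param profile `"tiny"` or `"small"`.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param density Motif insertions per 1000 nt (see
#'   [default_motif_classes()]).
#' @return A list with `manifest` (tibble), `manifest_path`, `files`.
#' @export
fixture_suite <- function(profile = c("tiny", "small"), dir = tempfile("fixtures"),
                          seed = 13L, density = 25) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    tiny = list(files = 6L, len = 5000L),
    small = list(files = 30L, len = 50000L))
  files <- generate_genomes(default_motif_classes(density), cfg$files, cfg$len,
                            out_dir = dir, seed = seed)
  manifest <- make_split(files, c(0.7, 0.2, 0.1))
  mp <- file.path(dir, "manifest.yaml")
  write_manifest(manifest, mp)
  list(manifest = manifest, manifest_path = mp, files = files)
}
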