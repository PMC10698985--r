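#' Synthetic dataset configuration
#'
#' Conditions for the planted-motif generator: sequences drawn from a
#' background residue distribution with a short interaction motif
#' planted at random positions; residues covered by a motif occurrence
#' are labeled 1 and labels are then flipped with a small noise
#' probability. The planting rate is solved from the noise level so the
#' final label prevalence matches `target_prevalence`.
#'
#' @param n_sequences Number of sequences (default 200).
#' @param length_range Min/max sequence length (default `c(30, 50)`).
#' @param motif Planted amino-acid motif (default `"CHWYK"`, length 5).
#' @param background Length-20 residue frequency vector (default
#'   uniform), in [AA_ALPHABET] order.
#' @param target_prevalence Target fraction of positive labels, in
#'   (0, 0.5) (default 0.15, the imbalance regime of curated PPI-site
#'   benchmarks, which run at roughly 10-18 percent positives).
#' @param noise_rate Label-flip probability (default 0.05).
#' @param pssm_margin Score bonus of the motif residue at motif
#'   positions in mock PSSMs (default 6).
#' @param seed Integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sequences = 200, length_range = c(30, 50),
                             motif = "CHWYK",
                             background = rep(1 / 20, 20),
                             target_prevalence = 0.15, noise_rate = 0.05,
                             pssm_margin = 6, seed = 1) {
  stopifnot(n_sequences >= 1, length(length_range) == 2,
            length_range[1] >= 2, length_range[2] >= length_range[1],
            length(background) == 20, all(background >= 0),
            sum(background) > 0,
            target_prevalence > 0, target_prevalence < 0.5,
            noise_rate >= 0, noise_rate < 0.5)
  check_residues(motif, "<motif>")
  if (nchar(motif) >= length_range[1]) {
    stop("motif must be shorter than the minimum sequence length",
         call. = FALSE)
  }
  plant_rate <- (target_prevalence - noise_rate) / (1 - 2 * noise_rate)
  if (plant_rate <= 0 || plant_rate >= 0.5) {
    stop("infeasible prevalence: target ", target_prevalence,
         " cannot be reached at noise rate ", noise_rate, call. = FALSE)
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 length_range = as.integer(length_range),
                 motif = motif,
                 background = background / sum(background),
                 target_prevalence = target_prevalence,
                 noise_rate = noise_rate,
                 plant_rate = plant_rate,
                 pssm_margin = pssm_margin,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a labeled synthetic dataset
#'
#' Draws sequences from the background distribution, plants
#' non-overlapping motif copies at seeded random positions at a rate
#' tuned to the target prevalence, labels motif-covered residues 1, and
#' flips each label independently with the configured noise rate. Fully
#' reproducible from the config seed. Each record carries the
#' noise-free motif coverage as attribute `"motif_mask"`.
#'
#' @param config A [synthetic_config].
#' @return List of [protein_record] objects.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  mot <- seq_chars(config$motif)
  mlen <- length(mot)
  with_seed(config$seed, {
    lapply(seq_len(config$n_sequences), function(s) {
      L <- sample(config$length_range[1]:config$length_range[2], 1)
      ch <- sample(AA_ALPHABET, L, replace = TRUE, prob = config$background)
      target <- config$plant_rate * L / mlen
      n_copies <- floor(target) + rbinom(1, 1, target - floor(target))
      covered <- logical(L)
      if (n_copies > 0) {
        starts <- sample.int(L - mlen + 1)
        placed <- 0
        for (st in starts) {
          span <- st:(st + mlen - 1)
          if (any(covered[span])) next
          ch[span] <- mot
          covered[span] <- TRUE
          placed <- placed + 1
          if (placed == n_copies) break
        }
      }
      labels <- as.integer(covered)
      if (config$noise_rate > 0) {
        flip <- rbinom(L, 1, config$noise_rate) == 1
        labels[flip] <- 1L - labels[flip]
      }
      rec <- protein_record(sprintf("syn%04d", s),
                            paste(ch, collapse = ""), labels)
      attr(rec, "motif_mask") <- covered
      rec
    })
  })
}

#' Generate a mock PSSM for a synthetic record
#'
#' Background positions receive small integer noise scores; at
#' motif-covered positions the column of the residue actually present
#' is raised by the configured margin, emulating the conservation
#' signal a profile search would produce. Scores are integers, matching
#' the log-odds printed by profile searches, so serialization round
#' trips exactly. Optionally writes the matrix in PSI-BLAST ASCII
#' layout readable by [parse_pssm].
#'
#' @param record A record from [generate_dataset].
#' @param config The [synthetic_config] used to generate it.
#' @param path Optional output path for the ASCII file.
#' @return Numeric L x 20 matrix (invisibly writes `path` if given).
#' @export
generate_mock_pssm <- function(record, config, path = NULL) {
  stopifnot(inherits(record, "protein_record"),
            inherits(config, "synthetic_config"))
  L <- nchar(record$sequence)
  idx <- aa_index(seq_chars(record$sequence))
  covered <- attr(record, "motif_mask")
  if (is.null(covered)) covered <- record$labels == 1L
  seed <- config$seed + sum(utf8ToInt(record$id))
  m <- with_seed(seed, {
    noise <- matrix(as.numeric(pmax(pmin(round(rnorm(L * 20, sd = 1.5)), 6),
                                    -6)), L, 20)
    noise
  })
  hot <- which(covered & !is.na(idx))
  m[cbind(hot, idx[hot])] <- m[cbind(hot, idx[hot])] + config$pssm_margin
  colnames(m) <- AA_ALPHABET
  if (!is.null(path)) write_pssm(m, record$sequence, path)
  m
}

#' Attach mock PSSMs to a record list
#'
#' @param records Records from [generate_dataset].
#' @param config The matching [synthetic_config].
#' @return The records, each with its `$pssm` filled in.
#' @export
attach_mock_pssms <- function(records, config) {
  lapply(records, function(r) {
    r$pssm <- generate_mock_pssm(r, config)
    r
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes the triplet-format sequence/label file plus one PSI-BLAST
#' ASCII mock PSSM file per record (`<id>.pssm`).
#'
#' @param config A [synthetic_config].
#' @param dir Output directory.
#' @param pssm Also write mock PSSM files (default `TRUE`).
#' @return The generated records, invisibly.
#' @export
simulate_to_dir <- function(config, dir, pssm = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- generate_dataset(config)
  write_triplet(records, file.path(dir, "sequences.txt"))
  if (pssm) {
    for (r in records) {
      generate_mock_pssm(r, config, file.path(dir, paste0(r$id, ".pssm")))
    }
  }
  invisible(records)
}
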