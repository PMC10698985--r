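#' Number of balanced partitions
#'
#' The majority (non-site) class is split into
#' `M = max(1, floor(n_neg / n_pos))` parts. Flooring guarantees that
#' every part paired with all positives has a negative/positive ratio
#' below 2 whenever negatives outnumber positives.
#'
#' @param n_neg Number of negative (non-site) samples.
#' @param n_pos Number of positive (site) samples, at least 1.
#' @return Integer M.
#' @export
compute_partition_count <- function(n_neg, n_pos) {
  if (n_pos < 1) stop("at least one positive sample is required",
                      call. = FALSE)
  max(1L, as.integer(floor(n_neg / n_pos)))
}

#' Build balanced training subsets
#'
#' Shuffles the negative sample indices with the given seed, splits them
#' into M near-equal disjoint parts (sizes differ by at most 1), and
#' pairs each part with all positive indices to form M training subsets.
#'
#' @param labels 0/1 vector over all training samples.
#' @param seed Integer seed for the negative shuffle.
#' @return An object of class `balanced_plan` with fields `M`,
#'   `positives`, `negative_parts` (list of index vectors), `subsets`
#'   (list of index vectors, positives first), `seed`.
#' @export
build_balanced_subsets <- function(labels, seed = 1) {
  labels <- as.integer(labels)
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both classes must be present to build balanced subsets",
         call. = FALSE)
  }
  M <- compute_partition_count(length(neg), length(pos))
  shuffled <- with_seed(seed, sample(neg))
  base <- length(neg) %/% M
  extra <- length(neg) %% M
  sizes <- rep(base, M) + c(rep(1L, extra), rep(0L, M - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  parts <- lapply(seq_len(M), function(m) sort(shuffled[starts[m]:ends[m]]))
  subsets <- lapply(parts, function(part) c(pos, part))
  structure(list(M = M, positives = pos, negative_parts = parts,
                 subsets = subsets, seed = as.integer(seed)),
            class = "balanced_plan")
}

#' @export
print.balanced_plan <- function(x, ...) {
  cat("<balanced_plan> M = ", x$M, ": ", length(x$positives),
      " positives + negative parts of sizes {",
      paste(vapply(x$negative_parts, length, 0L), collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}

#' Per-epoch subsampling of one balanced subset
#'
#' Subsamples the negatives of subset `subset_id` without replacement
#' down to the positive count, re-drawn each epoch (the RNG is seeded
#' with `seed XOR epoch`); all positives are always retained. A subset
#' that is already at most 1:1 is returned unchanged.
#'
#' @param plan A [build_balanced_subsets] result.
#' @param subset_id Subset index in `1..M`.
#' @param epoch Epoch number (>= 1).
#' @param seed Base seed; defaults to the plan's seed.
#' @return Integer vector of sample indices (positives then sampled
#'   negatives).
#' @export
epoch_subsample <- function(plan, subset_id, epoch, seed = plan$seed) {
  stopifnot(inherits(plan, "balanced_plan"),
            subset_id >= 1, subset_id <= plan$M, epoch >= 1)
  part <- plan$negative_parts[[subset_id]]
  n_pos <- length(plan$positives)
  if (length(part) <= n_pos) return(plan$subsets[[subset_id]])
  picked <- with_seed(bitwXor(as.integer(seed), as.integer(epoch)),
                      sample(part, n_pos))
  c(plan$positives, sort(picked))
}

#' Export a balancing plan as TSV
#'
#' One row per (sample, subset) membership with columns `sample_index`,
#' `subset_id`, `role` (`positive` / `negative`).
#'
#' @param plan A [build_balanced_subsets] result.
#' @param path Output path.
#' @export
write_plan <- function(plan, path) {
  rows <- do.call(rbind, lapply(seq_len(plan$M), function(m) {
    data.frame(sample_index = c(plan$positives, plan$negative_parts[[m]]),
               subset_id = m,
               role = c(rep("positive", length(plan$positives)),
                        rep("negative", length(plan$negative_parts[[m]]))))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
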