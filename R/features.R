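#' Feature extraction parameters
#'
#' Parameters of the windowed pseudo amino acid composition encoder:
#' `K` (residues kept on each side of the target, subsequence length
#' 2K+1), `lambda` (maximum sequence-order correlation level, so the
#' encoder emits 20 + lambda components) and `w` (weight of the
#' correlation terms relative to composition).
#'
#' @param K Half-width of the composition subsequence (default 10).
#' @param lambda Maximum correlation level (default 10, dimension 30).
#' @param w Correlation weight (default 0.05).
#' @return A named list.
#' @export
feature_params <- function(K = 10, lambda = 10, w = 0.05) {
  stopifnot(K >= 1, lambda >= 1, w > 0)
  list(K = as.integer(K), lambda = as.integer(lambda), w = w)
}

# dimension of the paired targeted-residue feature per feature module
fmod_dims <- function(params = feature_params()) {
  c(20L + 20L, 21L + 2L, 20L + 20L + params$lambda)
}

#' One-hot residue encoding
#'
#' Unit indicator over the 20 standard residues in alphabetical order;
#' `'X'` encodes as the zero vector.
#'
#' @param residue Single residue character.
#' @return Numeric vector of length 20.
#' @export
encode_one_hot <- function(residue) {
  if (residue == "X") return(numeric(20))
  i <- aa_index(residue)
  if (is.na(i)) stop("unknown residue letter: ", residue, call. = FALSE)
  v <- numeric(20)
  v[i] <- 1
  v
}

#' Entropy-density encoding of a sequence
#'
#' Component u is \eqn{-p_u \log_2 p_u} where \eqn{p_u} is the frequency
#' of amino acid u among the standard residues of the whole sequence
#' (0 where the residue is absent). Every residue of a sequence carries
#' the same entropy-density vector.
#'
#' @param sequence Sequence string.
#' @return Numeric vector of length 20.
#' @export
encode_entropy_density <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  ch <- check_residues(sequence)
  idx <- aa_index(ch)
  counts <- tabulate(idx[!is.na(idx)], nbins = 20)
  total <- sum(counts)
  p <- if (total > 0) counts / total else numeric(20)
  v <- numeric(20)
  nz <- p > 0
  v[nz] <- -p[nz] * log2(p[nz])
  names(v) <- AA_ALPHABET
  v
}

#' Physicochemical descriptor encoding
#'
#' Row lookup into the bundled 20 x 21 descriptor table
#' ([phychem_table]); `'X'` encodes as zeros.
#'
#' @param residue Single residue character.
#' @return Numeric vector of length 21.
#' @export
encode_phychem <- function(residue) {
  tab <- phychem_table()
  if (residue == "X") return(numeric(ncol(tab)))
  i <- aa_index(residue)
  if (is.na(i)) stop("unknown residue letter: ", residue, call. = FALSE)
  unname(tab[i, ])
}

#' Hydropathy index encoding
#'
#' Row lookup into the bundled 20 x 2 hydrophilicity/hydrophobicity
#' table ([hyin_table]); `'X'` encodes as zeros.
#'
#' @param residue Single residue character.
#' @return Numeric vector of length 2.
#' @export
encode_hyin <- function(residue) {
  tab <- hyin_table()
  if (residue == "X") return(numeric(2))
  i <- aa_index(residue)
  if (is.na(i)) stop("unknown residue letter: ", residue, call. = FALSE)
  unname(tab[i, ])
}

#' PSSM row encoding
#'
#' Returns row `i` of the profile matrix squashed elementwise to (0, 1)
#' by the logistic function, turning log-odds scores into probabilities.
#'
#' @param pssm Numeric L x 20 matrix.
#' @param i Residue position (1-based).
#' @return Numeric vector of length 20, values strictly in (0, 1).
#' @export
encode_pssm_row <- function(pssm, i) {
  if (i < 1 || i > nrow(pssm)) {
    stop("position ", i, " out of range for a ", nrow(pssm), "-row PSSM",
         call. = FALSE)
  }
  unname(plogis(as.numeric(pssm[i, ])))
}

#' Windowed pseudo amino acid composition (K-PseAA)
#'
#' Chou-type pseudo amino acid composition of the subsequence
#' `sequence[max(1, i-K) .. min(L, i+K)]`. The first 20 components are
#' normalized residue counts, components `20+j` are weighted
#' sequence-order correlation factors
#' \eqn{\theta_j = \frac{1}{L_s - j}\sum_i \Theta(R_i, R_{i+j})}, where
#' \eqn{\Theta} is the mean squared difference of three standardized
#' property scales (hydrophobicity, hydrophilicity, side-chain mass).
#' \eqn{\theta_j} is clamped to 0 when `j >= L_s` (edge subsequences
#' shorter than the correlation level). All components are normalized by
#' \eqn{\sum f + w \sum\theta} and sum to 1 whenever the subsequence
#' contains at least one standard residue. `'X'` residues are excluded
#' from composition counts and contribute 0 to every correlation pair.
#'
#' @param sequence Sequence string.
#' @param i Target residue position (1-based).
#' @param K Half-width of the subsequence.
#' @param lambda Maximum correlation level.
#' @param w Correlation weight.
#' @return Numeric vector of length `20 + lambda`.
#' @export
encode_kpseaa <- function(sequence, i, K = 10, lambda = 10, w = 0.05) {
  L <- nchar(sequence)
  if (i < 1 || i > L) {
    stop("position ", i, " out of range for a ", L, "-residue sequence",
         call. = FALSE)
  }
  stopifnot(K >= 1, lambda >= 1, w > 0)
  ch <- seq_chars(sequence)[max(1, i - K):min(L, i + K)]
  idx <- aa_index(ch)                    # NA for 'X'
  Ls <- length(idx)
  counts <- tabulate(idx[!is.na(idx)], nbins = 20)
  theta_mat <- pseaa_properties()$theta
  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    if (j >= Ls) break                   # theta_j = 0 at the edge clamp
    a <- idx[seq_len(Ls - j)]
    b <- idx[(1 + j):Ls]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      theta[j] <- sum(theta_mat[cbind(a[ok], b[ok])]) / (Ls - j)
    }
  }
  denom <- sum(counts) + w * sum(theta)
  if (denom == 0) return(numeric(20 + lambda))
  c(counts, w * theta) / denom
}

# per-sequence matrix of paired residue features (rows = positions)
residue_feature_matrix <- function(record, fmod, params = feature_params()) {
  stopifnot(inherits(record, "protein_record"))
  if (!fmod %in% 0:2) {
    stop("feature module index must be 0, 1 or 2, got ", fmod, call. = FALSE)
  }
  ch <- seq_chars(record$sequence)
  idx <- aa_index(ch)
  L <- length(ch)
  if (fmod == 0) {
    onehot <- matrix(0, L, 20)
    std <- !is.na(idx)
    onehot[cbind(which(std), idx[std])] <- 1
    den <- matrix(encode_entropy_density(record$sequence), L, 20, byrow = TRUE)
    return(cbind(onehot, den))
  }
  if (fmod == 1) {
    pc <- phychem_table()
    hy <- hyin_table()
    out <- matrix(0, L, ncol(pc) + ncol(hy))
    std <- which(!is.na(idx))
    out[std, seq_len(ncol(pc))] <- pc[idx[std], , drop = FALSE]
    out[std, ncol(pc) + seq_len(ncol(hy))] <- hy[idx[std], , drop = FALSE]
    return(out)
  }
  if (is.null(record$pssm)) {
    stop("record '", record$id, "': feature module 2 requires a PSSM",
         call. = FALSE)
  }
  prow <- plogis(record$pssm)
  kp <- t(vapply(seq_len(L), function(i) {
    encode_kpseaa(record$sequence, i, params$K, params$lambda, params$w)
  }, numeric(20 + params$lambda)))
  cbind(prow, kp)
}

#' Targeted residue feature
#'
#' The pair-concatenated feature vector of one residue for one feature
#' module: module 0 is one-hot + entropy density (dim 40), module 1 is
#' physicochemical + hydropathy (dim 23), module 2 is logistic-squashed
#' PSSM row + windowed pseudo amino acid composition (dim 50 at
#' `lambda = 10`).
#'
#' @param record A [protein_record].
#' @param i Residue position (1-based).
#' @param fmod Feature module index, 0, 1 or 2.
#' @param params [feature_params].
#' @return Numeric vector.
#' @export
build_targeted_feature <- function(record, i, fmod,
                                   params = feature_params()) {
  L <- nchar(record$sequence)
  if (i < 1 || i > L) {
    stop("position ", i, " out of range for record '", record$id, "'",
         call. = FALSE)
  }
  residue_feature_matrix(record, fmod, params)[i, ]
}

#' Sliding-window context matrix
#'
#' Rows are the targeted features of residues `i-W .. i+W` in order;
#' positions beyond either sequence end are zero rows flagged in the
#' padding mask.
#'
#' @param record A [protein_record].
#' @param i Target residue position (1-based).
#' @param W Window half-width (>= 1); the window holds 2W+1 residues.
#' @param fmod Feature module index.
#' @param params [feature_params].
#' @return List with `f_ctx` ((2W+1) x dim matrix) and `pad_mask`
#'   (logical vector, `TRUE` = zero-padded position).
#' @export
build_context_matrix <- function(record, i, W, fmod,
                                 params = feature_params()) {
  stopifnot(W >= 1)
  L <- nchar(record$sequence)
  if (i < 1 || i > L) {
    stop("position ", i, " out of range for record '", record$id, "'",
         call. = FALSE)
  }
  feat <- residue_feature_matrix(record, fmod, params)
  window_slice(feat, i, W)
}

# slice rows i-W..i+W out of a feature matrix with zero padding
window_slice <- function(feat, i, W) {
  L <- nrow(feat)
  pos <- (i - W):(i + W)
  pad <- pos < 1 | pos > L
  ctx <- matrix(0, 2 * W + 1, ncol(feat))
  ctx[!pad, ] <- feat[pos[!pad], , drop = FALSE]
  list(f_ctx = ctx, pad_mask = pad)
}

#' Full per-residue feature set
#'
#' Bundles the targeted feature, the windowed context matrix and its
#' padding mask for one residue, as consumed by [net_forward].
#'
#' @inheritParams build_context_matrix
#' @return An object of class `residue_feature_set` with fields `fmod`,
#'   `f_tr`, `f_ctx`, `pad_mask`, `target_position` (= W+1).
#' @export
build_residue_feature_set <- function(record, i, W, fmod,
                                      params = feature_params()) {
  ctx <- build_context_matrix(record, i, W, fmod, params)
  structure(list(fmod = fmod,
                 f_tr = ctx$f_ctx[W + 1, ],
                 f_ctx = ctx$f_ctx,
                 pad_mask = ctx$pad_mask,
                 target_position = W + 1L),
            class = "residue_feature_set")
}

#' Featurize a record collection into training arrays
#'
#' Computes per-sequence residue feature matrices once and assembles,
#' over all residues of all records, the context array, padding mask,
#' targeted-feature matrix and label vector used by the network engine.
#'
#' @param records List of [protein_record] objects.
#' @param fmod Feature module index.
#' @param W Window half-width.
#' @param params [feature_params].
#' @return List with `X` (N x (2W+1) x dim array), `mask` (N x (2W+1)
#'   logical), `ftr` (N x dim), `y` (N), `id` (N), `position` (N).
#' @export
featurize_records <- function(records, fmod, W, params = feature_params()) {
  lens <- vapply(records, function(r) nchar(r$sequence), 0L)
  N <- sum(lens)
  Lw <- 2L * W + 1L
  d <- fmod_dims(params)[fmod + 1]
  X <- array(0, c(N, Lw, d))
  mask <- matrix(FALSE, N, Lw)
  ftr <- matrix(0, N, d)
  y <- integer(N)
  id <- character(N)
  position <- integer(N)
  at <- 0L
  for (rec in records) {
    L <- nchar(rec$sequence)
    feat <- residue_feature_matrix(rec, fmod, params)
    padded <- rbind(matrix(0, W, d), feat, matrix(0, W, d))
    rows <- at + seq_len(L)
    for (l in seq_len(Lw)) {
      X[rows, l, ] <- padded[(l - 1L) + seq_len(L), , drop = FALSE]
      offs <- seq_len(L) + (l - W - 1L)
      mask[rows, l] <- offs < 1L | offs > L
    }
    ftr[rows, ] <- feat
    y[rows] <- rec$labels
    id[rows] <- rec$id
    position[rows] <- seq_len(L)
    at <- at + L
  }
  list(X = X, mask = mask, ftr = ftr, y = y, id = id, position = position,
       fmod = fmod, W = as.integer(W), params = params)
}
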