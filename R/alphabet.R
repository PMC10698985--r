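#' The 20 standard amino-acid letters
#'
#' Fixed alphabetical one-letter order used by every encoder in the
#' package. `'X'` (unknown residue) is additionally accepted in sequences
#' and is encoded as all-zeros by every encoder.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# residue letters -> 1..20 index into AA_ALPHABET; NA for 'X'
aa_index <- function(residues) match(residues, AA_ALPHABET)

# split a sequence string into single letters
seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

# reject any letter outside the 20-letter alphabet plus 'X'
check_residues <- function(sequence, id = "<sequence>") {
  ch <- seq_chars(sequence)
  bad <- setdiff(unique(ch), c(AA_ALPHABET, "X"))
  if (length(bad) > 0) {
    stop("record '", id, "': non-standard residue letter(s) ",
         paste(sQuote(bad), collapse = ", "),
         " (only the 20 standard amino acids plus 'X' are accepted)",
         call. = FALSE)
  }
  invisible(ch)
}

# ---- bundled lookup tables ------------------------------------------------

.table_cache <- new.env(parent = emptyenv())

load_bundled_table <- function(file) {
  if (!is.null(.table_cache[[file]])) return(.table_cache[[file]])
  path <- system.file("extdata", file, package = "ppistack")
  if (!nzchar(path) || !file.exists(path)) {
    stop("bundled table '", file, "' is missing from the installation",
         call. = FALSE)
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!identical(tab$aa, AA_ALPHABET)) {
    stop("bundled table '", file, "' rows are not the 20 standard residues ",
         "in alphabetical order", call. = FALSE)
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$aa
  storage.mode(m) <- "double"
  .table_cache[[file]] <- m
  m
}

#' Physicochemical descriptor table (synthetic stand-in)
#'
#' A 20 x 21 per-residue descriptor matrix constructed deterministically
#' from published hydropathy (Kyte-Doolittle), hydrophilicity (Hopp-Woods)
#' and side-chain mass scales by standardized polynomial expansion. It is
#' a synthetic stand-in with the dimensionality of descriptor sets
#' obtained by multivariate analysis of large amino-acid property
#' collections; the values are configuration, not logic, and are
#' validated structurally (20 rows, 21 finite columns).
#'
#' @return Numeric matrix, 20 rows (residues, alphabetical) x 21 columns.
#' @export
phychem_table <- function() load_bundled_table("phychem_synthetic.tsv")

#' Hydropathy index table
#'
#' Per-residue hydrophilicity (Hopp-Woods) and hydrophobicity
#' (Kyte-Doolittle hydropathy) indices.
#'
#' @return Numeric matrix, 20 rows x 2 columns
#'   (`hydrophilicity`, `hydrophobicity`).
#' @export
hyin_table <- function() load_bundled_table("hyin_index.tsv")

# standardized PseAA property scales (population-SD standardization, the
# convention of pseudo amino acid composition) and the derived 20x20
# mean-squared-difference correlation matrix Theta
pseaa_properties <- function() {
  if (!is.null(.table_cache[["pseaa_std"]])) {
    return(.table_cache[["pseaa_std"]])
  }
  raw <- load_bundled_table("pseaa_scales.tsv")
  std <- apply(raw, 2, function(x) {
    (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  })
  rownames(std) <- rownames(raw)
  theta <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (p in seq_len(ncol(std))) {
    theta <- theta + outer(std[, p], std[, p], function(a, b) (a - b)^2)
  }
  theta <- theta / ncol(std)
  out <- list(scales = std, theta = theta)
  .table_cache[["pseaa_std"]] <- out
  out
}

#' Published benchmark site statistics
#'
#' Site counts of the public PPI-site benchmark collections (number of
#' sequences, interaction sites and non-interaction sites per dataset),
#' shipped so dataset-level statistics (site percentages, balance
#' partition counts) can be recomputed without downloading the data.
#'
#' @return A data frame with columns `dataset`, `sequences`,
#'   `interaction_sites`, `noninteraction_sites`.
#' @export
benchmark_site_counts <- function() {
  path <- system.file("extdata", "benchmark_site_counts.tsv",
                      package = "ppistack")
  if (!nzchar(path)) {
    stop("bundled table 'benchmark_site_counts.tsv' is missing",
         call. = FALSE)
  }
  read.delim(path, stringsAsFactors = FALSE)
}
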