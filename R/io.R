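#' Construct a labeled protein record
#'
#' A protein record bundles a sequence over the 20 standard amino-acid
#' letters (plus `'X'` for unknown residues), one binary interaction-site
#' label per residue (1 = interaction site, the minority class), and an
#' optional position-specific scoring matrix with one 20-score row per
#' residue.
#'
#' @param id Record identifier.
#' @param sequence Amino-acid sequence string.
#' @param labels Integer/numeric vector of 0/1, one per residue.
#' @param pssm Optional numeric matrix, `nchar(sequence)` rows x 20 columns.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, labels, pssm = NULL) {
  id <- as.character(id)
  check_residues(sequence, id)
  labels <- as.integer(labels)
  if (length(labels) != nchar(sequence)) {
    stop("malformed record '", id, "': sequence has ", nchar(sequence),
         " residues but ", length(labels), " labels", call. = FALSE)
  }
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("malformed record '", id, "': labels must be 0 or 1", call. = FALSE)
  }
  if (!is.null(pssm)) {
    pssm <- as.matrix(pssm)
    if (nrow(pssm) != nchar(sequence) || ncol(pssm) != 20) {
      stop("record '", id, "': PSSM must be ", nchar(sequence),
           " x 20, got ", nrow(pssm), " x ", ncol(pssm), call. = FALSE)
    }
    storage.mode(pssm) <- "double"
  }
  structure(list(id = id, sequence = sequence, labels = labels, pssm = pssm),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, ": ", nchar(x$sequence), " residues, ",
      sum(x$labels), " interaction sites",
      if (!is.null(x$pssm)) ", with PSSM" else "", "\n", sep = "")
  invisible(x)
}

#' Read labeled protein sequences
#'
#' Reads per-residue labeled sequences in either the benchmark triplet
#' text format (three lines per record: `">id"`, the sequence, and a
#' `'0'`/`'1'` label string of equal length) or as a FASTA file paired
#' with a label TSV (`format = "fasta+tsv"`, columns `id` and `labels`,
#' the latter a 0/1 string per sequence).
#'
#' @param path Path to the triplet file, or to the FASTA file.
#' @param format `"triplet"` (default) or `"fasta+tsv"`.
#' @param labels_path For `"fasta+tsv"`: path of the label TSV.
#' @return A list of [protein_record] objects.
#' @export
read_labeled_sequences <- function(path, format = c("triplet", "fasta+tsv"),
                                   labels_path = NULL) {
  if (!is.character(format) || !format[1] %in% c("triplet", "fasta+tsv")) {
    stop("unknown format tag: ", format[1], call. = FALSE)
  }
  format <- format[1]
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "triplet") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) %% 3 != 0) {
      stop("malformed triplet file: number of non-empty lines (",
           length(lines), ") is not a multiple of 3", call. = FALSE)
    }
    n <- length(lines) %/% 3
    out <- vector("list", n)
    for (r in seq_len(n)) {
      hdr <- lines[3 * r - 2]
      if (!startsWith(hdr, ">")) {
        stop("malformed triplet file: expected '>' header at line ",
             3 * r - 2, call. = FALSE)
      }
      id <- trimws(sub("^>", "", hdr))
      seqline <- trimws(lines[3 * r - 1])
      labline <- trimws(lines[3 * r])
      if (grepl("[^01]", labline)) {
        stop("malformed record '", id, "': label line contains characters ",
             "other than 0/1", call. = FALSE)
      }
      labels <- as.integer(seq_chars(labline))
      out[[r]] <- protein_record(id, seqline, labels)
    }
    return(out)
  }
  # fasta + tsv
  if (is.null(labels_path)) {
    stop("format 'fasta+tsv' requires `labels_path`", call. = FALSE)
  }
  if (!file.exists(labels_path)) {
    stop("file not found: ", labels_path, call. = FALSE)
  }
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package", call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1)
  lab <- read.delim(labels_path, colClasses = "character")
  if (!all(c("id", "labels") %in% names(lab))) {
    stop("label TSV must have columns 'id' and 'labels'", call. = FALSE)
  }
  lapply(seq_along(seqs), function(k) {
    row <- match(ids[k], lab$id)
    if (is.na(row)) {
      stop("malformed record '", ids[k], "': no labels in ", labels_path,
           call. = FALSE)
    }
    labline <- lab$labels[row]
    if (grepl("[^01]", labline)) {
      stop("malformed record '", ids[k], "': labels must be a 0/1 string",
           call. = FALSE)
    }
    protein_record(ids[k], as.character(seqs[[k]]),
                   as.integer(seq_chars(labline)))
  })
}

#' Write records in triplet text format
#'
#' @param records List of [protein_record] objects.
#' @param path Output path.
#' @export
write_triplet <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    c(paste0(">", r$id), r$sequence, paste(r$labels, collapse = ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

# ---- PSSM -----------------------------------------------------------------

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the ASCII position-specific scoring matrix produced by
#' PSI-BLAST and returns the first 20 (log-odds) score columns as a
#' numeric matrix, one row per residue in sequence order.
#'
#' @param path Path to the ASCII PSSM file.
#' @return Numeric matrix, L x 20, with the residue letters as an
#'   attribute `"residues"`.
#' @export
parse_pssm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_row <- grepl("^\\s*[0-9]+\\s+[A-Z]\\b", lines)
  if (!any(is_row)) stop("PSSM parse error: no residue rows in ", path,
                         call. = FALSE)
  first <- which(is_row)[1]
  last <- first
  while (last < length(lines) && is_row[last + 1]) last <- last + 1
  rows <- lines[first:last]
  parsed <- lapply(seq_along(rows), function(k) {
    tok <- strsplit(trimws(rows[k]), "\\s+")[[1]]
    if (length(tok) < 22) {
      stop("PSSM parse error at residue row ", k, ": expected 20 score ",
           "columns, found ", length(tok) - 2, call. = FALSE)
    }
    idx <- suppressWarnings(as.integer(tok[1]))
    if (is.na(idx) || idx != k) {
      stop("PSSM parse error: residue row indices are not consecutive ",
           "(row ", k, " is numbered ", tok[1], ")", call. = FALSE)
    }
    scores <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(scores)) {
      stop("PSSM parse error at residue row ", k, ": non-numeric score cell",
           call. = FALSE)
    }
    list(res = tok[2], scores = scores)
  })
  m <- do.call(rbind, lapply(parsed, `[[`, "scores"))
  colnames(m) <- AA_ALPHABET
  attr(m, "residues") <- vapply(parsed, `[[`, "", "res")
  m
}

#' Write a score matrix in PSI-BLAST ASCII PSSM layout
#'
#' @param pssm Numeric matrix, L x 20 (columns in [AA_ALPHABET] order).
#' @param sequence Sequence string of length L.
#' @param path Output path.
#' @export
write_pssm <- function(pssm, sequence, path) {
  pssm <- as.matrix(pssm)
  ch <- seq_chars(sequence)
  if (nrow(pssm) != length(ch) || ncol(pssm) != 20) {
    stop("pssm must be length(sequence) x 20", call. = FALSE)
  }
  hdr <- c("",
           paste("Last position-specific scoring matrix computed,",
                 "weight matrix"),
           paste0("            ", paste(sprintf("%4s", AA_ALPHABET),
                                        collapse = ""), "  ",
                  paste(sprintf("%4s", AA_ALPHABET), collapse = "")))
  body <- vapply(seq_along(ch), function(i) {
    paste0(sprintf("%5d %s ", i, ch[i]),
           paste(sprintf("%4d", as.integer(round(pssm[i, ]))),
                 collapse = ""), "  ",
           paste(sprintf("%4d", rep(0L, 20)), collapse = ""),
           sprintf("  %5.2f %9.2f", 0, 0))
  }, "")
  tail_stats <- c("", "                      K         Lambda",
                  "Standard Ungapped    0.1340     0.3180",
                  "PSI Ungapped         0.1340     0.3180")
  writeLines(c(hdr, body, tail_stats), path)
  invisible(path)
}

# ---- dataset split --------------------------------------------------------

#' Split a dataset by sequence
#'
#' Randomly partitions records into train/validation/test subsets at the
#' sequence level (all residues of one sequence land in the same subset),
#' with sizes matching the given ratio up to rounding: each subset gets
#' the floor of its exact share and leftover sequences are assigned to
#' train first, then validation, then test.
#'
#' @param records List of [protein_record] objects (at least 5).
#' @param ratio Three positive integers, default `c(3, 1, 1)`.
#' @param seed Integer seed for the shuffle.
#' @return An object of class `dataset_split` with components `train`,
#'   `validation`, `test` (character id vectors) and `ratio`.
#' @export
split_dataset <- function(records, ratio = c(3, 1, 1), seed = 1) {
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate record ids", call. = FALSE)
  if (length(ratio) != 3 || any(ratio <= 0)) {
    stop("ratio must be three positive integers", call. = FALSE)
  }
  n <- length(ids)
  if (n < length(ratio)) {
    stop("fewer records (", n, ") than split parts", call. = FALSE)
  }
  shuffled <- with_seed(seed, sample(ids))
  sizes <- floor(n * ratio / sum(ratio))
  rem <- n - sum(sizes)
  if (rem > 0) {
    for (k in seq_len(rem)) {
      j <- ((k - 1) %% 3) + 1  # leftovers to train first, then val, then test
      sizes[j] <- sizes[j] + 1
    }
  }
  bounds <- cumsum(sizes)
  slice <- function(from, to) {
    if (to < from) character(0) else shuffled[from:to]
  }
  structure(list(train = slice(1, bounds[1]),
                 validation = slice(bounds[1] + 1, bounds[2]),
                 test = slice(bounds[2] + 1, bounds[3]),
                 ratio = ratio),
            class = "dataset_split")
}

#' Subset records by a split component
#'
#' @param records List of [protein_record] objects.
#' @param split A [split_dataset] result.
#' @param which One of `"train"`, `"validation"`, `"test"`.
#' @return The records whose ids fall in the chosen component.
#' @export
split_records <- function(records, split,
                          which = c("train", "validation", "test")) {
  which <- match.arg(which)
  ids <- vapply(records, `[[`, "", "id")
  records[ids %in% split[[which]]]
}

#' Write per-residue predictions as TSV
#'
#' Columns: `id`, `position` (0-based, the external file contract),
#' `score`, `call`.
#'
#' @param predictions Data frame with columns `id`, `position` (1-based,
#'   as used throughout the R API), `score`, `call`.
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  out <- data.frame(id = predictions$id,
                    position = predictions$position - 1L,
                    score = predictions$score,
                    call = predictions$call)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
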