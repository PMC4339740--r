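#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper around Biostrings readers returning plain upper-case
#' character sequences in file order. FASTQ records are structurally
#' validated first (4-line records, `@`/`+` markers, quality length equal
#' to sequence length) so that malformed files fail with the offending
#' line number; qualities are otherwise ignored — the decoding model has no
#' quality input.
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"` (default: guessed from the
#'   extension, falling back to fasta).
#' @return named character vector of sequences (names = record ids).
#' @export
read_sequences <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  format <- match.arg(format, c("fasta", "fastq"))
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  if (format == "fastq") .validate_fastq(path)
  x <- Biostrings::readDNAStringSet(path, format = format)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

.validate_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ (", path, "): truncated record at line ", length(lines))
  }
  for (k in seq_len(length(lines) %/% 4L)) {
    base <- (k - 1L) * 4L
    if (!startsWith(lines[base + 1L], "@")) {
      stop("malformed FASTQ: expected '@' header at line ", base + 1L)
    }
    if (!startsWith(lines[base + 3L], "+")) {
      stop("malformed FASTQ: expected '+' separator at line ", base + 3L)
    }
    if (nchar(lines[base + 4L]) != nchar(lines[base + 2L])) {
      stop("malformed FASTQ: quality length differs from sequence length at line ",
           base + 4L)
    }
  }
  invisible(TRUE)
}

#' Write sequences to FASTA or FASTQ
#'
#' FASTQ output carries a constant placeholder quality (`I`, Sanger Q40),
#' since the simulator has no quality model.
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(x) <- sprintf("seq%06d", seq_along(seqs))
  if (format == "fastq") {
    q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
      paste(rep("I", n), collapse = ""), character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

#' Serialize a barcode set
#'
#' Writes `<prefix>.fasta` (record ids = zero-padded message indices) and a
#' JSON sidecar `<prefix>.json` holding everything needed to reconstruct
#' the designed code: configuration, watermark, inner code words, the
#' DNA/Z4 mapping, the filter report and search provenance.
#'
#' @param set a `barcode_set` (or `designed_code`).
#' @param prefix output path prefix.
#' @return the sidecar path, invisibly.
#' @export
write_barcode_set <- function(set, prefix) {
  stopifnot(inherits(set, "barcode_set"))
  ids <- sprintf("%04d", set$indices)
  write_sequences(stats::setNames(set$barcodes, ids),
                  paste0(prefix, ".fasta"), "fasta")
  side <- list(
    config = set$config,
    watermark = dna_unmap(set$watermark),
    inner_words = apply(set$inner$words, 1L, dna_unmap),
    mapping = "A=0, C=1, G=2, T=3",
    outer_construction = set$outer$construction,
    d_H = set$outer$d_H,
    filter_report = if (!is.null(set$filter_report))
      unclass(set$filter_report) else NULL,
    search = set$search,
    status = set$status
  )
  path <- paste0(prefix, ".json")
  jsonlite::write_json(side, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_barcode_set
#' @param prefix path prefix used when writing (or the `.json` path itself).
#' @export
read_barcode_set <- function(prefix) {
  json_path <- if (grepl("\\.json$", prefix)) prefix else paste0(prefix, ".json")
  fasta_path <- sub("\\.json$", ".fasta", json_path)
  side <- jsonlite::fromJSON(json_path, simplifyVector = TRUE)
  cfg <- side$config
  outer <- build_outer_code(cfg$q1, cfg$n1, cfg$k1)
  words <- do.call(rbind, lapply(side$inner_words, dna_map))
  inner <- new_inner_code(words)
  w <- dna_map(side$watermark)
  full <- generate_barcode_set(outer, inner, w)
  seqs <- read_sequences(fasta_path, "fasta")
  idx <- as.integer(names(seqs))
  if (!identical(unname(full$barcodes[idx + 1L]), unname(seqs))) {
    stop("barcode FASTA does not match the code reconstructed from the sidecar")
  }
  out <- full
  out$barcodes <- unname(seqs)
  out$indices <- idx
  out$search <- side$search
  out$status <- side$status
  if (!is.null(side$filter_report)) {
    out$filter_report <- structure(as.list(side$filter_report),
                                   class = "filter_report")
  }
  class(out) <- c("designed_code", "barcode_set")
  out
}
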