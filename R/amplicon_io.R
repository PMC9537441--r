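#' Extract barcode keys from amplicon reads
#'
#' Locates the fixed-flank cassette motif
#' `five_flank (N20) linker (N20) three_flank` at any offset within each read
#' (amplicon libraries carry a 0-8 nt stagger before the motif) and returns
#' the 40-nt barcode key, i.e. the uppercase concatenation of the two N20
#' segments. With `max_flank_mismatch = 0` (the default, exact mode) the
#' three fixed segments must match perfectly; otherwise up to that many
#' mismatches are tolerated in each fixed segment separately. If there is no
#' plus-strand hit and `search_revcomp` is on, the reverse complement of the
#' read is searched. When several hits exist the leftmost plus-strand hit
#' wins and is counted once.
#'
#' @param reads Character vector of read sequences.
#' @param spec A [cassette_spec()].
#' @param max_flank_mismatch Mismatches allowed per fixed segment (default 0).
#' @param search_revcomp Also search the reverse complement (default TRUE).
#' @return A data.frame with columns `barcode_key` (NA when unmatched) and
#'   `reason` (NA when matched, else `"no_motif"`).
#' @examples
#' spec <- cassette_spec()
#' read <- paste0("ACGT", spec$five_flank, strrep("A", 20), spec$linker,
#'                strrep("C", 20), spec$three_flank, "TT")
#' extract_barcodes(read, spec)$barcode_key
#' @export
extract_barcodes <- function(reads, spec = cassette_spec(),
                             max_flank_mismatch = 0L, search_revcomp = TRUE) {
  reads <- toupper(as.character(reads))
  n <- length(reads)
  key <- rep(NA_character_, n)
  motif_len <- nchar(spec$five_flank) + 40L + nchar(spec$linker) +
    nchar(spec$three_flank)
  long_enough <- !is.na(reads) & nchar(reads) >= motif_len

  scan <- function(x) {
    if (max_flank_mismatch == 0L) {
      scan_exact(x, spec)
    } else {
      scan_mismatch(x, spec, max_flank_mismatch)
    }
  }

  key[long_enough] <- scan(reads[long_enough])
  if (search_revcomp) {
    miss <- long_enough & is.na(key)
    if (any(miss)) key[miss] <- scan(revcomp(reads[miss]))
  }
  data.frame(barcode_key = key,
             reason = ifelse(is.na(key), "no_motif", NA_character_),
             stringsAsFactors = FALSE)
}

#' @keywords internal
scan_exact <- function(reads, spec) {
  if (length(reads) == 0) return(character(0))
  pat <- sprintf("%s([ACGT]{20})%s([ACGT]{20})%s",
                 spec$five_flank, spec$linker, spec$three_flank)
  m <- regexpr(pat, reads, perl = TRUE)
  out <- rep(NA_character_, length(reads))
  hit <- m != -1L
  if (any(hit)) {
    cs <- attr(m, "capture.start")[hit, , drop = FALSE]
    cl <- attr(m, "capture.length")[hit, , drop = FALSE]
    out[hit] <- paste0(substr(reads[hit], cs[, 1L], cs[, 1L] + cl[, 1L] - 1L),
                       substr(reads[hit], cs[, 2L], cs[, 2L] + cl[, 2L] - 1L))
  }
  out
}

#' @keywords internal
scan_mismatch <- function(reads, spec, max_mm) {
  if (length(reads) == 0) return(character(0))
  # shortlist offsets with Biostrings (total mismatch budget = 3 * per-segment
  # budget), then verify the per-segment budgets at each shortlisted offset
  pat <- Biostrings::DNAString(paste0(spec$five_flank, strrep("N", 20),
                                      spec$linker, strrep("N", 20),
                                      spec$three_flank))
  nf <- nchar(spec$five_flank); nl <- nchar(spec$linker)
  tf <- nchar(spec$three_flank)
  subj <- Biostrings::DNAStringSet(reads)
  hits <- Biostrings::vmatchPattern(pat, subj, max.mismatch = 3L * max_mm,
                                    fixed = "subject")
  vapply(seq_along(reads), function(i) {
    starts <- sort(Biostrings::startIndex(hits)[[i]])
    for (s in starts) {
      r <- reads[i]
      f5 <- substr(r, s, s + nf - 1L)
      a <- substr(r, s + nf, s + nf + 19L)
      lk <- substr(r, s + nf + 20L, s + nf + 20L + nl - 1L)
      b <- substr(r, s + nf + 20L + nl, s + nf + 39L + nl)
      f3 <- substr(r, s + nf + 40L + nl, s + nf + 40L + nl + tf - 1L)
      if (hamming(f5, spec$five_flank) <= max_mm &&
          hamming(lk, spec$linker) <= max_mm &&
          hamming(f3, spec$three_flank) <= max_mm &&
          is_dna(a) && is_dna(b)) {
        return(paste0(a, b))
      }
    }
    NA_character_
  }, character(1))
}

#' @keywords internal
hamming <- function(x, y) {
  if (nchar(x) != nchar(y)) return(Inf)
  sum(charToRaw(x) != charToRaw(y))
}

#' Count barcodes against a reference library
#'
#' Extracts barcode keys per sample and counts each key iff it exactly
#' matches a reference key (the default, matching 100%-match counting).
#' With `hamming_rescue = d > 0`, extracted keys within Hamming distance
#' `d` of exactly one reference key are rescued to that key; ambiguous keys
#' (several references within `d`) stay unassigned.
#'
#' @param read_sets Named list of character vectors, one per sample (read
#'   sequences), or a named list of pre-extracted key vectors when
#'   `already_extracted = TRUE`.
#' @param reference Character vector of distinct 40-nt reference barcode
#'   keys (or a path to a FASTA/single-column TSV, see
#'   [read_barcode_reference()]).
#' @param spec A [cassette_spec()].
#' @param max_flank_mismatch Passed to [extract_barcodes()].
#' @param search_revcomp Passed to [extract_barcodes()].
#' @param hamming_rescue Hamming rescue distance (default 0 = exact only).
#' @param already_extracted Set TRUE if `read_sets` already holds extracted
#'   keys (NA = no motif).
#' @return A `barcode_count_table`: list with integer `counts` matrix
#'   (barcodes x samples), `totals` (assigned reads per sample) and
#'   `unassigned` matrix (reasons `no_motif`/`no_reference_match` x samples).
#' @export
count_barcodes <- function(read_sets, reference, spec = cassette_spec(),
                           max_flank_mismatch = 0L, search_revcomp = TRUE,
                           hamming_rescue = 0L, already_extracted = FALSE) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    reference <- read_barcode_reference(reference)
  }
  reference <- toupper(reference)
  if (length(reference) == 0) stop("reference is empty")
  if (anyDuplicated(reference)) stop("duplicate reference keys")
  if (is.null(names(read_sets)) || any(!nzchar(names(read_sets)))) {
    stop("read_sets must be a named list (one element per sample)")
  }
  samples <- names(read_sets)
  counts <- matrix(0L, nrow = length(reference), ncol = length(samples),
                   dimnames = list(reference, samples))
  unassigned <- matrix(0L, nrow = 2L, ncol = length(samples),
                       dimnames = list(c("no_motif", "no_reference_match"),
                                       samples))
  n_reads <- integer(length(samples)); names(n_reads) <- samples

  for (s in samples) {
    if (already_extracted) {
      keys <- as.character(read_sets[[s]])
    } else {
      keys <- extract_barcodes(read_sets[[s]], spec,
                               max_flank_mismatch = max_flank_mismatch,
                               search_revcomp = search_revcomp)$barcode_key
    }
    n_reads[s] <- length(keys)
    unassigned["no_motif", s] <- sum(is.na(keys))
    keys <- keys[!is.na(keys)]
    idx <- match(keys, reference)
    if (hamming_rescue > 0L && anyNA(idx)) {
      idx[is.na(idx)] <- rescue_keys(keys[is.na(idx)], reference,
                                     hamming_rescue)
    }
    unassigned["no_reference_match", s] <- sum(is.na(idx))
    tab <- tabulate(idx[!is.na(idx)], nbins = length(reference))
    counts[, s] <- as.integer(tab)
  }
  structure(list(counts = counts, totals = colSums(counts),
                 unassigned = unassigned, n_reads = n_reads),
            class = "barcode_count_table")
}

#' @keywords internal
rescue_keys <- function(keys, reference, d) {
  if (length(keys) == 0) return(integer(0))
  ref_mat <- do.call(rbind, strsplit(reference, ""))
  uk <- unique(keys)
  assign <- vapply(uk, function(k) {
    q <- strsplit(k, "")[[1L]]
    if (length(q) != ncol(ref_mat)) return(NA_integer_)
    dist <- rowSums(ref_mat != matrix(q, nrow = nrow(ref_mat),
                                      ncol = ncol(ref_mat), byrow = TRUE))
    near <- which(dist <= d)
    if (length(near) == 1L) near else NA_integer_
  }, integer(1))
  assign[match(keys, uk)]
}

#' @export
print.barcode_count_table <- function(x, ...) {
  cat("Barcode count table:", nrow(x$counts), "barcodes x",
      ncol(x$counts), "samples\n")
  cat("  assigned reads:", paste(sprintf("%s=%d", names(x$totals), x$totals),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Per-sample barcode fractions
#'
#' @param table A `barcode_count_table`.
#' @return Numeric matrix of counts / per-sample assigned totals.
#' @export
barcode_fractions <- function(table) {
  stopifnot(inherits(table, "barcode_count_table"))
  sweep(table$counts, 2L, pmax(table$totals, 1L), "/")
}

# ---- file I/O ---------------------------------------------------------------

#' Read amplicon FASTQ into a character vector of reads
#'
#' @param path FASTQ or FASTQ.gz file (single-end).
#' @param min_mean_quality Optional mean-quality filter (Phred); reads below
#'   it are dropped. Default `NULL` = off.
#' @return Character vector of read sequences.
#' @export
read_fastq_reads <- function(path, min_mean_quality = NULL) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = !is.null(min_mean_quality))
  if (!is.null(min_mean_quality)) {
    q <- Biostrings::PhredQuality(S4Vectors::mcols(x)$qualities)
    mq <- vapply(as(q, "IntegerList"), mean, numeric(1))
    x <- x[mq >= min_mean_quality]
  }
  as.character(x)
}

#' Read a barcode reference library
#'
#' Accepts a FASTA of cassette or key sequences, or a headerless
#' single-column TSV/text file of 40-nt keys. FASTA records longer than
#' 40 nt are assumed to be full cassettes and have their keys extracted via
#' the motif.
#'
#' @param path Input file.
#' @param spec A [cassette_spec()] (used for cassette FASTA input).
#' @return Character vector of barcode keys.
#' @export
read_barcode_reference <- function(path, spec = cassette_spec()) {
  is_fasta <- grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE) ||
    startsWith(readLines(path, n = 1L), ">")
  if (is_fasta) {
    seqs <- as.character(Biostrings::readDNAStringSet(path))
    keys <- ifelse(nchar(seqs) == 40L, seqs,
                   extract_barcodes(seqs, spec)$barcode_key)
    if (anyNA(keys)) stop("reference FASTA contains records without a valid cassette motif")
    return(unname(toupper(keys)))
  }
  keys <- read.table(path, header = FALSE, stringsAsFactors = FALSE)[[1L]]
  toupper(keys)
}

#' Write a barcode count table as TSV
#'
#' First column `barcode_key`, then one integer column per sample.
#' `write_count_table()` followed by [read_count_table()] is the identity on
#' counts, key order and sample order.
#'
#' @param table A `barcode_count_table`.
#' @param path Output TSV path.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "barcode_count_table"))
  keys <- rownames(table$counts)
  if (is.null(keys)) keys <- character(nrow(table$counts))
  df <- data.frame(barcode_key = keys,
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a barcode count table TSV
#'
#' @param path TSV written by [write_count_table()] (or compatible: header
#'   row of sample ids, first column `barcode_key`, integer counts).
#' @return A `barcode_count_table` (unassigned counts unknown, set to 0).
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty count table file")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (header[1L] != "barcode_key") {
    stop("parse error at line 1: first column must be 'barcode_key'")
  }
  samples <- header[-1L]
  n <- length(lines) - 1L
  counts <- matrix(0L, nrow = n, ncol = length(samples),
                   dimnames = list(NULL, samples))
  keys <- character(n)
  if (n > 0) {
    for (i in seq_len(n)) {
      f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
      if (length(f) != length(header)) {
        stop(sprintf("parse error at line %d: expected %d fields, found %d",
                     i + 1L, length(header), length(f)))
      }
      v <- suppressWarnings(as.integer(f[-1L]))
      if (anyNA(v)) {
        stop(sprintf("parse error at line %d: non-integer count", i + 1L))
      }
      keys[i] <- f[1L]
      counts[i, ] <- v
    }
  }
  rownames(counts) <- keys
  unassigned <- matrix(0L, nrow = 2L, ncol = length(samples),
                       dimnames = list(c("no_motif", "no_reference_match"),
                                       samples))
  structure(list(counts = counts, totals = colSums(counts),
                 unassigned = unassigned,
                 n_reads = colSums(counts)),
            class = "barcode_count_table")
}

#' Write a JSON run summary for a counting run
#'
#' @param table A `barcode_count_table`.
#' @param path Output JSON path.
#' @export
write_run_summary <- function(table, path) {
  stopifnot(inherits(table, "barcode_count_table"))
  summ <- lapply(colnames(table$counts), function(s) {
    list(reads_in = unname(table$n_reads[s]),
         assigned = unname(table$totals[s]),
         unassigned = as.list(table$unassigned[, s]))
  })
  names(summ) <- colnames(table$counts)
  jsonlite::write_json(summ, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
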