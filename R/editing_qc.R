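#' Global alignment of an amplicon read to a cassette reference
#'
#' Needleman-Wunsch global alignment (via Biostrings) with configurable
#' scores, returning the aligned pair and a CIGAR-like edit list (mismatch,
#' insertion, deletion runs in reference coordinates). Gap runs are
#' left-normalised (shifted as far 5' as sequence identity allows) so the
#' edit list is deterministic across score-equivalent placements.
#'
#' @param read Read sequence.
#' @param reference Cassette reference sequence.
#' @param match,mismatch,gap_open,gap_extend Alignment scores (defaults
#'   +1/-1/-4/-1, chosen for short indel-dominated amplicons).
#' @return An `amplicon_alignment`: list with `score`, `aligned_read`,
#'   `aligned_ref` and `edits` (data.frame: op in
#'   \{"mismatch","insertion","deletion"\}, ref_start, length, seq).
#'   For insertions `ref_start` is the reference position after which the
#'   bases are inserted.
#' @export
align_to_cassette <- function(read, reference, match = 1, mismatch = -1,
                              gap_open = 4, gap_extend = 1) {
  if (is.na(read) || !nzchar(read)) stop("empty read")
  assert_dna(read, "read")
  assert_dna(reference, "reference")
  if (nchar(read) > 2L * nchar(reference) ||
      nchar(reference) > 2L * nchar(read)) {
    stop("read length outside 2x of the reference length")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    pattern = read, subject = reference, type = "global",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend)
  ar <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  edits <- edits_from_gapped(ar, as_)
  structure(list(score = Biostrings::score(aln),
                 aligned_read = ar, aligned_ref = as_, edits = edits,
                 reference = reference, read = read),
            class = "amplicon_alignment")
}

#' @keywords internal
#' Derive a left-normalised edit list from a gapped alignment pair.
edits_from_gapped <- function(aligned_read, aligned_ref) {
  p <- strsplit(aligned_read, "")[[1L]]
  s <- strsplit(aligned_ref, "")[[1L]]
  n <- length(p)
  ref_chars <- s[s != "-"]
  ref_pos <- cumsum(s != "-")           # reference coordinate at each column
  op <- character(0); start <- integer(0); len <- integer(0); sq <- character(0)
  i <- 1L
  while (i <= n) {
    if (p[i] == "-") {                  # deletion from the reference
      j <- i
      while (j < n && p[j + 1L] == "-") j <- j + 1L
      d_start <- ref_pos[i]
      d_len <- j - i + 1L
      # left-shift while the base before the gap equals the base at gap end
      while (d_start > 1L &&
             ref_chars[d_start - 1L] == ref_chars[d_start + d_len - 1L]) {
        d_start <- d_start - 1L
      }
      op <- c(op, "deletion"); start <- c(start, d_start)
      len <- c(len, d_len)
      sq <- c(sq, paste0(ref_chars[seq.int(d_start, d_start + d_len - 1L)],
                         collapse = ""))
      i <- j + 1L
    } else if (s[i] == "-") {           # insertion relative to the reference
      j <- i
      while (j < n && s[j + 1L] == "-") j <- j + 1L
      ins <- p[i:j]
      anchor <- ref_pos[i]              # inserted after this reference base
      # left-shift: rotate while the ref base at the anchor equals the last
      # inserted base
      while (anchor > 0L && ref_chars[anchor] == ins[length(ins)]) {
        ins <- c(ins[length(ins)], ins[-length(ins)])
        anchor <- anchor - 1L
      }
      op <- c(op, "insertion"); start <- c(start, anchor)
      len <- c(len, j - i + 1L)
      sq <- c(sq, paste0(ins, collapse = ""))
      i <- j + 1L
    } else {
      if (p[i] != s[i]) {
        op <- c(op, "mismatch"); start <- c(start, ref_pos[i])
        len <- c(len, 1L); sq <- c(sq, p[i])
      }
      i <- i + 1L
    }
  }
  data.frame(op = op, ref_start = start, length = len, seq = sq,
             stringsAsFactors = FALSE)
}

#' Default cut window for a cassette spec
#'
#' The paired-nick edit window: from 3 nt inside the 3' end of site_a,
#' across the inter-site offset (linker), to 3 nt inside the 5' end of
#' site_b. Returned as inclusive \[start, end\] reference coordinates
#' (length 3 + offset + 3).
#'
#' @param spec A [cassette_spec()].
#' @return Integer vector `c(start, end)`.
#' @export
default_cut_window <- function(spec = cassette_spec()) {
  nf <- nchar(spec$five_flank); nl <- nchar(spec$linker)
  c(start = nf + 18L, end = nf + 20L + nl + 3L)
}

#' Classify the editing outcome of an aligned read
#'
#' The net indel length is insertions minus deletions restricted to the cut
#' window (an indel op counts with its full length when it overlaps the
#' window); a read is edited iff any indel overlaps the window. The frame
#' class follows net length mod 3: 0 = `in_frame`, 2 = `minus1_class` (the
#' "-1" frameshift that frames in the v2 selection marker), 1 =
#' `plus1_class`.
#'
#' @param alignment An `amplicon_alignment` from [align_to_cassette()].
#' @param cut_window Inclusive `c(start, end)` reference coordinates
#'   (default [default_cut_window()] of the default spec).
#' @param read_id Optional read identifier carried through.
#' @param barcode_key Optional assigned barcode key carried through.
#' @return An `editing_outcome` list: read_id, assigned_barcode_key,
#'   net_indel_len, edited, frame_class.
#' @export
classify_edit <- function(alignment, cut_window = default_cut_window(),
                          read_id = NA_character_,
                          barcode_key = NA_character_) {
  stopifnot(inherits(alignment, "amplicon_alignment"))
  s <- as.integer(cut_window[1L]); e <- as.integer(cut_window[2L])
  ref_len <- nchar(alignment$reference)
  if (s < 1L || e > ref_len || s > e) stop("cut window outside the reference")
  ed <- alignment$edits
  net <- 0L; edited <- FALSE
  if (nrow(ed)) {
    for (i in seq_len(nrow(ed))) {
      if (ed$op[i] == "deletion") {
        d0 <- ed$ref_start[i]; d1 <- d0 + ed$length[i] - 1L
        if (d1 >= s && d0 <= e) { net <- net - ed$length[i]; edited <- TRUE }
      } else if (ed$op[i] == "insertion") {
        p <- ed$ref_start[i]   # inserted between p and p+1
        if (p >= s && p <= e - 1L) { net <- net + ed$length[i]; edited <- TRUE }
      }
    }
  }
  frame_class <- c("in_frame", "plus1_class", "minus1_class")[(net %% 3L) + 1L]
  structure(list(read_id = read_id, assigned_barcode_key = barcode_key,
                 net_indel_len = net, edited = edited,
                 frame_class = frame_class),
            class = "editing_outcome")
}

#' Predicted reporter state for a frame class
#'
#' v1 (RFP-barcode-eGFP fusion): in-frame reads keep both fluorophores
#' (`RFP+/eGFP+`); any frameshift silences eGFP (`RFP+/eGFP-`).
#' v2 (polycistronic GFP/BSD/PuroR-HA): in-frame keeps `GFP+/BSD+`; only the
#' -1 frame class simultaneously frames out GFP and frames in the HA-tagged
#' puromycin marker (`GFP-/PuroR-HA+`, puromycin-resistant and
#' HA-detectable); the +1 class yields neither (`GFP-/PuroR-`).
#'
#' @param frame_class `"in_frame"`, `"minus1_class"` or `"plus1_class"`.
#' @param version `"v1"` or `"v2"`.
#' @return Reporter state string.
#' @export
reporter_state <- function(frame_class, version = c("v1", "v2")) {
  version <- match.arg(version)
  if (version == "v1") {
    ifelse(frame_class == "in_frame", "RFP+/eGFP+", "RFP+/eGFP-")
  } else {
    unname(c(in_frame = "GFP+/BSD+",
             minus1_class = "GFP-/PuroR-HA+",
             plus1_class = "GFP-/PuroR-")[frame_class])
  }
}

#' Expected frameshift fraction under an indel-size model
#'
#' Probability that the net indel length is not a multiple of 3. Under the
#' default model - net lengths uniform over sizes 1..30 - the fraction is
#' exactly 2/3 (20 of the 30 sizes are non-multiples of 3), the design-time
#' prediction for the fraction of targeted barcodes that silence the
#' reporter.
#'
#' @param lengths Integer net indel lengths with positive probability
#'   (default `1:30`; signs are irrelevant to the mod-3 class membership
#'   test used here, which checks `length %% 3 != 0`).
#' @param probs Probabilities for `lengths` (default uniform). Normalised
#'   internally.
#' @return The frameshift probability.
#' @examples
#' expected_frameshift_fraction()        # exactly 2/3
#' expected_frameshift_fraction(3, 1)    # 0: a point mass on size 3
#' @export
expected_frameshift_fraction <- function(lengths = 1:30, probs = NULL) {
  if (is.null(probs)) probs <- rep(1, length(lengths))
  if (length(probs) != length(lengths)) stop("lengths and probs differ in length")
  if (any(probs < 0) || sum(probs) == 0) stop("invalid probability weights")
  probs <- probs / sum(probs)
  if (all(lengths[probs > 0] == 0)) {
    warning("indel model places all mass at net length 0")
    return(0)
  }
  sum(probs[lengths %% 3 != 0])
}

#' Per-position edit profile along a cassette reference
#'
#' @param alignments List of `amplicon_alignment` objects against the same
#'   reference.
#' @return Data frame with per-reference-position deletion, insertion and
#'   substitution frequencies.
#' @export
position_profile <- function(alignments) {
  stopifnot(length(alignments) > 0)
  ref_len <- nchar(alignments[[1L]]$reference)
  del <- ins <- sub <- numeric(ref_len)
  for (a in alignments) {
    ed <- a$edits
    if (!nrow(ed)) next
    for (i in seq_len(nrow(ed))) {
      if (ed$op[i] == "deletion") {
        idx <- seq.int(ed$ref_start[i], ed$ref_start[i] + ed$length[i] - 1L)
        del[idx] <- del[idx] + 1
      } else if (ed$op[i] == "insertion") {
        p <- max(1L, ed$ref_start[i])
        ins[p] <- ins[p] + 1
      } else {
        sub[ed$ref_start[i]] <- sub[ed$ref_start[i]] + 1
      }
    }
  }
  n <- length(alignments)
  data.frame(position = seq_len(ref_len), deletion = del / n,
             insertion = ins / n, substitution = sub / n)
}

#' Composition purity and targeted fraction of a captured pool
#'
#' Assigns each read to a library barcode: first by exact motif extraction
#' (intact flanks and linker), then - for reads whose motif was destroyed by
#' editing - by best global alignment to the library cassettes, requiring
#' both N20 remnants outside the cut window to match the winning cassette
#' without edits. Reports the composition of the pool,
#' `composition_purity` (fraction of assignable reads carrying the intended
#' barcode) and `targeted_fraction` (fraction of assigned-to-target reads
#' whose cut window is edited).
#'
#' @param reads Character vector of read sequences.
#' @param target_barcode 40-nt barcode key of the intended clone.
#' @param reference_library Character vector of library barcode keys
#'   (must contain the target).
#' @param spec A [cassette_spec()].
#' @param cut_window Inclusive edit window (default [default_cut_window()]).
#' @return A `purity_report` list: composition (named fractions),
#'   composition_purity, targeted_fraction, n_assignable, n_unassignable.
#' @export
purity_report <- function(reads, target_barcode, reference_library,
                          spec = cassette_spec(),
                          cut_window = default_cut_window(spec)) {
  if (length(reads) == 0) stop("empty read set")
  reference_library <- toupper(reference_library)
  target_barcode <- toupper(target_barcode)
  if (!target_barcode %in% reference_library) {
    stop("target barcode not in the reference library")
  }
  cassettes <- paste0(spec$five_flank, substr(reference_library, 1, 20),
                      spec$linker, substr(reference_library, 21, 40),
                      spec$three_flank)
  names(cassettes) <- reference_library

  ext <- extract_barcodes(reads, spec)
  assigned <- ifelse(ext$barcode_key %in% reference_library,
                     ext$barcode_key, NA_character_)
  edited <- rep(FALSE, length(reads))

  # alignment fallback for motif-less (edited) reads
  nf <- nchar(spec$five_flank)
  n20a <- seq.int(nf + 1L, nf + 20L)
  n20b <- seq.int(nf + 20L + nchar(spec$linker) + 1L,
                  nf + 40L + nchar(spec$linker))
  keep_a <- n20a[n20a < cut_window[1L]]
  keep_b <- n20b[n20b > cut_window[2L]]
  for (i in which(is.na(assigned) & is.na(ext$barcode_key))) {
    r <- reads[i]
    if (!is_dna(r)) next
    if (nchar(r) < nchar(cassettes[1L]) / 2) next
    best <- -Inf; best_key <- NA_character_; best_aln <- NULL
    for (key in reference_library) {
      aln <- tryCatch(align_to_cassette(r, cassettes[[key]]),
                      error = function(e) NULL)
      if (is.null(aln)) next
      if (aln$score > best) { best <- aln$score; best_key <- key; best_aln <- aln }
    }
    if (is.na(best_key)) next
    if (remnants_match(best_aln, keep_a, keep_b)) {
      assigned[i] <- best_key
      oc <- classify_edit(best_aln, cut_window)
      edited[i] <- oc$edited
    }
  }

  assignable <- !is.na(assigned)
  comp <- table(factor(assigned[assignable], levels = reference_library))
  comp <- as.numeric(comp) / length(reads)
  names(comp) <- reference_library
  to_target <- assignable & assigned == target_barcode
  structure(list(
    composition = comp,
    composition_purity = if (sum(assignable) == 0) NA_real_ else
      sum(to_target) / sum(assignable),
    targeted_fraction = if (sum(to_target) == 0) 0 else
      mean(edited[to_target]),
    n_assignable = sum(assignable),
    n_unassignable = sum(!assignable),
    target_barcode = target_barcode),
    class = "purity_report")
}

#' @keywords internal
#' TRUE iff the alignment has no edits at the given reference positions
#' (the N20 remnants outside the cut window).
remnants_match <- function(alignment, keep_a, keep_b) {
  keep <- c(keep_a, keep_b)
  ed <- alignment$edits
  if (!nrow(ed)) return(TRUE)
  for (i in seq_len(nrow(ed))) {
    if (ed$op[i] == "insertion") {
      if (ed$ref_start[i] %in% keep[-length(keep)]) return(FALSE)
    } else {
      span <- seq.int(ed$ref_start[i], ed$ref_start[i] + ed$length[i] - 1L)
      if (any(span %in% keep)) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.purity_report <- function(x, ...) {
  cat("Purity report for", x$target_barcode, "\n")
  cat(sprintf("  composition purity: %.3f (%d assignable, %d unassignable)\n",
              x$composition_purity, x$n_assignable, x$n_unassignable))
  cat(sprintf("  targeted (edited) fraction: %.3f\n", x$targeted_fraction))
  invisible(x)
}
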