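#' Cassette specification
#'
#' Describes the fixed-flank, two-target-site barcode construct used for
#' nickase paired-gRNA barcoding: `five_flank (N20) linker (N20) three_flank`.
#' The two N20 segments are guide target sites in PAM-out orientation; the
#' PAMs are supplied by the fixed flanks (plus-strand NGG at the start of
#' `three_flank`, minus-strand NGG as the CCN at the end of `five_flank`).
#' The linker length equals the inter-site offset (15 bp by default, 9 bp
#' supported).
#'
#' @param five_flank 5' fixed flank (default `"CGTCCG"`).
#' @param linker Inter-site linker; its length is the nick offset
#'   (default `"GCCACCATGGTCGAC"`, 15 nt).
#' @param three_flank 3' fixed flank (default `"CGGTAG"`).
#' @param frame_phase Codon phase (0, 1 or 2) of the first base of
#'   `five_flank` within the fluorophore fusion reading frame.
#' @param version Reporter version, `"v1"` (RFP/eGFP fusion) or `"v2"`
#'   (polycistronic GFP/BSD/PuroR-HA reporter).
#' @param forbidden_motifs DNA motifs that must not occur in a cassette
#'   (default the MluI/BamHI cloning sites `ACGCGT`, `GGATCC`).
#' @return An object of class `cassette_spec`.
#' @examples
#' spec <- cassette_spec()
#' spec$offset_bp  # 15
#' @export
cassette_spec <- function(five_flank = "CGTCCG",
                          linker = "GCCACCATGGTCGAC",
                          three_flank = "CGGTAG",
                          frame_phase = 0L,
                          version = c("v1", "v2"),
                          forbidden_motifs = c("ACGCGT", "GGATCC")) {
  version <- match.arg(version)
  assert_dna(five_flank, "five_flank")
  assert_dna(linker, "linker")
  assert_dna(three_flank, "three_flank")
  if (length(forbidden_motifs)) assert_dna(forbidden_motifs, "forbidden_motifs")
  frame_phase <- as.integer(frame_phase)
  if (!frame_phase %in% 0:2) stop("frame_phase must be 0, 1 or 2")
  if (!nchar(linker) %in% c(9L, 15L)) {
    warning("linker length ", nchar(linker),
            " nt; supported nick offsets are 15 and 9 nt")
  }
  # PAM-out geometry must be realisable from the fixed flanks
  if (substr(three_flank, 2L, 3L) != "GG") {
    stop("three_flank must begin with an NGG triplet (plus-strand PAM)")
  }
  nf <- nchar(five_flank)
  if (substr(five_flank, nf - 2L, nf - 1L) != "CC") {
    stop("five_flank must end with a CCN triplet (minus-strand PAM)")
  }
  structure(
    list(five_flank = five_flank, linker = linker, three_flank = three_flank,
         offset_bp = nchar(linker), frame_phase = frame_phase,
         version = version, forbidden_motifs = forbidden_motifs),
    class = "cassette_spec")
}

#' @export
print.cassette_spec <- function(x, ...) {
  cat("Barcode cassette spec (", x$version, ")\n", sep = "")
  cat("  motif: ", x$five_flank, "(N20)", x$linker, "(N20)", x$three_flank,
      "\n", sep = "")
  cat("  offset:", x$offset_bp, "nt; frame phase:", x$frame_phase, "\n")
  cat("  forbidden motifs:", paste(x$forbidden_motifs, collapse = ", "), "\n")
  invisible(x)
}

#' Guide target site
#'
#' @param site_id Identifier, unique within a pool.
#' @param protospacer 20-nt plus-strand sequence as it appears in the cassette.
#' @param pool `"top"` or `"bottom"` (cassette position / oligo pool).
#' @param on_target_score Optional score in \[0, 100\].
#' @return A `guide_site` object.
#' @export
guide_site <- function(site_id, protospacer, pool = c("top", "bottom"),
                       on_target_score = NA_real_) {
  pool <- match.arg(pool)
  assert_dna(protospacer, "protospacer")
  if (nchar(protospacer) != 20L) stop("protospacer must be exactly 20 nt")
  structure(list(site_id = as.character(site_id), protospacer = protospacer,
                 pool = pool, on_target_score = as.numeric(on_target_score)),
            class = "guide_site")
}

# ---- candidate filtering ----------------------------------------------------

#' @keywords internal
#' Context string and candidate coordinates for a pool position.
#' Returns list(context, cand_start, cassette_offset) where cassette_offset is
#' the cassette coordinate of context position 1.
candidate_context <- function(spec, pool) {
  nf <- nchar(spec$five_flank)
  nl <- nchar(spec$linker)
  if (pool == "top") {
    list(context = paste0(spec$five_flank, "%s", spec$linker),
         cand_start = nf + 1L, cassette_offset = 1L)
  } else {
    # bottom candidate occupies cassette positions nf+20+nl+1 .. nf+20+nl+20
    list(context = paste0(spec$linker, "%s", spec$three_flank),
         cand_start = nl + 1L, cassette_offset = nf + 20L + 1L)
  }
}

#' @keywords internal
#' Stop-codon positions (context coords) in in-frame codons overlapping
#' [cand_start, cand_end] of `context`, with the frame anchored on the
#' cassette coordinate system.
stops_overlapping_candidate <- function(context, cand_start, cand_end,
                                        cassette_offset, frame_phase,
                                        all_frames = FALSE) {
  phases <- if (all_frames) 0:2 else frame_phase
  hits <- integer(0)
  for (ph in phases) {
    # cassette position j starts a codon iff (ph + j - 1) %% 3 == 0
    # context position i corresponds to cassette position i + cassette_offset - 1
    first_cass <- cassette_offset
    shift <- (-(ph + first_cass - 1L)) %% 3L  # context offset of first codon start
    starts <- seq.int(1L + shift, nchar(context), by = 3L)
    # keep codons whose 3-nt span intersects the candidate
    starts <- starts[starts + 2L >= cand_start & starts <= cand_end]
    hits <- c(hits, find_stop_codons(context, starts))
  }
  sort(unique(hits))
}

#' Filter guide candidates for a cassette position
#'
#' Accepts a 20-nt candidate iff it (a) is exactly 20 nt over A/C/G/T,
#' (b) introduces no stop codon (TAA/TAG/TGA) into any in-frame codon
#' overlapping the candidate when placed in its cassette position (junction
#' codons with the fixed flank/linker included), (c) contains no forbidden
#' motif, including motifs straddling junctions with the fixed segments, and
#' (d) has an on-target score at least `min_score` when scoring is enabled.
#' The first failing rule is recorded as the rejection reason.
#'
#' @param candidates Character vector of candidate 20-mers. Names, if present,
#'   become site ids.
#' @param spec A [cassette_spec()].
#' @param pool `"top"` or `"bottom"`.
#' @param min_score Minimum on-target score, or `NULL` to disable scoring.
#' @param scores Optional named numeric vector of scores for all candidates;
#'   when `NULL` and `min_score` is set, the built-in heuristic
#'   [heuristic_guide_score()] is used.
#' @param strict_frames If `TRUE`, exclude stops in all three forward frames
#'   rather than only the design frame.
#' @return A `design_report` list with `accepted` (data.frame: site_id,
#'   protospacer, pool, score) and `rejected` (data.frame: candidate, reason).
#' @export
filter_guide_candidates <- function(candidates, spec, pool = c("top", "bottom"),
                                    min_score = NULL, scores = NULL,
                                    strict_frames = FALSE) {
  pool <- match.arg(pool)
  if (length(candidates) == 0) stop("candidate list is empty")
  candidates <- toupper(as.character(candidates))
  ids <- names(candidates)
  if (is.null(ids)) ids <- sprintf("%s_%05d", pool, seq_along(candidates))
  use_score <- !is.null(min_score)
  if (use_score) {
    if (is.null(scores)) {
      scores <- heuristic_guide_score(candidates)
    } else {
      if (!is.null(names(scores))) scores <- scores[candidates]
      if (length(scores) != length(candidates) || anyNA(scores)) {
        stop("scores must be provided for all candidates when min_score is used")
      }
    }
  } else {
    scores <- rep(NA_real_, length(candidates))
  }

  ctx <- candidate_context(spec, pool)
  reason <- rep(NA_character_, length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[i]
    if (nchar(cand) != 20L) { reason[i] <- "bad_length"; next }
    if (!is_dna(cand)) { reason[i] <- "non_ACGT"; next }
    context <- sprintf(ctx$context, cand)
    cand_end <- ctx$cand_start + 19L
    stops <- stops_overlapping_candidate(context, ctx$cand_start, cand_end,
                                         ctx$cassette_offset, spec$frame_phase,
                                         all_frames = strict_frames)
    if (length(stops)) { reason[i] <- "stop_codon"; next }
    if (has_forbidden_motif(context, ctx$cand_start, cand_end,
                            spec$forbidden_motifs)) {
      reason[i] <- "forbidden_motif"; next
    }
    if (use_score && scores[i] < min_score) { reason[i] <- "low_score"; next }
  }

  ok <- is.na(reason)
  structure(
    list(accepted = data.frame(site_id = ids[ok], protospacer = candidates[ok],
                               pool = rep(pool, sum(ok)), score = scores[ok],
                               stringsAsFactors = FALSE),
         rejected = data.frame(candidate = candidates[!ok],
                               reason = reason[!ok],
                               stringsAsFactors = FALSE),
         pool = pool),
    class = "design_report")
}

#' @keywords internal
has_forbidden_motif <- function(context, cand_start, cand_end, motifs) {
  for (m in motifs) {
    hits <- gregexpr(m, context, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    w <- nchar(m)
    if (any(hits + w - 1L >= cand_start & hits <= cand_end)) return(TRUE)
  }
  FALSE
}

#' Built-in heuristic guide score
#'
#' A deliberately simple activity proxy for when no external on-target scores
#' are supplied: 100 if the GC fraction lies in \[0.3, 0.8\] and the sequence
#' has no homopolymer run of length 5 or more, else 0.
#'
#' @param x Character vector of 20-mers.
#' @return Numeric vector of scores (0 or 100).
#' @export
heuristic_guide_score <- function(x) {
  gc <- vapply(strsplit(toupper(x), ""), function(ch) {
    mean(ch %in% c("G", "C"))
  }, numeric(1))
  homo <- grepl("A{5}|C{5}|G{5}|T{5}", toupper(x))
  ifelse(gc >= 0.3 & gc <= 0.8 & !homo, 100, 0)
}

# ---- assembly ---------------------------------------------------------------

#' Assemble a barcode cassette from two guide sites
#'
#' Concatenates `five_flank + site_a + linker + site_b + three_flank` and
#' validates the PAM-out geometry: a plus-strand NGG immediately 3' of
#' `site_b` (start of `three_flank`) and a minus-strand NGG adjacent to
#' `site_a` (the CCN at the end of `five_flank`).
#'
#' @param site_a A top-pool [guide_site()].
#' @param site_b A bottom-pool [guide_site()].
#' @param spec A [cassette_spec()].
#' @return A `barcode_cassette` list with `full_sequence` and the 40-nt
#'   `barcode_key` (`site_a` then `site_b`).
#' @export
assemble_cassette <- function(site_a, site_b, spec = cassette_spec()) {
  if (!inherits(site_a, "guide_site") || !inherits(site_b, "guide_site")) {
    stop("site_a and site_b must be guide_site objects")
  }
  if (site_a$pool != "top" || site_b$pool != "bottom") {
    stop("pool mismatch: site_a must be from the top pool and site_b from the bottom pool")
  }
  # geometry re-check (cassette_spec() already enforces this for defaults,
  # but a hand-built spec list could violate it)
  nf <- nchar(spec$five_flank)
  if (substr(spec$three_flank, 2L, 3L) != "GG" ||
      substr(spec$five_flank, nf - 2L, nf - 1L) != "CC") {
    stop("PAM-out geometry unsatisfiable: flanks do not provide NGG/CCN PAMs")
  }
  full <- paste0(spec$five_flank, site_a$protospacer, spec$linker,
                 site_b$protospacer, spec$three_flank)
  structure(
    list(site_a = site_a, site_b = site_b, spec = spec,
         full_sequence = full,
         barcode_key = paste0(site_a$protospacer, site_b$protospacer)),
    class = "barcode_cassette")
}

#' @export
print.barcode_cassette <- function(x, ...) {
  cat("Barcode cassette", x$barcode_key, "\n")
  cat(" ", x$full_sequence, "\n")
  invisible(x)
}

#' Capturing guide spacers for a cassette
#'
#' Returns the two 20-nt gRNA spacers needed to target (capture) this
#' barcode: the plus-strand site (`site_b`, PAM in `three_flank`) is targeted
#' by a spacer equal to `site_b`; the minus-strand site (`site_a`, PAM on the
#' minus strand) by the reverse complement of `site_a`.
#'
#' @param cassette A `barcode_cassette`.
#' @return Named character vector `c(site_a = ..., site_b = ...)`.
#' @export
capture_guides_for <- function(cassette) {
  stopifnot(inherits(cassette, "barcode_cassette"))
  c(site_a = revcomp(cassette$site_a$protospacer),
    site_b = cassette$site_b$protospacer)
}

# ---- v2 frame safety --------------------------------------------------------

#' Frame-safety report for the v2 reporter
#'
#' The v2 polycistronic reporter requires that a -1 frameshift through the
#' barcode region reads into the selection-marker frame without premature
#' stops, and that no -1 programmed ribosomal frameshifting (PRF) slippery
#' site is present. This scans a region for stop codons in the design frame
#' (codons starting at position 1, 4, ...), stop codons in the -1-shifted
#' frame, and slippery heptamers `X1X1X1 X2X2X2 N` with X2 in {A, T}.
#'
#' @param region DNA string (a cassette or any reporter region).
#' @param spec A [cassette_spec()] with `version = "v2"`.
#' @param slippery_x2 Bases allowed as the X2 triplet of the slippery
#'   heptamer (default `c("A", "T")`).
#' @return List with `stops_frame0`, `stops_minus1` (codon start positions),
#'   `slippery_sites` (heptamer start positions) and `pass` (TRUE iff all
#'   three are empty).
#' @export
check_frames_v2 <- function(region, spec = cassette_spec(version = "v2"),
                            slippery_x2 = c("A", "T")) {
  if (spec$version != "v2") stop("check_frames_v2 requires a v2 spec")
  assert_dna(region, "region")
  n <- nchar(region)
  f0 <- find_stop_codons(region, seq.int(1L, n, by = 3L))
  # -1 slip: the ribosome steps back one nt, codons start one base earlier;
  # within the region the shifted codon starts are at positions 3, 6, ...
  fm1 <- if (n >= 3L) find_stop_codons(region, seq.int(3L, n, by = 3L)) else integer(0)
  slippery <- integer(0)
  if (n < 7L) {
    warning("region shorter than 7 nt; slippery-site scan skipped")
  } else {
    ch <- strsplit(region, "")[[1L]]
    for (i in seq_len(n - 6L)) {
      x1 <- ch[i]
      x2 <- ch[i + 3L]
      if (ch[i + 1L] == x1 && ch[i + 2L] == x1 &&
          x2 %in% slippery_x2 && ch[i + 4L] == x2 && ch[i + 5L] == x2) {
        slippery <- c(slippery, i)
      }
    }
  }
  list(stops_frame0 = f0, stops_minus1 = fm1, slippery_sites = slippery,
       pass = length(f0) == 0 && length(fm1) == 0 && length(slippery) == 0)
}

# ---- library enumeration ----------------------------------------------------

#' Enumerate the combinatorial cassette library
#'
#' Library complexity is `|top| * |bottom|`; every (top, bottom) pair is one
#' cassette with a distinct 40-nt barcode key. With 6,000 sites per pool
#' (~12,000 synthesized oligos) the design reaches 36 million barcodes.
#'
#' @param top,bottom Accepted sites: character vectors of protospacers
#'   (optionally named by site id) or the `accepted` data.frame of a
#'   [filter_guide_candidates()] report.
#' @param spec A [cassette_spec()].
#' @return A `cassette_library` list with `complexity` and a
#'   `cassettes(idx)` accessor that materialises cassette records
#'   (site ids, barcode_key, full_sequence) for library indices `idx`
#'   (row-major over top x bottom, each pair yielded exactly once).
#' @export
enumerate_library <- function(top, bottom, spec = cassette_spec()) {
  top <- as_site_table(top, "top")
  bottom <- as_site_table(bottom, "bottom")
  if (nrow(top) == 0 || nrow(bottom) == 0) stop("site pools must be non-empty")
  if (anyDuplicated(top$protospacer)) {
    stop("duplicate protospacers in the top pool would break barcode uniqueness")
  }
  if (anyDuplicated(bottom$protospacer)) {
    stop("duplicate protospacers in the bottom pool would break barcode uniqueness")
  }
  n1 <- nrow(top); n2 <- nrow(bottom)
  complexity <- as.numeric(n1) * as.numeric(n2)
  cassettes <- function(idx = seq_len(complexity)) {
    idx <- as.numeric(idx)
    if (any(idx < 1 | idx > complexity)) stop("cassette index out of range")
    i <- ((idx - 1) %/% n2) + 1  # top index (row-major)
    j <- ((idx - 1) %% n2) + 1
    data.frame(
      site_a_id = top$site_id[i], site_b_id = bottom$site_id[j],
      site_a = top$protospacer[i], site_b = bottom$protospacer[j],
      barcode_key = paste0(top$protospacer[i], bottom$protospacer[j]),
      full_sequence = paste0(spec$five_flank, top$protospacer[i], spec$linker,
                             bottom$protospacer[j], spec$three_flank),
      stringsAsFactors = FALSE)
  }
  structure(list(complexity = complexity, n_top = n1, n_bottom = n2,
                 top = top, bottom = bottom, spec = spec,
                 cassettes = cassettes),
            class = "cassette_library")
}

#' @export
print.cassette_library <- function(x, ...) {
  cat("Cassette library:", x$n_top, "top x", x$n_bottom, "bottom =",
      format(x$complexity, big.mark = ","), "barcodes\n")
  invisible(x)
}

#' @keywords internal
as_site_table <- function(x, pool) {
  if (is.data.frame(x)) {
    stopifnot(all(c("site_id", "protospacer") %in% names(x)))
    return(x[, c("site_id", "protospacer")])
  }
  if (inherits(x, "design_report")) return(x$accepted[, c("site_id", "protospacer")])
  ids <- names(x)
  x <- toupper(as.character(x))
  if (is.null(ids)) ids <- sprintf("%s_%05d", pool, seq_along(x))
  assert_dna(x, "protospacer")
  if (any(nchar(x) != 20L)) stop("protospacers must be 20 nt")
  data.frame(site_id = ids, protospacer = unname(x), stringsAsFactors = FALSE)
}

# ---- oligo emission ---------------------------------------------------------

#' Emit single-stranded synthesis oligos for the library
#'
#' Each top oligo carries `five_flank + site + linker prefix`, each bottom
#' oligo the reverse complement of `linker suffix + site + three_flank`; the
#' two share a complementary 3' pairing region of exactly `pairing_overlap`
#' nt centred in the linker, so that annealing any (top, bottom) pair and
#' extending reconstructs the full cassette sequence exactly.
#'
#' @param top_sites,bottom_sites Protospacer vectors or accepted-site tables.
#' @param spec A [cassette_spec()].
#' @param pairing_overlap Length of the complementary 3' region (<= linker
#'   length; default the full linker).
#' @return List with character vectors `top` and `bottom` (named by site id).
#' @export
emit_oligos <- function(top_sites, bottom_sites, spec = cassette_spec(),
                        pairing_overlap = nchar(spec$linker)) {
  top <- as_site_table(top_sites, "top")
  bottom <- as_site_table(bottom_sites, "bottom")
  nl <- nchar(spec$linker)
  if (pairing_overlap > nl) stop("pairing_overlap exceeds linker length")
  if (pairing_overlap < 1L) stop("pairing_overlap must be at least 1 nt")
  s2 <- ((nl - pairing_overlap) %/% 2L) + 1L   # overlap start within linker
  e1 <- s2 + pairing_overlap - 1L              # top oligo covers linker[1..e1]
  top_oligo <- paste0(spec$five_flank, top$protospacer,
                      substr(spec$linker, 1L, e1))
  bottom_plus <- paste0(substr(spec$linker, s2, nl), bottom$protospacer,
                        spec$three_flank)
  bottom_oligo <- revcomp(bottom_plus)
  names(top_oligo) <- top$site_id
  names(bottom_oligo) <- bottom$site_id
  list(top = top_oligo, bottom = bottom_oligo, overlap = pairing_overlap)
}

# ---- library output ---------------------------------------------------------

#' Write a cassette library as FASTA plus a TSV manifest
#'
#' @param library A `cassette_library` from [enumerate_library()].
#' @param fasta_path,manifest_path Output files; `NULL` skips that output.
#' @param idx Library indices to write (default all; guard large libraries).
#' @return Invisibly, the manifest data.frame.
#' @export
write_library <- function(library, fasta_path = NULL, manifest_path = NULL,
                          idx = NULL) {
  stopifnot(inherits(library, "cassette_library"))
  if (is.null(idx)) {
    if (library$complexity > 1e6) {
      stop("library too large to materialise; pass an explicit idx")
    }
    idx <- seq_len(library$complexity)
  }
  recs <- library$cassettes(idx)
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::DNAStringSet(recs$full_sequence)
    names(seqs) <- recs$barcode_key
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
  if (!is.null(manifest_path)) {
    utils::write.table(recs, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(recs)
}
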