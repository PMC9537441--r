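test_that("candidate filtering enforces stop-codon, motif and alphabet rules", {
  spec <- default_spec
  cand <- c(stop = "AAATAAGGCCGGCCGGCCGG",   # TAA lands on an in-frame codon
            clean = "CCCCCCCCCCCCCCCCCCCC",  # no stop possible in a C run
            mlu = "GGGGGGGGACGCGTGGGGGG",    # contains the MluI site
            bad = "GGGGGGGGNNGGGGGGGGGG",    # ambiguous bases
            short = "ACGT")
  rep <- filter_guide_candidates(cand, spec, "top")
  expect_equal(rep$accepted$protospacer, "CCCCCCCCCCCCCCCCCCCC")
  rej <- setNames(rep$rejected$reason, rep$rejected$candidate)
  expect_equal(unname(rej["AAATAAGGCCGGCCGGCCGG"]), "stop_codon")
  expect_equal(unname(rej["GGGGGGGGACGCGTGGGGGG"]), "forbidden_motif")
  expect_equal(unname(rej["GGGGGGGGNNGGGGGGGGGG"]), "non_ACGT")
  expect_equal(unname(rej["ACGT"]), "bad_length")
  expect_error(filter_guide_candidates(character(0), spec, "top"),
               "empty")
})

test_that("brute-force motif scan over candidate plus junction context agrees", {
  spec <- default_spec
  set.seed(11)
  cands <- random_dna(200, 20)
  rep <- filter_guide_candidates(cands, spec, "bottom")
  # independent oracle: plain substring search in linker + cand + three_flank,
  # counting hits that touch the candidate
  oracle_hit <- vapply(cands, function(cd) {
    ctx <- paste0(spec$linker, cd, spec$three_flank)
    any(vapply(spec$forbidden_motifs, function(m) {
      h <- gregexpr(m, ctx, fixed = TRUE)[[1L]]
      any(h != -1L & h + nchar(m) - 1L >= nchar(spec$linker) + 1L &
            h <= nchar(spec$linker) + 20L)
    }, logical(1)))
  }, logical(1))
  got_motif <- cands %in%
    rep$rejected$candidate[rep$rejected$reason == "forbidden_motif"]
  # candidates rejected earlier for stop codons never reach the motif rule
  stop_rej <- cands %in%
    rep$rejected$candidate[rep$rejected$reason == "stop_codon"]
  expect_equal(got_motif[!stop_rej], oracle_hit[!stop_rej],
               ignore_attr = TRUE)
})

test_that("junction-spanning stop codons are caught", {
  spec <- default_spec  # frame phase 0; codons at 1-4-7-...; 5' flank CGTCCG
  # top candidate starts at cassette position 7 (codon boundary); a candidate
  # ending ...T followed by linker GC... makes no stop, but the codon at
  # positions 25-27 spans candidate end (25,26) and linker start (27 = G):
  # candidate ending "TA" gives codon TAG with linker's G -> stop
  cand <- paste0(strrep("C", 18), "TA")
  rep <- filter_guide_candidates(cand, spec, "top")
  expect_equal(rep$rejected$reason, "stop_codon")
  # same bases one position earlier do not complete a stop codon
  cand2 <- paste0(strrep("C", 17), "TA", "C")
  rep2 <- filter_guide_candidates(cand2, spec, "top")
  expect_equal(nrow(rep2$rejected), 0L)
})

test_that("cassette assembly produces the fixed-flank motif and PAM geometry", {
  spec <- default_spec
  sa <- guide_site("a", strrep("A", 20), "top")
  sb <- guide_site("b", strrep("C", 20), "bottom")
  cs <- assemble_cassette(sa, sb, spec)
  expect_equal(cs$full_sequence,
               paste0("CGTCCG", strrep("A", 20), "GCCACCATGGTCGAC",
                      strrep("C", 20), "CGGTAG"))
  expect_equal(nchar(cs$full_sequence), 67L)
  expect_equal(cs$barcode_key, paste0(strrep("A", 20), strrep("C", 20)))
  # PAM-out: plus-strand NGG right after site_b, minus-strand NGG (CCN)
  # right before site_a
  expect_equal(substr(spec$three_flank, 2, 3), "GG")
  expect_equal(substr(spec$five_flank, 4, 5), "CC")
  expect_error(assemble_cassette(sb, sa, spec), "pool mismatch")
})

test_that("capture spacers re-match the cassette exactly once per strand", {
  spec <- default_spec
  cs <- assemble_cassette(guide_site("a", FIX_SITE_A, "top"),
                          guide_site("b", FIX_SITE_B, "bottom"), spec)
  spacers <- capture_guides_for(cs)
  expect_equal(unname(spacers["site_b"]), FIX_SITE_B)
  expect_equal(unname(spacers["site_a"]), revcomp(FIX_SITE_A))
  # brute-force scan of both strands for spacer followed by NGG
  scan_pam_sites <- function(spacer, seq) {
    hits <- 0L
    for (strand_seq in c(seq, revcomp(seq))) {
      g <- gregexpr(spacer, strand_seq, fixed = TRUE)[[1L]]
      for (h in g[g != -1L]) {
        pam <- substr(strand_seq, h + 20L, h + 22L)
        if (nchar(pam) == 3L && substr(pam, 2, 3) == "GG") hits <- hits + 1L
      }
    }
    hits
  }
  expect_equal(scan_pam_sites(spacers["site_b"], cs$full_sequence), 1L)
  expect_equal(scan_pam_sites(spacers["site_a"], cs$full_sequence), 1L)
})

test_that("library enumeration complexity is the product of pool sizes", {
  top <- c(a1 = "ACGTACGGCATCGGACTGCA", a2 = "CGATCGGACTACGGCATCCA",
           a3 = "GGCATCGACTACGACGGTCA")
  bottom <- c(b1 = "CATGCCGATCGACTACGGCA", b2 = "TACGACGGCATCGGCATCCA",
              b3 = "CCGGCATCGACTGACGATCA", b4 = "GACTACGGCACCGATCGTCA")
  lib <- enumerate_library(top, bottom)
  expect_equal(lib$complexity, 12)
  recs <- lib$cassettes()
  expect_equal(nrow(recs), 12L)
  expect_equal(anyDuplicated(recs$barcode_key), 0L)
  expect_equal(sort(unique(recs$site_a_id)), sort(names(top)))
  lib1 <- enumerate_library(top[1], bottom[1])
  expect_equal(lib1$complexity, 1)
  expect_error(enumerate_library(c(top, a9 = unname(top[1])), bottom),
               "duplicate")
})

test_that("complexity property holds across random pool sizes", {
  set.seed(7)
  for (i in 1:10) {
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    top <- random_dna(n1, 20); bottom <- random_dna(n2, 20)
    # de-duplicate (random 20-mers essentially never collide, but be safe)
    top <- unique(top); bottom <- unique(bottom)
    lib <- enumerate_library(top, bottom)
    expect_equal(lib$complexity, length(top) * length(bottom))
  }
})

test_that("oligo emission round-trips to the full cassette by anneal/extend", {
  spec <- default_spec
  set.seed(5)
  top <- random_dna(3, 20); bottom <- random_dna(3, 20)
  ol <- emit_oligos(top, bottom, spec, pairing_overlap = 15)
  # string-level anneal/extend oracle: the bottom oligo's revcomp must share
  # `overlap` bases with the top oligo's 3' end; the extension product is
  # top + remainder of revcomp(bottom)
  for (i in 1:3) for (j in 1:3) {
    t_o <- ol$top[[i]]; b_rc <- revcomp(ol$bottom[[j]])
    v <- ol$overlap
    expect_equal(substr(t_o, nchar(t_o) - v + 1L, nchar(t_o)),
                 substr(b_rc, 1L, v))
    product <- paste0(t_o, substr(b_rc, v + 1L, nchar(b_rc)))
    expected <- paste0(spec$five_flank, top[i], spec$linker, bottom[j],
                       spec$three_flank)
    expect_equal(product, expected)
  }
  # boundary: overlap = full linker
  expect_true(endsWith(ol$top[[1]], spec$linker))
  expect_error(emit_oligos(top, bottom, spec, pairing_overlap = 16),
               "exceeds linker")
})

test_that("v2 frame report flags stops in both frames and slippery sites", {
  ok <- check_frames_v2("GCCGCCGCCGCC")
  expect_true(ok$pass)
  # slippery heptamer TTTAAAC
  sl <- check_frames_v2(paste0("GCCGCC", "TTTAAAC", "GCCGCC"))
  expect_equal(sl$slippery_sites, 7L)
  expect_false(sl$pass)
  # a -1 shift creating TAG: design frame GGT AGC -> shifted codon (pos 3) TAG
  fm <- check_frames_v2("GGTAGCGCC")
  expect_equal(fm$stops_frame0, integer(0))
  expect_equal(fm$stops_minus1, 3L)
  expect_warning(check_frames_v2("GCCGCC"), "shorter than 7")
})

test_that("frame safety holds for every accepted cassette (phase 0)", {
  spec <- default_spec
  set.seed(21)
  cands_top <- random_dna(120, 20)
  cands_bot <- random_dna(120, 20)
  top <- filter_guide_candidates(cands_top, spec, "top")$accepted
  bot <- filter_guide_candidates(cands_bot, spec, "bottom")$accepted
  expect_gt(nrow(top), 10); expect_gt(nrow(bot), 10)
  lib <- enumerate_library(top[1:10, ], bot[1:10, ], spec)
  recs <- lib$cassettes()
  for (seq in recs$full_sequence) {
    codons <- substring(seq, seq(1, 66, 3), seq(3, 67, 3) + 0)
    # barcode insert codons: those overlapping positions 7..61
    starts <- seq(1, 64, 3)
    insert <- starts + 2 >= 7 & starts <= 61
    expect_false(any(codons[insert] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("heuristic guide score rewards balanced non-repetitive spacers", {
  expect_equal(heuristic_guide_score("ACGTACGGCATCGGACTGCA"), 100)
  expect_equal(heuristic_guide_score("AAAAACGGCATCGGACTGCA"), 0)  # homopolymer
  expect_equal(heuristic_guide_score(strrep("AT", 10)), 0)        # GC too low
})
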