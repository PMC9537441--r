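test_that("barcode extraction finds the motif at any stagger offset", {
  spec <- default_spec
  key <- paste0(strrep("A", 20), strrep("C", 20))
  for (st in c(0L, 2L, 4L, 8L)) {
    r <- make_read(key, stagger = st, pad = 2L)
    expect_equal(extract_barcodes(r, spec)$barcode_key, key)
  }
  # one substitution inside the linker kills the exact-mode match
  r <- make_read(key, stagger = 4L)
  pos <- 4L + 6L + 20L + 8L  # inside the linker
  repl <- if (substr(r, pos, pos) == "T") "A" else "T"
  broken <- paste0(substr(r, 1, pos - 1L), repl, substr(r, pos + 1L, nchar(r)))
  got <- extract_barcodes(broken, spec, search_revcomp = FALSE)
  expect_true(is.na(got$barcode_key))
  expect_equal(got$reason, "no_motif")
  # ...but is rescued with one mismatch allowed per fixed segment
  got1 <- extract_barcodes(broken, spec, max_flank_mismatch = 1L)
  expect_equal(got1$barcode_key, key)
  # reads shorter than the motif never match
  expect_equal(extract_barcodes("ACGTACGT", spec)$reason, "no_motif")
})

test_that("extraction is strand symmetric when revcomp search is on", {
  spec <- default_spec
  set.seed(3)
  keys <- random_dna(20, 40)
  reads <- vapply(keys, make_read, character(1))
  fwd <- extract_barcodes(reads, spec)$barcode_key
  rev <- extract_barcodes(revcomp(reads), spec)$barcode_key
  expect_equal(fwd, keys, ignore_attr = TRUE)
  expect_equal(rev, fwd)
  # and the reverse-complement hit disappears when the flag is off
  rc_off <- extract_barcodes(revcomp(reads), spec, search_revcomp = FALSE)
  expect_true(all(is.na(rc_off$barcode_key)))
})

test_that("ambiguous bases inside an N20 are rejected in exact mode", {
  spec <- default_spec
  key <- paste0(strrep("A", 19), "N", strrep("C", 20))
  r <- make_read(key)
  expect_true(is.na(extract_barcodes(r, spec)$barcode_key))
})

test_that("leftmost motif hit wins when a read has two", {
  spec <- default_spec
  k1 <- paste0(strrep("A", 20), strrep("C", 20))
  k2 <- paste0(strrep("G", 20), strrep("T", 20))
  two <- paste0(make_read(k1, stagger = 0L, pad = 0L),
                make_read(k2, stagger = 0L, pad = 0L))
  expect_equal(extract_barcodes(two, spec)$barcode_key, k1)
})

test_that("exact counting matches reference keys and tracks unassigned", {
  spec <- default_spec
  X <- paste0(strrep("A", 20), strrep("C", 20))
  Y <- paste0(strrep("G", 20), strrep("T", 20))
  Z <- paste0(strrep("T", 20), strrep("A", 20))
  reads <- c(rep(make_read(X), 90), rep(make_read(Y), 10),
             rep(make_read(Z), 5), rep("ACGTACGT", 3))
  tab <- count_barcodes(list(s1 = reads), reference = c(X, Y), spec)
  expect_equal(unname(tab$counts[X, "s1"]), 90L)
  expect_equal(unname(tab$counts[Y, "s1"]), 10L)
  expect_equal(unname(tab$unassigned["no_reference_match", "s1"]), 5L)
  expect_equal(unname(tab$unassigned["no_motif", "s1"]), 3L)
  # conservation: assigned + unassigned = reads in
  expect_equal(unname(tab$totals["s1"] + sum(tab$unassigned[, "s1"])),
               length(reads))
  fr <- barcode_fractions(tab)
  expect_equal(unname(fr[X, "s1"]), 0.9)
  expect_error(count_barcodes(list(s1 = reads), c(X, X), spec), "duplicate")
})

test_that("hamming rescue assigns near keys uniquely and leaves ties", {
  spec <- default_spec
  X <- paste0(strrep("A", 20), strrep("C", 20))
  Y <- paste0(strrep("A", 20), strrep("C", 19), "T")  # d(X, Y) = 1
  Z <- paste0(strrep("G", 20), strrep("T", 20))
  near_x <- paste0("T", strrep("A", 19), strrep("C", 20))  # d=1 to X, 2 to Y
  tie <- paste0(strrep("A", 20), strrep("C", 19), "G")     # d=1 to X and Y
  expect_equal(unname(count_barcodes(
    list(s = make_read(near_x)), c(X, Z), spec,
    hamming_rescue = 1L)$counts[X, "s"]), 1L)
  # exact mode does not rescue
  expect_equal(sum(count_barcodes(list(s = make_read(near_x)), c(X, Z),
                                  spec)$counts), 0L)
  # ambiguous between X and Y stays unassigned
  tab <- count_barcodes(list(s = make_read(tie)), c(X, Y), spec,
                        hamming_rescue = 1L)
  expect_equal(sum(tab$counts), 0L)
  expect_equal(unname(tab$unassigned["no_reference_match", "s"]), 1L)
})

test_that("counts agree with a naive substring-search oracle", {
  spec <- default_spec
  set.seed(17)
  ref <- random_dna(30, 40)
  picks <- sample(ref, 400, replace = TRUE)
  staggers <- sample(0:8, 400, replace = TRUE)
  reads <- mapply(make_read, picks, staggers)
  tab <- count_barcodes(list(s = unname(reads)), ref, spec)
  # oracle: count reads containing flank+key-motif verbatim
  oracle <- vapply(ref, function(k) {
    motif <- paste0(spec$five_flank, substr(k, 1, 20), spec$linker,
                    substr(k, 21, 40), spec$three_flank)
    sum(vapply(reads, function(r) grepl(motif, r, fixed = TRUE), logical(1)))
  }, numeric(1))
  expect_equal(unname(tab$counts[ref, "s"]), unname(as.integer(oracle)))
})

test_that("count table TSV round trip is the identity", {
  spec <- default_spec
  set.seed(29)
  ref <- random_dna(8, 40)
  counts <- matrix(rpois(16, 50), nrow = 8,
                   dimnames = list(ref, c("ctl", "trt")))
  tab <- structure(list(counts = counts, totals = colSums(counts),
                        unassigned = matrix(0L, 2, 2,
                                            dimnames = list(
                                              c("no_motif",
                                                "no_reference_match"),
                                              colnames(counts))),
                        n_reads = colSums(counts)),
                   class = "barcode_count_table")
  path <- tempfile(fileext = ".tsv")
  write_count_table(tab, path)
  back <- read_count_table(path)
  expect_equal(back$counts, tab$counts)
  expect_equal(colnames(back$counts), c("ctl", "trt"))
  expect_equal(back$totals, tab$totals)
  # degenerate: empty table writes a header-only file and reads back empty
  tab0 <- tab; tab0$counts <- counts[0, , drop = FALSE]
  tab0$totals <- colSums(tab0$counts); tab0$n_reads <- tab0$totals
  path0 <- tempfile(fileext = ".tsv")
  write_count_table(tab0, path0)
  expect_equal(nrow(read_count_table(path0)$counts), 0L)
  # malformed input reports the offending line
  writeLines(c("barcode_key\ta\tb", "AAAA\t1"), path0)
  expect_error(read_count_table(path0), "line 2")
  writeLines(c("barcode_key\ta", "AAAA\tx"), path0)
  expect_error(read_count_table(path0), "non-integer")
})

test_that("large-table round trip preserves column sums", {
  set.seed(31)
  n <- 10000L
  keys <- sprintf("BC%038d", seq_len(n))  # distinct row keys
  counts <- matrix(rpois(2L * n, 3), nrow = n,
                   dimnames = list(keys, c("a", "b")))
  tab <- structure(list(counts = counts, totals = colSums(counts),
                        unassigned = matrix(0L, 2, 2,
                                            dimnames = list(
                                              c("no_motif",
                                                "no_reference_match"),
                                              c("a", "b"))),
                        n_reads = colSums(counts)),
                   class = "barcode_count_table")
  path <- tempfile(fileext = ".tsv")
  write_count_table(tab, path)
  expect_equal(colSums(read_count_table(path)$counts), colSums(counts))
})

test_that("FASTQ reading and simulated FASTQ writing interoperate", {
  cfg <- sim_config(n_founders = 300, library_size = 3000, depth = 500,
                    days = 5, seq_error = 0)
  sim <- simulate_capture(cfg, seed = 9, as_fastq = TRUE)
  dir <- tempfile(); dir.create(dir)
  paths <- write_sim_fastq(sim, dir)
  reads <- read_fastq_reads(paths[["control"]])
  expect_equal(length(reads), length(sim$reads$control))
  expect_setequal(reads, sim$reads$control)
})
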