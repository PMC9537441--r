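# shared in-code fixtures: built fresh, never stored on disk

default_spec <- cassette_spec()

# non-repetitive 20-mers that pass the design filter (no stop codons in the
# cassette frame, no forbidden motifs, mixed composition)
FIX_SITE_A <- "ACGTACGGCATCGGACTGCA"
FIX_SITE_B <- "CATGCCGATCGACTACGGCA"

make_cassette <- function(a = FIX_SITE_A, b = FIX_SITE_B,
                          spec = default_spec) {
  paste0(spec$five_flank, a, spec$linker, b, spec$three_flank)
}

make_read <- function(key, stagger = 4L, pad = 10L, spec = default_spec) {
  paste0(strrep("T", stagger),
         spec$five_flank, substr(key, 1, 20), spec$linker,
         substr(key, 21, 40), spec$three_flank,
         strrep("G", pad))
}

# independent left-canonical placement of a planted deletion / insertion
# (brute-force string rule, no use of the package's alignment code)
canonical_deletion <- function(ref, pos, len) {
  ch <- strsplit(ref, "")[[1L]]
  while (pos > 1L && ch[pos - 1L] == ch[pos + len - 1L]) pos <- pos - 1L
  pos
}
canonical_insertion <- function(ref, anchor, ins) {
  ch <- strsplit(ref, "")[[1L]]
  ins <- strsplit(ins, "")[[1L]]
  while (anchor > 0L && ch[anchor] == ins[length(ins)]) {
    ins <- c(ins[length(ins)], ins[-length(ins)])
    anchor <- anchor - 1L
  }
  anchor
}

# small variant table generator for priority-score tests
random_variant_table <- function(n, n_genes = 50L) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  types <- c("missense", "frameshift_deletion", "stop_gain", "splicing",
             "other")
  mut_listed <- stats::runif(n) < 0.05
  data.frame(
    variant_id = sprintf("v%05d", seq_len(n)),
    gene = sample(genes, n, replace = TRUE),
    mutation_type = sample(types, n, replace = TRUE,
                           prob = c(0.6, 0.1, 0.1, 0.1, 0.1)),
    allele_frequency = stats::runif(n),
    cadd_raw = ifelse(stats::runif(n) < 0.8, stats::rnorm(n, 10, 8), NA),
    sift_raw = ifelse(stats::runif(n) < 0.8, stats::runif(n), NA),
    provean_raw = ifelse(stats::runif(n) < 0.8, stats::rnorm(n, -2, 3), NA),
    crispr_lfc = stats::rnorm(n, 0, 2),
    in_clinical_gene_list = mut_listed | stats::runif(n) < 0.1,
    in_clinical_mutation_list = mut_listed,
    stringsAsFactors = FALSE)
}

random_fpkm_table <- function(n_genes = 50L, n_samples = 4L) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  m <- matrix(stats::rexp(n_genes * n_samples, rate = 0.2),
              nrow = n_genes, dimnames = list(genes, paste0("s", 1:n_samples)))
  m[seq_len(n_genes %/% 5L), ] <- stats::runif(n_samples * (n_genes %/% 5L),
                                               0, 0.09)
  m
}
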