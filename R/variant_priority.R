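#' Expression filter from an FPKM table
#'
#' A gene counts as expressed iff its FPKM reaches `threshold` in at least
#' one sample; genes below the threshold in every sample are treated as
#' likely-passenger hosts and their variants are zeroed downstream.
#'
#' @param fpkm Numeric matrix or data.frame of FPKM values, genes in rows
#'   (rownames or a `gene` first column) and samples in columns.
#' @param threshold FPKM expression threshold (default 0.1).
#' @return Named logical vector, `TRUE` = expressed.
#' @export
expression_filter <- function(fpkm, threshold = 0.1) {
  if (is.data.frame(fpkm) && !is.null(fpkm$gene)) {
    genes <- fpkm$gene
    fpkm <- as.matrix(fpkm[, setdiff(names(fpkm), "gene"), drop = FALSE])
    rownames(fpkm) <- genes
  }
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0, na.rm = TRUE)) stop("FPKM values must be non-negative")
  flags <- apply(fpkm, 1L, function(v) any(v >= threshold, na.rm = TRUE))
  flags
}

# mutation types that the deleteriousness tools cannot score and that get
# the maximum component score instead
UNSCORABLE_MAX_TYPES <- c("frameshift_deletion", "stop_gain", "splicing")

#' Scale a deleteriousness/screen component to 0-100
#'
#' Orientation-normalised min-max scaling over the numerically scored
#' candidate set: values are sign-flipped when lower raw values mean more
#' deleterious (SIFT, PROVEAN), then mapped linearly so the least
#' deleterious scored candidate is 0 and the most deleterious is 100.
#' Variants of the unscorable high-impact types (frameshift deletion, stop
#' gain, splicing) receive 100; other missing values receive the median of
#' the scaled scored set (computed before imputation).
#'
#' @param values Raw component values (NA = not scored by the tool).
#' @param orientation `"higher_is_deleterious"` (CADD-like) or
#'   `"lower_is_deleterious"` (SIFT/PROVEAN-like).
#' @param mutation_type Optional character vector of mutation types aligned
#'   with `values`; types in `frameshift_deletion` / `stop_gain` /
#'   `splicing` are assigned 100 regardless of `values`.
#' @return Numeric vector of scaled values in \[0, 100\].
#' @examples
#' scale_component(c(2, 6, 10))                                  # 0 50 100
#' scale_component(c(0, 0.5, 1), "lower_is_deleterious")         # 100 50 0
#' @export
scale_component <- function(values,
                            orientation = c("higher_is_deleterious",
                                            "lower_is_deleterious"),
                            mutation_type = NULL) {
  orientation <- match.arg(orientation)
  values <- as.numeric(values)
  n <- length(values)
  special_max <- if (is.null(mutation_type)) rep(FALSE, n) else
    mutation_type %in% UNSCORABLE_MAX_TYPES
  scored <- !is.na(values) & !special_max
  if (!any(scored)) stop("at least one numerically scored candidate required")
  v <- values
  if (orientation == "lower_is_deleterious") v <- -v
  lo <- min(v[scored]); hi <- max(v[scored])
  out <- rep(NA_real_, n)
  if (hi == lo) {
    warning("degenerate spread (max == min); scored values set to 50")
    out[scored] <- 50
  } else {
    out[scored] <- 100 * (v[scored] - lo) / (hi - lo)
  }
  med <- stats::median(out[scored])   # fixed before imputation
  out[special_max] <- 100
  out[is.na(out)] <- med
  out
}

#' Priority score for one annotated variant
#'
#' Combines five 0-100 evidence components: AS = allele frequency x 100,
#' DS = mean of the scaled CADD/SIFT/PROVEAN deleteriousness scores, CS =
#' scaled CRISPR-screen fold change, GS = 100 iff the gene appears in the
#' clinical resistance gene list, MS = 100 iff the exact mutation appears in
#' the clinical mutation list. PS is the mean of the five when the host gene
#' is expressed and 0 otherwise.
#'
#' @param allele_frequency Alternative allele frequency in \[0, 1\].
#' @param ds_components Numeric vector of the (already scaled, 0-100)
#'   deleteriousness components; their mean is DS.
#' @param cs Scaled CRISPR screen score in \[0, 100\].
#' @param in_clinical_gene_list,in_clinical_mutation_list Logical flags
#'   (a listed mutation implies a listed gene).
#' @param expressed Logical expression flag for the host gene.
#' @return A `score_breakdown` list with AS, DS, CS, GS, MS, PS, expressed.
#' @export
priority_score <- function(allele_frequency, ds_components, cs,
                           in_clinical_gene_list = FALSE,
                           in_clinical_mutation_list = FALSE,
                           expressed = TRUE) {
  if (is.na(allele_frequency) || allele_frequency < 0 || allele_frequency > 1) {
    stop("allele_frequency must lie in [0, 1]")
  }
  if (in_clinical_mutation_list && !in_clinical_gene_list) {
    in_clinical_gene_list <- TRUE  # a listed mutation implies a listed gene
  }
  AS <- 100 * allele_frequency
  DS <- mean(ds_components)
  CS <- cs
  GS <- if (isTRUE(in_clinical_gene_list)) 100 else 0
  MS <- if (isTRUE(in_clinical_mutation_list)) 100 else 0
  PS <- if (isTRUE(expressed)) mean(c(AS, DS, CS, GS, MS)) else 0
  structure(list(AS = AS, DS = DS, CS = CS, GS = GS, MS = MS, PS = PS,
                 expressed = isTRUE(expressed)),
            class = "score_breakdown")
}

#' Rank a variant table by priority score
#'
#' Full table-level pipeline: expression-filter the host genes, scale the
#' three deleteriousness tool scores and the CRISPR screen fold change over
#' the candidate set, impute unscorable variants, compute the per-variant
#' components and PS, and return the table sorted by PS descending (ties
#' broken by DS, then AS, then variant id).
#'
#' @param variants Data frame with columns `variant_id`, `gene`,
#'   `mutation_type` (one of missense / frameshift_deletion / stop_gain /
#'   splicing / other), `allele_frequency`, `cadd_raw`, `sift_raw`,
#'   `provean_raw`, `crispr_lfc` (NA allowed in the raw score columns),
#'   `in_clinical_gene_list`, `in_clinical_mutation_list`.
#' @param fpkm FPKM matrix/data.frame for [expression_filter()].
#' @param expression_threshold FPKM threshold (default 0.1).
#' @param orientations Named orientations for the three tools (defaults:
#'   CADD higher-is-deleterious; SIFT and PROVEAN lower-is-deleterious).
#' @param cs_orientation Orientation for the screen fold change (default
#'   higher = enriched under drug = more resistance-associated).
#' @return The input data frame with added columns AS, DS, CS, GS, MS,
#'   expressed, PS, sorted by PS descending.
#' @export
prioritize_variants <- function(variants, fpkm, expression_threshold = 0.1,
                                orientations = c(cadd = "higher_is_deleterious",
                                                 sift = "lower_is_deleterious",
                                                 provean = "lower_is_deleterious"),
                                cs_orientation = "higher_is_deleterious") {
  req <- c("variant_id", "gene", "mutation_type", "allele_frequency",
           "cadd_raw", "sift_raw", "provean_raw", "crispr_lfc",
           "in_clinical_gene_list", "in_clinical_mutation_list")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols)) {
    stop("variants table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(variants$allele_frequency < 0 | variants$allele_frequency > 1,
          na.rm = TRUE)) {
    stop("allele_frequency must lie in [0, 1]")
  }
  flags <- expression_filter(fpkm, expression_threshold)
  expressed <- flags[variants$gene]
  if (anyNA(expressed)) {
    warning("genes absent from the FPKM table treated as not expressed: ",
            paste(unique(variants$gene[is.na(expressed)]), collapse = ", "))
    expressed[is.na(expressed)] <- FALSE
  }
  mt <- variants$mutation_type
  cadd <- scale_component(variants$cadd_raw, orientations[["cadd"]], mt)
  sift <- scale_component(variants$sift_raw, orientations[["sift"]], mt)
  prov <- scale_component(variants$provean_raw, orientations[["provean"]], mt)
  CS <- scale_component(variants$crispr_lfc, cs_orientation)

  out <- variants
  out$expressed <- unname(expressed)
  out$AS <- 100 * variants$allele_frequency
  out$DS <- (cadd + sift + prov) / 3
  out$CS <- CS
  out$GS <- ifelse(variants$in_clinical_gene_list |
                     variants$in_clinical_mutation_list, 100, 0)
  out$MS <- ifelse(variants$in_clinical_mutation_list, 100, 0)
  out$PS <- ifelse(out$expressed,
                   (out$AS + out$DS + out$CS + out$GS + out$MS) / 5, 0)
  out[order(-out$PS, -out$DS, -out$AS, out$variant_id), , drop = FALSE]
}
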