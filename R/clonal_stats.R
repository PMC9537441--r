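#' Posterior log2 fold-change statistic for single-replicate counts
#'
#' Conservative enrichment statistic for unreplicated barcode counts,
#' in the generalized fold change (GFOLD) family: the treatment and control
#' abundance rates are given Gamma posteriors, `lambda ~ Gamma(k + alpha)`
#' scaled by the per-sample assigned totals, and the statistic is the
#' c-quantile of the posterior distribution of `log2(lambda_trt/lambda_ctl)`.
#' A positive value means the whole lower tail of the posterior fold change
#' lies above 1.
#'
#' The `"numeric"` method is exact and closed-form: with
#' `B ~ Beta(k_trt + alpha, k_ctl + alpha)`,
#' `lambda_trt/lambda_ctl = (N_ctl/N_trt) * B/(1-B)`, and the quantile of a
#' monotone transform is the transform of the quantile, so the statistic is
#' `log2((N_ctl/N_trt) * qB/(1-qB))` with `qB = qbeta(c, ...)`. The
#' `"monte_carlo"` method draws from the two Gamma posteriors and takes the
#' empirical quantile; the two agree within Monte-Carlo error.
#'
#' @param k_trt,k_ctl Treatment / control counts (vectors allowed).
#' @param n_trt,n_ctl Per-sample assigned read totals (> 0).
#' @param alpha Prior pseudocount (default 1).
#' @param c Posterior quantile level in (0, 0.5) (default 0.01).
#' @param method `"numeric"` (exact, default) or `"monte_carlo"`.
#' @param draws Monte-Carlo draws (default 1e5).
#' @param seed Optional seed for the Monte-Carlo method.
#' @return Numeric vector of statistic values.
#' @examples
#' gfold_statistic(1000, 10, 1e6, 1e6)
#' @export
gfold_statistic <- function(k_trt, k_ctl, n_trt, n_ctl, alpha = 1,
                            c = 0.01, method = c("numeric", "monte_carlo"),
                            draws = 1e5, seed = NULL) {
  method <- match.arg(method)
  if (any(n_trt <= 0) || any(n_ctl <= 0)) stop("library sizes must be positive")
  if (c <= 0 || c >= 0.5) stop("c must lie in (0, 0.5)")
  if (any(k_trt < 0) || any(k_ctl < 0)) stop("counts must be non-negative")
  a <- k_trt + alpha
  b <- k_ctl + alpha
  if (method == "numeric") {
    qb <- stats::qbeta(c, a, b)
    log2((n_ctl / n_trt) * qb / (1 - qb))
  } else {
    if (!is.null(seed)) set.seed(seed)
    n <- max(length(a), length(b), length(n_trt), length(n_ctl))
    a <- rep_len(a, n); b <- rep_len(b, n)
    n_trt <- rep_len(n_trt, n); n_ctl <- rep_len(n_ctl, n)
    vapply(seq_len(n), function(i) {
      lt <- stats::rgamma(draws, shape = a[i]) / n_trt[i]
      lc <- stats::rgamma(draws, shape = b[i]) / n_ctl[i]
      unname(stats::quantile(log2(lt / lc), probs = c, type = 7))
    }, numeric(1))
  }
}

#' Point estimate of the normalized log2 fold change
#'
#' @inheritParams gfold_statistic
#' @return `log2(((k_trt + alpha)/n_trt) / ((k_ctl + alpha)/n_ctl))`.
#' @export
point_l2fc <- function(k_trt, k_ctl, n_trt, n_ctl, alpha = 1) {
  log2(((k_trt + alpha) / n_trt) / ((k_ctl + alpha) / n_ctl))
}

#' Call enriched barcodes per treatment replicate
#'
#' A barcode is enriched in a replicate iff its posterior fold-change
#' statistic against the control sample exceeds `threshold` (one-sided,
#' treatment over control; threshold 4 by default). Set
#' `depletion = TRUE` to call depleted barcodes (statistic on the swapped
#' contrast) instead.
#'
#' @param table A `barcode_count_table`.
#' @param control_sample Name of the control column.
#' @param treated_samples Names of the treated replicate columns.
#' @param threshold Enrichment threshold on the statistic (default 4).
#' @param alpha,c Passed to [gfold_statistic()].
#' @param depletion Call depletion instead of enrichment.
#' @return An `enrichment_summary`: gfold matrix (barcodes x replicates),
#'   logical `enriched` matrix, per-replicate sets and counts, union count.
#' @export
call_enriched <- function(table, control_sample, treated_samples,
                          threshold = 4, alpha = 1, c = 0.01,
                          depletion = FALSE) {
  stopifnot(inherits(table, "barcode_count_table"))
  samples <- colnames(table$counts)
  if (!control_sample %in% samples) stop("control sample not in table")
  if (!all(treated_samples %in% samples)) stop("treated sample not in table")
  if (any(table$totals[c(control_sample, treated_samples)] == 0)) {
    stop("zero assigned reads in a sample")
  }
  k_ctl <- table$counts[, control_sample]
  n_ctl <- table$totals[control_sample]
  gf <- sapply(treated_samples, function(s) {
    if (depletion) {
      gfold_statistic(k_ctl, table$counts[, s], n_ctl, table$totals[s],
                      alpha = alpha, c = c)
    } else {
      gfold_statistic(table$counts[, s], k_ctl, table$totals[s], n_ctl,
                      alpha = alpha, c = c)
    }
  })
  gf <- matrix(gf, nrow = nrow(table$counts),
               dimnames = list(rownames(table$counts), treated_samples))
  enriched <- gf > threshold
  sets <- lapply(treated_samples, function(s) rownames(gf)[enriched[, s]])
  names(sets) <- treated_samples
  structure(
    list(threshold = threshold, gfold = gf, enriched = enriched,
         enriched_sets = sets,
         n_enriched_per_replicate = colSums(enriched),
         n_enriched_union = length(unique(unlist(sets))),
         control_sample = control_sample, treated_samples = treated_samples,
         depletion = depletion),
    class = "enrichment_summary")
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat("Enrichment summary (threshold ", x$threshold, ")\n", sep = "")
  cat("  per replicate:", paste(sprintf("%s=%d", names(x$n_enriched_per_replicate),
                                        x$n_enriched_per_replicate),
                                collapse = ", "), "\n")
  cat("  union:", x$n_enriched_union, "barcodes\n")
  invisible(x)
}

#' Binomial preexistence probability
#'
#' Probability that one barcode is enriched in exactly `r` of `R`
#' independent treatment replicates by chance, `C(R, r) P^r (1-P)^(R-r)`,
#' where `P` is the per-barcode probability of being selected as resistant
#' in a single replicate. With `adjust = TRUE` the probability is multiplied
#' by the detected barcode complexity (a Bonferroni-style adjustment over
#' all detected barcodes); set `cap = TRUE` to clamp the adjusted value at 1.
#'
#' @param P Per-barcode selection probability in \[0, 1\].
#' @param R Number of replicates (default 5).
#' @param r Number of replicates in which the barcode is enriched.
#' @param complexity Detected barcode complexity (required when `adjust`).
#' @param adjust Multiply by `complexity`.
#' @param cap Clamp the adjusted probability at 1 (default FALSE, i.e. the
#'   plain product).
#' @return Probability (or expected count when adjusted).
#' @examples
#' preexistence_probability(0.0007, 5, 5)                      # 1.68e-16
#' preexistence_probability(0.0007, 5, 5, 230000, adjust = TRUE) # 3.86e-11
#' @export
preexistence_probability <- function(P, R = 5L, r, complexity = NULL,
                                     adjust = FALSE, cap = FALSE) {
  if (any(P < 0 | P > 1)) stop("P must lie in [0, 1]")
  if (any(r < 0) || any(r > R)) stop("r must lie in 0..R")
  p <- choose(R, r) * P^r * (1 - P)^(R - r)
  if (adjust) {
    if (is.null(complexity)) stop("complexity required when adjust = TRUE")
    if (any(complexity < 1)) stop("complexity must be >= 1")
    p <- p * complexity
    if (cap) p <- pmin(p, 1)
  }
  p
}

#' Estimate the per-barcode selection probability
#'
#' `P = n_enriched_union / complexity`: the fraction of detected founder
#' barcodes that became enriched in at least one replicate, also reported as
#' the percentage of founder clones contributing to resistance.
#'
#' @param n_enriched_union Number of unique enriched barcodes over all
#'   replicates.
#' @param complexity Detected barcode complexity.
#' @return List with `P` and `percent_contributing` (= 100 * P).
#' @examples
#' estimate_selection_probability(157, 230000)  # P ~ 0.0007, ~0.07%
#' @export
estimate_selection_probability <- function(n_enriched_union, complexity) {
  if (complexity <= 0) stop("complexity must be positive")
  if (n_enriched_union < 0 || n_enriched_union > complexity) {
    stop("n_enriched_union must lie in 0..complexity")
  }
  P <- n_enriched_union / complexity
  list(P = P, percent_contributing = 100 * P)
}

#' Clonal dynamics summary
#'
#' Computes, per sample, the descending cumulative barcode-share curve, the
#' top-k share and the maximum clone share; and, when an
#' [call_enriched()] summary is supplied, the cross-replicate overlap
#' histogram of each replicate's top-`top_n` enriched barcodes (fraction of
#' them enriched in exactly m of the R replicates) and per-barcode origin
#' labels: enriched in all R replicates = `preexisting_candidate`, exactly
#' one = `late_emerging`, otherwise `intermediate`.
#'
#' The "top n most enriched" ranking key is the statistic value descending,
#' ties broken by treated count and then lexicographic barcode key.
#'
#' @param table A `barcode_count_table`.
#' @param samples Sample columns to summarise (default all).
#' @param enrichment Optional `enrichment_summary`.
#' @param top_n Top enriched barcodes per replicate to compare (default 50).
#' @return A `dynamics_summary` list.
#' @export
dynamics_summary <- function(table, samples = colnames(table$counts),
                             enrichment = NULL, top_n = 50L) {
  stopifnot(inherits(table, "barcode_count_table"))
  if (length(samples) < 1L) stop("need at least one sample")
  fr <- barcode_fractions(table)[, samples, drop = FALSE]
  per_sample <- lapply(samples, function(s) {
    f <- sort(fr[, s], decreasing = TRUE)
    f <- f[f > 0]
    cum <- cumsum(f)
    list(cumulative_curve = unname(cum),
         top_k_share = function(k) if (length(cum) == 0) 0 else
           unname(cum[min(k, length(cum))]),
         top10_share = if (length(cum) == 0) 0 else
           unname(cum[min(10L, length(cum))]),
         max_clone_share = if (length(f) == 0) 0 else unname(f[1L]))
  })
  names(per_sample) <- samples

  overlap <- NULL; origin <- NULL
  if (!is.null(enrichment)) {
    reps <- enrichment$treated_samples
    R <- length(reps)
    n_reps_enriched <- rowSums(enrichment$enriched)
    overlap <- sapply(reps, function(s) {
      keys <- rownames(enrichment$gfold)[enrichment$enriched[, s]]
      if (length(keys) == 0) return(rep(NA_real_, R))
      if (length(keys) > top_n) {
        ord <- order(-enrichment$gfold[keys, s],
                     -table$counts[keys, s], keys)
        keys <- keys[ord][seq_len(top_n)]
      } else if (length(keys) < top_n) {
        warning("fewer than top_n enriched barcodes in replicate ", s,
                "; using all ", length(keys))
      }
      m <- n_reps_enriched[keys]
      vapply(seq_len(R), function(j) mean(m == j), numeric(1))
    })
    rownames(overlap) <- paste0("in_", seq_len(R), "_replicates")
    union_keys <- rownames(enrichment$gfold)[n_reps_enriched > 0]
    origin <- ifelse(n_reps_enriched[union_keys] == R, "preexisting_candidate",
                     ifelse(n_reps_enriched[union_keys] == 1L, "late_emerging",
                            "intermediate"))
    names(origin) <- union_keys
  }
  structure(list(per_sample = per_sample, overlap_histogram = overlap,
                 origin_labels = origin, top_n = top_n),
            class = "dynamics_summary")
}

#' Write a dynamics summary as JSON
#'
#' @param dyn A `dynamics_summary`.
#' @param path Output JSON path.
#' @export
write_dynamics_json <- function(dyn, path) {
  stopifnot(inherits(dyn, "dynamics_summary"))
  out <- list(
    per_sample = lapply(dyn$per_sample, function(p) {
      list(cumulative_curve = p$cumulative_curve,
           top10_share = p$top10_share,
           max_clone_share = p$max_clone_share)
    }),
    overlap_histogram = if (is.null(dyn$overlap_histogram)) NULL else
      as.data.frame(dyn$overlap_histogram),
    origin_labels = if (is.null(dyn$origin_labels)) NULL else
      as.list(dyn$origin_labels))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
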