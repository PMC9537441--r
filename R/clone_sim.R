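#' Simulation configuration for barcoded clonal evolution
#'
#' Parameters of the synthetic clonal-evolution experiment: lentiviral
#' barcoding of founder cells at low MOI from a skewed library, expansion to
#' per-barcode coverage, a multinomial split into one untreated control pool
#' and several independent drug-treated replicate pools, daily
#' birth/death/persistence dynamics over the treatment course, and
#' multinomial amplicon sequencing of the final pools. Defaults are a
#' desk-scale rendition of a 40-day drug-selection experiment: 1e4 founder
#' cells (a scale-down of the 3e6-cell study), MOI 0.3, five treated
#' replicates plus a vehicle control, and both preexisting and
#' persister-derived acquired resistance.
#'
#' @param n_founders Cells exposed to the barcoding virus (cells with zero
#'   integrations are removed by selection).
#' @param library_size Number of distinct barcodes in the library.
#' @param library_skew Lognormal sigma of barcode sampling weights.
#' @param moi Poisson mean integrations per cell (default 0.3).
#' @param expansion_coverage Target mean cells per clone per pool before
#'   treatment (default 120, i.e. > 100x coverage for each pool).
#' @param expansion_death Per-generation cell death probability during
#'   expansion (Galton-Watson; default 0.05).
#' @param rho_pre Fraction of founder clones that are preexisting resistant.
#' @param persister_fraction Fraction of sensitive cells entering the
#'   drug-tolerant persister state at treatment start.
#' @param mu_acq Per-division probability that a persister division yields a
#'   stably resistant cell.
#' @param kill_prob_sensitive Daily kill probability of sensitive
#'   non-persister cells under drug.
#' @param persister_division_rate Daily division probability of persisters.
#' @param resistant_fitness_mean,resistant_fitness_sd Mean and sd of the
#'   per-day multiplicative growth factor of resistant clones (drawn once
#'   per clone, truncated below at 1.05).
#' @param normal_growth Per-day growth factor without drug (control arm).
#' @param days Treatment duration in days (default 40).
#' @param n_replicates Number of treated replicates (default 5); a parallel
#'   control pool is always added.
#' @param passage_cap,passage_target Pool size triggering passaging and the
#'   size passaged back to (binomial thinning); defaults 2e6 / 1e6.
#' @param depth Sequencing reads per sample (default 1e5).
#' @param seq_error Per-base substitution error rate (default 1e-3).
#' @param read_length Simulated read length (default 100).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 1e4, library_size = 1e5,
                       library_skew = 1, moi = 0.3,
                       expansion_coverage = 120, expansion_death = 0.05,
                       rho_pre = 2e-3, persister_fraction = 0.01,
                       mu_acq = 2e-4, kill_prob_sensitive = 0.3,
                       persister_division_rate = 0.1,
                       resistant_fitness_mean = 1.45,
                       resistant_fitness_sd = 0.1,
                       normal_growth = 1.6,
                       days = 40L, n_replicates = 5L,
                       passage_cap = 2e6, passage_target = 1e6,
                       depth = 1e5, seq_error = 1e-3, read_length = 100L) {
  cfg <- list(n_founders = n_founders, library_size = library_size,
              library_skew = library_skew, moi = moi,
              expansion_coverage = expansion_coverage,
              expansion_death = expansion_death,
              rho_pre = rho_pre, persister_fraction = persister_fraction,
              mu_acq = mu_acq, kill_prob_sensitive = kill_prob_sensitive,
              persister_division_rate = persister_division_rate,
              resistant_fitness_mean = resistant_fitness_mean,
              resistant_fitness_sd = resistant_fitness_sd,
              normal_growth = normal_growth,
              days = as.integer(days), n_replicates = as.integer(n_replicates),
              passage_cap = passage_cap, passage_target = passage_target,
              depth = depth, seq_error = seq_error,
              read_length = as.integer(read_length))
  probs <- c("rho_pre", "persister_fraction", "mu_acq",
             "kill_prob_sensitive", "persister_division_rate", "seq_error",
             "expansion_death")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (cfg$moi <= 0) stop("moi must be positive")
  if (cfg$days < 1L) stop("days must be >= 1")
  if (cfg$depth < 1) stop("depth must be >= 1")
  structure(cfg, class = "sim_config")
}

#' @keywords internal
rtrunc_fitness <- function(n, mean, sd, lower = 1.05) {
  pmax(stats::rnorm(n, mean, sd), lower)
}

#' Barcode a founder population
#'
#' Each founder cell draws `Poisson(moi)` lentiviral integrations; cells
#' with none are discarded (antibiotic selection). Barcodes are drawn with
#' lognormally skewed weights from the library, so some library barcodes can
#' label more than one founder (collisions) and some founders can carry more
#' than one barcode (multiple integrations). At MOI 0.3 about 14% of
#' barcoded cells are expected to carry two or more barcodes.
#'
#' @param config A [sim_config()].
#' @return A `founder_pool`: data.frames `clones` (clone_id,
#'   n_integrations) and `integrations` (clone_id, barcode_id,
#'   barcode_key), plus `multi_barcode_fraction` and the key map.
#' @export
barcode_founders <- function(config = sim_config()) {
  if (config$moi <= 0) stop("moi must be positive")
  if (config$library_size < config$n_founders) {
    warning("library_size < n_founders: many founders will share a barcode")
  }
  k <- stats::rpois(config$n_founders, config$moi)
  k <- k[k > 0]
  n_clones <- length(k)
  if (n_clones == 0) stop("no barcoded founders (moi too low for n_founders)")
  w <- stats::rlnorm(config$library_size, 0, config$library_skew)
  ids <- sample.int(config$library_size, sum(k), replace = TRUE, prob = w)
  used <- sort(unique(ids))
  keys <- random_dna(length(used), 40L)
  while (anyDuplicated(keys)) {
    dup <- duplicated(keys)
    keys[dup] <- random_dna(sum(dup), 40L)
  }
  key_map <- data.frame(barcode_id = used, barcode_key = keys,
                        stringsAsFactors = FALSE)
  integrations <- data.frame(clone_id = rep.int(seq_len(n_clones), k),
                             barcode_id = ids, stringsAsFactors = FALSE)
  integrations$barcode_key <-
    key_map$barcode_key[match(integrations$barcode_id, key_map$barcode_id)]
  structure(
    list(clones = data.frame(clone_id = seq_len(n_clones),
                             n_integrations = k),
         integrations = integrations,
         key_map = key_map,
         multi_barcode_fraction = mean(k >= 2L),
         config = config),
    class = "founder_pool")
}

#' Expand a founder pool before treatment
#'
#' Galton-Watson expansion: per generation every cell leaves either two
#' offspring (probability `1 - expansion_death`) or none, until the mean
#' cells per clone reaches `expansion_coverage * (n_replicates + 1)` so that
#' every pool of the subsequent split receives the target coverage. Extinct
#' clones (stochastic barcode dropout) are reported and removed.
#'
#' @param pool A `founder_pool`.
#' @param config A [sim_config()] (defaults to the pool's).
#' @return An `expanded_pool`: cell counts per surviving clone, dropout ids,
#'   number of generations.
#' @export
expand_pool <- function(pool, config = pool$config) {
  stopifnot(inherits(pool, "founder_pool"))
  n <- rep(1L, nrow(pool$clones))
  target <- config$expansion_coverage * (config$n_replicates + 1L)
  generations <- 0L
  while (mean(n) < target && generations < 60L) {
    surv <- stats::rbinom(length(n), n, 1 - config$expansion_death)
    n <- 2L * surv
    generations <- generations + 1L
    if (all(n == 0L)) break
  }
  dropout <- pool$clones$clone_id[n == 0L]
  structure(list(clone_id = pool$clones$clone_id, cells = n,
                 dropout = dropout, generations = generations,
                 pool = pool, config = config),
            class = "expanded_pool")
}

#' Drug-treat an expanded pool
#'
#' Splits the expanded cells multinomially into one control and
#' `n_replicates` treated pools, then runs the daily dynamics. Preexisting
#' resistant clones (fraction `rho_pre`, shared across replicates, fitness
#' drawn once per clone) grow exponentially under drug; sensitive
#' non-persister cells die with `kill_prob_sensitive` per day; persisters
#' survive, divide at `persister_division_rate` and convert to stable
#' resistance with probability `mu_acq` per division (acquired events are
#' replicate-private, with fitness drawn at acquisition). The control pool
#' grows at `normal_growth` without drug. All pools are passaged (binomially
#' thinned to `passage_target`) whenever they exceed `passage_cap`. A
#' whole-replicate extinction is reported, not an error.
#'
#' @param expanded An `expanded_pool`.
#' @param config A [sim_config()].
#' @param store_trajectories Keep per-clone daily count matrices
#'   (clones x days per replicate; default FALSE, only the per-day audit
#'   totals are kept).
#' @return A `treatment_result`: `final` counts matrix (clones x samples,
#'   control first), `origin` data.frame (clone_id, preexisting, fitness),
#'   `acquisitions` (replicate, clone_id, day, fitness), per-day `audit`,
#'   `extinct_replicates`, and optionally `trajectories`.
#' @export
treat <- function(expanded, config = expanded$config,
                  store_trajectories = FALSE) {
  stopifnot(inherits(expanded, "expanded_pool"))
  nc <- length(expanded$cells)
  R <- config$n_replicates
  samples <- c("control", paste0("R", seq_len(R)))
  # multinomial split, cell by cell i.i.d. across pools
  split <- vapply(expanded$cells, function(x) {
    if (x == 0L) integer(R + 1L) else
      as.integer(stats::rmultinom(1L, x, rep(1, R + 1L)))
  }, integer(R + 1L))  # (R+1) x clones

  preexisting <- stats::runif(nc) < config$rho_pre
  fitness_pre <- rep(NA_real_, nc)
  fitness_pre[preexisting] <- rtrunc_fitness(sum(preexisting),
                                             config$resistant_fitness_mean,
                                             config$resistant_fitness_sd)

  final <- matrix(0, nrow = nc, ncol = R + 1L,
                  dimnames = list(expanded$clone_id, samples))
  audit <- list()
  acq_list <- list()
  trajectories <- if (store_trajectories) list() else NULL

  # control arm: neutral growth with passaging
  n <- as.numeric(split[1L, ])
  for (day in seq_len(config$days)) {
    births <- stats::rpois(nc, n * (config$normal_growth - 1))
    n <- n + births
    removed <- 0
    if (sum(n) > config$passage_cap) {
      keep <- config$passage_target / sum(n)
      thinned <- stats::rbinom(nc, pmin(n, .Machine$integer.max), keep)
      removed <- sum(n) - sum(thinned)
      n <- as.numeric(thinned)
    }
    audit[[length(audit) + 1L]] <-
      data.frame(sample = "control", day = day, births = sum(births),
                 deaths = 0, passage_removed = removed, total = sum(n))
  }
  final[, "control"] <- n

  for (rep_i in seq_len(R)) {
    n0 <- as.numeric(split[rep_i + 1L, ])
    r <- ifelse(preexisting, n0, 0)
    sens0 <- n0 - r
    p <- stats::rbinom(nc, pmin(sens0, .Machine$integer.max),
                       config$persister_fraction)
    s <- sens0 - p
    fit <- fitness_pre
    traj <- if (store_trajectories)
      matrix(0, nrow = nc, ncol = config$days) else NULL
    for (day in seq_len(config$days)) {
      s_surv <- stats::rbinom(nc, pmin(s, .Machine$integer.max),
                              1 - config$kill_prob_sensitive)
      deaths <- sum(s) - sum(s_surv)
      s <- as.numeric(s_surv)
      div <- stats::rbinom(nc, pmin(p, .Machine$integer.max),
                           config$persister_division_rate)
      acq <- stats::rbinom(nc, div, config$mu_acq)
      p <- p + div - acq
      new_acq <- which(acq > 0L & is.na(fit))
      if (length(new_acq)) {
        fit[new_acq] <- rtrunc_fitness(length(new_acq),
                                       config$resistant_fitness_mean,
                                       config$resistant_fitness_sd)
        acq_list[[length(acq_list) + 1L]] <-
          data.frame(replicate = samples[rep_i + 1L],
                     clone_id = expanded$clone_id[new_acq], day = day,
                     fitness = fit[new_acq])
      }
      r <- r + acq
      grow <- !is.na(fit) & r > 0
      births_r <- numeric(nc)
      if (any(grow)) {
        births_r[grow] <- stats::rpois(sum(grow), r[grow] * (fit[grow] - 1))
        r <- r + births_r
      }
      removed <- 0
      tot <- sum(s) + sum(p) + sum(r)
      if (tot > config$passage_cap) {
        keep <- config$passage_target / tot
        s_new <- stats::rbinom(nc, pmin(s, .Machine$integer.max), keep)
        p_new <- stats::rbinom(nc, pmin(p, .Machine$integer.max), keep)
        r_new <- stats::rbinom(nc, pmin(r, .Machine$integer.max), keep)
        removed <- tot - sum(s_new) - sum(p_new) - sum(r_new)
        s <- as.numeric(s_new); p <- as.numeric(p_new); r <- as.numeric(r_new)
      }
      if (store_trajectories) traj[, day] <- s + p + r
      audit[[length(audit) + 1L]] <-
        data.frame(sample = samples[rep_i + 1L], day = day,
                   births = sum(div) + sum(births_r), deaths = deaths,
                   passage_removed = removed, total = sum(s) + sum(p) + sum(r))
    }
    final[, rep_i + 1L] <- s + p + r
    if (store_trajectories) trajectories[[samples[rep_i + 1L]]] <- traj
  }

  acquisitions <- if (length(acq_list)) do.call(rbind, acq_list) else
    data.frame(replicate = character(0), clone_id = integer(0),
               day = integer(0), fitness = numeric(0))
  audit <- do.call(rbind, audit)
  extinct <- samples[colSums(final) == 0]
  structure(
    list(final = final,
         origin = data.frame(clone_id = expanded$clone_id,
                             preexisting = preexisting,
                             fitness = fitness_pre),
         acquisitions = acquisitions, audit = audit,
         extinct_replicates = extinct,
         trajectories = trajectories,
         expanded = expanded, config = config, samples = samples),
    class = "treatment_result")
}

#' Sequence the final pools
#'
#' Amplicon sequencing model: per sample, `depth` reads are a multinomial
#' draw over barcode templates weighted by final cell counts (a clone
#' carrying several barcodes contributes its cells to each of them). In
#' counts mode the draw is returned directly as a `barcode_count_table`. In
#' FASTQ mode each read embeds its barcode in the full cassette motif with a
#' random 0-8 nt stagger prefix, is padded with random bases to
#' `read_length`, and receives per-base substitution errors at `seq_error`.
#'
#' @param treatment A `treatment_result`.
#' @param config A [sim_config()].
#' @param as_fastq Generate read sequences instead of exact counts.
#' @param spec A [cassette_spec()] for FASTQ mode.
#' @return A `sim_output`: in counts mode a `barcode_count_table` under
#'   `$count_table`; in FASTQ mode a named list of read vectors under
#'   `$reads` (plus the reference keys); always the ground truth.
#' @export
sequence_pools <- function(treatment, config = treatment$config,
                           as_fastq = FALSE, spec = cassette_spec()) {
  stopifnot(inherits(treatment, "treatment_result"))
  if (config$depth < 1) stop("depth must be >= 1")
  integ <- treatment$expanded$pool$integrations
  keys <- sort(unique(integ$barcode_key))
  samples <- treatment$samples
  counts <- matrix(0L, nrow = length(keys), ncol = length(samples),
                   dimnames = list(keys, samples))
  for (s in samples) {
    cells <- treatment$final[, s]
    w <- tapply(cells[integ$clone_id], integ$barcode_key, sum)
    w <- w[keys]; w[is.na(w)] <- 0
    if (sum(w) == 0) {
      if (s %in% treatment$extinct_replicates) next
      stop("empty pool in sample ", s)
    }
    counts[, s] <- as.integer(stats::rmultinom(1L, config$depth, w))
  }
  truth <- sim_truth(treatment)
  if (!as_fastq) {
    tab <- structure(list(counts = counts, totals = colSums(counts),
                          unassigned = matrix(
                            0L, 2L, length(samples),
                            dimnames = list(c("no_motif", "no_reference_match"),
                                            samples)),
                          n_reads = colSums(counts)),
                     class = "barcode_count_table")
    return(structure(list(count_table = tab, reference = keys, truth = truth,
                          treatment = treatment),
                     class = "sim_output"))
  }
  reads <- lapply(samples, function(s) {
    cnt <- counts[, s]
    idx <- rep.int(seq_along(keys), cnt)
    if (length(idx) == 0) return(character(0))
    cassette <- paste0(spec$five_flank, substr(keys[idx], 1, 20), spec$linker,
                       substr(keys[idx], 21, 40), spec$three_flank)
    stagger <- sample(0:8, length(idx), replace = TRUE)
    pre <- vapply(stagger, function(k) if (k == 0) "" else
      paste0(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
      character(1))
    r <- paste0(pre, cassette)
    pad <- config$read_length - nchar(r)
    need <- pad > 0
    if (any(need)) {
      sfx <- vapply(pad[need], function(k)
        paste0(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
        character(1))
      r[need] <- paste0(r[need], sfx)
    }
    r <- substr(r, 1L, config$read_length)
    mutate_reads(r, config$seq_error)[sample.int(length(r))]
  })
  names(reads) <- samples
  structure(list(reads = reads, reference = keys, truth = truth,
                 counts_drawn = counts, treatment = treatment),
            class = "sim_output")
}

#' @keywords internal
mutate_reads <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  L <- nchar(reads)
  n_err <- stats::rbinom(length(reads), L, rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0L)) {
    pos <- sample.int(L[i], n_err[i])
    ch <- strsplit(reads[i], "")[[1L]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    reads[i] <- paste0(ch, collapse = "")
  }
  reads
}

#' @keywords internal
#' Barcode-level ground truth from a treatment result.
sim_truth <- function(treatment) {
  integ <- treatment$expanded$pool$integrations
  origin <- treatment$origin
  reps <- setdiff(treatment$samples, "control")
  pre_clones <- origin$clone_id[origin$preexisting]
  pre_keys <- unique(integ$barcode_key[integ$clone_id %in% pre_clones])
  resistant_by_rep <- lapply(reps, function(s) {
    acq <- treatment$acquisitions
    acq_clones <- acq$clone_id[acq$replicate == s]
    unique(integ$barcode_key[integ$clone_id %in% c(pre_clones, acq_clones)])
  })
  names(resistant_by_rep) <- reps
  list(preexisting_keys = pre_keys, resistant_by_replicate = resistant_by_rep)
}

#' Write simulated reads as FASTQ files
#'
#' @param sim_out A FASTQ-mode `sim_output`.
#' @param dir Output directory; one `<sample>.fastq.gz` per sample.
#' @return Invisibly, the written paths.
#' @export
write_sim_fastq <- function(sim_out, dir) {
  stopifnot(inherits(sim_out, "sim_output"), !is.null(sim_out$reads))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(sim_out$reads), function(s) {
    r <- sim_out$reads[[s]]
    x <- Biostrings::DNAStringSet(r)
    names(x) <- sprintf("%s_read%06d", s, seq_along(r))
    path <- file.path(dir, paste0(s, ".fastq.gz"))
    q <- Biostrings::BStringSet(strrep("I", nchar(r)))
    Biostrings::writeXStringSet(x, path, format = "fastq", compress = TRUE,
                                qualities = q)
    path
  }, character(1))
  invisible(paths)
}

#' Run the full simulation
#'
#' Convenience wrapper: [barcode_founders()] -> [expand_pool()] -> [treat()]
#' -> [sequence_pools()], under one seed for exact reproducibility
#' (identical config + seed give identical output).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for all stochastic steps.
#' @param as_fastq Sequence in FASTQ mode (default counts mode).
#' @param store_trajectories Passed to [treat()].
#' @return A `sim_output` (see [sequence_pools()]) with the `treatment`
#'   result attached.
#' @export
simulate_capture <- function(config = sim_config(), seed = NULL,
                             as_fastq = FALSE, store_trajectories = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  founders <- barcode_founders(config)
  expanded <- expand_pool(founders, config)
  trt <- treat(expanded, config, store_trajectories = store_trajectories)
  sequence_pools(trt, config, as_fastq = as_fastq)
}

#' Evaluate enrichment calls against the simulation ground truth
#'
#' Precision and recall of enriched-barcode calls over barcodes whose final
#' share in the treated sample exceeds `share_floor`, plus the confusion
#' matrix of true clone origin (preexisting vs acquired) against the
#' cross-replicate enrichment pattern (enriched in all replicates, in
#' exactly one, or in between).
#'
#' @param sim_out A `sim_output`.
#' @param enrichment An `enrichment_summary` from [call_enriched()] on the
#'   simulated count table.
#' @param table The `barcode_count_table` that was analysed.
#' @param share_floor Minimum final share for a barcode to enter the
#'   precision/recall universe (default 0.01).
#' @return List with per-replicate and pooled `precision`/`recall` and the
#'   origin-by-pattern `confusion` matrix.
#' @export
evaluate_pipeline <- function(sim_out, enrichment, table,
                              share_floor = 0.01) {
  stopifnot(inherits(sim_out, "sim_output"),
            inherits(enrichment, "enrichment_summary"))
  fr <- barcode_fractions(table)
  reps <- enrichment$treated_samples
  truth <- sim_out$truth$resistant_by_replicate
  tp <- fp <- fn <- 0L
  per_rep <- lapply(reps, function(s) {
    in_universe <- rownames(fr)[fr[, s] > share_floor]
    called <- intersect(enrichment$enriched_sets[[s]], in_universe)
    true_res <- intersect(truth[[s]], in_universe)
    tp_i <- length(intersect(called, true_res))
    fp_i <- length(setdiff(called, true_res))
    fn_i <- length(setdiff(true_res, called))
    tp <<- tp + tp_i; fp <<- fp + fp_i; fn <<- fn + fn_i
    c(precision = if (tp_i + fp_i == 0) NA_real_ else tp_i / (tp_i + fp_i),
      recall = if (tp_i + fn_i == 0) NA_real_ else tp_i / (tp_i + fn_i))
  })
  names(per_rep) <- reps

  n_reps_enriched <- rowSums(enrichment$enriched)
  union_keys <- rownames(enrichment$enriched)[n_reps_enriched > 0]
  pattern <- ifelse(n_reps_enriched[union_keys] == length(reps), "all_replicates",
                    ifelse(n_reps_enriched[union_keys] == 1L,
                           "single_replicate", "intermediate"))
  pre <- sim_out$truth$preexisting_keys
  any_resistant <- unique(unlist(truth))
  origin <- ifelse(union_keys %in% pre, "preexisting",
                   ifelse(union_keys %in% any_resistant, "acquired",
                          "not_resistant"))
  confusion <- table(factor(origin, levels = c("preexisting", "acquired",
                                               "not_resistant")),
                     factor(pattern, levels = c("all_replicates",
                                                "intermediate",
                                                "single_replicate")))
  list(per_replicate = per_rep,
       precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       confusion = confusion)
}
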