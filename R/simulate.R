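#' Configuration for the neutral clonal-expansion simulator
#'
#' Defaults reproduce the calibration setup: a uniform-random 348-nt
#' founder, constant binary division, two equal-half regions mutating at
#' Poisson rates of 0.5 and 1.0 expected mutations per sequence per
#' generation, 10 generations (1024 cells, ~15 mutations per sequence —
#' inside the 10-20 mutations / >=300 sequences regime where the test is
#' calibrated), a sample of 300 final-generation cells, and a sampling bias
#' in which the descendants of one randomly chosen third-generation cell
#' (one of the first eight siblings) are sampled with twice the
#' probability of everyone else.
#'
#' @param founder_length founder sequence length in nt (multiple of 3).
#' @param offspring_per_cell mean offspring per cell per generation; the
#'   neutral integer default 2 gives exactly `offspring^generations` cells.
#' @param region_boundaries 0-based cut points splitting the sequence into
#'   regions; default one cut at the midpoint.
#' @param region_rates expected mutations per sequence per generation in
#'   each region (length = number of regions).
#' @param generations number of division generations.
#' @param sample_size cells sampled from the final generation.
#' @param bias_generation generation whose cells define the over-sampled
#'   sub-lineage (default 3: one of the first eight siblings).
#' @param bias_factor sampling-weight multiplier for descendants of the
#'   chosen cell.
#' @param selection optional `list(region =, delta_mu =)`: cells that have
#'   acquired at least one NS mutation in that region (classified against
#'   their direct parent, inherited by descendants) draw their offspring
#'   number with mean `offspring_per_cell + delta_mu`.
#' @param per_site if `TRUE`, draw per-site Bernoulli mutations with
#'   probability rate/region-length instead of Poisson counts per region.
#' @param seed default RNG seed used by the simulation entry points.
#' @param max_population guard against accidentally huge runs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(founder_length = 348L, offspring_per_cell = 2,
                       region_boundaries = NULL,
                       region_rates = c(0.5, 1.0), generations = 10L,
                       sample_size = 300L, bias_generation = 3L,
                       bias_factor = 2, selection = NULL, per_site = FALSE,
                       seed = NULL, max_population = 2^15) {
  if (is.null(region_boundaries)) {
    region_boundaries <- founder_length %/% 2L
  }
  bounds <- c(0L, as.integer(region_boundaries), as.integer(founder_length))
  if (is.unsorted(bounds, strictly = TRUE)) {
    stop("region boundaries must be strictly increasing within the sequence")
  }
  if (length(region_rates) != length(bounds) - 1L) {
    stop("need one mutation rate per region")
  }
  if (any(region_rates < 0)) stop("mutation rates must be >= 0")
  if (bias_factor <= 0) stop("bias_factor must be > 0")
  if (!is.null(selection)) {
    stopifnot(is.list(selection), !is.null(selection$region),
              !is.null(selection$delta_mu))
    if (selection$delta_mu <= -offspring_per_cell) {
      stop("delta_mu must exceed -offspring_per_cell")
    }
  }
  cfg <- list(founder_length = as.integer(founder_length),
              offspring_per_cell = offspring_per_cell,
              region_bounds = bounds,
              region_labels = paste0("R", seq_len(length(bounds) - 1L)),
              region_rates = region_rates,
              generations = as.integer(generations),
              sample_size = as.integer(sample_size),
              bias_generation = as.integer(bias_generation),
              bias_factor = bias_factor,
              selection = selection, per_site = isTRUE(per_site),
              seed = seed, max_population = max_population)
  class(cfg) <- "sim_config"
  cfg
}

#' Region map implied by a simulation configuration
#'
#' @param config a `sim_config`.
#' @return region-map data frame usable by [enumerate_mutation_events()].
#' @export
sim_region_map <- function(config) {
  b <- config$region_bounds
  region_map(config$region_labels, b[-length(b)], b[-1])
}

# classify new mutations against the parent codon (direct-ancestor rule)
.mutation_is_ns <- function(parent_row, pos, new_base) {
  cs <- ((pos - 1L) %/% 3L) * 3L + 1L
  from <- paste0(DNA_BASES[parent_row[cs]], DNA_BASES[parent_row[cs + 1L]],
                 DNA_BASES[parent_row[cs + 2L]])
  to <- from
  substr(to, pos - cs + 1L, pos - cs + 1L) <- DNA_BASES[new_base]
  ifelse(from == to, FALSE, classify_mutation(from, to) == "NS")
}

#' Simulate a neutrally expanding mutating clone
#'
#' Forward-time binary expansion from a uniform-random founder. Every
#' generation each cell produces `offspring_per_cell` children; each child
#' draws a Poisson number of mutations per region (positions uniform
#' within the region, substitutions uniform over the three alternative
#' bases — no transition/transversion bias), applied on top of its
#' parent's sequence. Back/recurrent mutations are allowed and stop codons
#' are retained: the neutral model has no phenotype.
#'
#' @param config a `sim_config`.
#' @param seed RNG seed (defaults to `config$seed`); identical config and
#'   seed give byte-identical output.
#' @return a `simulated_lineage`: list with `config`, `founder`,
#'   `generations` (per generation: `seq` integer matrix, `parent`
#'   indices, `selected` flags, `anc` bias-generation ancestor ids) and
#'   `mutation_log` (generation, cell, pos, from, to; 1-based positions).
#' @export
simulate_pool <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  L <- config$founder_length
  G <- config$generations
  nb <- length(config$region_rates)
  bounds <- config$region_bounds
  sel_cfg <- config$selection
  sel_region_idx <- if (!is.null(sel_cfg)) {
    match(sel_cfg$region, config$region_labels)
  } else NA_integer_
  if (!is.null(sel_cfg) && is.na(sel_region_idx)) {
    stop("unknown selected region: ", sel_cfg$region)
  }

  founder <- sample.int(4L, L, replace = TRUE)
  gens <- vector("list", G + 1L)
  gens[[1]] <- list(seq = matrix(founder, 1L), parent = NA_integer_,
                    selected = FALSE, anc = NA_integer_)
  log_rows <- vector("list", G)

  for (g in seq_len(G)) {
    par <- gens[[g]]
    npar <- nrow(par$seq)
    mu <- config$offspring_per_cell
    if (!is.null(sel_cfg) && sel_cfg$delta_mu != 0) {
      m <- ifelse(par$selected, mu + sel_cfg$delta_mu, mu)
      counts <- floor(m) + stats::rbinom(npar, 1L, m - floor(m))
    } else if (mu == round(mu)) {
      counts <- rep.int(as.integer(mu), npar)
    } else {
      counts <- floor(mu) + stats::rbinom(npar, 1L, mu - floor(mu))
    }
    nchild <- sum(counts)
    if (nchild > config$max_population) {
      stop("population exceeds max_population guard (",
           config$max_population, ")")
    }
    if (nchild == 0L) stop("population went extinct at generation ", g)
    parent_idx <- rep.int(seq_len(npar), counts)
    S <- par$seq[parent_idx, , drop = FALSE]
    selected <- if (length(par$selected) == npar) par$selected[parent_idx]
                else rep(FALSE, nchild)
    anc <- if (g == config$bias_generation) seq_len(nchild)
           else if (g > config$bias_generation) par$anc[parent_idx]
           else rep(NA_integer_, nchild)

    rows <- integer(0); poss <- integer(0)
    for (r in seq_len(nb)) {
      lo <- bounds[r] + 1L; hi <- bounds[r + 1L]
      if (config$per_site) {
        rl <- hi - lo + 1L
        pr <- min(config$region_rates[r] / rl, 1)
        hits <- which(matrix(stats::runif(nchild * rl) < pr, nchild, rl),
                      arr.ind = TRUE)
        rows <- c(rows, hits[, 1]); poss <- c(poss, lo - 1L + hits[, 2])
      } else {
        k <- stats::rpois(nchild, config$region_rates[r])
        tot <- sum(k)
        if (tot) {
          rows <- c(rows, rep.int(seq_len(nchild), k))
          poss <- c(poss, sample.int(hi - lo + 1L, tot, replace = TRUE) +
                      lo - 1L)
        }
      }
    }

    if (length(rows)) {
      parent_base <- S[cbind(rows, poss)]
      if (anyDuplicated(cbind(rows, poss))) {
        from <- integer(length(rows)); to <- integer(length(rows))
        shift <- sample.int(3L, length(rows), replace = TRUE)
        for (t in seq_along(rows)) {
          from[t] <- S[rows[t], poss[t]]
          to[t] <- (from[t] - 1L + shift[t]) %% 4L + 1L
          S[rows[t], poss[t]] <- to[t]
        }
      } else {
        from <- parent_base
        shift <- sample.int(3L, length(rows), replace = TRUE)
        to <- (from - 1L + shift) %% 4L + 1L
        S[cbind(rows, poss)] <- to
      }
      log_rows[[g]] <- data.frame(generation = g, cell = rows, pos = poss,
                                  from = from, to = to)
      if (!is.null(sel_cfg)) {
        in_sel <- poss > bounds[sel_region_idx] &
          poss <= bounds[sel_region_idx + 1L]
        if (any(in_sel)) {
          idx <- which(in_sel)
          is_ns <- vapply(idx, function(t) {
            isTRUE(.mutation_is_ns(par$seq[parent_idx[rows[t]], ],
                                   poss[t], to[t]))
          }, logical(1))
          hit_cells <- unique(rows[idx[is_ns]])
          selected[hit_cells] <- TRUE
        }
      }
    }
    gens[[g + 1L]] <- list(seq = S, parent = parent_idx,
                           selected = selected, anc = anc)
  }

  out <- list(config = config, founder = int_to_seq(matrix(founder, 1L)),
              generations = gens,
              mutation_log = do.call(rbind, log_rows[!vapply(log_rows,
                                                             is.null,
                                                             logical(1))]))
  class(out) <- "simulated_lineage"
  out
}

#' Simulate a clone in which NS mutations in one region are advantageous
#'
#' Identical to [simulate_pool()] except that cells carrying at least one
#' non-synonymous mutation in the selected region (relative to their
#' direct parent at the moment of mutation; the flag is inherited) draw
#' their offspring number with mean `offspring_per_cell + delta_mu` using
#' nearest-integer stochastic rounding. With `delta_mu = 0` the RNG path
#' is identical to the neutral simulator.
#'
#' @param config a `sim_config` whose `selection` field is set.
#' @param seed RNG seed.
#' @return a `simulated_lineage`.
#' @export
simulate_with_selection <- function(config, seed = config$seed) {
  if (is.null(config$selection)) stop("config$selection must be set")
  simulate_pool(config, seed)
}

#' Sample final-generation cells with a lineage bias
#'
#' One cell of the bias generation (default: one of the eight
#' third-generation cells) is chosen uniformly; final-generation cells
#' descending from it get sampling weight `bias_factor`, all others weight
#' 1, and `sample_size` cells are drawn without replacement with those
#' weights. This emulates preferential sampling of one sub-lineage.
#'
#' @param lineage a `simulated_lineage`.
#' @param config a `sim_config` (defaults to the one inside `lineage`).
#' @param seed optional RNG seed (by default continues the current stream).
#' @return named character vector of sampled sequences (`cell<index>`).
#' @export
sample_biased <- function(lineage, config = lineage$config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  final <- lineage$generations[[length(lineage$generations)]]
  n <- nrow(final$seq)
  if (config$sample_size > n) {
    stop("sample_size (", config$sample_size,
         ") exceeds final population (", n, ")")
  }
  anc <- final$anc
  n_anc <- max(anc, na.rm = TRUE)
  chosen <- sample.int(n_anc, 1L)
  w <- ifelse(!is.na(anc) & anc == chosen, config$bias_factor, 1)
  idx <- sample.int(n, config$sample_size, prob = w)
  seqs <- int_to_seq(final$seq[idx, , drop = FALSE])
  names(seqs) <- sprintf("cell%05d", idx)
  attr(seqs, "biased_ancestor") <- chosen
  attr(seqs, "cell_index") <- idx
  seqs
}

#' Run the full LONR analysis on one simulated clone
#'
#' Simulates a pool, samples it with bias, collapses duplicate reads,
#' builds the neighbor-joining tree over the unique sequences plus the
#' founder, roots at the founder, reconstructs ancestors by Fitch
#' parsimony, enumerates mutation events, and reports the per-region
#' NS-vs-S Welch test.
#'
#' @param config a `sim_config`.
#' @param seed RNG seed for this replicate.
#' @return list with `events`, `report` (per-region `region_report`), and
#'   `tree`.
#' @export
simulate_replicate <- function(config, seed = config$seed) {
  lineage <- simulate_pool(config, seed)
  seqs <- sample_biased(lineage, config)
  lonr_from_sequences(seqs, germline = unname(lineage$founder),
                      region_map = sim_region_map(config),
                      clone_id = paste0("sim", seed %||% 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' LONR events and report from sequences plus a known germline
#'
#' The shared analysis core: collapse duplicates, NJ tree over unique
#' sequences + germline, root at the germline, Fitch reconstruction, event
#' enumeration, region report.
#'
#' @param seqs named character vector of sampled sequences.
#' @param germline germline/founder sequence (same length).
#' @param region_map optional region map.
#' @param clone_id clone label for the event table.
#' @param collapse collapse identical reads into weighted leaves
#'   (leaf counts still count reads).
#' @return list with `events`, `report`, `tree`.
#' @export
lonr_from_sequences <- function(seqs, germline, region_map = NULL,
                                clone_id = "clone", collapse = TRUE) {
  germline_id <- "germline_ref"
  while (germline_id %in% names(seqs)) {
    germline_id <- paste0(germline_id, "_")
  }
  if (collapse) {
    cd <- collapse_duplicates(seqs)
    useqs <- cd$sequences; mult <- cd$multiplicity; members <- cd$members
  } else {
    useqs <- seqs
    mult <- stats::setNames(rep(1L, length(seqs)), names(seqs))
    members <- NULL
  }
  all_seqs <- c(useqs, stats::setNames(germline, germline_id))
  if (length(useqs) < 2L) {
    ev <- empty_events()
    return(list(events = ev, report = region_report(ev), tree = NULL))
  }
  d <- hamming_matrix(all_seqs)
  phy <- neighbor_joining(d)
  tree <- root_at_germline(phy, germline_id, all_seqs,
                           multiplicity = mult, members = members)
  tree <- fitch_reconstruct(tree)
  events <- enumerate_mutation_events(tree, region_map, clone_id)
  list(events = events, report = region_report(events), tree = tree)
}

#' Empirical false-positive rate of the region-level selection test
#'
#' Runs `n_replicates` independent neutral simulations through the full
#' pipeline and reports the fraction in which the designated region's
#' NS-vs-S Welch test is significant at `alpha`. Under neutrality this
#' should match `alpha` in the calibrated regime (>= 300 sampled
#' sequences, 10-20 mutations per sequence).
#'
#' @param config a neutral `sim_config` (`selection` must be `NULL`).
#' @param n_replicates number of independent replicates.
#' @param alpha significance threshold.
#' @param region region label to monitor (default: the last, higher-rate
#'   region, which carries the most mutation events per tree).
#' @param seed master seed; per-replicate seeds are drawn from it.
#' @return list with `rate`, 95% binomial `ci` (exact), `n_significant`,
#'   `n_tested`, and `per_replicate` (region p-values and NS-S mean
#'   differences per replicate).
#' @export
false_positive_rate <- function(config, n_replicates = 300L, alpha = 0.05,
                                region = NULL, seed = 1L) {
  if (!is.null(config$selection) && config$selection$delta_mu != 0) {
    stop("false_positive_rate requires a neutral configuration")
  }
  if (is.null(region)) region <- config$region_labels[length(config$region_labels)]
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  pvals <- rep(NA_real_, n_replicates)
  diffs <- rep(NA_real_, n_replicates)
  for (i in seq_len(n_replicates)) {
    res <- simulate_replicate(config, rep_seeds[i])
    row <- res$report[res$report$region == region &
                        res$report$subset == "all", , drop = FALSE]
    if (nrow(row) == 1L) {
      pvals[i] <- row$p_value
      diffs[i] <- row$mean_difference
    }
  }
  tested <- !is.na(pvals)
  nsig <- sum(pvals[tested] < alpha)
  bt <- stats::binom.test(nsig, sum(tested))
  list(rate = nsig / sum(tested), ci = unname(bt$conf.int),
       n_significant = nsig, n_tested = sum(tested),
       per_replicate = data.frame(seed = rep_seeds, p_value = pvals,
                                  mean_difference = diffs))
}
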