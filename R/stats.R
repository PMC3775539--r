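#' Welch two-sample t-test with explicit degenerate-case flags
#'
#' Unpaired, unequal-variance t-test between two samples (the comparison
#' used between NS and S LONR values). Rather than erroring, degenerate
#' inputs return `NA` statistics with a flag: `"too_few"` when either group
#' has fewer than two values, `"zero_variance"` when both groups are
#' constant, `"ok"` otherwise.
#'
#' @param a,b numeric vectors.
#' @return list with `t`, `df` (Welch-Satterthwaite), `p` (two-sided),
#'   `mean_a`, `mean_b`, and `flag`.
#' @export
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  ma <- if (length(a)) mean(a) else NA_real_
  mb <- if (length(b)) mean(b) else NA_real_
  if (length(a) < 2L || length(b) < 2L) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean_a = ma, mean_b = mb, flag = "too_few"))
  }
  if (stats::var(a) + stats::var(b) == 0) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean_a = ma, mean_b = mb, flag = "zero_variance"))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = ma, mean_b = mb, flag = "ok")
}

#' Region-level NS-vs-S LONR selection report
#'
#' Pools mutation events by region and compares the LONR values of
#' non-synonymous and synonymous events with a Welch t-test. A positive
#' `mean_difference` (mean NS LONR minus mean S LONR) indicates that
#' lineages acquiring amino-acid changes in that region left more sampled
#' descendants than their unmutated siblings, i.e. positive selection.
#'
#' Two aggregation variants are reported side by side, because published
#' region summaries do not fully disambiguate them: `mean_difference` pools
#' every event in the scope, while `per_clone_mean_difference` first takes
#' the NS-S difference within each clone and then averages over clones.
#' A second set of rows (`subset == "significant"`) restricts the pool to
#' clones whose own per-region test has `p < sig_p`.
#'
#' @param events event data frame from [enumerate_mutation_events()]
#'   (possibly row-bound over many clones).
#' @param sig_p per-clone significance threshold for the restricted rows.
#' @param adjust also append Benjamini-Hochberg adjusted p-values across
#'   regions within each subset (a convenience column, not part of the
#'   original method, which reports raw p-values).
#' @return data frame, one row per region x subset, with event counts,
#'   group means, mean difference, Welch `t_statistic`/`df`/`p_value`, a
#'   degenerate-case `flag`, and `p_adjusted` when `adjust = TRUE`.
#' @export
region_report <- function(events, sig_p = 0.01, adjust = TRUE) {
  if (nrow(events) == 0L) {
    return(data.frame(region = character(), subset = character(),
                      n_clones = integer(), n_ns = integer(), n_s = integer(),
                      mean_lonr_ns = numeric(), mean_lonr_s = numeric(),
                      mean_difference = numeric(),
                      per_clone_mean_difference = numeric(),
                      t_statistic = numeric(), df = numeric(),
                      p_value = numeric(), flag = character(),
                      stringsAsFactors = FALSE))
  }
  events <- events[!is.na(events$mutation_class), , drop = FALSE]

  one_scope <- function(ev, region, subset) {
    ns <- ev$lonr[ev$mutation_class == "NS"]
    s <- ev$lonr[ev$mutation_class == "S"]
    tt <- welch_t_test(ns, s)
    pc <- vapply(split(ev, ev$clone_id), function(e) {
      d <- mean(e$lonr[e$mutation_class == "NS"]) -
        mean(e$lonr[e$mutation_class == "S"])
      d
    }, numeric(1))
    pc <- pc[is.finite(pc)]
    data.frame(region = region, subset = subset,
               n_clones = length(unique(ev$clone_id)),
               n_ns = length(ns), n_s = length(s),
               mean_lonr_ns = tt$mean_a, mean_lonr_s = tt$mean_b,
               mean_difference = tt$mean_a - tt$mean_b,
               per_clone_mean_difference =
                 if (length(pc)) mean(pc) else NA_real_,
               t_statistic = tt$t, df = tt$df, p_value = tt$p,
               flag = tt$flag, stringsAsFactors = FALSE)
  }

  out <- list()
  for (reg in unique(events$region)) {
    ev <- events[events$region == reg, , drop = FALSE]
    if (nrow(ev) == 0L) next
    out[[length(out) + 1L]] <- one_scope(ev, reg, "all")
    # clones individually significant in this region
    keep <- vapply(split(ev, ev$clone_id), function(e) {
      tt <- welch_t_test(e$lonr[e$mutation_class == "NS"],
                         e$lonr[e$mutation_class == "S"])
      !is.na(tt$p) && tt$p < sig_p
    }, logical(1))
    sig_clones <- names(keep)[keep]
    if (length(sig_clones)) {
      evs <- ev[ev$clone_id %in% sig_clones, , drop = FALSE]
      out[[length(out) + 1L]] <- one_scope(evs, reg, "significant")
    }
  }
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  if (adjust) {
    rep$p_adjusted <- NA_real_
    for (sb in unique(rep$subset)) {
      idx <- rep$subset == sb
      rep$p_adjusted[idx] <- stats::p.adjust(rep$p_value[idx], method = "BH")
    }
  }
  rep
}

#' Per-codon LONR profile
#'
#' Averages LONR over the three nucleotide positions of each codon, for all
#' events combined and for NS and S events separately. Codons with no
#' events get `NA`, never zero. Note this weights each mutation event
#' equally, so heavily mutated positions contribute more than rarely
#' mutated ones.
#'
#' @param events event data frame.
#' @param seq_length frame length in nucleotides.
#' @return data frame with one row per codon: `codon` (0-based), event
#'   counts and mean LONR overall / NS / S.
#' @export
position_profile <- function(events, seq_length) {
  n_codon <- ceiling(seq_length / 3)
  codon <- events$position %/% 3L
  prof <- data.frame(codon = seq_len(n_codon) - 1L)
  agg <- function(sel) {
    cnt <- tabulate(codon[sel] + 1L, nbins = n_codon)
    sums <- rep(0, n_codon)
    if (any(sel)) {
      ag <- tapply(events$lonr[sel], codon[sel], sum)
      sums[as.integer(names(ag)) + 1L] <- ag
    }
    list(n = cnt, mean = ifelse(cnt > 0, sums / cnt, NA_real_))
  }
  all <- agg(rep(TRUE, nrow(events)))
  ns <- agg(!is.na(events$mutation_class) & events$mutation_class == "NS")
  s <- agg(!is.na(events$mutation_class) & events$mutation_class == "S")
  prof$n_events <- all$n
  prof$mean_lonr <- all$mean
  prof$n_ns <- ns$n
  prof$mean_lonr_ns <- ns$mean
  prof$n_s <- s$n
  prof$mean_lonr_s <- s$mean
  prof
}

#' NS fraction of leaf mutations relative to the clone ancestor
#'
#' Counts, for every leaf, its NS and S mutations relative to the ancestral
#' sequence (each mismatching position classified by substituting that
#' position alone into the ancestral codon), averages the counts over
#' leaves, and returns mean-NS / (mean-NS + mean-S).
#'
#' @param leaves named character vector of leaf sequences.
#' @param ancestor ancestral sequence of the clone (same length).
#' @return list with `fraction` (`NA` when no mutations at all), `mean_ns`,
#'   `mean_s`, and `flag` (`"ok"` or `"no_mutations"`).
#' @export
ns_fraction <- function(leaves, ancestor) {
  if (length(leaves) < 1L) stop("need at least one leaf")
  if (any(nchar(leaves) != nchar(ancestor))) {
    stop("leaves and ancestor must have the same length")
  }
  A <- seq_to_int(stats::setNames(ancestor, "anc"))[1, ]
  M <- seq_to_int(leaves)
  L <- length(A)
  counts <- matrix(0, nrow(M), 2, dimnames = list(NULL, c("NS", "S")))
  for (i in seq_len(nrow(M))) {
    dd <- which(!is.na(A) & !is.na(M[i, ]) & M[i, ] != A)
    if (!length(dd)) next
    cs <- ((dd - 1L) %/% 3L) * 3L + 1L
    ok <- cs + 2L <= L & !is.na(A[cs]) & !is.na(A[cs + 1L]) & !is.na(A[cs + 2L])
    dd <- dd[ok]; cs <- cs[ok]
    if (!length(dd)) next
    from_codon <- paste0(DNA_BASES[A[cs]], DNA_BASES[A[cs + 1L]],
                         DNA_BASES[A[cs + 2L]])
    to_codon <- from_codon
    off <- dd - cs
    substr(to_codon, off + 1L, off + 1L) <- DNA_BASES[M[i, dd]]
    cls <- classify_mutation(from_codon, to_codon)
    counts[i, "NS"] <- sum(cls == "NS", na.rm = TRUE)
    counts[i, "S"] <- sum(cls == "S", na.rm = TRUE)
  }
  mns <- mean(counts[, "NS"])
  ms <- mean(counts[, "S"])
  if (mns + ms == 0) {
    list(fraction = NA_real_, mean_ns = mns, mean_s = ms,
         flag = "no_mutations")
  } else {
    list(fraction = mns / (mns + ms), mean_ns = mns, mean_s = ms,
         flag = "ok")
  }
}

#' Spearman rank correlation with a degenerate-input flag
#'
#' Rank correlation with average ranks for ties; used to check that the
#' NS/(S+NS) fraction is (or is not) associated with clone size.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with `rho` and `flag` (`"ok"` or `"constant_input"`).
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rho = NA_real_, flag = "constant_input"))
  }
  list(rho = stats::cor(x, y, method = "spearman"), flag = "ok")
}
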