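#' Write a data frame as TSV with stable formatting
#'
#' Header line, tab separation, no quoting, floats at 6 significant
#' digits — reruns with the same inputs produce byte-identical files.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  fmt <- df
  for (cn in names(fmt)) {
    if (is.double(fmt[[cn]])) fmt[[cn]] <- signif(fmt[[cn]], 6)
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Run the full repertoire analysis pipeline
#'
#' Reads a repertoire FASTA plus a germline V/J library, then runs:
#' germline assignment -> match-fraction filter -> grouping by
#' (V, J, V-J distance) and truncation -> per-group NJ tree + Fitch
#' reconstruction -> clone partition at the mutation cutoff -> per-clone
#' tree, mutation events and LONR values -> pooled region report. Clones
#' whose tree carries fewer than `min_mutations_per_tree` reconstructed
#' substitutions are skipped (too little signal for the NS-vs-S
#' comparison). Writes `assignments.tsv`, `events.tsv`, `report.tsv` and a
#' JSON `manifest.json` reconciling record counts at every stage.
#'
#' @param reads_fasta path to the repertoire FASTA (or a named character
#'   vector of reads).
#' @param v_fasta,j_fasta germline library FASTA paths (or a pre-built
#'   library list passed as `library`).
#' @param out_dir output directory (created if needed).
#' @param regions_json optional JSON region config for the V genes.
#' @param library optional pre-built germline library (overrides
#'   `v_fasta`/`j_fasta`).
#' @param min_match match-fraction threshold for keeping assignments.
#' @param clone_cutoff maximum within-clone edge mutation count.
#' @param min_mutations_per_tree minimum parsimony score for a clone tree
#'   to be analysed.
#' @param sig_p per-clone significance threshold for the report's
#'   restricted rows.
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `assignments`, `events`, `report`,
#'   `manifest`, and the output paths.
#' @export
run_pipeline <- function(reads_fasta, v_fasta = NULL, j_fasta = NULL,
                         out_dir = ".", regions_json = NULL, library = NULL,
                         min_match = 0.5, clone_cutoff = 4L,
                         min_mutations_per_tree = 10L, sig_p = 0.01,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  reads <- if (is.character(reads_fasta) && length(reads_fasta) == 1L &&
               file.exists(reads_fasta)) read_fasta(reads_fasta) else reads_fasta
  if (is.null(library)) {
    if (is.null(v_fasta) || is.null(j_fasta)) {
      stop("either a germline library or v_fasta/j_fasta must be given")
    }
    library <- read_germline_library(v_fasta, j_fasta, regions_json)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  say("assigning germlines to ", length(reads), " reads")
  asg <- assign_germline_all(reads, library)
  n_failed <- sum(is.na(asg$v_gene))
  kept <- filter_assignments(asg, min_match)
  say(nrow(kept), " of ", nrow(asg), " assignments pass match > ", min_match)

  groups <- group_and_truncate(kept, reads, library)
  n_dropped_trunc <- length(attr(groups, "dropped"))

  all_events <- list()
  n_clones <- 0L
  n_clones_analyzed <- 0L
  n_clones_skipped_small <- 0L
  n_clones_skipped_mut <- 0L
  for (grp in groups) {
    cd <- collapse_duplicates(grp$members)
    gl_id <- "germline_ref"
    seqs <- c(cd$sequences, stats::setNames(grp$germline, gl_id))
    clones <- if (length(cd$sequences) >= 2L) {
      d <- hamming_matrix(seqs)
      phy <- neighbor_joining(d)
      tr <- root_at_germline(phy, gl_id, seqs,
                             multiplicity = cd$multiplicity,
                             members = cd$members)
      tr <- fitch_reconstruct(tr)
      partition_into_clones(tr, clone_cutoff)
    } else list(unlist(cd$members, use.names = FALSE))
    n_clones <- n_clones + length(clones)
    for (ci in seq_along(clones)) {
      ids <- clones[[ci]]
      cl_seqs <- grp$members[ids]
      clone_id <- paste0(grp$v_gene, "|", grp$j_gene, "|", grp$vj_distance,
                         "|c", ci)
      if (length(unique(cl_seqs)) < 2L) {
        n_clones_skipped_small <- n_clones_skipped_small + 1L
        next
      }
      res <- lonr_from_sequences(cl_seqs, grp$germline,
                                 region_map = grp$region_map,
                                 clone_id = clone_id)
      if (is.null(res$tree) ||
          res$tree$parsimony_score < min_mutations_per_tree) {
        n_clones_skipped_mut <- n_clones_skipped_mut + 1L
        next
      }
      n_clones_analyzed <- n_clones_analyzed + 1L
      all_events[[length(all_events) + 1L]] <- res$events
    }
  }
  events <- if (length(all_events)) do.call(rbind, all_events)
            else empty_events()
  report <- region_report(events, sig_p = sig_p)
  say(nrow(events), " mutation events from ", n_clones_analyzed, " clones")

  manifest <- list(
    tool = "lonr", version = as.character(utils::packageVersion("lonr")),
    parameters = list(min_match = min_match, clone_cutoff = clone_cutoff,
                      min_mutations_per_tree = min_mutations_per_tree,
                      sig_p = sig_p),
    counts = list(reads_in = length(reads),
                  assignment_failed = n_failed,
                  assignments_filtered_out = nrow(asg) - n_failed - nrow(kept),
                  truncation_dropped = n_dropped_trunc,
                  reads_grouped = nrow(kept) - n_dropped_trunc,
                  groups = length(groups),
                  clones = n_clones,
                  clones_skipped_too_small = n_clones_skipped_small,
                  clones_skipped_too_few_mutations = n_clones_skipped_mut,
                  clones_analyzed = n_clones_analyzed,
                  mutation_events = nrow(events)))

  paths <- list(assignments = file.path(out_dir, "assignments.tsv"),
                events = file.path(out_dir, "events.tsv"),
                report = file.path(out_dir, "report.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_tsv_report(asg, paths$assignments)
  write_tsv_report(events, paths$events)
  write_tsv_report(report, paths$report)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(assignments = asg, events = events, report = report,
                 manifest = manifest, paths = paths))
}
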